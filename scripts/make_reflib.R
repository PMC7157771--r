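#!/usr/bin/env Rscript
# Regenerates the bundled SYNTHETIC exemplar library at
# inst/extdata/reflib_synthetic/ (deterministic; run from the repo root).
# The exemplars are pseudo-random proteins with field-realistic lengths and
# labels; they are functional stand-ins, not curated family sequences.

suppressMessages(pkgload::load_all(".", quiet = TRUE))

set.seed(20260925)

spec <- list(
  # id, role, family, superfamily, subgroup, length
  list("tnpA_Tn3",    "transposase", NA, NA, "Tn3",    985),
  list("tnpA_Tn21",   "transposase", NA, NA, "Tn21",   990),
  list("tnpA_Tn163",  "transposase", NA, NA, "Tn163",  975),
  list("tnpA_IS1071", "transposase", NA, NA, "IS1071", 995),
  list("tnpA_IS3000", "transposase", NA, NA, "IS3000", 980),
  list("tnpA_Tn4430", "transposase", NA, NA, "Tn4430", 988),
  list("tnpA_Tn4651", "transposase", NA, NA, "Tn4651", 992),
  list("tnpA_Tn3000", "transposase", NA, NA, "Tn3000", 986),
  list("tnpR_1", "resolvase_S", NA, NA, NA, 185),
  list("tnpR_2", "resolvase_S", NA, NA, NA, 190),
  list("tnpI_1", "resolvase_Y", NA, NA, NA, 305),
  list("tnpS_1", "resolvase_Y_het", NA, NA, NA, 300),
  list("tnpT_1", "helper", NA, NA, NA, 250),
  list("ParE_1",  "toxin", "ParE",  "RelE/ParE", NA,  95),
  list("ParE_2",  "toxin", "ParE",  "RelE/ParE", NA, 100),
  list("Gp49_1",  "toxin", "Gp49",  "RelE/ParE", NA,  92),
  list("PIN_3_1", "toxin", "PIN_3", "PIN",       NA, 130),
  list("PIN_1",   "toxin", "PIN",   "PIN",       NA, 135),
  list("HEPN_1",  "toxin", "HEPN",  "HEPN",      NA, 150),
  list("ParD_1",    "antitoxin", "ParD",     "RelB/ParD", NA,  90),
  list("ParD_2",    "antitoxin", "ParD",     "RelB/ParD", NA,  88),
  list("RHH_6_1",   "antitoxin", "RHH_6",    "VapB",      NA,  85),
  list("HTH_37_1",  "antitoxin", "HTH_37",   "HigA",      NA,  95),
  list("PhdYeFM_1", "antitoxin", "Phd/YeFM", "Phd/YeFM",  NA,  88),
  list("AbrB_1",    "antitoxin", "AbrB",     "AbrB/MazE", NA,  86),
  list("MNT_1",     "antitoxin", "Mnt",      "Mnt",       NA, 120)
)

meta <- do.call(rbind, lapply(spec, function(s)
  data.frame(id = s[[1]], role = s[[2]], family = s[[3]],
             superfamily = s[[4]], subgroup = s[[5]],
             notes = "synthetic exemplar", hmm_profile = NA_character_,
             stringsAsFactors = FALSE)))
meta$aa_sequence <- vapply(spec, function(s) random_protein(s[[6]]), "")
# the two exemplars of a family are related (85% identity), as real
# paralog sets would be
meta$aa_sequence[meta$id == "ParE_2"] <-
  paste0(mutate_to_identity(meta$aa_sequence[meta$id == "ParE_1"], 85,
                            "protein"), "AAGLM")
meta$aa_sequence[meta$id == "ParD_2"] <-
  substr(mutate_to_identity(meta$aa_sequence[meta$id == "ParD_1"], 85,
                            "protein"), 1, 88)
meta$aa_sequence[meta$id == "tnpR_2"] <-
  paste0(mutate_to_identity(meta$aa_sequence[meta$id == "tnpR_1"], 80,
                            "protein"), "AGKLM")

lib <- structure(list(proteins = meta, version = "synthetic-1.0"),
                 class = "tn_reflibrary")
stopifnot(length(validate_reference_library(lib)) == 0)
write_reference_library(lib, "inst/extdata/reflib_synthetic")
cat("wrote inst/extdata/reflib_synthetic (",
    nrow(meta), "exemplars )\n")
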