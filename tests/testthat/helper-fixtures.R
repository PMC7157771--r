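# Shared fixtures, built once per test run.

.test_env <- new.env()

test_lib <- function() {
  if (is.null(.test_env$lib)) .test_env$lib <- load_reference_library()
  .test_env$lib
}

# A hand-built hit table row (defaults give a plausible passing hit).
make_hit <- function(seq_id = "s", start = 0, end = 300, strand = "+",
                     ref_id = "ref1", role = "toxin", family = "ParE",
                     score = 100, identity = 80, coverage = 90) {
  data.frame(seq_id = seq_id, start = start, end = end, strand = strand,
             frame = 0L, partial = FALSE, aa_len = (end - start) %/% 3 - 1,
             aa_sequence = "M", ref_id = ref_id, role = role,
             family = family, superfamily = NA_character_,
             subgroup = NA_character_, score = score, identity = identity,
             coverage = coverage, q_start = 1L, q_end = 10L, r_start = 1L,
             r_end = 10L, ref_len = 100L, stringsAsFactors = FALSE)
}

as_hits <- function(...) {
  h <- do.call(rbind, list(...))
  class(h) <- c("tn_hits", "data.frame")
  h
}

# Build a locus directly from a hit table (bypassing clustering).
make_locus <- function(hits) {
  structure(list(seq_id = hits$seq_id[1], start = min(hits$start),
                 end = max(hits$end), members = hits[order(hits$start), ],
                 configuration = NULL, completeness = NA_character_,
                 missing_roles = character(), subgroup = NA_character_,
                 resolvase_type = "none", ta_order = NA_character_,
                 notes = character()),
            class = "tn_locus")
}

# Random feature table for round-trip tests.
random_features <- function(n, seq_id = "chr") {
  starts <- sort(sample.int(5000, n))
  feature_table(
    seq_id = rep(seq_id, n), start = starts,
    end = starts + sample(10:500, n, replace = TRUE),
    strand = sample(c("+", "-", "*"), n, replace = TRUE),
    feature_type = sample(c("toxin", "antitoxin", "res_site", "gene"), n,
                          replace = TRUE),
    attributes = lapply(seq_len(n), function(i)
      c(id = paste0("f", i), note = sample(c("a b", "x;y", "plain"), 1))))
}
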