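#' @name reference_library
#' @title Labeled exemplar protein library
#' @description
#' The screen classifies ORFs by best local-alignment hit against a small
#' library of labeled exemplar proteins. Each exemplar carries a `role`
#' (transposase, one of the three resolvase types, the TnpT helper, toxin
#' or antitoxin), a `family` (toxins/antitoxins only, e.g. ParE, Gp49,
#' PIN_3; ParD, HTH_37), a `superfamily`, and for transposases a TnpA
#' `subgroup` (Tn3, Tn21, Tn163, IS1071, IS3000, Tn4430, Tn4651, Tn3000).
#' Family assignment is best-hit against these exemplars rather than a live
#' profile-HMM search; the metadata schema reserves an `hmm_profile` field
#' so an HMM backend can be slotted in later.
NULL

.ref_roles <- c("transposase", "resolvase_S", "resolvase_Y",
                "resolvase_Y_het", "helper", "toxin", "antitoxin")

.resolvase_roles <- c("resolvase_S", "resolvase_Y", "resolvase_Y_het")

.tnpa_subgroups <- c("Tn3", "Tn21", "Tn163", "IS1071", "IS3000",
                     "Tn4430", "Tn4651", "Tn3000")

#' Load a reference protein library
#'
#' A library directory contains one or more protein FASTA files (`*.faa` or
#' `*.fasta`) and a `metadata.tsv` with columns `id`, `role`, `family`,
#' `superfamily`, `subgroup` (empty for non-transposases) and optionally
#' `notes` and further fields, which are preserved as attributes.
#'
#' @param path Library directory. Defaults to the bundled synthetic
#'   exemplar library shipped with the package.
#' @return A `tn_reflibrary`: list with `proteins` (data.frame: id, role,
#'   family, superfamily, subgroup, aa_sequence plus extra metadata
#'   columns) and `version`.
#' @export
load_reference_library <- function(path = default_reference_library_path()) {
  if (!dir.exists(path)) stop("reference library directory not found: ", path)
  meta_path <- file.path(path, "metadata.tsv")
  if (!file.exists(meta_path)) stop("reference library metadata.tsv missing in ", path)
  meta <- read_table_tsv(meta_path)
  need <- c("id", "role", "family", "superfamily", "subgroup")
  missing <- setdiff(need, names(meta))
  if (length(missing) > 0)
    stop("metadata.tsv lacks column(s): ", paste(missing, collapse = ", "))
  fastas <- list.files(path, pattern = "\\.(faa|fasta|fa)$", full.names = TRUE)
  if (length(fastas) == 0) stop("no protein FASTA files in ", path)
  aa <- do.call(c, lapply(fastas, Biostrings::readAAStringSet))
  names(aa) <- sub("\\s.*$", "", names(aa))
  only_meta <- setdiff(meta$id, names(aa))
  only_fa <- setdiff(names(aa), meta$id)
  if (length(only_meta) || length(only_fa))
    stop("reference library id mismatch; metadata without FASTA: [",
         paste(only_meta, collapse = ", "), "]; FASTA without metadata: [",
         paste(only_fa, collapse = ", "), "]")
  meta$aa_sequence <- as.character(aa[meta$id])
  for (col in c("family", "superfamily", "subgroup"))
    meta[[col]][is.na(meta[[col]]) | meta[[col]] == ""] <- NA_character_
  version_file <- file.path(path, "VERSION")
  version <- if (file.exists(version_file)) readLines(version_file)[1] else "unversioned"
  lib <- structure(list(proteins = meta, version = version),
                   class = "tn_reflibrary")
  issues <- validate_reference_library(lib)
  if (length(issues) > 0)
    stop("invalid reference library:\n  ", paste(issues, collapse = "\n  "))
  lib
}

#' Path of the bundled synthetic exemplar library
#' @return Directory path inside the installed package.
#' @export
default_reference_library_path <- function() {
  system.file("extdata", "reflib_synthetic", package = "tnta", mustWork = TRUE)
}

#' @export
print.tn_reflibrary <- function(x, ...) {
  cat(sprintf("<tn_reflibrary> version %s: %d exemplars (%s)\n", x$version,
              nrow(x$proteins),
              paste(sprintf("%d %s", table(x$proteins$role),
                            names(table(x$proteins$role))), collapse = ", ")))
  invisible(x)
}

#' Validate a reference library
#'
#' Reports (never throws) one issue string per violated rule: duplicate
#' ids, invalid roles, role-inconsistent metadata (subgroup on anything but
#' a transposase, family on anything but toxin/antitoxin), invalid amino
#' acid alphabet, and missing required roles (at least one exemplar each of
#' transposase, resolvase_S, toxin and antitoxin).
#'
#' @param lib A `tn_reflibrary`.
#' @return Character vector of issues; empty iff the library is valid.
#' @export
validate_reference_library <- function(lib) {
  p <- lib$proteins
  issues <- character()
  dup <- unique(p$id[duplicated(p$id)])
  for (d in dup) issues <- c(issues, sprintf("%s: duplicate id", d))
  bad_role <- p$id[!p$role %in% .ref_roles]
  for (b in bad_role) issues <- c(issues, sprintf("%s: unknown role", b))
  has_sub <- !is.na(p$subgroup) & p$subgroup != ""
  for (i in which(has_sub & p$role != "transposase"))
    issues <- c(issues, sprintf("%s: subgroup set on role %s", p$id[i], p$role[i]))
  has_fam <- !is.na(p$family) & p$family != ""
  for (i in which(has_fam & !p$role %in% c("toxin", "antitoxin")))
    issues <- c(issues, sprintf("%s: family set on role %s", p$id[i], p$role[i]))
  for (i in seq_len(nrow(p))) {
    if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", p$aa_sequence[i]))
      issues <- c(issues, sprintf("%s: aa_sequence outside 20-letter alphabet + X",
                                  p$id[i]))
  }
  for (r in c("transposase", "resolvase_S", "toxin", "antitoxin"))
    if (!any(p$role == r))
      issues <- c(issues, sprintf("library: no exemplar with role %s", r))
  issues
}

#' Write a reference library to a directory
#'
#' Inverse of [load_reference_library()]; used by tests and by library
#' construction scripts.
#'
#' @param lib A `tn_reflibrary`.
#' @param path Output directory (created if needed).
#' @export
write_reference_library <- function(lib, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  p <- lib$proteins
  aa <- Biostrings::AAStringSet(p$aa_sequence)
  names(aa) <- p$id
  Biostrings::writeXStringSet(aa, file.path(path, "proteins.faa"))
  meta <- p[, setdiff(names(p), "aa_sequence"), drop = FALSE]
  write_table_tsv(meta, file.path(path, "metadata.tsv"))
  writeLines(lib$version, file.path(path, "VERSION"))
  invisible(path)
}
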