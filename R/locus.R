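.role_token <- c(transposase = "tnpA", resolvase_S = "tnpR",
                 resolvase_Y = "tnpI", resolvase_Y_het = "tnpS",
                 helper = "tnpT", toxin = "T", antitoxin = "A")

#' Keep the best hit per ORF
#'
#' At most one hit per ORF survives: highest alignment score, ties broken
#' by higher identity, then by lexicographically smallest reference id, so
#' the result is invariant under permutation of the input.
#'
#' @param hits A `tn_hits` data.frame from [screen_sequence()].
#' @return The filtered `tn_hits`.
#' @export
select_best_hits <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  key <- paste(hits$seq_id, hits$start, hits$end, hits$strand)
  ord <- order(key, -hits$score, -hits$identity, hits$ref_id)
  h <- hits[ord, , drop = FALSE]
  h <- h[!duplicated(paste(h$seq_id, h$start, h$end, h$strand)), , drop = FALSE]
  h <- h[order(h$start, h$strand), , drop = FALSE]
  rownames(h) <- NULL
  class(h) <- c("tn_hits", "data.frame")
  h
}

#' Cluster hits into candidate transposition modules
#'
#' Single-linkage clustering on the genomic intervals of the hits: two
#' hits belong to one locus when the gap between their nucleotide
#' intervals (next start minus previous end, measured end-to-start) is at
#' most `max_gap` bp, inclusive, possibly through a chain of intermediate
#' hits. Loci are returned sorted by span start.
#'
#' @param hits A `tn_hits` data.frame, all from one sequence.
#' @param max_gap Maximum inter-hit gap in bp (default 2000).
#' @return A list of `tn_locus` objects (unannotated: members and span).
#' @export
cluster_hits <- function(hits, max_gap = 2000) {
  if (nrow(hits) == 0) return(list())
  if (length(unique(hits$seq_id)) > 1)
    stop("cluster_hits expects hits from a single sequence; got: ",
         paste(unique(hits$seq_id), collapse = ", "))
  h <- hits[order(hits$start, hits$end), , drop = FALSE]
  run_end <- h$end[1]
  cluster <- integer(nrow(h)); cluster[1] <- 1L
  for (i in seq_len(nrow(h))[-1]) {
    if (h$start[i] - run_end <= max_gap) {
      cluster[i] <- cluster[i - 1]
      run_end <- max(run_end, h$end[i])
    } else {
      cluster[i] <- cluster[i - 1] + 1L
      run_end <- h$end[i]
    }
  }
  lapply(split(seq_len(nrow(h)), cluster), function(idx) {
    m <- h[idx, , drop = FALSE]
    rownames(m) <- NULL
    structure(list(seq_id = m$seq_id[1], start = min(m$start),
                   end = max(m$end), members = m,
                   configuration = NULL, completeness = NA_character_,
                   missing_roles = character(), subgroup = NA_character_,
                   resolvase_type = "none", ta_order = NA_character_,
                   notes = character()),
              class = "tn_locus")
  })
}

#' @export
print.tn_locus <- function(x, ...) {
  cat(sprintf("<tn_locus> %s:[%d,%d) %d genes%s\n", x$seq_id, x$start, x$end,
              nrow(x$members),
              if (!is.null(x$configuration))
                paste0("  ", render_config(x$configuration)) else ""))
  invisible(x)
}

#' Render the configuration string of a locus
#'
#' One token per member gene in genomic order using the field's role
#' naming (toxin `T`, antitoxin `A`, transposase `tnpA`, serine resolvase
#' `tnpR`, tyrosine resolvase `tnpI`, heteromeric resolvase `tnpS` +
#' helper `tnpT`). Unclassified ORFs lying strictly between classified
#' members render as `X`. When a res site is supplied and falls between
#' two genes, a `!res!` marker is inserted at that position.
#'
#' @param locus A `tn_locus`.
#' @param res Optional `tn_ressite` (see [assemble_res_site()]).
#' @param orfs Optional `tn_orfs` table used to place `X` tokens.
#' @return A `tn_config`.
#' @export
classify_configuration <- function(locus, res = NULL, orfs = NULL) {
  m <- locus$members
  items <- data.frame(start = m$start, end = m$end, strand = m$strand,
                      name = unname(.role_token[m$role]),
                      stringsAsFactors = FALSE)
  if (!is.null(orfs) && nrow(orfs) > 0 && nrow(items) >= 2) {
    inner_lo <- min(items$end); inner_hi <- max(items$start)
    for (i in seq_len(nrow(orfs))) {
      o_s <- orfs$start[i]; o_e <- orfs$end[i]
      overlaps <- any(pmax(items$start, o_s) < pmin(items$end, o_e))
      between <- any(vapply(seq_len(nrow(items) - 1), function(k) {
        ordered <- items[order(items$start), ]
        o_s >= ordered$end[k] && o_e <= ordered$start[k + 1]
      }, TRUE))
      if (!overlaps && between)
        items <- rbind(items, data.frame(start = o_s, end = o_e,
                                         strand = orfs$strand[i], name = "X",
                                         stringsAsFactors = FALSE))
    }
  }
  items <- items[order(items$start), , drop = FALSE]
  if (!is.null(res)) {
    mid <- (res$region[1] + res$region[2]) / 2
    pos <- sum(items$end <= mid)
    if (pos >= 1 && pos < nrow(items)) {
      items <- rbind(items[seq_len(pos), , drop = FALSE],
                     data.frame(start = NA, end = NA, strand = NA,
                                name = "!res!", stringsAsFactors = FALSE),
                     items[seq(pos + 1, nrow(items)), , drop = FALSE])
    }
  }
  strands <- ifelse(items$name == "!res!", NA_character_, items$strand)
  config_string(items$name, strands)
}

#' Assess locus completeness
#'
#' `full_with_TA` requires at least one transposase, one resolvase-role
#' gene, one toxin and one antitoxin hit; `full_no_TA` requires the
#' transposition backbone without a complete TA pair; anything else is
#' `partial`, with the missing roles listed. A weak toxin hit (passing
#' identity but covering less than half its reference) whose genomic
#' region extends beyond the called ORF is annotated `truncated_toxin` —
#' the signature of a toxin gene disrupted by an internal stop.
#'
#' @param locus A `tn_locus`.
#' @param weak_hits Optional sub-threshold hits (`attr(hits, "weak")`).
#' @return A list: `completeness`, `missing_roles`, `notes`.
#' @export
assess_completeness <- function(locus, weak_hits = NULL) {
  roles <- locus$members$role
  have_backbone <- "transposase" %in% roles & any(roles %in% .resolvase_roles)
  have_ta <- "toxin" %in% roles & "antitoxin" %in% roles
  missing <- character()
  if (!"transposase" %in% roles) missing <- c(missing, "transposase")
  if (!any(roles %in% .resolvase_roles)) missing <- c(missing, "resolvase")
  if (!"toxin" %in% roles) missing <- c(missing, "toxin")
  if (!"antitoxin" %in% roles) missing <- c(missing, "antitoxin")
  completeness <- if (have_backbone && have_ta) "full_with_TA"
  else if (have_backbone) "full_no_TA" else "partial"
  notes <- character()
  if (!is.null(weak_hits) && nrow(weak_hits) > 0) {
    w <- weak_hits[weak_hits$role == "toxin" &
                     weak_hits$coverage < 50 &
                     weak_hits$start >= locus$start - 2000 &
                     weak_hits$end <= locus$end + 2000, , drop = FALSE]
    # region extends beyond the ORF: the reference alignment stops short of
    # the reference end, i.e. the rest of the gene lies past the ORF stop
    if (nrow(w) > 0 && any(w$r_end < w$ref_len)) notes <- c(notes, "truncated_toxin")
  }
  list(completeness = completeness, missing_roles = missing, notes = notes)
}

#' TnpA subgroup of a locus
#'
#' The subgroup label of the best transposase hit (highest score, ties by
#' identity then reference id); `NA` when the locus has no transposase.
#'
#' @param locus A `tn_locus`.
#' @return Subgroup string or `NA`.
#' @export
assign_subgroup <- function(locus) {
  tp <- locus$members[locus$members$role == "transposase", , drop = FALSE]
  if (nrow(tp) == 0) return(NA_character_)
  tp <- tp[order(-tp$score, -tp$identity, tp$ref_id), , drop = FALSE]
  tp$subgroup[1]
}

resolvase_type_of <- function(roles) {
  if ("resolvase_Y_het" %in% roles || "helper" %in% roles) "S/T"
  else if ("resolvase_Y" %in% roles) "I"
  else if ("resolvase_S" %in% roles) "R"
  else "none"
}

#' Annotate a locus
#'
#' Fills configuration, completeness, missing roles, subgroup, resolvase
#' type, TA order and notes on a clustered locus.
#'
#' @param locus A `tn_locus` from [cluster_hits()].
#' @param res Optional `tn_ressite` for the `!res!` marker.
#' @param orfs Optional ORF table for `X` tokens.
#' @param weak_hits Optional weak-hit table for truncation notes.
#' @return The annotated `tn_locus`.
#' @export
annotate_locus <- function(locus, res = NULL, orfs = NULL, weak_hits = NULL) {
  locus$configuration <- classify_configuration(locus, res = res, orfs = orfs)
  comp <- assess_completeness(locus, weak_hits = weak_hits)
  locus$completeness <- comp$completeness
  locus$missing_roles <- comp$missing_roles
  locus$notes <- comp$notes
  locus$subgroup <- assign_subgroup(locus)
  locus$resolvase_type <- resolvase_type_of(locus$members$role)
  ta <- classify_ta_order(locus$configuration)
  if (!is.null(attr(ta, "note"))) locus$notes <- c(locus$notes, attr(ta, "note"))
  locus$ta_order <- as.character(ta)
  locus
}

#' Run the whole detection pipeline on one sequence
#'
#' Screen, best-hit selection, proximity clustering and annotation in one
#' call — the programmatic equivalent of the `scan` command.
#'
#' @inheritParams screen_sequence
#' @param max_gap Clustering gap in bp (default 2000).
#' @param with_res Also run the res-site scanner on each locus that has a
#'   resolvase gene, and use it for the `!res!` marker.
#' @return A list of annotated `tn_locus` objects; the hit table is
#'   attached as `attr(, "hits")`.
#' @export
scan_genome <- function(record, lib = load_reference_library(),
                        min_identity = 40, min_coverage = 60,
                        max_gap = 2000, min_aa = 80, with_res = FALSE) {
  hits <- screen_sequence(record, lib, min_identity = min_identity,
                          min_coverage = min_coverage, min_aa = min_aa)
  weak <- attr(hits, "weak")
  best <- select_best_hits(hits)
  loci <- cluster_hits(best, max_gap = max_gap)
  orfs <- find_orfs(record, min_aa = min_aa)
  loci <- lapply(loci, function(lc) {
    res <- NULL
    if (with_res && any(lc$members$role %in% .resolvase_roles))
      res <- tryCatch(scan_res_site(lc, record), error = function(e) NULL)
    weak_l <- rbind(weak, find_weak_toxin_hits(record, lc, lib,
                                               min_identity = min_identity))
    lc <- annotate_locus(lc, res = res, orfs = orfs, weak_hits = weak_l)
    lc$res_site <- res
    lc
  })
  attr(loci, "hits") <- hits
  loci
}

# Locus-local rescan for disrupted toxin genes: a toxin ORF cut short by an
# internal stop falls below the main screen's min_aa, so the locus
# neighborhood is rescreened with small ORFs against the toxin exemplars
# only; sub-threshold coverage hits feed the truncated_toxin annotation.
find_weak_toxin_hits <- function(record, locus, lib, min_identity = 40,
                                 pad = 2000) {
  lo <- max(0, locus$start - pad)
  hi <- min(nchar(record$sequence), locus$end + pad)
  sub <- seq_record(locus$seq_id, substr(record$sequence, lo + 1, hi))
  tox <- lib
  tox$proteins <- lib$proteins[lib$proteins$role == "toxin", , drop = FALSE]
  h <- screen_sequence(sub, tox, min_identity = min_identity,
                       min_coverage = 60, min_aa = 20)
  w <- attr(h, "weak")
  if (nrow(w) > 0) {
    w$start <- w$start + lo
    w$end <- w$end + lo
  }
  w
}

#' Loci as a summary table
#'
#' @param loci A list of annotated `tn_locus` objects.
#' @return A data.frame matching the `.loci.tsv` export: seq_id, span,
#'   configuration, completeness, subgroup, resolvase_type, ta_order,
#'   toxin/antitoxin family and notes.
#' @export
loci_table <- function(loci) {
  if (length(loci) == 0)
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), configuration = character(),
                      completeness = character(), subgroup = character(),
                      resolvase_type = character(), ta_order = character(),
                      toxin_family = character(),
                      antitoxin_family = character(), notes = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(loci, function(lc) {
    m <- lc$members
    tox <- m$family[m$role == "toxin"]; at <- m$family[m$role == "antitoxin"]
    data.frame(seq_id = lc$seq_id, start = lc$start, end = lc$end,
               configuration = if (is.null(lc$configuration)) ""
               else render_config(lc$configuration),
               completeness = lc$completeness,
               subgroup = lc$subgroup %||% NA_character_,
               resolvase_type = lc$resolvase_type,
               ta_order = lc$ta_order,
               toxin_family = if (length(tox)) tox[1] else NA_character_,
               antitoxin_family = if (length(at)) at[1] else NA_character_,
               notes = paste(lc$notes, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
}

#' Locus member genes as a feature table (for GFF3 export)
#'
#' @param loci A list of `tn_locus` objects.
#' @return A [feature_table()] with one row per member gene plus res-site
#'   features when present.
#' @export
loci_features <- function(loci) {
  ft <- feature_table()
  for (lc in loci) {
    m <- lc$members
    ft <- rbind(ft, feature_table(
      seq_id = m$seq_id, start = m$start, end = m$end, strand = m$strand,
      feature_type = m$role,
      attributes = lapply(seq_len(nrow(m)), function(i) {
        a <- c(ref_id = m$ref_id[i],
               identity = sprintf("%.1f", m$identity[i]),
               coverage = sprintf("%.1f", m$coverage[i]))
        if (!is.na(m$family[i])) a <- c(a, family = m$family[i])
        a
      })))
    if (!is.null(lc$res_site)) ft <- rbind(ft, res_site_features(lc$res_site, lc$seq_id))
  }
  class(ft) <- c("tn_features", "data.frame")
  ft
}
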