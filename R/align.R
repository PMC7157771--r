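#' Optimal local protein alignment
#'
#' Smith-Waterman local alignment under BLOSUM62 with affine gaps
#' (opening 11, extension 1 — the classic protein-search defaults).
#' Percent identity is identities divided by all alignment columns
#' (gap columns included); coverage is the aligned span of the reference
#' divided by the reference length. Both conventions are stated because
#' downstream screening thresholds depend on them.
#'
#' @param query,ref Non-empty protein strings.
#' @param matrix Substitution matrix name (passed to Biostrings).
#' @param gap_open,gap_extend Affine gap penalties (positive numbers).
#' @return A list of class `tn_alignment`: `score`, `identity_pct`,
#'   `coverage_pct`, `query_interval` and `ref_interval` (1-based inclusive
#'   on the unaligned sequences), and the gapped `aligned_query` /
#'   `aligned_ref` strings.
#' @export
align_protein <- function(query, ref, matrix = "BLOSUM62",
                          gap_open = 11, gap_extend = 1) {
  if (!nzchar(query)) stop("empty query sequence")
  if (!nzchar(ref)) stop("empty reference sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(ref), type = "local",
    substitutionMatrix = matrix, gapOpening = gap_open,
    gapExtension = gap_extend)
  summarize_local_alignment(aln, nchar(ref))
}

# Shared extraction of score/identity/coverage from a local alignment.
summarize_local_alignment <- function(aln, ref_len, i = 1) {
  sc <- Biostrings::score(aln)[i]
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)[i]), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)[i]), "")[[1]]
  if (sc <= 0 || length(p) == 0) {
    return(structure(list(score = max(sc, 0), identity_pct = 0,
                          coverage_pct = 0,
                          query_interval = c(NA_integer_, NA_integer_),
                          ref_interval = c(NA_integer_, NA_integer_),
                          aligned_query = "", aligned_ref = ""),
                     class = "tn_alignment"))
  }
  ident <- 100 * sum(p == s & p != "-") / length(p)
  r_start <- IRanges::start(Biostrings::subject(aln))[i]
  r_end <- IRanges::end(Biostrings::subject(aln))[i]
  q_start <- IRanges::start(Biostrings::pattern(aln))[i]
  q_end <- IRanges::end(Biostrings::pattern(aln))[i]
  cov <- 100 * (r_end - r_start + 1) / ref_len
  structure(list(score = sc, identity_pct = ident, coverage_pct = cov,
                 query_interval = c(q_start, q_end),
                 ref_interval = c(r_start, r_end),
                 aligned_query = paste(p, collapse = ""),
                 aligned_ref = paste(s, collapse = "")),
            class = "tn_alignment")
}

#' @export
print.tn_alignment <- function(x, ...) {
  cat(sprintf("<tn_alignment> score %.1f, identity %.1f%%, coverage %.1f%%\n",
              x$score, x$identity_pct, x$coverage_pct))
  invisible(x)
}

#' Screen a sequence against the reference library
#'
#' Calls ORFs with [find_orfs()] and aligns each translation against every
#' library exemplar; every (ORF, exemplar) pair with identity strictly
#' above `min_identity` and reference coverage of at least `min_coverage`
#' becomes a hit carrying the exemplar's role/family labels. Identity is
#' measured over all alignment columns and coverage over the reference
#' sequence (full-role detection is the screen's purpose). Pairs passing
#' the identity threshold with coverage in `[weak_coverage, min_coverage)`
#' are returned separately as weak hits; locus annotation uses them to flag
#' truncated toxin genes.
#'
#' @param record A [seq_record()].
#' @param lib A reference library from [load_reference_library()].
#' @param min_identity Percent identity threshold (exclusive), default 40.
#' @param min_coverage Percent reference coverage threshold (inclusive),
#'   default 60.
#' @param min_aa Minimum ORF length in residues, default 80.
#' @param weak_coverage Lower coverage bound for the weak-hit tier.
#' @return A `data.frame` of class `tn_hits`, one row per passing
#'   (ORF, exemplar) pair, with the ORF coordinates, reference labels and
#'   alignment statistics; weak hits are attached as `attr(, "weak")`.
#' @export
screen_sequence <- function(record, lib, min_identity = 40, min_coverage = 60,
                            min_aa = 80, weak_coverage = 20) {
  stopifnot(inherits(lib, "tn_reflibrary"))
  orfs <- find_orfs(record, min_aa = min_aa)
  hits <- empty_hits()
  if (nrow(orfs) > 0) {
    rows <- list()
    for (j in seq_len(nrow(lib$proteins))) {
      ref <- lib$proteins[j, ]
      # identity > min_identity bounds alignment columns by aa_len/0.4, and
      # the covered reference span by the same, so pairs that cannot reach
      # the relevant coverage threshold are skipped without aligning
      cov_needed <- if (ref$role %in% c("toxin", "antitoxin"))
        weak_coverage else min_coverage
      feasible <- which(100 * (orfs$aa_len / (min_identity / 100)) /
                          nchar(ref$aa_sequence) >= cov_needed)
      if (length(feasible) == 0) next
      orfs_j <- orfs[feasible, , drop = FALSE]
      pat <- Biostrings::AAStringSet(orfs_j$aa_sequence)
      aln <- Biostrings::pairwiseAlignment(
        pat, Biostrings::AAString(ref$aa_sequence), type = "local",
        substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
      scores <- Biostrings::score(aln)
      r_start <- IRanges::start(Biostrings::subject(aln))
      r_end <- IRanges::end(Biostrings::subject(aln))
      q_start <- IRanges::start(Biostrings::pattern(aln))
      q_end <- IRanges::end(Biostrings::pattern(aln))
      ref_len <- nchar(ref$aa_sequence)
      cov <- 100 * (r_end - r_start + 1) / ref_len
      # identity over all alignment columns (gap columns included)
      ni <- Biostrings::nindel(aln)
      n_cols <- Biostrings::nmatch(aln) + Biostrings::nmismatch(aln) +
        Biostrings::insertion(ni)[, "WidthSum"] +
        Biostrings::deletion(ni)[, "WidthSum"]
      ident <- 100 * Biostrings::nmatch(aln) / pmax(n_cols, 1)
      cov[scores <= 0] <- 0; ident[scores <= 0] <- 0
      keep <- ident > min_identity & cov >= weak_coverage
      if (!any(keep)) next
      rows[[length(rows) + 1]] <- data.frame(
        seq_id = orfs_j$seq_id[keep], start = orfs_j$start[keep],
        end = orfs_j$end[keep], strand = orfs_j$strand[keep],
        frame = orfs_j$frame[keep], partial = orfs_j$partial[keep],
        aa_len = orfs_j$aa_len[keep], aa_sequence = orfs_j$aa_sequence[keep],
        ref_id = ref$id, role = ref$role,
        family = ref$family, superfamily = ref$superfamily,
        subgroup = ref$subgroup,
        score = scores[keep], identity = ident[keep], coverage = cov[keep],
        q_start = q_start[keep], q_end = q_end[keep],
        r_start = r_start[keep], r_end = r_end[keep], ref_len = ref_len,
        stringsAsFactors = FALSE)
    }
    if (length(rows) > 0) hits <- do.call(rbind, rows)
  }
  strong <- hits[hits$coverage >= min_coverage, , drop = FALSE]
  weak <- hits[hits$coverage < min_coverage, , drop = FALSE]
  strong <- strong[order(strong$start, strong$strand, strong$ref_id), , drop = FALSE]
  rownames(strong) <- NULL
  class(strong) <- c("tn_hits", "data.frame")
  attr(strong, "weak") <- weak
  strong
}

empty_hits <- function() {
  data.frame(seq_id = character(), start = integer(), end = integer(),
             strand = character(), frame = integer(), partial = logical(),
             aa_len = integer(), aa_sequence = character(),
             ref_id = character(), role = character(), family = character(),
             superfamily = character(), subgroup = character(),
             score = numeric(), identity = numeric(), coverage = numeric(),
             q_start = integer(), q_end = integer(), r_start = integer(),
             r_end = integer(), ref_len = integer(), stringsAsFactors = FALSE)
}
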