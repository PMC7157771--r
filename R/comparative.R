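#' Exact shared words between two sequences (dot-plot matches)
#'
#' Lists every pair of positions at which the two sequences share an exact
#' word of length `wordsize`, in both orientations: a `-` strand row means
#' the word of A at `posA` equals the reverse complement of the word of B
#' starting at `posB` (positions 1-based on the forward strands).
#'
#' @param seqA,seqB DNA strings, each at least `wordsize` long.
#' @param wordsize Word length (default 10).
#' @return A list of class `tn_matchlist`: `wordsize` and `matches`
#'   (data.frame posA, posB, strand, sorted by strand, posA, posB).
#' @export
dotplot_matches <- function(seqA, seqB, wordsize = 10) {
  seqA <- toupper(seqA); seqB <- toupper(seqB)
  if (nchar(seqA) < wordsize || nchar(seqB) < wordsize)
    stop("both sequences must be at least wordsize long")
  wordsA <- substring(seqA, 1:(nchar(seqA) - wordsize + 1),
                      wordsize:nchar(seqA))
  wordsB <- substring(seqB, 1:(nchar(seqB) - wordsize + 1),
                      wordsize:nchar(seqB))
  pair_up <- function(wa, wb, strand) {
    ia <- split(seq_along(wa), wa)
    ib <- split(seq_along(wb), wb)
    shared <- intersect(names(ia), names(ib))
    if (length(shared) == 0)
      return(data.frame(posA = integer(), posB = integer(),
                        strand = character(), stringsAsFactors = FALSE))
    do.call(rbind, lapply(shared, function(w) {
      g <- expand.grid(posA = ia[[w]], posB = ib[[w]])
      g$strand <- strand
      g
    }))
  }
  fwd <- pair_up(wordsA, wordsB, "+")
  wordsB_rc <- vapply(wordsB, revcomp, "", USE.NAMES = FALSE)
  rev <- pair_up(wordsA, wordsB_rc, "-")
  matches <- rbind(fwd, rev)
  matches <- matches[order(matches$strand, matches$posA, matches$posB), ,
                     drop = FALSE]
  rownames(matches) <- NULL
  structure(list(wordsize = wordsize, matches = matches),
            class = "tn_matchlist")
}

#' @export
print.tn_matchlist <- function(x, ...) {
  cat(sprintf("<tn_matchlist> wordsize %d: %d matches (%d forward, %d reverse)\n",
              x$wordsize, nrow(x$matches), sum(x$matches$strand == "+"),
              sum(x$matches$strand == "-")))
  invisible(x)
}

# Pairwise DNA alignment under match +1 / mismatch -1 / gap -2, returning
# the aligned strings. Profiles use free end gaps ("overlap") so a shared
# prefix scores cleanly against a longer partner; module identity uses
# strict end-to-end global alignment. Identity values downstream depend on
# this scoring, hence it is fixed here.
align_dna_global <- function(seqA, seqB, type = "overlap") {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seqA), Biostrings::DNAString(seqB),
    type = type, substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 2)
  list(a = as.character(Biostrings::alignedPattern(aln)),
       b = as.character(Biostrings::alignedSubject(aln)),
       score = Biostrings::score(aln))
}

#' Windowed identity profile along a pairwise alignment
#'
#' Globally aligns the two sequences (match +1, mismatch -1, gap -2, free
#' end gaps) and reports, for windows of `window` bp centered every `step`
#' bp on A coordinates, the fraction of A positions whose aligned B
#' character is identical (a position aligned to a gap counts as
#' non-identical).
#'
#' @param seqA,seqB DNA strings.
#' @param window Window size in bp on sequence A.
#' @param step Step between window centers in bp.
#' @return A list of class `tn_idprofile`: `window`, `step`, `centers`
#'   (1-based A coordinates, strictly increasing), `identity` (fractions).
#' @export
identity_profile <- function(seqA, seqB, window = 100, step = 10) {
  aln <- align_dna_global(seqA, seqB)
  a <- strsplit(aln$a, "")[[1]]; b <- strsplit(aln$b, "")[[1]]
  keep <- a != "-"
  idvec <- (a == b)[keep]                       # per A position
  n <- length(idvec)
  if (n < window) stop("alignment shorter than one window")
  cs <- c(0, cumsum(idvec))
  half <- window / 2
  centers <- seq(from = ceiling(half), to = n - floor(half), by = step)
  if (length(centers) < 1) stop("degenerate alignment: fewer than one window")
  lo <- pmax(1, centers - ceiling(half) + 1)
  hi <- pmin(n, centers + floor(half))
  ident <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  structure(list(window = window, step = step, centers = centers,
                 identity = ident), class = "tn_idprofile")
}

#' @export
print.tn_idprofile <- function(x, ...) {
  cat(sprintf("<tn_idprofile> %d windows (w=%d, s=%d), identity %.3f-%.3f\n",
              length(x$centers), x$window, x$step, min(x$identity),
              max(x$identity)))
  invisible(x)
}

#' Detect a recombination breakpoint on an identity profile
#'
#' Two-segment least-squares change point: the split minimizing the total
#' squared deviation of window identities from their per-segment means. A
#' breakpoint is reported only when one segment's mean identity is at
#' least `high` and the other's at most `low` — the signature of a chimera
#' identical to the reference on one side of the junction and diverged on
#' the other. The confidence interval collects the split positions whose
#' fit cost is within 5% of the optimum.
#'
#' @param profile A `tn_idprofile` with at least 10 windows.
#' @param high,low Segment-mean thresholds (defaults 0.95 / 0.85).
#' @return A list of class `tn_breakpoint` (`position` on A coordinates,
#'   `left_identity`, `right_identity`, `ci` = c(lo, hi),
#'   `in_res_site_I` = NA until [breakpoint_in_res_site()] is applied), or
#'   `NULL` when no qualifying split exists.
#' @export
detect_breakpoint <- function(profile, high = 0.95, low = 0.85) {
  x <- profile$identity
  n <- length(x)
  if (n < 10) stop("profile has fewer than 10 windows")
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  total_s <- cs[n]; total_s2 <- cs2[n]
  k <- seq_len(n - 1)
  ssL <- cs2[k] - cs[k]^2 / k
  nR <- n - k
  sR <- total_s - cs[k]; s2R <- total_s2 - cs2[k]
  ssR <- s2R - sR^2 / nR
  cost <- ssL + ssR
  kstar <- which.min(cost)
  mL <- cs[kstar] / kstar
  mR <- (total_s - cs[kstar]) / (n - kstar)
  qualifies <- (mL >= high && mR <= low) || (mL <= low && mR >= high)
  if (!qualifies) return(NULL)
  boundary <- function(kk) (profile$centers[kk] + profile$centers[kk + 1]) / 2
  in_ci <- which(cost <= min(cost) * 1.05)
  structure(list(position = boundary(kstar),
                 left_identity = mL, right_identity = mR,
                 ci = c(boundary(min(in_ci)), boundary(max(in_ci))),
                 in_res_site_I = NA), class = "tn_breakpoint")
}

#' @export
print.tn_breakpoint <- function(x, ...) {
  cat(sprintf(
    "<tn_breakpoint> at %.0f (CI %.0f-%.0f), identity %.3f | %.3f%s\n",
    x$position, x$ci[1], x$ci[2], x$left_identity, x$right_identity,
    if (is.na(x$in_res_site_I)) "" else
      sprintf("; in res site I: %s", x$in_res_site_I)))
  invisible(x)
}

#' Does a breakpoint fall at res subsite I?
#'
#' The change-point estimator has window-level resolution, so the test is
#' interval overlap: `in_res_site_I` is `TRUE` when the breakpoint's
#' confidence interval intersects the subsite I span (both on the same
#' coordinate system, typically the reference parent).
#'
#' @param bp A `tn_breakpoint`.
#' @param res A `tn_ressite` with genomic coordinates on the same sequence
#'   as the breakpoint profile's A coordinates.
#' @return The `tn_breakpoint` with `in_res_site_I` filled.
#' @export
breakpoint_in_res_site <- function(bp, res) {
  siteI <- res$subsites[["I"]]
  lo <- siteI$left_start + 1; hi <- siteI$right_end  # 1-based inclusive
  bp$in_res_site_I <- bp$ci[1] <= hi && bp$ci[2] >= lo
  bp
}

#' Percent DNA identity between the TA modules of two loci
#'
#' Extracts the span from toxin start to antitoxin end (or the reverse,
#' whichever order the genes are in) on both sequences, aligns them
#' globally and reports identical columns over all alignment columns as a
#' percentage.
#'
#' @param recordA,recordB [seq_record()]s.
#' @param locusA,locusB Their `tn_locus` objects; both need a toxin and an
#'   antitoxin member.
#' @return Percent identity (0-100).
#' @export
ta_module_identity <- function(recordA, locusA, recordB, locusB) {
  span <- function(record, locus) {
    m <- locus$members
    ta <- m[m$role %in% c("toxin", "antitoxin"), , drop = FALSE]
    if (!all(c("toxin", "antitoxin") %in% ta$role))
      stop("locus lacks a complete TA pair")
    substr(record$sequence, min(ta$start) + 1, max(ta$end))
  }
  a <- span(recordA, locusA); b <- span(recordB, locusB)
  aln <- align_dna_global(a, b, type = "global")
  p <- strsplit(aln$a, "")[[1]]; s <- strsplit(aln$b, "")[[1]]
  100 * sum(p == s & p != "-") / length(p)
}
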