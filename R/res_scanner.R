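#' Extract the res-site search region of a locus
#'
#' The resolution site lies on the 5' side of the resolvase gene: between
#' the divergent resolvase and transposase genes when those transcribe
#' away from each other, between the divergent `tnpS` and `tnpT` genes for
#' heteromeric resolvase systems, and otherwise in a window of up to
#' `window` bp directly upstream of the resolvase start, clipped at the
#' neighboring gene.
#'
#' @param locus A `tn_locus` with at least one resolvase-role hit.
#' @param record The [seq_record()] the locus was found on.
#' @param window Maximum upstream window for colinear arrangements (bp).
#' @return A list: `seq` (the sub-sequence), `offset` (0-based genomic
#'   start of the sub-sequence), `resolvase_start` (genomic 0-based
#'   coordinate of the resolvase gene's 5' end).
#' @export
extract_search_region <- function(locus, record, window = 400) {
  m <- locus$members
  res_rows <- m[m$role %in% .resolvase_roles, , drop = FALSE]
  if (nrow(res_rows) == 0) stop("locus has no resolvase-role gene")
  r <- res_rows[order(-res_rows$score), , drop = FALSE][1, ]
  helper <- m[m$role == "helper", , drop = FALSE]
  lo <- hi <- NULL
  if (r$role == "resolvase_Y_het" && nrow(helper) > 0) {
    # rst site between divergent tnpS and tnpT
    h <- helper[1, ]
    lo <- min(r$end, h$end); hi <- max(r$start, h$start)
  } else {
    tnp <- m[m$role == "transposase", , drop = FALSE]
    # divergent resolvase/transposase share the res region on the
    # resolvase 5' side; no window cap applies there
    divergent <- nrow(tnp) > 0 && r$strand != tnp$strand[1] &&
      ((r$strand == "-" && tnp$start[1] >= r$end) ||
         (r$strand == "+" && tnp$end[1] <= r$start))
    cap <- if (divergent) Inf else window
    others <- m[!(m$start == r$start & m$end == r$end), , drop = FALSE]
    if (r$strand == "+") {
      left_ends <- others$end[others$end <= r$start]
      lo <- max(c(r$start - cap, left_ends, 0))
      hi <- r$start
    } else {
      right_starts <- others$start[others$start >= r$end]
      len <- nchar(record$sequence)
      lo <- r$end
      hi <- min(c(r$end + cap, right_starts, len))
    }
  }
  if (is.null(lo) || hi <= lo) stop("no upstream space to search for a res site")
  resolvase_start <- if (r$strand == "+") r$start else r$end
  list(seq = substr(record$sequence, lo + 1, hi), offset = lo,
       resolvase_start = resolvase_start)
}

#' Find inverted-repeat motifs
#'
#' Exhaustively enumerates all spaced inverted repeats with arm length in
#' `[arm_min, arm_max]`, loop length in `[loop_min, loop_max]` and at most
#' `max_mismatch` mismatches between the left arm and the reverse
#' complement of the right arm. Score is arm matches minus mismatches
#' (`arm_len - 2*mismatches` is not used; scoring is `arm_len - mismatches`).
#' Overlapping motifs are allowed at this stage; [assemble_res_site()]
#' resolves them.
#'
#' @param seq DNA string (coordinates in the result are 0-based within it).
#' @param arm_min,arm_max Arm length bounds (bp).
#' @param loop_min,loop_max Loop (spacer) length bounds (bp).
#' @param max_mismatch Maximum arm mismatches.
#' @return A data.frame of class `tn_irmotifs`, highest score first:
#'   `left_start`, `left_end`, `right_start`, `right_end` (0-based
#'   half-open), `arm_len`, `loop_len`, `mismatches`, `score`.
#' @export
find_inverted_repeats <- function(seq, arm_min = 8, arm_max = 14,
                                  loop_min = 0, loop_max = 14,
                                  max_mismatch = 3) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 2 * arm_min) stop("sequence shorter than twice the minimum arm")
  v <- strsplit(seq, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  cv <- unname(comp[v])
  rows <- list()
  for (L in arm_min:arm_max) {
    for (loop in loop_min:loop_max) {
      span <- 2L * L + loop
      if (span > n) next
      i0 <- 0:(n - span)                      # 0-based left arm starts
      # left arm position k (1..L) vs complement of right arm mirrored:
      # left[k] == comp(right[L - k + 1]); right starts at i0 + L + loop
      mism <- integer(length(i0))
      for (k in seq_len(L)) {
        a <- v[i0 + k]
        b <- cv[i0 + L + loop + (L - k + 1)]
        mism <- mism + (a != b | a == "N")
      }
      ok <- which(mism <= max_mismatch)
      if (length(ok) == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        left_start = i0[ok], left_end = i0[ok] + L,
        right_start = i0[ok] + L + loop, right_end = i0[ok] + span,
        arm_len = L, loop_len = loop, mismatches = mism[ok],
        score = L - mism[ok])
    }
  }
  out <- if (length(rows) == 0) data.frame(
    left_start = integer(), left_end = integer(), right_start = integer(),
    right_end = integer(), arm_len = integer(), loop_len = integer(),
    mismatches = integer(), score = integer())
  else do.call(rbind, rows)
  out <- out[order(-out$score, out$left_start, out$arm_len, out$loop_len), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tn_irmotifs", "data.frame")
  out
}

#' Assemble a res site from inverted-repeat motifs
#'
#' Selects three mutually non-overlapping motifs with inter-subsite gaps
#' in `[0, max_gap]` bp maximizing total score (deterministic tie-break on
#' genomic position, so the result is invariant under permutation of the
#' motif list). The resolvase-proximal subsite is labeled III and the
#' distal one I. When no triple exists a two-motif assembly is returned as
#' a partial site if `allow_partial` is set; otherwise `NULL`.
#'
#' @param motifs A `tn_irmotifs` table in genomic coordinates (i.e. with
#'   the region offset already added).
#' @param resolvase_start Genomic 0-based coordinate of the resolvase 5'
#'   end.
#' @param region Numeric length-2: genomic span \[start, end) searched.
#' @param genome_seq The full genome sequence (for crossover location).
#' @param max_gap Maximum gap between consecutive subsites (bp).
#' @param allow_partial Report a two-subsite assembly as a partial site.
#' @return A `tn_ressite` or `NULL`: list with `subsites` (named I/II/III
#'   rows), `region`, `orientation` (`"left"`/`"right"`: the side where
#'   the resolvase lies), `crossover` (0-based genomic start of the AT
#'   dinucleotide in subsite I, or `NA`), `partial` flag.
#' @export
assemble_res_site <- function(motifs, resolvase_start, region, genome_seq,
                              max_gap = 60, allow_partial = FALSE) {
  if (nrow(motifs) == 0) return(NULL)
  m <- motifs[order(motifs$left_start, motifs$right_end, motifs$arm_len,
                    motifs$loop_len), , drop = FALSE]
  n <- nrow(m)
  # best chain of length 1..3 ending at motif i (DP over position-sorted
  # motifs); ties on total score prefer fewer total mismatches, so a
  # perfect subsite beats a mismatched extension of itself
  adj <- m$score - 1e-3 * m$mismatches
  best <- matrix(-Inf, nrow = n, ncol = 3)
  prev <- matrix(NA_integer_, nrow = n, ncol = 3)
  best[, 1] <- adj
  for (k in 2:3) {
    for (i in seq_len(n)) {
      gaps <- m$left_start[i] - m$right_end
      cand <- which(gaps >= 0 & gaps <= max_gap & best[, k - 1] > -Inf)
      if (length(cand) == 0) next
      sc <- best[cand, k - 1] + adj[i]
      j <- cand[order(-sc, cand)][1]
      best[i, k] <- best[j, k - 1] + adj[i]
      prev[i, k] <- j
    }
  }
  pick_chain <- function(k) {
    if (all(best[, k] == -Inf)) return(NULL)
    i <- order(-best[, k], seq_len(n))[1]
    chain <- i
    kk <- k
    while (kk > 1) { i <- prev[i, kk]; chain <- c(i, chain); kk <- kk - 1 }
    m[chain, , drop = FALSE]
  }
  chain <- pick_chain(3)
  partial <- FALSE
  if (is.null(chain)) {
    if (!allow_partial) return(NULL)
    chain <- pick_chain(2)
    if (is.null(chain)) return(NULL)
    partial <- TRUE
    warning("only a two-subsite (partial) res assembly was found")
  }
  orientation <- if (resolvase_start >= region[2]) "right"
  else if (resolvase_start <= region[1]) "left"
  else if (abs(resolvase_start - region[2]) <= abs(resolvase_start - region[1]))
    "right" else "left"
  # subsite III is resolvase-proximal
  chain <- chain[order(chain$left_start), , drop = FALSE]
  labels3 <- if (orientation == "right") c("I", "II", "III") else c("III", "II", "I")
  labels2 <- if (orientation == "right") c("I", "III") else c("III", "I")
  labels <- if (nrow(chain) == 3) labels3 else labels2
  subsites <- setNames(split(chain, seq_len(nrow(chain))), labels)
  siteI <- subsites[["I"]]
  crossover <- locate_crossover(siteI, genome_seq)
  structure(list(subsites = subsites, region = region,
                 orientation = orientation, crossover = crossover,
                 partial = partial, ta_adjacent = NA),
            class = "tn_ressite")
}

#' @export
print.tn_ressite <- function(x, ...) {
  spans <- vapply(x$subsites, function(s)
    sprintf("[%d,%d)", s$left_start, s$right_end), "")
  cat(sprintf("<tn_ressite> %s; resolvase side: %s; crossover AT at %s%s\n",
              paste(names(spans), spans, collapse = " "), x$orientation,
              ifelse(is.na(x$crossover), "none", x$crossover),
              if (isTRUE(x$partial)) " (partial)" else ""))
  invisible(x)
}

#' Locate the crossover AT dinucleotide in subsite I
#'
#' Recombination resolving the cointegrate occurs at an AT dinucleotide
#' near the center of res subsite I. Returns the 0-based genomic start of
#' the AT occurrence closest to the center of the subsite span (ties go to
#' the leftmost), or `NA` when the span contains no AT.
#'
#' @param siteI One motif row (the subsite I entry of a `tn_ressite`).
#' @param genome_seq Full genome sequence.
#' @return Integer position or `NA` (with attribute `flag = "no_AT"`).
#' @export
locate_crossover <- function(siteI, genome_seq) {
  span_start <- siteI$left_start; span_end <- siteI$right_end
  if (span_end - span_start < 4) stop("subsite I span shorter than 4 bp")
  s <- substr(genome_seq, span_start + 1, span_end)
  hits <- gregexpr("(?=AT)", s, perl = TRUE)[[1]]
  if (hits[1] == -1) {
    out <- NA_integer_
    attr(out, "flag") <- "no_AT"
    return(out)
  }
  p0 <- as.integer(hits) - 1L                   # 0-based within span
  center <- (nchar(s) - 2) / 2
  p <- p0[order(abs(p0 - center), p0)][1]
  span_start + p
}

#' Is the TA pair adjacent to res subsite I?
#'
#' In canonical TA-carrying transposons the TA genes sit directly
#' downstream of res subsite I while the resolvase neighbors subsite III.
#' Returns `TRUE` iff the nearest locus gene on the non-resolvase side of
#' subsite I is the toxin or the antitoxin.
#'
#' @param res A `tn_ressite`.
#' @param locus The `tn_locus` it belongs to (must contain TA genes).
#' @return Logical.
#' @export
annotate_ta_adjacency <- function(res, locus) {
  m <- locus$members
  if (!("toxin" %in% m$role) && !("antitoxin" %in% m$role))
    stop("locus has no TA genes")
  siteI <- res$subsites[["I"]]
  if (res$orientation == "right") {
    side <- m[m$end <= siteI$left_start, , drop = FALSE]
    if (nrow(side) == 0) return(FALSE)
    nearest <- side[order(-side$end), , drop = FALSE][1, ]
  } else {
    side <- m[m$start >= siteI$right_end, , drop = FALSE]
    if (nrow(side) == 0) return(FALSE)
    nearest <- side[order(side$start), , drop = FALSE][1, ]
  }
  nearest$role %in% c("toxin", "antitoxin")
}

#' Scan a locus for its res site
#'
#' Convenience wrapper: extracts the search region, enumerates inverted
#' repeats, assembles the best subsite triple and annotates TA adjacency.
#'
#' @param locus A `tn_locus` with a resolvase gene.
#' @param record The [seq_record()] scanned.
#' @param arm_min,arm_max,loop_min,loop_max,max_mismatch Motif geometry
#'   bounds (see [find_inverted_repeats()]).
#' @param max_gap Maximum inter-subsite gap (bp).
#' @param allow_partial Accept two-subsite assemblies.
#' @return A `tn_ressite` (coordinates genomic) or `NULL`.
#' @export
scan_res_site <- function(locus, record, arm_min = 8, arm_max = 14,
                          loop_min = 0, loop_max = 14, max_mismatch = 3,
                          max_gap = 60, allow_partial = FALSE) {
  reg <- extract_search_region(locus, record)
  if (nchar(reg$seq) < 2 * arm_min) return(NULL)
  motifs <- find_inverted_repeats(reg$seq, arm_min, arm_max, loop_min,
                                  loop_max, max_mismatch)
  for (col in c("left_start", "left_end", "right_start", "right_end"))
    motifs[[col]] <- motifs[[col]] + reg$offset
  res <- assemble_res_site(motifs, reg$resolvase_start,
                           region = c(reg$offset, reg$offset + nchar(reg$seq)),
                           genome_seq = record$sequence, max_gap = max_gap,
                           allow_partial = allow_partial)
  if (is.null(res)) return(NULL)
  if (any(locus$members$role %in% c("toxin", "antitoxin")))
    res$ta_adjacent <- annotate_ta_adjacency(res, locus)
  res
}

# res-site features for GFF3 export
res_site_features <- function(res, seq_id) {
  ft <- feature_table(seq_id = seq_id, start = res$region[1],
                      end = res$region[2], strand = "*",
                      feature_type = "res_site",
                      attributes = list(c(orientation = res$orientation)))
  for (nm in names(res$subsites)) {
    s <- res$subsites[[nm]]
    ft <- rbind(ft, feature_table(
      seq_id = seq_id, start = s$left_start, end = s$right_end, strand = "*",
      feature_type = paste0("res_subsite_", nm),
      attributes = list(c(arm_len = as.character(s$arm_len),
                          mismatches = as.character(s$mismatches)))))
  }
  if (!is.na(res$crossover))
    ft <- rbind(ft, feature_table(seq_id = seq_id, start = res$crossover,
                                  end = res$crossover + 2L, strand = "*",
                                  feature_type = "crossover_AT",
                                  attributes = list(character())))
  class(ft) <- c("tn_features", "data.frame")
  ft
}
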