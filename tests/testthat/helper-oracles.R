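# Independent brute-force oracles. These deliberately re-derive results by
# the most literal method available and share no code with the package
# implementations they check.

# Exhaustive affine-gap Smith-Waterman score (three-state DP), gap of
# length L costs open + L * ext.
sw_score_oracle <- function(q, r, open = 11, ext = 1) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B <- BLOSUM62
  qv <- strsplit(q, "")[[1]]; rv <- strsplit(r, "")[[1]]
  n <- length(qv); m <- length(rv)
  M <- matrix(-Inf, n + 1, m + 1); Ix <- M; Iy <- M
  M[1, ] <- 0; M[, 1] <- 0
  bestscore <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- B[qv[i - 1], rv[j - 1]]
      M[i, j] <- s + max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                         Iy[i - 1, j - 1], 0)
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
      bestscore <- max(bestscore, M[i, j])
    }
  }
  bestscore
}

# Naive inverted-repeat enumeration: every (start, arm, loop) combination
# tested with substr + complement lookups.
ir_oracle <- function(seq, arm_min = 8, arm_max = 14, loop_min = 0,
                      loop_max = 14, max_mismatch = 3) {
  seq <- toupper(seq)
  n <- nchar(seq)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rows <- list()
  for (i in 0:(n - 1)) {
    for (L in arm_min:arm_max) {
      for (loop in loop_min:loop_max) {
        if (i + 2 * L + loop > n) next
        left <- strsplit(substr(seq, i + 1, i + L), "")[[1]]
        right <- strsplit(substr(seq, i + L + loop + 1, i + 2 * L + loop),
                          "")[[1]]
        rc_right <- rev(unname(comp[right]))
        mm <- sum(left != rc_right | left == "N")
        if (mm <= max_mismatch)
          rows[[length(rows) + 1]] <- data.frame(
            left_start = i, left_end = i + L,
            right_start = i + L + loop, right_end = i + 2 * L + loop,
            arm_len = L, loop_len = loop, mismatches = mm, score = L - mm)
      }
    }
  }
  if (length(rows) == 0) return(data.frame(
    left_start = integer(), left_end = integer(), right_start = integer(),
    right_end = integer(), arm_len = integer(), loop_len = integer(),
    mismatches = integer(), score = integer()))
  do.call(rbind, rows)
}

# Naive all-pairs word comparison for dot plots.
dotplot_oracle <- function(a, b, w = 10) {
  a <- toupper(a); b <- toupper(b)
  na <- nchar(a) - w + 1; nb <- nchar(b) - w + 1
  rows <- list()
  for (i in seq_len(na)) {
    wa <- substr(a, i, i + w - 1)
    for (j in seq_len(nb)) {
      wb <- substr(b, j, j + w - 1)
      if (wa == wb)
        rows[[length(rows) + 1]] <- data.frame(posA = i, posB = j,
                                               strand = "+")
      if (wa == tnta::revcomp(wb))
        rows[[length(rows) + 1]] <- data.frame(posA = i, posB = j,
                                               strand = "-")
    }
  }
  if (length(rows) == 0) return(data.frame(posA = integer(),
                                           posB = integer(),
                                           strand = character()))
  do.call(rbind, rows)
}

# Independent six-frame ORF scan: for every in-frame stop codon, report the
# first start codon after the previous stop.
orf_oracle <- function(seq, min_aa = 80) {
  seq <- toupper(seq)
  L <- nchar(seq)
  gc_tab <- Biostrings::getGeneticCode("11")
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else tnta::revcomp(seq)
    for (frame in 0:2) {
      nc <- (L - frame) %/% 3
      if (nc < 1) next
      cods <- substring(s, frame + seq(1, by = 3, length.out = nc),
                        frame + seq(3, by = 3, length.out = nc))
      stops <- which(cods %in% c("TAA", "TAG", "TGA"))
      boundaries <- c(0, stops, if (length(stops) == 0 || max(stops) < nc)
        NA else NULL)
      segs <- cbind(head(c(0, stops), -1),
                    tail(c(0, stops), -1))
      if (length(stops) == 0 || max(stops) < nc)
        segs <- rbind(segs, c(if (length(stops)) max(stops) else 0, NA))
      for (r in seq_len(nrow(segs))) {
        lo <- segs[r, 1] + 1
        stop_ci <- segs[r, 2]
        hi <- if (is.na(stop_ci)) nc else stop_ci - 1
        if (lo > hi) next
        starts <- which(cods[lo:hi] %in% c("ATG", "GTG", "TTG"))
        if (length(starts) == 0) next
        ci <- lo + starts[1] - 1
        n_aa <- hi - ci + 1
        if (n_aa < min_aa) next
        nt_start <- frame + (ci - 1) * 3
        nt_end <- frame + (if (is.na(stop_ci)) hi else stop_ci) * 3
        orf_nt <- substr(s, nt_start + 1, nt_end)
        if (grepl("N", orf_nt, fixed = TRUE)) next
        aa <- as.character(Biostrings::translate(
          Biostrings::DNAString(substr(orf_nt, 1, 3 * n_aa)),
          genetic.code = gc_tab, if.fuzzy.codon = "X"))
        aa <- paste0("M", substr(aa, 2, nchar(aa)))
        if (strand == "+") { gs <- nt_start; ge <- nt_end }
        else { gs <- L - nt_end; ge <- L - nt_start }
        out[[length(out) + 1]] <- data.frame(
          start = gs, end = ge, strand = strand, frame = frame,
          partial = is.na(stop_ci), aa_sequence = aa,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) return(data.frame(start = integer(),
                                          end = integer(),
                                          strand = character(),
                                          frame = integer(),
                                          partial = logical(),
                                          aa_sequence = character()))
  df <- do.call(rbind, out)
  df[order(df$start, df$strand), ]
}

# Union-find single-linkage clustering of intervals: any two hits whose
# interval gap is <= max_gap end up in one cluster.
cluster_oracle <- function(starts, ends, max_gap) {
  n <- length(starts)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  union_ <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[min(ra, rb)] <<- parent[max(ra, rb)] <<- min(ra, rb)
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    gap <- max(starts[i], starts[j]) - min(ends[i], ends[j])
    if (gap <= max_gap) union_(i, j)
  }
  vapply(seq_len(n), find, 1L)
}
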