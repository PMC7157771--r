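#' Find open reading frames in all six frames
#'
#' Scans both strands in all three frames for ORFs running from a start
#' codon (ATG, GTG or TTG) to the nearest in-frame stop under genetic code
#' 11 (bacterial); an ORF reaching the contig end without a stop is
#' reported with `partial = TRUE`. Nested ORFs sharing a stop are collapsed
#' to the longest (first start after the previous stop). ORFs whose span
#' contains an N are skipped rather than guessed. The initiator residue is
#' reported as M regardless of the start codon, as gene callers do.
#'
#' @param record A [seq_record()] (or plain DNA string).
#' @param min_aa Minimum protein length in residues (stop excluded).
#' @param genetic_code NCBI genetic code id; default `"11"`.
#' @return A `data.frame` (class `tn_orfs`) with columns `seq_id`, `start`,
#'   `end` (0-based half-open nucleotide coordinates on the forward strand;
#'   `end` includes the stop codon when present), `strand`, `frame` (0-2 on
#'   the ORF's own strand), `partial`, `aa_len` and `aa_sequence`, sorted
#'   by (start, strand).
#' @export
find_orfs <- function(record, min_aa = 80, genetic_code = "11") {
  seq <- if (inherits(record, "tn_seqrecord")) record$sequence else check_dna(record)
  seq_id <- if (inherits(record, "tn_seqrecord")) record$id else "seq"
  L <- nchar(seq)
  out <- list()
  if (L >= 3) {
    gc_tab <- Biostrings::getGeneticCode(genetic_code)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seq else revcomp(seq)
      for (frame in 0:2) {
        n_codon <- (L - frame) %/% 3
        if (n_codon < 1) next
        frame_nt <- substr(s, frame + 1, frame + 3 * n_codon)
        aa <- strsplit(as.character(Biostrings::translate(
          Biostrings::DNAString(frame_nt), genetic.code = gc_tab,
          if.fuzzy.codon = "X")), "")[[1]]
        codon_start <- seq(1, by = 3, length.out = n_codon)
        codons <- substring(frame_nt, codon_start, codon_start + 2)
        is_stop <- aa == "*"
        is_start <- codons %in% c("ATG", "GTG", "TTG")
        stops <- which(is_stop)
        seg_start <- c(1L, stops + 1L)
        seg_stop <- c(stops, NA_integer_)  # NA: runs to contig end
        for (g in seq_along(seg_start)) {
          a <- seg_start[g]; b <- seg_stop[g]
          last <- if (is.na(b)) n_codon else b - 1L
          if (a > last) next
          st_idx <- which(is_start[a:last])
          if (length(st_idx) == 0) next
          ci <- a + st_idx[1] - 1L
          n_aa <- last - ci + 1L
          if (n_aa < min_aa) next
          nt_start <- frame + (ci - 1L) * 3L           # 0-based on strand s
          nt_end <- frame + (if (is.na(b)) last else b) * 3L
          orf_nt <- substr(s, nt_start + 1, nt_end)
          if (grepl("N", orf_nt, fixed = TRUE)) next
          aa_seq <- paste(c("M", aa[seq(ci + 1L, length.out = n_aa - 1L)]),
                          collapse = "")
          if (strand == "+") {
            g_start <- nt_start; g_end <- nt_end
          } else {
            g_start <- L - nt_end; g_end <- L - nt_start
          }
          out[[length(out) + 1]] <- data.frame(
            seq_id = seq_id, start = g_start, end = g_end, strand = strand,
            frame = frame, partial = is.na(b), aa_len = n_aa,
            aa_sequence = aa_seq, stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- if (length(out) == 0) data.frame(
    seq_id = character(), start = integer(), end = integer(),
    strand = character(), frame = integer(), partial = logical(),
    aa_len = integer(), aa_sequence = character(), stringsAsFactors = FALSE)
  else do.call(rbind, out)
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("tn_orfs", "data.frame")
  res
}
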