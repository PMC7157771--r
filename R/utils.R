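#' @importFrom stats runif setNames
#' @importFrom utils read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a random DNA sequence
#'
#' Draws bases independently with the stated GC content. Used by the
#' synthetic-data generators for genomic background.
#'
#' @param n Sequence length in bp.
#' @param gc GC content as a fraction in \[0, 1\].
#' @return A character scalar over A/C/G/T of length `n`.
#' @export
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Random protein sequence over the 20-letter alphabet
#'
#' @param n Length in residues. The first residue is always M so that
#'   reverse translation yields a canonical ATG start.
#' @return A character scalar.
#' @export
random_protein <- function(n) {
  stopifnot(n >= 1)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  paste0("M", paste(sample(aa, n - 1, replace = TRUE), collapse = ""))
}

#' Reverse complement of a DNA string
#'
#' @param x A character scalar over the DNA alphabet (IUPAC codes allowed).
#' @return The reverse complement as a character scalar.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Uppercase and check the DNA alphabet used internally (A/C/G/T/N).
check_dna <- function(x, what = "sequence") {
  x <- toupper(x)
  if (nchar(x) < 1) stop(what, " is empty")
  if (grepl("[^ACGTN]", x)) stop(what, " contains characters outside A/C/G/T/N")
  x
}

# Flip a strand symbol.
flip_strand <- function(s) ifelse(s == "+", "-", "+")

# Deterministic child seed derivation (kept below 2^31).
child_seed <- function(seed, i) {
  (as.integer(seed) * 1103L + as.integer(i) * 12347L) %% 2147483587L
}
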