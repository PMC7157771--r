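#' Configuration strings
#'
#' Gene arrangements within a transposition module are written in arrow
#' notation, tokens left to right in genomic order: a gene on the plus
#' strand renders as `NAME>`, on the minus strand as `<NAME`, and an
#' optional strandless marker `!res!` records the position of the res
#' resolution site. Gene names are `T` (toxin), `A` (antitoxin), `X`
#' (unclassified ORF), `tnpA`, `tnpR`, `tnpI`, `tnpS`, `tnpT`.
#' For example `<T <A tnpR> tnpA>` is the canonical arrangement with
#' divergent TA genes upstream of colinear tnpR/tnpA.
#'
#' @param names Character vector of token names.
#' @param strands Parallel vector of `+`/`-`; `NA` for `!res!` tokens.
#' @return An object of class `tn_config`.
#' @export
config_string <- function(names = character(), strands = character()) {
  stopifnot(length(names) == length(strands))
  ok <- names %in% c("T", "A", "X", "tnpA", "tnpR", "tnpI", "tnpS", "tnpT", "!res!")
  if (any(!ok)) stop("unknown configuration token(s): ",
                     paste(unique(names[!ok]), collapse = ", "))
  strands <- as.character(strands)
  is_res <- names == "!res!"
  if (any(!is.na(strands[is_res]))) stop("'!res!' token carries no strand")
  if (any(is.na(strands[!is_res])) || any(!strands[!is_res] %in% c("+", "-")))
    stop("every gene token must carry strand '+' or '-'")
  structure(list(names = names, strands = strands), class = "tn_config")
}

#' Render a configuration to its string form
#' @param config A `tn_config`.
#' @return A character scalar such as `"<T <A tnpR> tnpA>"`.
#' @export
render_config <- function(config) {
  stopifnot(inherits(config, "tn_config"))
  toks <- mapply(function(n, s) {
    if (n == "!res!") "!res!" else if (s == "-") paste0("<", n) else paste0(n, ">")
  }, config$names, config$strands)
  paste(toks, collapse = " ")
}

#' Parse a configuration string
#'
#' Inverse of [render_config()]: `parse_config(render_config(x))` equals
#' `x` for every valid configuration.
#'
#' @param text A string of whitespace-separated tokens.
#' @return A `tn_config`.
#' @export
parse_config <- function(text) {
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  if (length(toks) == 0 || identical(toks, ""))
    return(config_string())
  names <- character(length(toks)); strands <- character(length(toks))
  for (i in seq_along(toks)) {
    t <- toks[i]
    if (t == "!res!") { names[i] <- "!res!"; strands[i] <- NA_character_ }
    else if (grepl("^<[^<>]+$", t)) { names[i] <- sub("^<", "", t); strands[i] <- "-" }
    else if (grepl("^[^<>]+>$", t)) { names[i] <- sub(">$", "", t); strands[i] <- "+" }
    else stop("cannot parse configuration token: '", t, "'")
  }
  config_string(names, strands)
}

#' @export
print.tn_config <- function(x, ...) {
  cat(render_config(x), "\n")
  invisible(x)
}

#' Mirror a configuration
#'
#' Reverses token order and flips every strand — the configuration seen
#' when reading the opposite DNA strand. TA order classification is
#' invariant under mirroring.
#'
#' @param config A `tn_config`.
#' @return The mirrored `tn_config`.
#' @export
mirror_config <- function(config) {
  n <- rev(config$names)
  s <- rev(ifelse(is.na(config$strands), NA_character_,
                  ifelse(config$strands == "+", "-", "+")))
  config_string(n, s)
}

#' Classify toxin/antitoxin gene order
#'
#' Considering only the `T` and `A` tokens: `absent` when no TA pair is
#' present; `undetermined` when the two genes lie on opposite strands or
#' when multiple toxin or antitoxin tokens occur (with an explanatory
#' note); otherwise the gene transcribed first (leftmost for a plus-strand
#' pair, rightmost for a minus-strand pair) decides: antitoxin first is
#' the `normal` arrangement, toxin first the `reversed` one.
#'
#' @param config A `tn_config` or a configuration string.
#' @return A character scalar among `normal`, `reversed`, `undetermined`,
#'   `absent`; an attribute `note` explains undetermined calls.
#' @export
classify_ta_order <- function(config) {
  if (is.character(config)) config <- parse_config(config)
  stopifnot(inherits(config, "tn_config"))
  it <- which(config$names == "T"); ia <- which(config$names == "A")
  if (length(it) == 0 && length(ia) == 0) return("absent")
  if (length(it) > 1 || length(ia) > 1) {
    out <- "undetermined"
    attr(out, "note") <- "multiple toxin or antitoxin tokens"
    return(out)
  }
  if (length(it) == 0 || length(ia) == 0) {
    out <- "undetermined"
    attr(out, "note") <- "unpaired toxin or antitoxin"
    return(out)
  }
  st <- config$strands[it]; sa <- config$strands[ia]
  if (st != sa) {
    out <- "undetermined"
    attr(out, "note") <- "toxin and antitoxin on opposite strands"
    return(out)
  }
  first <- if (st == "+") min(it, ia) else max(it, ia)
  if (first == ia) "normal" else "reversed"
}
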