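#' Construct a sequence record
#'
#' The package's in-memory representation of one genome, plasmid or contig:
#' an identifier, free-text description, an uppercase DNA sequence over
#' A/C/G/T/N and an optional feature table. All internal coordinates are
#' 0-based half-open; conversion to 1-based inclusive happens only at the
#' GFF3/GenBank format boundary.
#'
#' @param id Non-empty record identifier.
#' @param sequence DNA string; uppercased on ingest.
#' @param description Optional free-text description.
#' @param source_format `"fasta"` or `"genbank"`.
#' @param features A feature table as returned by [feature_table()]; may be
#'   empty.
#' @return An object of class `tn_seqrecord`.
#' @export
seq_record <- function(id, sequence, description = "",
                       source_format = c("fasta", "genbank"),
                       features = feature_table()) {
  source_format <- match.arg(source_format)
  if (!is.character(id) || length(id) != 1 || !nzchar(id))
    stop("record id must be a non-empty string")
  sequence <- check_dna(sequence)
  features <- validate_features(features, nchar(sequence), id)
  structure(
    list(id = id, description = description, sequence = sequence,
         source_format = source_format, features = features),
    class = "tn_seqrecord")
}

#' @export
print.tn_seqrecord <- function(x, ...) {
  cat(sprintf("<tn_seqrecord> %s (%d bp, %d features)\n",
              x$id, nchar(x$sequence), nrow(x$features)))
  invisible(x)
}

#' Build a feature table
#'
#' A feature table is a `data.frame` with one row per annotated interval:
#' `seq_id`, `start`/`end` (0-based half-open), `strand` (`+`/`-`, or `*`
#' for strandless features such as res subsites), `feature_type`, and an
#' `attributes` list-column of named character vectors.
#'
#' @param seq_id,start,end,strand,feature_type Parallel vectors.
#' @param attributes A list of named character vectors (one per row), or
#'   `NULL` for no attributes.
#' @return A `data.frame` of class `tn_features`.
#' @export
feature_table <- function(seq_id = character(), start = integer(),
                          end = integer(), strand = character(),
                          feature_type = character(), attributes = NULL) {
  n <- length(seq_id)
  if (is.null(attributes)) attributes <- rep(list(character()), n)
  stopifnot(length(start) == n, length(end) == n, length(strand) == n,
            length(feature_type) == n, length(attributes) == n)
  df <- data.frame(seq_id = as.character(seq_id),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand),
                   feature_type = as.character(feature_type),
                   stringsAsFactors = FALSE)
  df$attributes <- attributes
  class(df) <- c("tn_features", "data.frame")
  df
}

validate_features <- function(features, seqlen = NULL, seq_id = NULL) {
  if (is.null(features)) return(feature_table())
  stopifnot(is.data.frame(features))
  if (nrow(features) == 0) return(feature_table())
  if (any(features$start < 0) || any(features$start >= features$end))
    stop("feature coordinates must satisfy 0 <= start < end")
  if (!is.null(seqlen) && any(features$end > seqlen))
    stop("feature end exceeds sequence length")
  if (!all(features$strand %in% c("+", "-", "*")))
    stop("feature strand must be '+', '-' or '*'")
  features
}

#' Read sequences from FASTA or GenBank
#'
#' @param path Path to an existing file.
#' @param format `"fasta"` or `"genbank"`. GenBank feature lines (as written
#'   by [write_genbank()] / the simulator) are carried into the record's
#'   feature table with identical coordinates.
#' @return A list of [seq_record()] objects, in file order.
#' @export
read_sequences <- function(path, format = c("fasta", "genbank")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file does not exist: ", path)
  if (file.size(path) == 0) stop("input file is empty: ", path)
  if (format == "fasta") {
    set <- tryCatch(Biostrings::readDNAStringSet(path),
                    error = function(e) stop("malformed FASTA in ", path,
                                             ": ", conditionMessage(e)))
    if (length(set) == 0) stop("no FASTA records in ", path)
    lapply(seq_along(set), function(i) {
      nm <- names(set)[i]
      id <- sub("\\s.*$", "", nm)
      desc <- sub("^\\S+\\s*", "", nm)
      seq_record(id, as.character(set[[i]]), description = desc,
                 source_format = "fasta")
    })
  } else {
    read_genbank(path)
  }
}

#' Write records to FASTA
#'
#' @param records A list of [seq_record()] objects.
#' @param path Output path.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "tn_seqrecord")) records <- list(records)
  set <- Biostrings::DNAStringSet(vapply(records, `[[`, "", "sequence"))
  names(set) <- vapply(records, function(r)
    trimws(paste(r$id, r$description)), "")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write a feature table as GFF3
#'
#' Internal 0-based half-open coordinates are converted to the 1-based
#' inclusive GFF3 convention; attribute values are escaped by rtracklayer.
#'
#' @param features A [feature_table()].
#' @param path Output path.
#' @export
write_gff3 <- function(features, path) {
  features <- validate_features(features)
  if (nrow(features) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  strand <- ifelse(features$strand == "*", "*", features$strand)
  gr <- GenomicRanges::GRanges(
    seqnames = features$seq_id,
    ranges = IRanges::IRanges(start = features$start + 1L,
                              end = features$end),
    strand = strand)
  gr$type <- features$feature_type
  keys <- unique(unlist(lapply(features$attributes, names)))
  for (k in keys) {
    S4Vectors::mcols(gr)[[k]] <- vapply(features$attributes, function(a)
      if (k %in% names(a)) unname(a[[k]]) else NA_character_, "")
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 file back into a feature table
#'
#' @param path Path to a GFF3 file.
#' @return A [feature_table()] with 0-based half-open coordinates.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0) return(feature_table())
  mc <- as.data.frame(S4Vectors::mcols(gr))
  drop <- intersect(c("source", "type", "score", "phase"), names(mc))
  attr_cols <- setdiff(names(mc), drop)
  attrs <- lapply(seq_len(nrow(mc)), function(i) {
    v <- vapply(attr_cols, function(k) {
      val <- mc[[k]][i]
      if (is.list(val) || inherits(val, "List")) val <- unlist(val)
      if (length(val) == 0 || is.na(val[1])) NA_character_ else
        paste(as.character(val), collapse = ",")
    }, "")
    v[!is.na(v)]
  })
  feature_table(
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    feature_type = as.character(gr$type),
    attributes = attrs)
}

#' Write records as a tab-separated table
#'
#' Emits a header line followed by one row per record, tab-separated,
#' newline-terminated.
#'
#' @param rows A data.frame, or list of named lists.
#' @param path Output path.
#' @param columns Ordered column names; every row must provide each one.
#' @export
write_table_tsv <- function(rows, path, columns = NULL) {
  if (!is.data.frame(rows)) rows <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  if (is.null(rows)) rows <- data.frame()
  if (is.null(columns)) columns <- names(rows)
  missing <- setdiff(columns, names(rows))
  if (length(missing) > 0 && nrow(rows) > 0)
    stop("missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(rows) == 0) {
    writeLines(paste(columns, collapse = "\t"), path)
    return(invisible(path))
  }
  write.table(rows[, columns, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a tab-separated table written by [write_table_tsv()]
#'
#' @param path Input path.
#' @return A data.frame.
#' @export
read_table_tsv <- function(path) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, comment.char = "")
}

# ---- minimal GenBank flat-file support -------------------------------------
# Only what the simulator needs to round-trip: LOCUS/DEFINITION, a FEATURES
# table of simple (possibly complemented) single-interval features with
# string qualifiers, and the ORIGIN sequence block.

#' Write a record as a minimal GenBank flat file
#'
#' Writes LOCUS, DEFINITION, a FEATURES table (single-interval features,
#' `complement()` for minus-strand, string qualifiers from the attribute
#' map) and the ORIGIN sequence. The dialect is the minimal subset needed
#' to round-trip simulator output through [read_sequences()].
#'
#' @param record A [seq_record()].
#' @param path Output path.
#' @export
write_genbank <- function(record, path) {
  stopifnot(inherits(record, "tn_seqrecord"))
  con <- file(path, "w")
  on.exit(close(con))
  len <- nchar(record$sequence)
  writeLines(sprintf("LOCUS       %s %d bp    DNA     linear   UNK",
                     record$id, len), con)
  writeLines(sprintf("DEFINITION  %s",
                     ifelse(nzchar(record$description),
                            record$description, ".")), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  ft <- record$features
  if (nrow(ft) > 0) {
    for (i in seq_len(nrow(ft))) {
      loc <- sprintf("%d..%d", ft$start[i] + 1L, ft$end[i])
      if (ft$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     %-16s%s", ft$feature_type[i], loc), con)
      writeLines(sprintf("                     /strandless=\"%s\"",
                         if (ft$strand[i] == "*") "true" else "false"), con)
      a <- ft$attributes[[i]]
      for (k in names(a))
        writeLines(sprintf("                     /%s=\"%s\"", k, a[[k]]), con)
    }
  }
  writeLines("ORIGIN", con)
  s <- tolower(record$sequence)
  pos <- seq(1, len, by = 60)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59, len))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, paste(groups, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

read_genbank <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("input file is empty: ", path)
  starts <- grep("^LOCUS", lines)
  if (length(starts) == 0) stop("malformed GenBank file (no LOCUS): ", path)
  ends <- grep("^//\\s*$", lines)
  if (length(ends) != length(starts))
    stop("malformed GenBank file (unterminated record): ", path)
  lapply(seq_along(starts), function(k) {
    block <- lines[starts[k]:ends[k]]
    id <- strsplit(trimws(sub("^LOCUS", "", block[1])), "\\s+")[[1]][1]
    defline <- grep("^DEFINITION", block, value = TRUE)
    desc <- if (length(defline)) trimws(sub("^DEFINITION", "", defline[1])) else ""
    if (desc == ".") desc <- ""
    ori <- grep("^ORIGIN", block)
    if (length(ori) == 0) stop("malformed GenBank record (no ORIGIN): ", path)
    seq_lines <- block[(ori[1] + 1):(length(block) - 1)]
    sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    feat_start <- grep("^FEATURES", block)
    features <- feature_table()
    if (length(feat_start) > 0 && ori[1] > feat_start[1] + 1) {
      flines <- block[(feat_start[1] + 1):(ori[1] - 1)]
      is_feat <- grepl("^     \\S", flines)
      idx <- which(is_feat)
      seq_ids <- c(); st <- c(); en <- c(); strand <- c(); type <- c()
      attrs <- list()
      for (j in seq_along(idx)) {
        header <- flines[idx[j]]
        type_j <- sub("^\\s+", "", substr(header, 1, 21))
        type_j <- trimws(type_j)
        loc <- trimws(substr(header, 22, nchar(header)))
        strand_j <- if (grepl("^complement\\(", loc)) "-" else "+"
        nums <- as.integer(strsplit(gsub("[^0-9.]", "", loc), "\\.\\.")[[1]])
        qual_end <- if (j < length(idx)) idx[j + 1] - 1 else length(flines)
        quals <- flines[seq(idx[j] + 1, length.out = max(0, qual_end - idx[j]))]
        a <- character()
        for (q in quals) {
          m <- regmatches(q, regexec("^\\s+/([^=]+)=\"(.*)\"\\s*$", q))[[1]]
          if (length(m) == 3) a[m[2]] <- m[3]
        }
        if ("strandless" %in% names(a)) {
          if (identical(unname(a[["strandless"]]), "true")) strand_j <- "*"
          a <- a[names(a) != "strandless"]
        }
        seq_ids <- c(seq_ids, id); st <- c(st, nums[1] - 1L)
        en <- c(en, nums[2]); strand <- c(strand, strand_j)
        type <- c(type, type_j); attrs[[j]] <- a
      }
      if (length(idx) > 0)
        features <- feature_table(seq_ids, st, en, strand, type, attrs)
    }
    seq_record(id, sequence, description = desc, source_format = "genbank",
               features = features)
  })
}
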