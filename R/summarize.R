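.catalog_columns <- c("toxin_family", "toxin_xref", "toxin_superfamily",
                      "antitoxin_family", "antitoxin_xref",
                      "antitoxin_superfamily", "resolvase_type", "subgroup",
                      "configuration", "transposon_names", "nb")

#' Load a catalog of TA-carrying transposons
#'
#' Reads a TSV with one row per (toxin family, antitoxin, resolvase type,
#' subgroup, configuration) combination: cross-references, the
#' configuration string, a `;`-separated list of transposon names with
#' accessions, and the instance count `nb`. The packaged catalog fixture
#' (`tnta_catalog_path()`) holds the published census of TA systems across
#' Tn3-family transposons. Each row is validated: `nb` must equal the
#' number of listed transposon names and the configuration must parse.
#'
#' @param path TSV path; defaults to the packaged catalog.
#' @return A data.frame of class `tn_catalog` with a `names_list`
#'   list-column of the split transposon names.
#' @export
load_catalog <- function(path = tnta_catalog_path()) {
  df <- read_table_tsv(path)
  missing <- setdiff(.catalog_columns, names(df))
  if (length(missing) > 0)
    stop("catalog lacks column(s): ", paste(missing, collapse = ", "))
  if (nrow(df) == 0) {
    df$names_list <- list()
    class(df) <- c("tn_catalog", "data.frame")
    return(df)
  }
  df$nb <- as.integer(df$nb)
  df$names_list <- lapply(strsplit(df$transposon_names, ";"), trimws)
  for (i in seq_len(nrow(df))) {
    n_names <- length(df$names_list[[i]])
    if (df$nb[i] != n_names)
      stop(sprintf("catalog row %d (%s-%s): nb=%d but %d transposon names",
                   i, df$toxin_family[i], df$antitoxin_family[i],
                   df$nb[i], n_names))
    parse_config(df$configuration[i])  # validates the grammar
    if (df$nb[i] < 1) stop(sprintf("catalog row %d: nb must be >= 1", i))
  }
  class(df) <- c("tn_catalog", "data.frame")
  df
}

#' Path of the packaged catalog fixture
#' @return File path inside the installed package.
#' @export
tnta_catalog_path <- function() {
  system.file("extdata", "table1_catalog.tsv", package = "tnta",
              mustWork = TRUE)
}

#' Aggregate a catalog into summary counts
#'
#' Counts are weighted by `nb` (one row stands for `nb` transposon
#' instances). Antitoxin variant labels are collapsed into families with
#' an explicit merge map before counting: by default the DNA-binding-
#' domain-less ParD variant merges into ParD and the structure-matched HTH
#' into HTH_37 — making the merge visible data keeps the family count
#' auditable. TA gene order is classified from each row's configuration
#' string.
#'
#' @param rows A `tn_catalog`.
#' @param antitoxin_merge Named character vector mapping variant labels to
#'   their parent families.
#' @return A list of class `tn_summary`: `total_instances`,
#'   `n_toxin_families`, `n_antitoxin_families`, `pair_counts` (data.frame
#'   toxin_family, antitoxin_group, n), `n_distinct_pairs`,
#'   `subgroup_counts`, `ta_order_counts`, `reversed_by_subgroup`.
#' @export
aggregate_counts <- function(rows,
                             antitoxin_merge = c("ParD-noDBD" = "ParD",
                                                 "HTH" = "HTH_37")) {
  stopifnot(inherits(rows, "tn_catalog"))
  if (nrow(rows) == 0)
    return(structure(list(total_instances = 0L, n_toxin_families = 0L,
                          n_antitoxin_families = 0L,
                          pair_counts = data.frame(), n_distinct_pairs = 0L,
                          subgroup_counts = integer(),
                          ta_order_counts = integer(),
                          reversed_by_subgroup = integer()),
                     class = "tn_summary"))
  at_group <- rows$antitoxin_family
  hit <- at_group %in% names(antitoxin_merge)
  at_group[hit] <- antitoxin_merge[at_group[hit]]
  ta_order <- vapply(rows$configuration,
                     function(cfg) as.character(classify_ta_order(cfg)), "")
  pair_key <- paste(rows$toxin_family, at_group, sep = "\r")
  pair_counts <- aggregate(rows$nb, by = list(key = pair_key), FUN = sum)
  parts <- strsplit(pair_counts$key, "\r", fixed = TRUE)
  pair_counts <- data.frame(
    toxin_family = vapply(parts, `[`, "", 1),
    antitoxin_group = vapply(parts, `[`, "", 2),
    n = pair_counts$x, stringsAsFactors = FALSE)
  pair_counts <- pair_counts[order(-pair_counts$n, pair_counts$toxin_family), ]
  rownames(pair_counts) <- NULL
  subgroup_counts <- tapply(rows$nb, rows$subgroup, sum)
  ta_order_counts <- tapply(rows$nb, ta_order, sum)
  rev_rows <- ta_order == "reversed"
  reversed_by_subgroup <- if (any(rev_rows))
    tapply(rows$nb[rev_rows], rows$subgroup[rev_rows], sum) else integer()
  structure(list(
    total_instances = sum(rows$nb),
    n_toxin_families = length(unique(rows$toxin_family)),
    n_antitoxin_families = length(unique(at_group)),
    pair_counts = pair_counts,
    n_distinct_pairs = nrow(pair_counts),
    subgroup_counts = as.integer(subgroup_counts) |>
      setNames(names(subgroup_counts)),
    ta_order_counts = as.integer(ta_order_counts) |>
      setNames(names(ta_order_counts)),
    reversed_by_subgroup = as.integer(reversed_by_subgroup) |>
      setNames(names(reversed_by_subgroup))),
    class = "tn_summary")
}

#' @export
print.tn_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "<tn_summary> %d TA-carrying transposon instances\n",
    "  %d toxin families, %d antitoxin families (merged), %d distinct pairs\n"),
    x$total_instances, x$n_toxin_families, x$n_antitoxin_families,
    x$n_distinct_pairs))
  if (nrow(x$pair_counts) > 0) {
    for (i in seq_len(nrow(x$pair_counts)))
      cat(sprintf("    %s-%s: %d\n", x$pair_counts$toxin_family[i],
                  x$pair_counts$antitoxin_group[i], x$pair_counts$n[i]))
  }
  if (length(x$ta_order_counts))
    cat("  TA order:", paste(names(x$ta_order_counts), x$ta_order_counts,
                             collapse = ", "), "\n")
  invisible(x)
}
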