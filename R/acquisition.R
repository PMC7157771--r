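#' Construct a toxin set
#'
#' A toxin set holds the protein sequences of one toxin family: the
#' transposon-associated members plus the unlinked reference (seed)
#' sequences against which acquisition events are counted.
#'
#' @param id Unique sequence identifiers.
#' @param aa_sequence Protein strings.
#' @param origin `"tn_associated"` or `"seed"` per entry.
#' @param family Single family label for the whole set.
#' @return A data.frame of class `tn_toxinset`.
#' @export
toxin_set <- function(id, aa_sequence, origin, family) {
  stopifnot(length(id) == length(aa_sequence),
            length(origin) == length(id), length(family) == 1)
  if (anyDuplicated(id)) stop("duplicate ids in toxin set")
  if (!all(origin %in% c("tn_associated", "seed")))
    stop("origin must be 'tn_associated' or 'seed'")
  df <- data.frame(id = id, aa_sequence = aa_sequence, origin = origin,
                   family = family, stringsAsFactors = FALSE)
  class(df) <- c("tn_toxinset", "data.frame")
  df
}

#' Collapse identical sequences to representatives
#'
#' Exact string duplicates are collapsed; the representative of each group
#' is its lexicographically smallest id and the group size is recorded in
#' the multiplicity map. Invariant under permutation of the input.
#'
#' @param set A `tn_toxinset`.
#' @return A list: `representatives` (a `tn_toxinset` subset, in order of
#'   representative id) and `multiplicity` (named integer vector).
#' @export
dedupe_identical <- function(set) {
  groups <- split(set$id, set$aa_sequence)
  reps <- vapply(groups, function(ids) sort(ids)[1], "")
  mult <- vapply(groups, length, 1L)
  names(mult) <- reps
  ord <- order(reps)
  keep <- set[match(reps[ord], set$id), , drop = FALSE]
  rownames(keep) <- NULL
  class(keep) <- c("tn_toxinset", "data.frame")
  list(representatives = keep, multiplicity = mult[ord])
}

#' Pairwise p-distances between representative proteins
#'
#' Globally aligns every pair (BLOSUM62, affine gaps) and reports the
#' p-distance: mismatched columns over aligned columns, gap columns
#' excluded.
#'
#' @param representatives A `tn_toxinset` (or data.frame with `id` and
#'   `aa_sequence`) of at least 2 entries.
#' @return A symmetric matrix with zero diagonal, dimnames = ids.
#' @export
pairwise_distances <- function(representatives) {
  n <- nrow(representatives)
  if (n < 2) stop("need at least 2 representatives")
  ids <- representatives$id
  seqs <- representatives$aa_sequence
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    pat <- Biostrings::AAStringSet(rep(seqs[i], n - i))
    sub <- Biostrings::AAStringSet(seqs[(i + 1):n])
    aln <- Biostrings::pairwiseAlignment(
      pat, sub, type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5)
    # aligned (non-gap) columns are exactly the match + mismatch columns
    nm <- Biostrings::nmatch(aln); nx <- Biostrings::nmismatch(aln)
    pd <- ifelse(nm + nx == 0, 1, nx / (nm + nx))
    for (k in seq_along(pd)) d[i, i + k] <- d[i + k, i] <- pd[k]
  }
  d
}

#' Build a rooted neighbor-joining tree
#'
#' Neighbor-joining on the distance matrix, rooted on the seed side: when
#' the seed leaves are monophyletic in the unrooted topology the root is
#' placed on the branch separating them, otherwise the tree is rooted at a
#' single (lexicographically first) seed leaf — a position guaranteed to
#' lie outside every transposon-only clade. With no seeds the tree is
#' midpoint rooted.
#'
#' @param dist Symmetric distance matrix, n >= 3, with dimnames.
#' @param origins Optional named vector (id -> `"tn_associated"`/`"seed"`)
#'   used for rooting.
#' @return An [ape::phylo] rooted tree.
#' @export
build_nj_tree <- function(dist, origins = NULL) {
  if (nrow(dist) < 3) stop("neighbor-joining needs at least 3 taxa")
  tr <- ape::nj(as.matrix(dist))
  tr$edge.length[tr$edge.length < 0] <- 0
  seeds <- if (is.null(origins)) character()
  else intersect(sort(names(origins)[origins == "seed"]), tr$tip.label)
  if (length(seeds) >= 1) {
    if (length(seeds) > 1 &&
        ape::is.monophyletic(tr, seeds)) {
      tr <- ape::root(tr, outgroup = seeds, resolve.root = TRUE)
    } else {
      tr <- ape::root(tr, outgroup = seeds[1], resolve.root = TRUE)
    }
  } else {
    tr <- phangorn::midpoint(tr)
  }
  tr
}

#' Count independent acquisition events on a toxin tree
#'
#' An acquisition event is a maximal clade whose leaves are all
#' transposon-associated — equivalently, the minimum number of
#' seed-to-transposon origin transitions under the given rooting.
#'
#' @param tree A rooted [ape::phylo].
#' @param origins Named vector covering every leaf
#'   (`"tn_associated"`/`"seed"`).
#' @return Integer count (0 when no leaf is transposon-associated).
#' @export
count_acquisition_events <- function(tree, origins) {
  tips <- tree$tip.label
  missing <- setdiff(tips, names(origins))
  if (length(missing) > 0)
    stop("unlabeled leaf/leaves: ", paste(missing, collapse = ", "))
  n <- length(tips)
  n_node <- n + tree$Nnode
  all_tn <- logical(n_node)
  all_tn[seq_len(n)] <- origins[tips] == "tn_associated"
  if (!any(all_tn[seq_len(n)])) return(0L)
  edge <- tree$edge
  po <- ape::reorder.phylo(tree, "postorder")$edge
  # internal node is all-tn iff every child subtree is
  agg <- rep(TRUE, n_node)
  agg[seq_len(n)] <- all_tn[seq_len(n)]
  for (i in seq_len(nrow(po))) {
    parent <- po[i, 1]; child <- po[i, 2]
    agg[parent] <- agg[parent] && agg[child]
  }
  parent_of <- rep(NA_integer_, n_node)
  parent_of[edge[, 2]] <- edge[, 1]
  root <- setdiff(edge[, 1], edge[, 2])[1]
  count <- 0L
  for (v in seq_len(n_node)) {
    if (!agg[v]) next
    if (v == root) { count <- 1L; break }
    if (!agg[parent_of[v]]) count <- count + 1L
  }
  count
}

#' Acquisition-event report for a toxin set
#'
#' Dedupe, distance, NJ tree and event count in one call; the per-family
#' line of the TSV report.
#'
#' @param set A `tn_toxinset`.
#' @return A list: `tree`, `representatives`, `multiplicity`, `n_events`,
#'   and a one-row `report` data.frame (family, n_sequences,
#'   n_representatives, n_events).
#' @export
count_events_for_set <- function(set) {
  dd <- dedupe_identical(set)
  reps <- dd$representatives
  if (nrow(reps) < 3) stop("need at least 3 distinct sequences")
  d <- pairwise_distances(reps)
  origins <- setNames(reps$origin, reps$id)
  tr <- build_nj_tree(d, origins)
  k <- count_acquisition_events(tr, origins)
  list(tree = tr, representatives = reps, multiplicity = dd$multiplicity,
       n_events = k,
       report = data.frame(family = set$family[1], n_sequences = nrow(set),
                           n_representatives = nrow(reps), n_events = k,
                           stringsAsFactors = FALSE))
}
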