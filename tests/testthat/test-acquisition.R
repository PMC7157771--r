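test_that("identical sequences collapse to one lexicographically-first representative", {
  s <- random_protein(50)
  ts <- toxin_set(c("TnXc4.2", "TnXc4", "TnXc4.1", "TnXc4.3"),
                  rep(s, 4), rep("tn_associated", 4), "PIN_3")
  dd <- dedupe_identical(ts)
  expect_equal(nrow(dd$representatives), 1)
  expect_equal(dd$representatives$id, "TnXc4")
  expect_equal(unname(dd$multiplicity), 4L)

  set.seed(8)
  distinct <- toxin_set(paste0("t", 1:5),
                        replicate(5, random_protein(40)),
                        rep("tn_associated", 5), "ParE")
  expect_equal(nrow(dedupe_identical(distinct)$representatives), 5)
  perm <- distinct[sample(5), ]
  class(perm) <- class(distinct)
  expect_equal(dedupe_identical(perm)$representatives$id,
               dedupe_identical(distinct)$representatives$id)
})

test_that("p-distances follow the mutation-count oracle", {
  set.seed(9)
  base <- random_protein(100)
  two_off <- strsplit(base, "")[[1]]
  two_off[c(10, 60)] <- ifelse(two_off[c(10, 60)] == "A", "V", "A")
  ts <- toxin_set(c("a", "b", "c"),
                  c(base, base, paste(two_off, collapse = "")),
                  rep("tn_associated", 3), "ParE")
  d <- pairwise_distances(ts)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 0.02)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))

  # recomputation oracle: mutating exactly m of n positions gives m/n
  for (i in 1:5) {
    n <- 80
    m <- sample(5:30, 1)
    v <- strsplit(random_protein(n), "")[[1]]
    w <- v
    idx <- sample(2:n, m)
    for (j in idx) w[j] <- setdiff(c("A", "C", "D", "E"), w[j])[1]
    ts2 <- toxin_set(c("x", "y"), c(paste(v, collapse = ""),
                                    paste(w, collapse = "")),
                     rep("seed", 2), "f")
    expect_equal(pairwise_distances(ts2)["x", "y"], m / n)
  }
})

test_that("neighbor joining recovers additive trees and is permutation-stable", {
  # additive 4-taxon metric from the tree ((a:1,b:2):1,(c:3,d:1):2)
  d <- matrix(0, 4, 4, dimnames = list(c("a", "b", "c", "d"),
                                       c("a", "b", "c", "d")))
  d["a", "b"] <- d["b", "a"] <- 3
  d["a", "c"] <- d["c", "a"] <- 7
  d["a", "d"] <- d["d", "a"] <- 5
  d["b", "c"] <- d["c", "b"] <- 8
  d["b", "d"] <- d["d", "b"] <- 6
  d["c", "d"] <- d["d", "c"] <- 4
  tr <- build_nj_tree(d)
  truth <- ape::read.tree(text = "((a:1,b:2):1,(c:3,d:1):2);")
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(truth)), 0,
               ignore_attr = TRUE)

  expect_error(build_nj_tree(d[1:2, 1:2]), "at least 3")

  set.seed(14)
  ts <- simulate_toxin_origins(3, seed = 77)
  dd <- dedupe_identical(ts)
  dm <- pairwise_distances(dd$representatives)
  ref <- build_nj_tree(dm, setNames(dd$representatives$origin,
                                    dd$representatives$id))
  for (i in 1:20) {
    p <- sample(nrow(dm))
    got <- build_nj_tree(dm[p, p], setNames(dd$representatives$origin,
                                            dd$representatives$id))
    expect_equal(ape::dist.topo(ape::unroot(got), ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("event counting: constructed trees, bounds and duplicate invariance", {
  tr <- ape::read.tree(text = "((t1,t2),(s1,s2));")
  origins <- c(t1 = "tn_associated", t2 = "tn_associated",
               s1 = "seed", s2 = "seed")
  expect_equal(count_acquisition_events(tr, origins), 1L)

  all_seed <- c(t1 = "seed", t2 = "seed", s1 = "seed", s2 = "seed")
  expect_equal(count_acquisition_events(tr, all_seed), 0L)

  tr2 <- ape::read.tree(text = "(((t1,s1),(t2,s2)),s3);")
  origins2 <- c(t1 = "tn_associated", t2 = "tn_associated",
                s1 = "seed", s2 = "seed", s3 = "seed")
  expect_equal(count_acquisition_events(tr2, origins2), 2L)

  expect_error(count_acquisition_events(tr, origins[1:3]), "unlabeled")

  # bounds + collapsing duplicates never changes the count
  set.seed(15)
  for (k in c(2, 4)) {
    ts <- simulate_toxin_origins(k, n_per_origin = 2, seed = 40 + k)
    out <- count_events_for_set(ts)
    n_tn <- sum(ts$origin == "tn_associated")
    expect_gte(out$n_events, 1)
    expect_lte(out$n_events, n_tn)
    dup <- ts[c(seq_len(nrow(ts)), 1), ]
    dup$id[nrow(dup)] <- "dup_of_first"
    class(dup) <- class(ts)
    expect_equal(count_events_for_set(dup)$n_events, out$n_events)
  }
})

test_that("simulated origin counts are recovered through the full path", {
  ok <- 0
  for (r in 1:10) {
    ts <- simulate_toxin_origins(3, divergence = 0.3, seed = 1300 + r)
    if (count_events_for_set(ts)$n_events == 3) ok <- ok + 1
  }
  expect_gte(ok, 9)
  # k singleton origins with one descendant each
  ts <- simulate_toxin_origins(5, n_per_origin = 1, seed = 13)
  expect_equal(count_events_for_set(ts)$n_events, 5)
})
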