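test_that("best-hit selection follows score, identity, then ref id, order-independently", {
  h <- as_hits(make_hit(ref_id = "r1", score = 120),
               make_hit(ref_id = "r2", score = 90))
  expect_equal(select_best_hits(h)$ref_id, "r1")

  h <- as_hits(make_hit(ref_id = "r1", score = 100, identity = 80),
               make_hit(ref_id = "r2", score = 100, identity = 70))
  expect_equal(select_best_hits(h)$ref_id, "r1")

  h <- as_hits(make_hit(ref_id = "zz", score = 100, identity = 80),
               make_hit(ref_id = "aa", score = 100, identity = 80))
  expect_equal(select_best_hits(h)$ref_id, "aa")
  set.seed(3)
  for (i in 1:50) {
    perm <- h[sample(nrow(h)), ]
    class(perm) <- class(h)
    expect_equal(select_best_hits(perm)$ref_id, "aa")
  }
})

test_that("proximity clustering respects the 2 kb gap rule inclusively", {
  h <- as_hits(make_hit(start = 0, end = 500),
               make_hit(start = 2400, end = 3000),
               make_hit(start = 5100, end = 6000))
  loci <- cluster_hits(h, max_gap = 2000)
  expect_length(loci, 2)
  expect_equal(nrow(loci[[1]]$members), 2)   # gap 1900 <= 2000
  expect_equal(nrow(loci[[2]]$members), 1)   # gap 2100 > 2000

  expect_length(cluster_hits(as_hits(make_hit())), 1)
  bad <- as_hits(make_hit(seq_id = "a"), make_hit(seq_id = "b"))
  expect_error(cluster_hits(bad), "single sequence")
})

test_that("clustering equals a union-find oracle on random hit sets", {
  set.seed(5)
  for (i in 1:100) {
    n <- sample(2:12, 1)
    starts <- sample.int(30000, n)
    ends <- starts + sample(100:3000, n, replace = TRUE)
    hits <- do.call(as_hits, lapply(seq_len(n), function(j)
      make_hit(start = starts[j], end = ends[j], ref_id = paste0("r", j))))
    gap <- sample(c(500, 2000, 5000), 1)
    loci <- cluster_hits(hits, max_gap = gap)
    # partition from the implementation
    got <- integer(n)
    for (k in seq_along(loci)) {
      idx <- match(loci[[k]]$members$ref_id, paste0("r", seq_len(n)))
      got[idx] <- k
    }
    want <- cluster_oracle(starts, ends, gap)
    expect_equal(length(unique(got)), length(unique(want)))
    # same partition: co-membership matrices agree
    expect_equal(outer(got, got, "=="), outer(want, want, "=="))
  }
})

test_that("configuration strings render the published arrangements", {
  lc <- make_locus(as_hits(
    make_hit(start = 0, end = 300, strand = "-", role = "toxin"),
    make_hit(start = 360, end = 600, strand = "-", role = "antitoxin"),
    make_hit(start = 700, end = 1200, strand = "+", role = "resolvase_S"),
    make_hit(start = 1300, end = 4000, strand = "+", role = "transposase")))
  expect_equal(render_config(classify_configuration(lc)),
               "<T <A tnpR> tnpA>")

  lc2 <- make_locus(as_hits(
    make_hit(start = 0, end = 300, strand = "-", role = "antitoxin"),
    make_hit(start = 360, end = 600, strand = "-", role = "toxin"),
    make_hit(start = 700, end = 1200, strand = "+", role = "resolvase_S"),
    make_hit(start = 1300, end = 4000, strand = "+", role = "transposase")))
  expect_equal(render_config(classify_configuration(lc2)),
               "<A <T tnpR> tnpA>")

  # res marker between antitoxin and the tyrosine resolvase
  lc3 <- make_locus(as_hits(
    make_hit(start = 0, end = 300, strand = "-", role = "toxin"),
    make_hit(start = 360, end = 600, strand = "-", role = "antitoxin"),
    make_hit(start = 800, end = 1700, strand = "+", role = "resolvase_Y"),
    make_hit(start = 1800, end = 4500, strand = "+", role = "transposase")))
  res <- structure(list(region = c(620, 760)), class = "tn_ressite")
  expect_equal(render_config(classify_configuration(lc3, res = res)),
               "<T <A !res! tnpI> tnpA>")
})

test_that("unclassified ORFs between members render as X tokens", {
  lc <- make_locus(as_hits(
    make_hit(start = 0, end = 300, strand = "-", role = "toxin"),
    make_hit(start = 360, end = 600, strand = "-", role = "antitoxin"),
    make_hit(start = 1300, end = 1800, strand = "+", role = "resolvase_S"),
    make_hit(start = 1900, end = 4000, strand = "+", role = "transposase")))
  orfs <- data.frame(seq_id = "s", start = c(700, 2000), end = c(1000, 2400),
                     strand = c("-", "+"))
  # the first ORF lies between members (X); the second overlaps tnpA (no X)
  expect_equal(render_config(classify_configuration(lc, orfs = orfs)),
               "<T <A <X tnpR> tnpA>")
})

test_that("completeness classification and missing roles", {
  full <- make_locus(as_hits(
    make_hit(role = "toxin", start = 0, end = 300),
    make_hit(role = "antitoxin", start = 400, end = 700),
    make_hit(role = "resolvase_S", start = 800, end = 1300),
    make_hit(role = "transposase", start = 1400, end = 4000)))
  out <- assess_completeness(full)
  expect_equal(out$completeness, "full_with_TA")
  expect_length(out$missing_roles, 0)

  partial <- make_locus(as_hits(make_hit(role = "transposase")))
  out <- assess_completeness(partial)
  expect_equal(out$completeness, "partial")
  expect_setequal(out$missing_roles, c("resolvase", "toxin", "antitoxin"))

  backbone <- make_locus(as_hits(
    make_hit(role = "resolvase_S", start = 800, end = 1300),
    make_hit(role = "transposase", start = 1400, end = 4000)))
  expect_equal(assess_completeness(backbone)$completeness, "full_no_TA")
})

test_that("a planted internal stop in the toxin is flagged truncated_toxin", {
  lib <- test_lib()
  sim <- simulate_transposon(sim_spec(seed = 21, truncate_toxin = TRUE), lib)
  loci <- scan_genome(sim$record, lib)
  expect_length(loci, 1)
  expect_true("truncated_toxin" %in% loci[[1]]$notes)
  # and the fully intact module is not flagged
  sim_ok <- simulate_transposon(sim_spec(seed = 21), lib)
  loci_ok <- scan_genome(sim_ok$record, lib)
  expect_false("truncated_toxin" %in% loci_ok[[1]]$notes)
})

test_that("subgroup propagates from the best transposase hit", {
  lc <- make_locus(as_hits(
    transform(make_hit(role = "transposase", ref_id = "t1", score = 500),
              subgroup = "Tn3000"),
    transform(make_hit(role = "transposase", ref_id = "t2", score = 300,
                       start = 4000, end = 7000), subgroup = "Tn21")))
  expect_equal(assign_subgroup(lc), "Tn3000")
  expect_true(is.na(assign_subgroup(make_locus(as_hits(make_hit())))))
})
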