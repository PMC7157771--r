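test_that("search region extraction follows the divergent and colinear rules", {
  # divergent tnpR (-) / tnpA (+): the full intergenic region
  rec <- seq_record("s", random_dna(3000))
  lc <- make_locus(as_hits(
    make_hit(start = 100, end = 650, strand = "-", role = "resolvase_S"),
    make_hit(start = 900, end = 2500, strand = "+", role = "transposase")))
  reg <- extract_search_region(lc, rec)
  expect_equal(reg$offset, 650)
  expect_equal(nchar(reg$seq), 250)

  # colinear with 1 kb of space: clipped to the 400 bp window
  lc2 <- make_locus(as_hits(
    make_hit(start = 0, end = 200, strand = "+", role = "antitoxin"),
    make_hit(start = 1200, end = 1700, strand = "+", role = "resolvase_S"),
    make_hit(start = 1800, end = 2900, strand = "+", role = "transposase")))
  reg2 <- extract_search_region(lc2, rec)
  expect_equal(reg2$offset, 800)
  expect_equal(nchar(reg2$seq), 400)

  expect_error(extract_search_region(make_locus(as_hits(make_hit())), rec),
               "no resolvase")

  # the planted res site lies inside the extracted region
  sim <- simulate_transposon(sim_spec(seed = 31), test_lib())
  reg3 <- extract_search_region(truth_locus(sim), sim$record)
  planted <- sim$truth[sim$truth$feature_type == "res_site", ]
  expect_lte(reg3$offset, planted$start)
  expect_gte(reg3$offset + nchar(reg3$seq), planted$end)
})

test_that("inverted repeats: constructed palindrome, poly-A null, enumeration oracle", {
  arm <- "GCTAGGCTCA"
  pal <- paste0(arm, "CCCC", revcomp(arm))   # C-loop: extensions mismatch
  motifs <- find_inverted_repeats(pal)
  top <- motifs[1, ]
  expect_equal(top$left_start, 0)
  expect_equal(top$arm_len, 10)
  expect_equal(top$loop_len, 4)
  expect_equal(top$mismatches, 0)
  expect_equal(top$score, 10)
  expect_equal(max(motifs$score), 10)

  expect_equal(nrow(find_inverted_repeats(strrep("A", 60))), 0)
  expect_error(find_inverted_repeats("ACGT"), "shorter")

  set.seed(13)
  for (i in 1:30) {
    s <- random_dna(120)
    got <- find_inverted_repeats(s)
    want <- ir_oracle(s)
    expect_equal(nrow(got), nrow(want))
    key <- function(d) sort(paste(d$left_start, d$arm_len, d$loop_len,
                                  d$mismatches))
    expect_equal(key(got), key(want))
  }
})

test_that("res assembly labels subsites with III proximal to the resolvase", {
  lib <- test_lib()
  sim <- simulate_transposon(sim_spec(seed = 101), lib)
  res <- scan_res_site(truth_locus(sim), sim$record)
  expect_false(is.null(res))
  expect_named(res$subsites, c("I", "II", "III"))
  planted <- sim$truth
  for (nm in c("I", "II", "III")) {
    p <- planted[planted$feature_type == paste0("res_subsite_", nm), ]
    s <- res$subsites[[nm]]
    inter <- max(0, min(p$end, s$right_end) - max(p$start, s$left_start))
    uni <- max(p$end, s$right_end) - min(p$start, s$left_start)
    expect_gte(inter / uni, 0.8)
  }
  cross <- planted[planted$feature_type == "crossover_AT", ]
  expect_equal(res$crossover, cross$start)
  expect_true(res$ta_adjacent)
})

test_that("subsite recovery holds across 100 simulated modules", {
  lib <- test_lib()
  jac_ok <- 0; cross_ok <- 0; n <- 100
  for (i in seq_len(n)) {
    sim <- simulate_transposon(sim_spec(seed = 9000 + i), lib)
    res <- scan_res_site(truth_locus(sim), sim$record)
    if (is.null(res) || length(res$subsites) < 3) next
    planted <- sim$truth
    jac <- vapply(c("I", "II", "III"), function(nm) {
      p <- planted[planted$feature_type == paste0("res_subsite_", nm), ]
      s <- res$subsites[[nm]]
      inter <- max(0, min(p$end, s$right_end) - max(p$start, s$left_start))
      inter / (max(p$end, s$right_end) - min(p$start, s$left_start))
    }, 0)
    if (all(jac >= 0.8)) jac_ok <- jac_ok + 1
    cross <- planted[planted$feature_type == "crossover_AT", ]
    if (!is.na(res$crossover) && res$crossover == cross$start)
      cross_ok <- cross_ok + 1
  }
  expect_equal(jac_ok, n)
  expect_gte(cross_ok / n, 0.95)
})

test_that("res assembly is invariant under motif permutation and reflection", {
  lib <- test_lib()
  sim <- simulate_transposon(sim_spec(seed = 55), lib)
  lc <- truth_locus(sim)
  reg <- extract_search_region(lc, sim$record)
  motifs <- find_inverted_repeats(reg$seq)
  for (col in c("left_start", "left_end", "right_start", "right_end"))
    motifs[[col]] <- motifs[[col]] + reg$offset
  region <- c(reg$offset, reg$offset + nchar(reg$seq))
  ref <- assemble_res_site(motifs, reg$resolvase_start, region,
                           sim$record$sequence)
  set.seed(2)
  for (i in 1:20) {
    shuf <- motifs[sample(nrow(motifs)), ]
    got <- assemble_res_site(shuf, reg$resolvase_start, region,
                             sim$record$sequence)
    expect_equal(got$subsites, ref$subsites)
  }

  # reflection: the mirrored module keeps its subsite labels
  L <- nchar(sim$record$sequence)
  rc_rec <- seq_record("rc", revcomp(sim$record$sequence))
  m <- lc$members
  m2 <- m
  m2$start <- L - m$end; m2$end <- L - m$start
  m2$strand <- ifelse(m$strand == "+", "-", "+")
  m2$seq_id <- "rc"
  rc_locus <- make_locus(as_hits(m2))
  res_rc <- scan_res_site(rc_locus, rc_rec)
  expect_false(is.null(res_rc))
  pI <- sim$truth[sim$truth$feature_type == "res_subsite_I", ]
  sI <- res_rc$subsites[["I"]]
  # mirrored planted subsite I
  mI <- c(L - pI$end, L - pI$start)
  inter <- max(0, min(mI[2], sI$right_end) - max(mI[1], sI$left_start))
  expect_gte(inter / (max(mI[2], sI$right_end) - min(mI[1], sI$left_start)),
             0.8)
})

test_that("crossover location picks the central AT with a leftmost tie-break", {
  siteI <- data.frame(left_start = 0, right_end = 10)
  expect_equal(locate_crossover(siteI, "GGGGATCCCC"), 4)
  # two ATs equidistant from the span center
  siteI <- data.frame(left_start = 0, right_end = 8)
  expect_equal(locate_crossover(siteI, "ATGGGGAT"), 0)
  siteI <- data.frame(left_start = 0, right_end = 8)
  out <- locate_crossover(siteI, "GGGGGGGG")
  expect_true(is.na(out))
  expect_equal(attr(out, "flag"), "no_AT")
})

test_that("TA adjacency is true for canonical modules and false beyond tnpA", {
  lib <- test_lib()
  sim <- simulate_transposon(sim_spec(seed = 61), lib)
  res <- scan_res_site(truth_locus(sim), sim$record)
  expect_true(annotate_ta_adjacency(res, truth_locus(sim)))

  # constructed negative: an unknown gene sits between site I and the TA pair
  lc <- make_locus(as_hits(
    make_hit(start = 0, end = 300, strand = "-", role = "toxin"),
    make_hit(start = 350, end = 650, strand = "-", role = "antitoxin"),
    make_hit(start = 700, end = 950, strand = "+", role = "unknown"),
    make_hit(start = 1100, end = 1600, strand = "+", role = "resolvase_S")))
  fake_res <- structure(list(
    subsites = list(I = data.frame(left_start = 980, right_end = 1010),
                    II = data.frame(left_start = 1015, right_end = 1045),
                    III = data.frame(left_start = 1050, right_end = 1080)),
    region = c(960, 1090), orientation = "right", crossover = 995,
    partial = FALSE, ta_adjacent = NA), class = "tn_ressite")
  expect_false(annotate_ta_adjacency(fake_res, lc))

  no_ta <- make_locus(as_hits(make_hit(role = "resolvase_S")))
  expect_error(annotate_ta_adjacency(fake_res, no_ta), "no TA genes")
})
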