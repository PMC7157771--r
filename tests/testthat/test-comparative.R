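test_that("dot-plot matches: self-comparison diagonal and reverse complement", {
  set.seed(4)
  s <- random_dna(50)
  ml <- dotplot_matches(s, s, wordsize = 10)
  fwd <- ml$matches[ml$matches$strand == "+", ]
  expect_true(all(paste(1:41, 1:41) %in% paste(fwd$posA, fwd$posB)))
  if (!anyDuplicated(substring(s, 1:41, 10:50)))
    expect_equal(nrow(fwd), 41)

  rc <- dotplot_matches(s, revcomp(s), wordsize = 10)
  rev <- rc$matches[rc$matches$strand == "-", ]
  # word at A position i maps to B position n - w + 2 - i on the - strand
  expect_true(all(paste(1:41, 50 - 10 + 2 - (1:41)) %in%
                    paste(rev$posA, rev$posB)))
  expect_error(dotplot_matches("ACGT", s), "at least wordsize")
})

test_that("dot-plot matches equal the brute-force oracle and transpose symmetry", {
  set.seed(11)
  a <- random_dna(60); b <- random_dna(80)
  got <- dotplot_matches(a, b, wordsize = 6)$matches
  want <- dotplot_oracle(a, b, 6)
  key <- function(d) sort(paste(d$posA, d$posB, d$strand))
  expect_equal(key(got), key(want))

  tr <- dotplot_matches(b, a, wordsize = 6)$matches
  expect_equal(key(got), sort(paste(tr$posB, tr$posA, tr$strand)))
})

test_that("identity profiles: identical, mutated and concatenated inputs", {
  set.seed(5)
  s <- random_dna(1500)
  prof <- identity_profile(s, s)
  expect_true(all(prof$identity == 1))
  expect_true(all(diff(prof$centers) > 0))

  mut <- mutate_to_identity(s, 90, "dna", seed = 5)
  prof_m <- identity_profile(s, as.character(mut))
  expect_gte(mean(prof_m$identity), 0.85)
  expect_lte(mean(prof_m$identity), 0.95)

  # A vs A + suffix: all windows over the shared prefix are 1.0
  prof_c <- identity_profile(s, paste0(s, random_dna(500)))
  expect_true(all(prof_c$identity == 1))

  expect_error(identity_profile("ACGTACGT", "ACGTACGT"), "window")
})

test_that("breakpoint detection: flat profiles yield null, short profiles error", {
  flat <- structure(list(window = 100, step = 10,
                         centers = seq(50, 1000, 10),
                         identity = rep(1, 96)), class = "tn_idprofile")
  expect_null(detect_breakpoint(flat))
  flat$identity <- rep(0.5, 96)
  expect_null(detect_breakpoint(flat))
  short <- structure(list(window = 100, step = 10, centers = 1:5,
                          identity = rep(1, 5)), class = "tn_idprofile")
  expect_error(detect_breakpoint(short), "fewer than 10")
})

test_that("planted chimera junctions are recovered within window resolution", {
  lib <- test_lib()
  for (i in 1:3) {
    A <- simulate_transposon(sim_spec(seed = 500 + i, id = "A"), lib)
    B <- mutate_simulated(A, 60, seed = 600 + i, id = "B")
    ch <- simulate_chimera(A, B)
    prof <- identity_profile(ch$record$sequence, A$record$sequence)
    bp <- detect_breakpoint(prof)
    expect_false(is.null(bp))
    expect_lte(abs(bp$position - ch$junction), 100 / 2 + 10)
    expect_gte(bp$left_identity, 0.95)
    expect_lte(bp$right_identity, 0.85)
    expect_true(bp$ci[1] <= bp$position && bp$position <= bp$ci[2])
    res <- scan_res_site(truth_locus(A), A$record)
    bp <- breakpoint_in_res_site(bp, res)
    expect_true(bp$in_res_site_I)
  }
})

test_that("TA module identity: identical, 95%-diverged and unrelated pairs", {
  lib <- test_lib()
  A <- simulate_transposon(sim_spec(seed = 71, id = "A"), lib)
  expect_equal(ta_module_identity(A$record, truth_locus(A),
                                  A$record, truth_locus(A)), 100)
  A2 <- mutate_simulated(A, 95, seed = 72)
  got <- ta_module_identity(A$record, truth_locus(A),
                            A2$record, truth_locus(A2))
  expect_lte(abs(got - 95), 2)
  for (s in 1:3) {
    B <- simulate_transposon(sim_spec(seed = 5000 + s, id = "B",
                                      toxin_family = "Gp49",
                                      antitoxin_family = "HTH_37"), lib)
    expect_lt(ta_module_identity(A$record, truth_locus(A),
                                 B$record, truth_locus(B)), 60)
  }
  no_ta <- make_locus(as_hits(make_hit(role = "transposase")))
  expect_error(ta_module_identity(A$record, no_ta, A$record, no_ta),
               "TA pair")
})
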