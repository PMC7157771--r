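test_that("mutagenesis hits its identity target and is seed-deterministic", {
  set.seed(30)
  s <- random_dna(1000)
  expect_equal(as.character(mutate_to_identity(s, 100, "dna", seed = 1)), s)

  m1 <- mutate_to_identity(s, 90, "dna", seed = 2)
  m2 <- mutate_to_identity(s, 90, "dna", seed = 2)
  expect_identical(as.character(m1), as.character(m2))
  realized <- 100 * mean(strsplit(s, "")[[1]] ==
                           strsplit(as.character(m1), "")[[1]])
  expect_gte(realized, 85)
  expect_lte(realized, 95)

  # identity contract across 200 random specs (direct recount)
  for (i in 1:200) {
    n <- sample(30:400, 1)
    tgt <- runif(1, 20, 100)
    alpha <- sample(c("dna", "protein"), 1)
    x <- if (alpha == "dna") random_dna(n) else random_protein(n)
    y <- mutate_to_identity(x, tgt, alpha)
    real <- 100 * mean(strsplit(x, "")[[1]] ==
                         strsplit(as.character(y), "")[[1]])
    expect_lte(abs(real - tgt), 5)
    expect_equal(real, attr(y, "realized_identity"))
  }
  expect_error(mutate_to_identity("ACGT", 10, "dna"), ">= 20")
})

test_that("simulated modules are recovered exactly and are bit-reproducible", {
  lib <- test_lib()
  sim <- simulate_transposon(sim_spec(seed = 3), lib)
  loci <- scan_genome(sim$record, lib)
  expect_length(loci, 1)
  expect_equal(render_config(loci[[1]]$configuration), "<T <A tnpR> tnpA>")
  expect_equal(loci[[1]]$completeness, "full_with_TA")

  sim2 <- simulate_transposon(sim_spec(seed = 3), lib)
  expect_identical(sim$record$sequence, sim2$record$sequence)
  expect_identical(sim$truth, sim2$truth)

  expect_error(sim_spec(configuration = "T> A>", seed = 1),
               "no resolvase")
  expect_error(sim_spec(seed = 1, identities = 150), "identities")

  # realized protein identities stay within the contract
  sim70 <- simulate_transposon(sim_spec(seed = 4, identities = 70), lib)
  expect_true(all(abs(sim70$realized_identities - 70) <= 5))
})

test_that("genome simulation embeds modules with shifted truth and respects space", {
  lib <- test_lib()
  g <- simulate_genome(list(sim_spec(seed = 41, id = "m1"),
                            sim_spec(seed = 42, id = "m2")),
                       background_length = 25000, seed = 40, lib = lib)
  expect_equal(length(g$modules), 2)
  genes <- g$truth[g$truth$feature_type == "toxin", ]
  expect_equal(nrow(genes), 2)
  # planted gene sequences appear verbatim at the shifted coordinates
  for (i in seq_len(nrow(genes))) {
    sub <- substr(g$record$sequence, genes$start[i] + 1, genes$end[i])
    expect_equal(nchar(sub), genes$end[i] - genes$start[i])
  }
  loci <- scan_genome(g$record, lib)
  expect_length(loci, 2)

  expect_error(simulate_genome(list(sim_spec(seed = 1, id = "a"),
                                    sim_spec(seed = 2, id = "b")),
                               background_length = 2500, seed = 3,
                               lib = lib),
               "insufficient space")
})

test_that("a reverse-complemented genome yields the mirrored configurations", {
  lib <- test_lib()
  g <- simulate_genome(list(sim_spec(seed = 51, identities = 85, id = "m")),
                       background_length = 12000, seed = 50, lib = lib)
  loci <- scan_genome(g$record, lib)
  rc <- seq_record("rc", revcomp(g$record$sequence))
  loci_rc <- scan_genome(rc, lib)
  expect_length(loci_rc, length(loci))
  expect_equal(render_config(loci_rc[[1]]$configuration),
               render_config(mirror_config(loci[[1]]$configuration)))
  expect_equal(loci_rc[[1]]$ta_order, loci[[1]]$ta_order)
})

test_that("chimera construction: self-join is seamless, custom junctions recorded", {
  lib <- test_lib()
  A <- simulate_transposon(sim_spec(seed = 61, id = "A"), lib)
  self <- simulate_chimera(A, A)
  expect_identical(self$record$sequence, A$record$sequence)
  prof <- identity_profile(self$record$sequence, A$record$sequence)
  expect_null(detect_breakpoint(prof))

  B <- mutate_simulated(A, 60, seed = 62, id = "B")
  custom <- simulate_chimera(A, B, junction = 1200)
  expect_equal(custom$junction, 1200)
  expect_identical(substr(custom$record$sequence, 1, 1200),
                   substr(A$record$sequence, 1, 1200))
  expect_identical(substr(custom$record$sequence, 1201, 1300),
                   substr(B$record$sequence, 1201, 1300))

  no_cross <- simulate_transposon(sim_spec(seed = 63, plant_res = FALSE),
                                  lib)
  expect_error(simulate_chimera(no_cross, A), "crossover")
})

test_that("toxin-origin simulation spans the k=1 pipeline case", {
  ts <- simulate_toxin_origins(1, seed = 70)
  expect_s3_class(ts, "tn_toxinset")
  expect_equal(sum(ts$origin == "tn_associated"), 3)
  expect_equal(count_events_for_set(ts)$n_events, 1)
})
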