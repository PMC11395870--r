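test_that("event dosage follows 1 -/+ ff/2 with partial-window scaling", {
  w <- tiny_windows(10, len = 1e6)
  del <- list(list(type = "het_del", chrom = "chr1", start = 4e6,
                   end = 6e6))
  d <- nipscnv:::event_dosage(w, del, ff = 0.2, sex = "female")
  expect_equal(d[5:6], c(0.9, 0.9))
  expect_equal(d[-(5:6)], rep(1, 8))

  dup <- list(list(type = "het_dup", chrom = "chr1", start = 0,
                   end = 1e6))
  expect_equal(nipscnv:::event_dosage(w, dup, 0.2, "female")[1], 1.1)

  # half-overlapped window gets half the dosage shift
  half <- list(list(type = "het_del", chrom = "chr1", start = 4.5e6,
                    end = 6e6))
  expect_equal(nipscnv:::event_dosage(w, half, 0.2, "female")[5], 0.95)

  tri <- list(list(type = "trisomy", chrom = "chr1"))
  expect_equal(nipscnv:::event_dosage(w, tri, 0.2, "female"),
               rep(1.1, 10))
})

test_that("a trisomy shifts per-window expectations by 1 + ff/2", {
  cfg <- sim_config(genome = synthetic_genome("macro"), n_samples = 1,
                    gc_bias = gc_bias_spec("none"), seed = 2,
                    depth = list(mean = 8e6, sd = 0))
  set.seed(2)
  reps <- replicate(40, {
    r <- simulate_sample(cfg, ff = 0.2, sex = "female", depth = 8e6,
                         events = list(list(type = "trisomy",
                                            chrom = "chrA4")))
    w <- cfg$windows
    a4 <- w$chrom == "chrA4"
    a1 <- w$chrom == "chrA1"
    sum(r$counts$raw[a4]) / sum(w$expected_unique[a4]) /
      (sum(r$counts$raw[a1]) / sum(w$expected_unique[a1]))
  })
  expect_equal(mean(reps), 1.1, tolerance = 0.01)
})

test_that("cohorts are reproducible and respect the truncation range", {
  cfg <- sim_config(genome = synthetic_genome("macro"), n_samples = 10,
                    seed = 33)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(lapply(a$samples, function(s) s$raw),
                   lapply(b$samples, function(s) s$raw))
  expect_identical(a$truth, b$truth)

  set.seed(1)
  fm <- ff_model("post_enrichment")
  draws <- fm$draw(2000)
  expect_true(all(draws >= 0.0757 & draws <= 0.3554))
  expect_lt(abs(mean(draws) - 0.1932), 0.004)
  expect_lt(abs(sd(draws) - 0.0604), 0.004)

  fp <- ff_model("pre_enrichment")
  dp <- fp$draw(2000)
  expect_true(all(dp >= 0.0353 & dp <= 0.2894))
  expect_lt(abs(mean(dp) - 0.0944), 0.003)
})

test_that("cohort fetal fractions match the generating mean", {
  cfg <- sim_config(genome = synthetic_genome("macro"), n_samples = 200,
                    seed = 44)
  coh <- simulate_cohort(cfg)
  se <- 0.0604 / sqrt(200)
  expect_lt(abs(mean(coh$truth$ff) - 0.1932), 3 * se)
})

test_that("per-window means follow the generative law of large numbers", {
  w <- tiny_windows(20, len = 1e6,
                    gc = seq(0.35, 0.5, length.out = 20))
  cfg <- sim_config(windows = w, n_samples = 1,
                    depth = list(mean = 2e5, sd = 0),
                    gc_bias = gc_bias_spec("quadratic", peak = 0.4,
                                           strength = 8),
                    fetal_sex_ratio = 0, seed = 55)
  set.seed(55)
  sims <- replicate(500, simulate_sample(cfg, ff = 0.1, sex = "female",
                                         depth = 2e5)$counts$raw)
  emp <- rowMeans(sims)
  bias <- cfg$gc_bias$fun(w$gc)
  # female background chrY reads (~b_female * depth = 20) leave the windows
  expected <- (2e5 - ff_baselines()$b_female * 2e5) * bias / sum(bias)
  expect_true(all(abs(emp - expected) / expected < 0.03))
})

test_that("degenerate simulation requests error out", {
  expect_error(simulate_cohort(sim_config(
    genome = synthetic_genome("macro"), n_samples = 1, seed = 1,
    events = list(list(sample = 1, type = "het_del", chrom = "chr9",
                       start = 0, end = 1e6)))), "chrom")
  expect_error(sim_config(genome = synthetic_genome("macro"),
                          events = list(list(sample = 1, type = "het_del",
                                             chrom = "chrA1", start = 0,
                                             end = 9e9))),
               "outside genome bounds")
  cfg <- sim_config(genome = synthetic_genome("macro"), n_samples = 5)
  cfg$n_samples <- 0
  expect_error(simulate_cohort(cfg), "n_samples")
})

test_that("male fetuses carry chrY reads linear in fetal fraction", {
  cfg <- sim_config(genome = synthetic_genome("macro"), n_samples = 1,
                    depth = list(mean = 5e6, sd = 0), seed = 66)
  set.seed(66)
  ry <- vapply(c(0.05, 0.15, 0.25), function(f) {
    r <- simulate_sample(cfg, ff = f, sex = "male", depth = 5e6)
    r$counts$chrY_reads / r$counts$total_unique_reads
  }, numeric(1))
  bl <- ff_baselines()
  expected <- bl$b_female + c(0.05, 0.15, 0.25) *
    (bl$b_male_adult - bl$b_female)
  expect_equal(ry, expected, tolerance = 0.1)
  rf <- simulate_sample(cfg, ff = 0.2, sex = "female", depth = 5e6)
  expect_lt(rf$counts$chrY_reads / rf$counts$total_unique_reads, 2e-4)
  # chrY window counts agree with the chrY read tally
  wy <- cfg$windows$chrom == "chrY"
  expect_equal(sum(rf$counts$raw[wy]), rf$counts$chrY_reads)
})
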