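test_that("batch statistics match hand arithmetic and guard degeneracy", {
  corr <- list(crn_stub(100, "a"), crn_stub(110, "b"), crn_stub(120, "c"))
  st <- batch_stats(corr, force = TRUE, normalize = FALSE)
  expect_equal(st$mean, 110)
  expect_equal(st$sd, 10)  # n-1 denominator
  z <- z_scores("a", st, loo = FALSE)
  expect_equal(z$z, -1.0)
  zb <- z_scores("b", st, loo = FALSE)
  expect_equal(zb$z, 0)

  # identical samples -> SD 0 -> window unusable, z missing
  same <- lapply(1:8, function(i) crn_stub(c(100, 200), paste0("s", i)))
  st0 <- batch_stats(same, normalize = FALSE)
  expect_false(any(st0$usable))
  expect_true(all(is.na(z_scores("s1", st0)$z)))

  expect_error(batch_stats(list(crn_stub(100))), "fewer than 8")
  expect_error(batch_stats(list(crn_stub(100)), force = TRUE),
               "at least 2")
})

test_that("leave-one-out z-scores exclude the scored sample", {
  set.seed(21)
  corr <- lapply(1:10, function(i)
    crn_stub(rnorm(50, 1000, 30), paste0("s", i)))
  st <- batch_stats(corr, normalize = FALSE)
  z <- z_scores("s3", st)
  x <- corr[[3]]$crn
  others <- vapply(corr[-3], function(s) s$crn, numeric(50))
  manual <- (x - rowMeans(others)) / apply(others, 1, sd)
  expect_equal(z$z, manual, tolerance = 1e-10)
})

test_that("discretisation boundaries assign to the outer bin", {
  cuts <- c(-4, -2.5, 2.5, 4)
  expect_equal(as.character(discretize(-4.3, cuts)), "S--")
  expect_equal(as.character(discretize(0, cuts)), "S0")
  expect_equal(as.character(discretize(-2.5, cuts)), "S-")
  expect_equal(as.character(discretize(-4, cuts)), "S--")
  expect_equal(as.character(discretize(2.5, cuts)), "S+")
  expect_equal(as.character(discretize(4, cuts)), "S++")
  s <- discretize(c(NA, 5), cuts)
  expect_equal(as.character(s), c("S0", "S++"))
  expect_equal(attr(s, "mask"), c(TRUE, FALSE))
  expect_error(discretize(0, cuts = c(1, 1, 2, 3)), "increasing")
})

test_that("viterbi decodes canonical sequences and breaks ties to neutral", {
  p <- hmm_params()
  expect_equal(viterbi(rep("S0", 5), p), rep("neutral", 5))
  seq5 <- c("S0", "S3-", "S3-", "S0", "S0")
  expect_equal(viterbi(seq5, p), bf_viterbi(seq5, p))
  expect_equal(viterbi(seq5, p),
               c("neutral", "loss", "loss", "neutral", "neutral"))
  gain5 <- c("S0", "S3+", "S3+", "S3+", "S0")
  expect_equal(viterbi(gain5, p), bf_viterbi(gain5, p))

  # spec-classic 5-symbol parameterisation, checked against enumeration
  p5 <- hmm_params(cuts = c(-4, -2.5, 2.5, 4),
                   emission = rbind(
                     loss = c(0.45, 0.35, 0.18, 0.01, 0.01),
                     neutral = diff(pnorm(c(-Inf, -4, -2.5, 2.5, 4, Inf))),
                     gain = c(0.01, 0.01, 0.18, 0.35, 0.45)))
  seq5b <- c("S0", "S--", "S--", "S0", "S0")
  expect_equal(viterbi(seq5b, p5), bf_viterbi(seq5b, p5))
  expect_equal(viterbi(seq5b, p5),
               c("neutral", "loss", "loss", "neutral", "neutral"))

  # uniform parameters make every path equally likely: prefer neutral
  k <- 7
  pu <- hmm_params(emission = matrix(1 / k, 3, k),
                   transition = matrix(1 / 3, 3, 3),
                   initial = rep(1 / 3, 3))
  expect_equal(viterbi(c("S3-", "S0", "S3+"), pu), rep("neutral", 3))

  pz <- hmm_params(emission = rbind(loss = c(0.5, 0.5, 0, 0, 0, 0, 0),
                                    neutral = c(0, 0, 0.5, 0.5, 0, 0, 0),
                                    gain = c(0, 0, 0, 0, 0, 0.5, 0.5)))
  expect_error(viterbi(c("S0", "S1+"), pz), "impossible emission")
  expect_error(viterbi("nope", hmm_params()), "alphabet")
})

test_that("viterbi equals brute-force enumeration on random instances", {
  set.seed(99)
  for (case in 1:200) {
    p <- random_hmm_params()
    n <- sample(1:8, 1)
    symbols <- sample(p$symbols, n, replace = TRUE)
    expect_equal(viterbi(symbols, p), bf_viterbi(symbols, p),
                 info = paste("case", case))
  }
})

test_that("segments take window-aligned coordinates and drop weak runs", {
  w <- tiny_windows(4, len = 1e6)
  path <- c("neutral", "loss", "loss", "neutral")
  segs <- segment_calls(path, c(0, -5, -5, 0), w)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$start, 1e6)
  expect_equal(segs$end, 3e6)
  expect_equal(segs$size_mb, 2.00)
  expect_equal(segs$n_windows, 2)
  expect_equal(segs$size_bp, segs$end - segs$start)

  expect_equal(nrow(segment_calls(rep("neutral", 4), c(0, 0, 0, 0), w)), 0)

  # a run with weak evidence (mean z -2) is filtered out
  weak <- segment_calls(path, c(0, -2, -2, 0), w)
  expect_equal(nrow(weak), 0)
})

test_that("syndrome matching needs state agreement and enough overlap", {
  catalog <- read_syndrome_catalog()
  ws <- catalog[catalog$chrom == "chr7", ]
  seg <- function(start, end, state)
    structure(data.frame(chrom = "chr7", start = start, end = end,
                         state = state, n_windows = 2, mean_z = -4,
                         seg_score = -5.7, size_bp = end - start,
                         size_mb = round((end - start) / 1e6, 2)),
              genome_build = "GRCh37")
  hit <- match_syndromes(seg(72.6e6, 74.3e6, "loss"), catalog)
  expect_equal(hit$classification, "pathogenic_match")
  expect_equal(hit$syndrome, "Williams-Beuren (7q11.23)")
  expect_equal(hit$overlap_fraction, 1.0)

  # a gain over a loss region does not match
  expect_equal(match_syndromes(seg(72.6e6, 74.3e6, "gain"),
                               catalog)$classification, "unmatched")
  # 30% coverage of the region is below the 0.5 floor
  small <- seg(ws$start, ws$start + 0.3 * (ws$end - ws$start), "loss")
  expect_equal(match_syndromes(small, catalog)$classification, "unmatched")

  bad <- seg(72.6e6, 74.3e6, "loss")
  attr(bad, "genome_build") <- "GRCh38"
  expect_error(match_syndromes(bad, catalog), "build mismatch")
})

test_that("null batch z-profiles are standardised per window", {
  cfg <- sim_config(genome = synthetic_genome("macro"), n_samples = 50,
                    seed = 31)
  coh <- simulate_cohort(cfg)
  corr <- lapply(coh$samples, gc_correct, windows = coh$windows)
  st <- batch_stats(corr)
  Z <- vapply(names(coh$samples), function(id) z_scores(id, st)$z,
              numeric(nrow(coh$windows)))
  aut <- coh$windows$chrom %in% paste0("chrA", 1:4) & st$usable
  per_window_mean <- rowMeans(Z[aut, ])
  per_window_sd <- apply(Z[aut, ], 1, sd)
  expect_lt(abs(mean(per_window_mean)), 0.1)
  expect_lt(abs(mean(per_window_sd) - 1), 0.15)
})
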