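test_that("ISCN strings reproduce the microarray report format", {
  seg <- data.frame(chrom = "chr7", start = 72669480, end = 74154209,
                    state = "loss")
  expect_equal(format_iscn(seg),
               "arr[GRCh37] 7q11.23(72,669,481_74,154,209)x1")
  seg$state <- "gain"
  expect_equal(format_iscn(seg),
               "arr[GRCh37] 7q11.23(72,669,481_74,154,209)x3")
  seg$state <- "loss"
  expect_equal(format_iscn(seg, cytobands = NULL),
               "arr[GRCh37] chr7:72,669,481_74,154,209x1")
  # off-table region falls back to chr:start_end
  far <- data.frame(chrom = "chr7", start = 10e6, end = 11e6,
                    state = "loss")
  expect_match(format_iscn(far), "chr7:10,000,001_11,000,000x1",
               fixed = TRUE)
})

test_that("ISCN strings parse back to sizes at 2 decimal places", {
  p1 <- parse_iscn("arr[GRCh37] 7q11.23(72,669,481_74,154,209)x1")
  expect_equal(p1$size_mb, 1.48)
  expect_equal(p1$copy, 1L)
  expect_equal(p1$chrom, "7")
  expect_equal(p1$build, "GRCh37")
  p2 <- parse_iscn("arr[GRCh37] 7q11.23 (72,664,089_74,154,209)x1")
  expect_equal(p2$size_mb, 1.49)
  p3 <- parse_iscn("arr[GRCh37] chr7:72,669,481_74,154,209x1")
  expect_equal(p3$size_bp, p1$size_bp)
  expect_error(parse_iscn("nonsense"), "cannot parse")
})

test_that("cohort fetal-fraction summaries behave like the enrichment table", {
  set.seed(9)
  g <- rnorm(100, 10, 2)
  same <- cohort_ff_summary(g, g)
  expect_equal(same$test$p.value, 1)
  expect_equal(unname(same$test$statistic), 0)
  expect_equal(same$table$p50, rep(median(g), 2))

  pre <- 100 * ff_model("pre_enrichment")$draw(1000)
  post <- 100 * ff_model("post_enrichment")$draw(1000)
  cmp <- cohort_ff_summary(pre, post, c("pre", "post"))
  expect_lt(cmp$test$p.value, 0.001)
  expect_gt(cmp$table$mean[2], cmp$table$mean[1])

  expect_error(cohort_ff_summary(1, g), "degenerate")
  expect_error(cohort_ff_summary(rep(1, 5), g), "degenerate")
})

test_that("screen results survive a JSON round trip", {
  co <- small_cohort(10, n_windows = 120, depth = 6e6, seed = 19)
  scr <- screen_cohort(co$samples, co$windows)
  r <- scr$results[[1]]
  path <- tempfile(fileext = ".json")
  write_screen_json(r, path)
  back <- read_screen_json(path)
  expect_equal(back$sample_id, r$sample_id)
  expect_equal(back$status, r$status)
  expect_equal(back$ff$ff, r$ff$ff)
  expect_equal(back$ff$method, r$ff$method)
  expect_equal(back$ff$qc_pass, r$ff$qc_pass)
  expect_equal(unname(back$aneuploidy$z), unname(r$aneuploidy$z))
  expect_equal(back$aneuploidy$status, r$aneuploidy$status)
  expect_equal(back$segments[names(back$segments) != "row.names"],
               r$segments[names(r$segments) != "row.names"],
               ignore_attr = TRUE)
  expect_equal(back$risk_labels, r$risk_labels)
})

test_that("config hashes change iff an effective parameter changes", {
  a <- screen_config()
  b <- screen_config()
  expect_identical(config_hash(a), config_hash(b))
  c <- screen_config(z_threshold = 3.5)
  expect_false(identical(config_hash(a), config_hash(c)))
  d <- screen_config(qc = qc_thresholds(min_ff = 0.04))
  expect_false(identical(config_hash(a), config_hash(d)))
})

test_that("the pipeline runs end to end from a YAML config", {
  dir <- tempfile("run")
  dir.create(dir)
  cfg <- sim_config(genome = synthetic_genome("ws"),
                    target_avg_len = 4e6, n_samples = 10,
                    depth = list(mean = 6e6, sd = 3e5), seed = 77)
  coh <- simulate_cohort(cfg)
  write_window_map(coh$windows, file.path(dir, "windows.tsv"))
  write_counts(coh$samples, file.path(dir, "counts.tsv"))
  yml <- file.path(dir, "run.yaml")
  writeLines(c(sprintf("windows: %s", file.path(dir, "windows.tsv")),
               sprintf("counts: %s", file.path(dir, "counts.tsv")),
               sprintf("out_dir: %s", file.path(dir, "out")),
               "seed: 5"), yml)
  scr <- run_pipeline(yml)
  expect_s3_class(scr, "nips_screen")
  expect_true(file.exists(file.path(dir, "out", "cohort.tsv")))
  expect_true(file.exists(file.path(dir, "out", "segments.bed")))
  expect_true(file.exists(file.path(dir, "out", "run.log")))
  expect_true(file.exists(file.path(dir, "out", "sample_s001.json")))
  first <- readLines(file.path(dir, "out", "cohort.tsv"))
  # rerunning the same configuration is byte-identical
  run_pipeline(yml)
  expect_identical(readLines(file.path(dir, "out", "cohort.tsv")), first)

  # missing paths fail validation before any compute
  writeLines(c("windows: /nonexistent/w.tsv",
               sprintf("counts: %s", file.path(dir, "counts.tsv"))),
             file.path(dir, "bad.yaml"))
  expect_error(run_pipeline(file.path(dir, "bad.yaml")), "does not exist")
  writeLines("out_dir: x", file.path(dir, "bad2.yaml"))
  expect_error(run_pipeline(file.path(dir, "bad2.yaml")),
               "missing required path")
})

test_that("euploid samples screen clean and QC failures become no-calls", {
  cfg <- sim_config(genome = synthetic_genome("ws"), target_avg_len = 4e6,
                    n_samples = 12, seed = 88)
  coh <- simulate_cohort(cfg)
  # depress one sample's depth below the QC floor
  low <- coh$samples[[3]]
  low$raw <- rbinom(length(low$raw), low$raw, 0.3)
  low$total_unique_reads <- sum(low$raw)
  low$chrY_reads <- round(low$chrY_reads * 0.3)
  coh$samples[[3]] <- low
  expect_warning(scr <- screen_cohort(coh$samples, coh$windows),
                 "failed QC")
  expect_equal(scr$results[[3]]$status, "no-call")
  expect_equal(nrow(scr$results[[3]]$segments), 0)
  pos <- vapply(scr$results, function(r) length(r$risk_labels) > 0,
                logical(1))
  expect_equal(sum(pos), 0)
  s <- summary(scr)
  expect_equal(nrow(s), 12)
  expect_true(all(s$risk[pos == FALSE] == "low risk"))
})

test_that("a case-parameter deletion screens high risk for WS", {
  hits <- vapply(1:3, function(seed) {
    cfg <- sim_config(
      genome = synthetic_genome("ws"), target_avg_len = 8.8e5,
      n_samples = 30,
      events = list(list(sample = 1, type = "het_del", chrom = "chr7",
                         start = 73040000, end = 74800000, ff = 0.15,
                         depth = 9.95e6, sex = "male")),
      seed = seed)
    coh <- simulate_cohort(cfg)
    scr <- screen_cohort(coh$samples, coh$windows)
    any(grepl("Williams", scr$results[["s001"]]$risk_labels))
  }, logical(1))
  # detection at fetal fraction 15% / 9.95 M unique reads is not certain
  # window-by-window, but succeeds in the clear majority of lots
  expect_gte(sum(hits), 2)
})
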