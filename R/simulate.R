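# Synthetic cohort generator. Emulates the generative structure the
# screening pipeline assumes: per-window unique-read counts with Poisson
# noise (optional overdispersion), a smooth GC-bias curve, fetal fractions
# drawn from truncated-normal cohort distributions matching the study's
# pre-/post-enrichment summaries, fetal CNV dosage (1 -/+ ff/2 for
# heterozygous deletions/duplications, 1 + ff/2 for trisomies) and a chrY
# read proportion linear in fetal fraction for male fetuses. Enrichment is
# modelled purely as the shift between the two fetal-fraction
# distributions; fragment-length physics is deliberately not simulated.

# Truncated-normal moments for underlying (mu, sigma) and bounds.
truncnorm_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  Z <- stats::pnorm(b) - stats::pnorm(a)
  fa <- stats::dnorm(a); fb <- stats::dnorm(b)
  m <- mu + sigma * (fa - fb) / Z
  v <- sigma^2 * (1 + (a * fa - b * fb) / Z - ((fa - fb) / Z)^2)
  c(mean = m, sd = sqrt(v))
}

# Solve for underlying (mu, sigma) such that the truncated distribution has
# the requested mean and SD (the printed cohort summaries describe the
# truncated distribution, not the latent one).
calibrate_truncnorm <- function(mean, sd, lo, hi) {
  obj <- function(p) {
    mm <- truncnorm_moments(p[1], exp(p[2]), lo, hi)
    (mm[1] - mean)^2 + (mm[2] - sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 5000))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

rtruncnorm <- function(n, mu, sigma, lo, hi) {
  plo <- stats::pnorm(lo, mu, sigma)
  phi <- stats::pnorm(hi, mu, sigma)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mu, sigma)
}

#' Cohort fetal-fraction model
#'
#' Truncated-normal fetal-fraction distributions. The two presets match the
#' study cohort summaries: pre-enrichment mean 9.44%, SD 4.03%, truncated at
#' the printed 1st/99th percentiles (3.53%, 28.94%); post-enrichment mean
#' 19.32%, SD 6.04%, truncated at (7.57%, 35.54%). The underlying normal
#' parameters are moment-matched so the *truncated* distribution reproduces
#' the printed mean and SD.
#'
#' @param mode `"post_enrichment"`, `"pre_enrichment"` or `"fixed"`.
#' @param mean,sd,range target truncated mean/SD and truncation range (as
#'   fractions); defaults come from the preset.
#' @param value fetal fraction for `mode = "fixed"`.
#' @return An `ff_model` with a `draw(n)` sampler.
#' @export
ff_model <- function(mode = c("post_enrichment", "pre_enrichment", "fixed"),
                     mean = NULL, sd = NULL, range = NULL, value = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    stopifnot(!is.null(value), value >= 0, value <= 1)
    return(structure(list(mode = mode, value = value,
                          draw = function(n) rep(value, n)),
                     class = "ff_model"))
  }
  preset <- switch(mode,
    pre_enrichment  = list(mean = 0.0944, sd = 0.0403,
                           range = c(0.0353, 0.2894)),
    post_enrichment = list(mean = 0.1932, sd = 0.0604,
                           range = c(0.0757, 0.3554)))
  mean <- mean %||% preset$mean
  sd <- sd %||% preset$sd
  range <- range %||% preset$range
  stopifnot(range[1] >= 0, range[2] <= 1, range[1] < range[2])
  cal <- calibrate_truncnorm(mean, sd, range[1], range[2])
  structure(list(mode = mode, mean = mean, sd = sd, range = range,
                 mu = unname(cal["mu"]), sigma = unname(cal["sigma"]),
                 draw = function(n)
                   rtruncnorm(n, cal["mu"], cal["sigma"], range[1],
                              range[2])),
            class = "ff_model")
}

#' GC-bias curve specification
#'
#' @param type `"none"` or `"quadratic"` (a smooth dip away from the peak
#'   GC, mimicking PCR under-representation of GC-poor and GC-rich windows).
#' @param peak GC at maximum representation (default 0.40).
#' @param strength curvature; the default 8 depresses windows at the GC
#'   extremes of the synthetic genome (~0.33/0.51) by roughly 5-10%.
#' @return A `gc_bias_spec` with a `fun(gc)` multiplier.
#' @export
gc_bias_spec <- function(type = c("quadratic", "none"), peak = 0.40,
                         strength = 8) {
  type <- match.arg(type)
  fun <- if (type == "none") function(gc) rep(1, length(gc))
         else function(gc) pmax(0.1, 1 - strength * (gc - peak)^2)
  structure(list(type = type, peak = peak, strength = strength, fun = fun),
            class = "gc_bias_spec")
}

#' Simulation configuration
#'
#' @param windows a `window_map`; built from `genome` at `target_avg_len`
#'   when `NULL`.
#' @param genome a genome spec (default [synthetic_genome()] `"macro"`).
#' @param target_avg_len window size target when building windows.
#' @param n_samples cohort size.
#' @param depth total unique reads per sample: `list(mean, sd)` (default
#'   10 M +/- 1 M, the laboratory-scale average).
#' @param ff an [ff_model()] (default post-enrichment).
#' @param gc_bias a [gc_bias_spec()].
#' @param events list of spiked events; each is a list with `sample` (index
#'   or `"random"`), `type` (`"het_del"`, `"het_dup"`, `"trisomy"`),
#'   `chrom`, and for focal events `start`/`end` (0-based half-open), plus
#'   optional pinned `ff`, `depth`, `sex` for the carrier sample.
#' @param fetal_sex_ratio probability of a male fetus.
#' @param baselines chrY [ff_baselines()].
#' @param overdispersion variance inflation of window counts (1 = Poisson).
#' @param batch_id label.
#' @param seed optional RNG seed applied by [simulate_cohort()].
#' @return A `sim_config`.
#' @export
sim_config <- function(windows = NULL, genome = synthetic_genome("macro"),
                       target_avg_len = 1e6, n_samples = 50,
                       depth = list(mean = 10e6, sd = 1e6),
                       ff = ff_model("post_enrichment"),
                       gc_bias = gc_bias_spec("quadratic"),
                       events = list(), fetal_sex_ratio = 0.5,
                       baselines = ff_baselines(), overdispersion = 1,
                       batch_id = "sim", seed = NULL) {
  if (is.null(windows)) {
    track <- uniform_track(genome, gc = synthetic_gc_profile)
    windows <- build_windows(track, target_avg_len = target_avg_len)
  }
  stopifnot(n_samples >= 1, overdispersion >= 1)
  for (ev in events) {
    stopifnot(ev$type %in% c("het_del", "het_dup", "trisomy"),
              ev$chrom %in% windows$chrom)
    if (ev$type != "trisomy") {
      lim <- range(windows$end[windows$chrom == ev$chrom])
      if (ev$start < 0 || ev$end > max(lim) || ev$end <= ev$start)
        stop("event outside genome bounds: ", ev$chrom, ":", ev$start, "-",
             ev$end)
    }
  }
  structure(list(windows = windows, n_samples = n_samples, depth = depth,
                 ff = ff, gc_bias = gc_bias, events = events,
                 fetal_sex_ratio = fetal_sex_ratio, baselines = baselines,
                 overdispersion = overdispersion, batch_id = batch_id,
                 seed = seed),
            class = "sim_config")
}

# Per-window dosage multiplier for one sample's events; partial window
# overlap scales the shift by the overlapped fraction of the window.
event_dosage <- function(windows, events, ff, sex) {
  d <- rep(1, nrow(windows))
  for (ev in events) {
    shift <- if (ev$type == "het_del") -ff / 2 else ff / 2
    if (ev$type == "trisomy") {
      w <- windows$chrom == ev$chrom
      d[w] <- d[w] * (1 + shift)
    } else {
      w <- which(windows$chrom == ev$chrom & windows$end > ev$start &
                 windows$start < ev$end)
      if (length(w)) {
        ov <- pmin(windows$end[w], ev$end) - pmax(windows$start[w], ev$start)
        frac <- ov / (windows$end[w] - windows$start[w])
        d[w] <- d[w] * (1 + frac * shift)
      }
    }
  }
  if (identical(sex, "male")) {
    x <- windows$chrom %in% c("chrX", "X")
    d[x] <- d[x] * (1 - ff / 2)
  }
  d
}

#' Simulate one plasma sample
#'
#' Expected count per non-Y window is
#' `lambda_w = depth_rest * share_w * gcbias(gc_w) * dosage_w` with
#' `share_w` proportional to the window's uniquely mappable positions and
#' dosage `1 -/+ ff/2` inside fetal heterozygous deletions/duplications (or
#' trisomic chromosomes), scaled by partial-overlap fraction. Observed
#' counts are Poisson (or overdispersed negative binomial). chrY reads are
#' binomial at proportion `b_female + ff * (b_male_adult - b_female)` for a
#' male fetus and `b_female` otherwise, and are spread multinomially over
#' the Y windows.
#'
#' @param config a [sim_config()].
#' @param sample_id label.
#' @param ff,sex,depth,events per-sample overrides (defaults drawn from the
#'   config by [simulate_cohort()]).
#' @return list with `counts` (a [sample_counts()]) and `truth` (one-row
#'   data.frame).
#' @export
simulate_sample <- function(config, sample_id = "s1", ff = NULL,
                            sex = NULL, depth = NULL, events = NULL) {
  w <- config$windows
  if (is.null(ff)) ff <- config$ff$draw(1)
  if (is.null(sex))
    sex <- if (stats::runif(1) < config$fetal_sex_ratio) "male" else "female"
  if (is.null(depth))
    depth <- max(1e5, round(stats::rnorm(1, config$depth$mean,
                                         config$depth$sd)))
  if (is.null(events)) events <- list()
  b <- config$baselines
  py <- if (sex == "male") b$b_female + ff * (b$b_male_adult - b$b_female)
        else b$b_female
  chry <- stats::rbinom(1, depth, py)
  is_y <- w$chrom %in% c("chrY", "Y")
  dosage <- event_dosage(w, events, ff, sex)
  gcb <- config$gc_bias$fun(ifelse(is.na(w$gc), 0.4, w$gc))
  wt <- w$expected_unique * gcb * dosage
  wt[is_y] <- 0
  lambda <- (depth - chry) * wt / sum(wt)
  raw <- numeric(nrow(w))
  od <- config$overdispersion
  nz <- lambda > 0
  raw[nz] <- if (od > 1)
    stats::rnbinom(sum(nz), mu = lambda[nz], size = lambda[nz] / (od - 1))
  else stats::rpois(sum(nz), lambda[nz])
  if (any(is_y) && chry > 0) {
    yw <- w$expected_unique[is_y]
    raw[is_y] <- as.numeric(stats::rmultinom(1, chry,
                                             prob = yw / sum(yw)))
  }
  counts <- sample_counts(sample_id, raw, total_unique_reads = sum(raw),
                          chrY_reads = chry, batch_id = config$batch_id)
  evstr <- if (length(events))
    paste(vapply(events, function(e)
      if (e$type == "trisomy") paste0("trisomy:", e$chrom)
      else sprintf("%s:%s:%.0f-%.0f", e$type, e$chrom, e$start, e$end),
      character(1)), collapse = ";") else ""
  truth <- data.frame(sample_id = sample_id, ff = ff, sex = sex,
                      depth_target = depth, total_reads = sum(raw),
                      chrY_reads = chry, events = evstr,
                      dosage_shift = if (length(events)) ff / 2 else 0,
                      stringsAsFactors = FALSE)
  list(counts = counts, truth = truth)
}

#' Simulate a cohort with ground truth
#'
#' Draws per-sample fetal fraction, fetal sex and depth from the config,
#' assigns spiked events (pinning the carrier's fetal fraction / depth /
#' sex when the event specifies them), and simulates each sample
#' independently. Bitwise reproducible for a fixed `seed`.
#'
#' @param config a [sim_config()].
#' @return A `sim_cohort`: `samples` (named list of [sample_counts()]),
#'   `truth` (the truth table, one row per sample), `windows`, `config`.
#' @export
simulate_cohort <- function(config) {
  if (config$n_samples < 1) stop("n_samples must be >= 1")
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_samples
  ffs <- config$ff$draw(n)
  sexes <- ifelse(stats::runif(n) < config$fetal_sex_ratio, "male",
                  "female")
  depths <- pmax(1e5, round(stats::rnorm(n, config$depth$mean,
                                         config$depth$sd)))
  ev_by_sample <- vector("list", n)
  for (ev in config$events) {
    s <- if (identical(ev$sample, "random")) sample.int(n, 1) else ev$sample
    if (s < 1 || s > n) stop("event sample index out of range")
    ev_by_sample[[s]] <- c(ev_by_sample[[s]], list(ev))
    if (!is.null(ev$ff)) ffs[s] <- ev$ff
    if (!is.null(ev$depth)) depths[s] <- ev$depth
    if (!is.null(ev$sex)) sexes[s] <- ev$sex
  }
  ids <- sprintf("s%03d", seq_len(n))
  samples <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    r <- simulate_sample(config, sample_id = ids[i], ff = ffs[i],
                         sex = sexes[i], depth = depths[i],
                         events = ev_by_sample[[i]] %||% list())
    samples[[i]] <- r$counts
    truth[[i]] <- r$truth
  }
  names(samples) <- ids
  structure(list(samples = samples, truth = do.call(rbind, truth),
                 windows = config$windows, config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("simulated cohort: %d samples, %d windows, %d spiked event(s)\n",
              length(x$samples), nrow(x$windows),
              sum(nzchar(x$truth$events))))
  invisible(x)
}

#' Emit a small SAM fixture with embedded truth
#'
#' Writes single-end 50 bp records whose positions follow the per-window
#' expected counts, plus configurable fractions of duplicate-flagged,
#' unmapped, low-MAPQ and high-mismatch records that the filters must
#' remove. The intended per-window retained counts are embedded in `@CO`
#' header lines, so counting the fixture has a known answer. Guarded to tiny
#' genomes (<= 5 Mb).
#'
#' @param windows a `window_map` over a genome of at most 5 Mb.
#' @param n_reads retained (passing) reads to emit.
#' @param frac_dup,frac_unmapped,frac_lowmapq,frac_mismatch fractions of
#'   additional contaminating records.
#' @param path optional output path.
#' @return Character vector of SAM lines (invisibly if `path` given).
#' @export
emit_sam_fixture <- function(windows, n_reads = 100, frac_dup = 0,
                             frac_unmapped = 0, frac_lowmapq = 0,
                             frac_mismatch = 0, path = NULL) {
  genome_len <- sum(windows$end - windows$start)
  if (genome_len > 5e6)
    stop("fixture guard: genome too large (> 5 Mb)")
  chrom_len <- tapply(windows$end, windows$chrom, max)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%.0f", names(chrom_len), chrom_len))
  wt <- windows$expected_unique
  kept_per_win <- as.numeric(stats::rmultinom(1, n_reads, wt / sum(wt)))
  mk <- function(i, qname, flag, mapq, nm) {
    pos <- windows$start[i] +
      floor(stats::runif(1) * max(1, windows$end[i] - windows$start[i] - 50))
    sprintf("%s\t%d\t%s\t%.0f\t%d\t50M\t*\t0\t0\t%s\t*\tNM:i:%d", qname,
            flag, windows$chrom[i], pos + 1, mapq,
            paste(rep("A", 50), collapse = ""), nm)
  }
  recs <- character(0)
  q <- 0
  for (i in seq_len(nrow(windows))) {
    for (r in seq_len(kept_per_win[i])) {
      q <- q + 1
      recs <- c(recs, mk(i, sprintf("keep%05d", q), 0L, 60L, 0L))
    }
  }
  add_contaminants <- function(frac, maker) {
    k <- round(frac * n_reads)
    if (k > 0) for (j in seq_len(k)) {
      i <- sample.int(nrow(windows), 1)
      recs <<- c(recs, maker(i, j))
    }
  }
  add_contaminants(frac_dup, function(i, j)
    mk(i, sprintf("dup%05d", j), 1024L, 60L, 0L))
  add_contaminants(frac_lowmapq, function(i, j)
    mk(i, sprintf("multi%05d", j), 0L, 0L, 0L))
  add_contaminants(frac_mismatch, function(i, j)
    mk(i, sprintf("mm%05d", j), 0L, 60L, 5L))
  k <- round(frac_unmapped * n_reads)
  if (k > 0) recs <- c(recs, vapply(seq_len(k), function(j)
    sprintf("unm%05d\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t*", j,
            paste(rep("A", 50), collapse = "")), character(1)))
  truth <- sprintf("@CO\ttruth_raw=%s",
                   paste(sprintf("%.0f", kept_per_win), collapse = ","))
  lines <- c(hdr, truth, recs)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
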