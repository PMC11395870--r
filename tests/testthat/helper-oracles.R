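# Independent oracles and small fixture builders shared across tests.

# Brute-force maximum-probability state path by full path enumeration in
# log space (independent of the dynamic-programming implementation).
bf_viterbi <- function(symbols, params) {
  obs <- match(symbols, params$symbols)
  n <- length(obs)
  logE <- log(params$emission)
  logT <- log(params$transition)
  logI <- log(params$initial)
  paths <- as.matrix(expand.grid(rep(list(1:3), n)))
  lp <- logI[paths[, 1]] + logE[cbind(paths[, 1], obs[1])]
  if (n > 1) for (t in 2:n)
    lp <- lp + logT[cbind(paths[, t - 1], paths[, t])] +
      logE[cbind(paths[, t], obs[t])]
  params$states[paths[which.max(lp), ]]
}

# Random valid HMM parameters over the default 7-symbol alphabet.
random_hmm_params <- function() {
  k <- 7L
  norm_rows <- function(m) sweep(m, 1, rowSums(m), `/`)
  hmm_params(
    emission = norm_rows(matrix(stats::runif(3 * k, 0.01, 1), 3, k)),
    transition = norm_rows(matrix(stats::runif(9, 0.01, 1), 3, 3)),
    initial = local({ p <- stats::runif(3, 0.01, 1); p / sum(p) }))
}

# Hand accumulation of mappability bins into constant-quota windows: the
# independent oracle for build_windows (plain loop, no vectorisation).
oracle_windows <- function(bins, target_avg_len) {
  chrom_len <- max(bins$end) - min(bins$start)
  total <- sum(bins$unique_positions)
  nwin <- max(1, round(chrom_len / target_avg_len))
  quota <- total / nwin
  rows <- list()
  win_start <- bins$start[1]
  acc <- 0
  prev <- 0
  w <- 1
  for (i in seq_len(nrow(bins))) {
    acc <- acc + bins$unique_positions[i]
    if ((acc >= quota * w - 1e-9 && w < nwin) || i == nrow(bins)) {
      rows[[w]] <- data.frame(start = win_start, end = bins$end[i],
                              expected_unique = acc - prev)
      win_start <- bins$end[i]
      prev <- acc
      w <- w + 1
    }
  }
  do.call(rbind, rows)
}

# Tiny uniform window map: `n` adjacent windows of `len` bp on one
# chromosome, optionally with a GC gradient.
tiny_windows <- function(n = 10, len = 1e6, chrom = "chr1", gc = 0.45) {
  df <- data.frame(chrom = chrom, start = (seq_len(n) - 1) * len,
                   end = seq_len(n) * len, expected_unique = len,
                   gc = if (length(gc) == 1) rep(gc, n) else gc,
                   usable = TRUE)
  nipscnv:::new_window_map(df)
}

# Corrected-counts stub with given CRN vector.
crn_stub <- function(crn, id = "s1", batch = "b1") {
  structure(list(sample_id = id, crn = crn, model = NULL,
                 total_unique_reads = sum(crn, na.rm = TRUE),
                 chrY_reads = 0, batch_id = batch),
            class = "corrected_counts")
}

# Quick euploid cohort on a small single-chromosome genome with a GC
# gradient: windows, per-sample Poisson counts with optional bias curve.
small_cohort <- function(n_samples, n_windows = 300, depth = 3e6,
                         bias = function(gc) rep(1, length(gc)),
                         seed = 1) {
  set.seed(seed)
  gc <- 0.42 + 0.08 * sin(seq(0, 6 * pi, length.out = n_windows))
  w <- tiny_windows(n_windows, len = 1e6, gc = gc)
  lambda <- depth * bias(gc) / sum(bias(gc))
  samples <- lapply(seq_len(n_samples), function(i)
    sample_counts(sprintf("s%02d", i), stats::rpois(n_windows, lambda)))
  list(windows = w, samples = samples, lambda = lambda, gc = gc)
}
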