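# The core caller: per-window same-lot Z-scores on GC-corrected counts,
# discretisation into symbols, three-state (loss / neutral / gain)
# discrete-emission hidden Markov decoding, segmentation, and matching of
# segments against a catalog of known microdeletion/microduplication
# syndromes. A heterozygous fetal deletion at fetal fraction ff depresses
# the corrected count of the affected windows by a factor ff/2, i.e. by
# roughly (ff/2) * sqrt(lambda) standard units at Poisson depth lambda.

#' Same-lot per-window batch statistics
#'
#' Computes the per-window mean (`CRN_mean`) and sample standard deviation
#' (`SD_CRN`, n-1 denominator) of corrected read numbers across the batch.
#' Because library depth varies between samples, every sample's CRN vector
#' is first rescaled so its total over commonly usable windows equals the
#' batch median total; otherwise depth variation would dominate `SD_CRN`.
#' Windows with any missing value, zero SD, or SD beyond `sd_outlier_mult`
#' times the median window SD are flagged unusable.
#'
#' @details
#' The statistics are computed in two passes: after a first pass, cells
#' (window x sample) whose plain z-score exceeds `mask_z` in magnitude are
#' masked and the per-window mean/SD recomputed over the remaining samples.
#' Without this guard a CNV carrier inflates the reference SD of its own
#' windows for every other sample in the lot — in a scaled-down lot that can
#' contain more than one carrier of the same syndrome, self-masking plus
#' leave-one-out alone is not enough. Windows retaining fewer than 60% of
#' samples after masking are flagged unusable.
#'
#' @param corrected list of `corrected_counts` with equal window counts.
#' @param force allow batches smaller than 8 samples.
#' @param normalize rescale samples to a common total before the statistics
#'   (default `TRUE`; disable only for hand-constructed examples).
#' @param sd_outlier_mult unusable-window SD cap, as a multiple of the
#'   median window SD.
#' @param mask_z cell-level outlier threshold for the second pass.
#' @return A `batch_stats` object holding the scaled CRN matrix, per-window
#'   `mean` and `sd`, the outlier `mask`, the `usable` window mask and
#'   batch metadata.
#' @export
batch_stats <- function(corrected, force = FALSE, normalize = TRUE,
                        sd_outlier_mult = 5, mask_z = 3) {
  n <- length(corrected)
  if (n < 8 && !force)
    stop("batch has fewer than 8 samples; use force = TRUE to override")
  if (n < 2) stop("need at least 2 samples for batch statistics")
  nw <- unique(vapply(corrected, function(s) length(s$crn), integer(1)))
  if (length(nw) != 1L) stop("samples have mismatched window counts")
  X <- matrix(vapply(corrected, function(s) s$crn, numeric(nw)),
              nrow = nw)
  complete <- rowSums(is.na(X)) == 0L
  if (!any(complete)) stop("no window is usable in every sample")
  if (normalize) {
    totals <- colSums(X[complete, , drop = FALSE])
    if (any(totals <= 0)) stop("sample with zero usable signal")
    ref <- stats::median(totals)
    X <- sweep(X, 2, ref / totals, `*`)
  } else {
    ref <- NA_real_
  }
  mu1 <- rowMeans(X)
  sd1 <- sqrt(pmax((rowSums(X^2) - n * mu1^2) / (n - 1), 0))
  # second pass: mask outlying cells so one sample's CNV cannot inflate
  # the reference SD for the rest of the lot
  mask <- matrix(FALSE, nw, ncol(X))
  safe <- complete & sd1 > 0
  if (n >= 8 && any(safe)) {
    z1 <- (X[safe, , drop = FALSE] - mu1[safe]) / sd1[safe]
    mask[safe, ] <- abs(z1) > mask_z
  }
  keep <- !mask
  n_w <- rowSums(keep)
  Xk <- X
  Xk[mask] <- 0
  mu <- rowSums(Xk) / n_w
  ss <- rowSums(Xk^2)
  v <- (ss - n_w * mu^2) / pmax(n_w - 1, 1)
  sd <- sqrt(pmax(v, 0))
  usable <- complete & sd > 0 & n_w >= pmax(2, ceiling(0.6 * n))
  if (any(usable)) {
    sd_cap <- sd_outlier_mult * stats::median(sd[usable])
    usable <- usable & sd <= sd_cap
  }
  structure(list(mean = mu, sd = sd, usable = usable, n_samples = n,
                 n_kept = n_w, mask = mask,
                 batch_id = corrected[[1]]$batch_id, X = X, ss = ss,
                 sample_ids = vapply(corrected, function(s) s$sample_id,
                                     character(1)),
                 ref_total = ref, normalized = normalize),
            class = "batch_stats")
}

#' @export
print.batch_stats <- function(x, ...) {
  cat(sprintf("batch %s: %d samples, %d/%d usable windows\n", x$batch_id,
              x$n_samples, sum(x$usable), length(x$usable)))
  invisible(x)
}

#' Per-window Z-scores against the batch
#'
#' `Z_win = (CRN_win - CRN_mean) / SD_CRN` per usable window. By default the
#' batch statistics are recomputed leaving the scored sample out
#' (leave-one-out), so a true CNV does not inflate its own reference SD;
#' with `loo = FALSE` the stored all-sample statistics are used directly.
#'
#' @param sample a `corrected_counts` or a sample id present in the batch.
#' @param stats a [batch_stats()].
#' @param loo leave-one-out statistics for in-batch samples (default
#'   `TRUE`).
#' @return A `z_profile`: `sample_id` and numeric `z` (NA at unusable
#'   windows).
#' @export
z_scores <- function(sample, stats, loo = TRUE) {
  id <- if (is.character(sample)) sample else sample$sample_id
  in_batch <- id %in% stats$sample_ids
  n <- stats$n_samples
  if (in_batch) {
    x <- stats$X[, match(id, stats$sample_ids)]
  } else {
    if (is.character(sample)) stop("sample ", id, " not in batch")
    x <- sample$crn
    if (stats$normalized) {
      complete <- rowSums(is.na(stats$X)) == 0L
      tot <- sum(x[complete & !is.na(x)])
      if (tot <= 0) stop("sample with zero usable signal")
      x <- x * stats$ref_total / tot
    }
  }
  if (loo && in_batch) {
    if (n < 3) stop("leave-one-out needs at least 3 samples")
    nk <- stats$n_kept
    m <- (nk * stats$mean - x) / (nk - 1)
    v <- (stats$ss - x^2 - (nk - 1) * m^2) / (nk - 2)
    sd <- sqrt(pmax(v, 0))
    # cells masked as outliers are already excluded from the statistics
    self_masked <- stats$mask[, match(id, stats$sample_ids)]
    m[self_masked] <- stats$mean[self_masked]
    sd[self_masked] <- stats$sd[self_masked]
  } else {
    m <- stats$mean
    sd <- stats$sd
  }
  z <- (x - m) / sd
  z[!stats$usable | !is.finite(z)] <- NA_real_
  structure(list(sample_id = id, z = as.numeric(z)), class = "z_profile")
}

default_symbols <- function(k) {
  stopifnot(k >= 3, k %% 2 == 1)
  h <- (k - 1) / 2
  if (k == 5) return(c("S--", "S-", "S0", "S+", "S++"))
  c(paste0("S", h:1, "-"), "S0", paste0("S", 1:h, "+"))
}

#' Discretise Z-scores into HMM symbols
#'
#' Cut points split the z axis into ordered bins; a z exactly on a cut is
#' assigned to the bin farther from zero (so with the classic cuts
#' (-4, -2.5, 2.5, 4), z = -2.5 is `S-` and z = 2.5 is `S+`). Missing
#' z-values become the central (neutral) symbol and are recorded in the
#' `mask` attribute.
#'
#' @param z a `z_profile` or numeric vector.
#' @param cuts strictly increasing cut points (default -4, -2.5, 2.5, 4).
#' @param symbols optional symbol names (length `length(cuts) + 1`).
#' @return Character vector of symbols with attribute `mask` (logical,
#'   `TRUE` where z was missing).
#' @export
discretize <- function(z, cuts = c(-4, -2.5, 2.5, 4), symbols = NULL) {
  if (inherits(z, "z_profile")) z <- z$z
  if (is.unsorted(cuts, strictly = TRUE))
    stop("cuts must be strictly increasing")
  k <- length(cuts) + 1L
  if (is.null(symbols)) symbols <- default_symbols(k)
  if (length(symbols) != k) stop("need ", k, " symbols for ", k - 1, " cuts")
  mask <- is.na(z)
  zz <- ifelse(mask, 0, z)
  idx <- rep(1L, length(zz))
  for (cut in cuts)
    idx <- idx + if (cut < 0) (zz > cut) else (zz >= cut)
  out <- symbols[idx]
  attr(out, "mask") <- mask
  out
}

#' Default screening HMM parameters
#'
#' Three states (loss, neutral, gain) emitting one of seven z-score bins
#' (cuts -4, -3, -2, 2, 3, 4). Neutral emissions are the standard normal
#' bin masses (the batch z of an unaffected window is ~ N(0,1)); loss and
#' gain emissions approximate the bin masses of a shifted unit-variance
#' Gaussian at |z| ~ 4 — the per-window shift of a heterozygous fetal event
#' at screening-grade fetal fraction and depth — with small floors so no
#' observation is impossible. The neutral state is sticky (self-transition
#' 0.99); loss/gain runs persist at 0.85 and return to neutral, and direct
#' loss<->gain transitions are negligible.
#'
#' @param cuts z-score cut points.
#' @param emission 3 x (length(cuts)+1) row-stochastic matrix, rows
#'   loss/neutral/gain.
#' @param transition 3 x 3 row-stochastic matrix.
#' @param initial initial state distribution.
#' @return An `hmm_params` object.
#' @export
hmm_params <- function(cuts = c(-4, -3, -2, 2, 3, 4),
                       emission = NULL, transition = NULL, initial = NULL) {
  if (is.unsorted(cuts, strictly = TRUE))
    stop("cuts must be strictly increasing")
  k <- length(cuts) + 1L
  symbols <- default_symbols(k)
  states <- c("loss", "neutral", "gain")
  if (is.null(emission)) {
    if (k != 7L)
      stop("default emissions are defined for 7 symbols; supply 'emission'")
    loss <- c(0.46, 0.36, 0.15, 0.025, 0.003, 0.001, 0.001)
    neutral <- diff(stats::pnorm(c(-Inf, cuts, Inf)))
    emission <- rbind(loss = loss, neutral = neutral, gain = rev(loss))
  }
  if (is.null(transition))
    transition <- rbind(loss    = c(0.85, 0.1498, 0.0002),
                        neutral = c(0.005, 0.99, 0.005),
                        gain    = c(0.0002, 0.1498, 0.85))
  if (is.null(initial)) initial <- c(loss = 0.005, neutral = 0.99,
                                     gain = 0.005)
  dimnames(emission) <- list(states, symbols)
  dimnames(transition) <- list(states, states)
  names(initial) <- states
  if (any(emission < 0) || any(transition < 0) || any(initial < 0))
    stop("probabilities must be non-negative")
  if (any(abs(rowSums(emission) - 1) > 1e-9))
    stop("emission rows must sum to 1")
  if (any(abs(rowSums(transition) - 1) > 1e-9))
    stop("transition rows must sum to 1")
  if (abs(sum(initial) - 1) > 1e-9) stop("initial must sum to 1")
  structure(list(states = states, symbols = symbols, cuts = cuts,
                 emission = emission, transition = transition,
                 initial = initial),
            class = "hmm_params")
}

#' Viterbi decoding of a symbol sequence
#'
#' Maximum-a-posteriori state path by dynamic programming in log space.
#' Exact ties are broken deterministically, preferring neutral, then loss,
#' then gain (a conservative screening posture).
#'
#' @param symbols character vector of emitted symbols.
#' @param params an [hmm_params()].
#' @return Character vector of states, one per symbol.
#' @export
viterbi <- function(symbols, params = hmm_params()) {
  if (!all(symbols %in% params$symbols))
    stop("symbol outside the HMM alphabet: ",
         setdiff(symbols, params$symbols)[1])
  pref <- c("neutral", "loss", "gain")
  states <- params$states
  ord <- match(pref, states)
  logE <- log(params$emission)
  logT <- log(params$transition)
  logI <- log(params$initial)
  n <- length(symbols)
  if (n == 0L) return(character(0))
  obs <- match(symbols, params$symbols)
  if (any(!is.finite(apply(logE[, obs, drop = FALSE], 2, max))))
    stop("impossible emission: a symbol has probability 0 under all states")
  delta <- matrix(-Inf, n, 3)
  psi <- matrix(1L, n, 3)
  delta[1, ] <- logI + logE[, obs[1]]
  if (n > 1) for (t in 2:n) {
    for (j in 1:3) {
      best <- -Inf; arg <- ord[1]
      for (i in ord) {
        cand <- delta[t - 1, i] + logT[i, j]
        if (cand > best) { best <- cand; arg <- i }
      }
      delta[t, j] <- best + logE[j, obs[t]]
      psi[t, j] <- arg
    }
  }
  path <- integer(n)
  best <- -Inf
  for (i in ord) if (delta[n, i] > best) { best <- delta[n, i]; path[n] <- i }
  if (n > 1) for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  states[path]
}

#' Decode CNV states across the genome
#'
#' Runs [discretize()] and [viterbi()] independently per chromosome (the
#' HMM never crosses chromosome boundaries). By default only autosomes are
#' decoded: in a mixed-fetal-sex batch the X/Y window SDs reflect fetal sex,
#' not copy number.
#'
#' @param z a `z_profile`.
#' @param windows a `window_map`.
#' @param params an [hmm_params()].
#' @param chroms chromosomes to decode (default: all non-X/Y).
#' @return Character state vector aligned with the window map (`"neutral"`
#'   outside decoded chromosomes).
#' @export
decode_cnv <- function(z, windows, params = hmm_params(), chroms = NULL) {
  if (is.null(chroms))
    chroms <- setdiff(unique(windows$chrom), c("chrX", "chrY", "X", "Y"))
  path <- rep("neutral", nrow(windows))
  for (chrom in intersect(unique(windows$chrom), chroms)) {
    w <- which(windows$chrom == chrom)
    sym <- discretize(z$z[w], cuts = params$cuts, symbols = params$symbols)
    path[w] <- viterbi(sym, params)
  }
  path
}

#' Segment a decoded state path
#'
#' Maximal runs of loss or gain become candidate segments with genomic
#' coordinates taken from the first and last window (half-open). Candidates
#' are kept when the segment evidence score `|sum(z) / sqrt(n)|` (a
#' Stouffer-type combination of the per-window z-scores) reaches
#' `min_seg_score`; weak runs produced by emission quirks are dropped.
#'
#' @param path state vector from [decode_cnv()].
#' @param z the matching `z_profile`.
#' @param windows the `window_map`.
#' @param min_seg_score segment score threshold (default 3.5).
#' @return data.frame of `cnv_segments`: `chrom`, `start`, `end` (0-based
#'   half-open), `state`, `n_windows`, `mean_z`, `seg_score`, `size_bp`,
#'   `size_mb` (2 dp).
#' @export
segment_calls <- function(path, z, windows, min_seg_score = 3.5) {
  if (inherits(z, "z_profile")) z <- z$z
  segs <- list()
  for (chrom in unique(windows$chrom)) {
    w <- which(windows$chrom == chrom)
    r <- rle(path[w])
    stops <- cumsum(r$lengths)
    starts <- stops - r$lengths + 1L
    for (i in which(r$values != "neutral")) {
      ix <- w[starts[i]:stops[i]]
      zz <- z[ix]
      zz <- zz[!is.na(zz)]
      if (!length(zz)) next
      score <- sum(zz) / sqrt(length(zz))
      if (abs(score) < min_seg_score) next
      start <- windows$start[ix[1]]
      end <- windows$end[ix[length(ix)]]
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = chrom, start = start, end = end, state = r$values[i],
        n_windows = length(ix), mean_z = mean(zz), seg_score = score,
        size_bp = end - start, size_mb = round((end - start) / 1e6, 2),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(segs)) do.call(rbind, segs) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               state = character(), n_windows = integer(),
               mean_z = numeric(), seg_score = numeric(),
               size_bp = numeric(), size_mb = numeric())
  attr(out, "genome_build") <- attr(windows, "genome_build")
  out
}

#' Read a syndrome-region catalog
#'
#' TSV with columns `name`, `chrom`, `start`, `end` (0-based half-open,
#' GRCh37 for the packaged catalog), `expected_state` (loss/gain) and
#' `min_overlap`, plus a `#genome_build=` header. The packaged catalog
#' covers Williams-Beuren (7q11.23), 22q11.2 deletion, Prader-Willi /
#' Angelman (15q11.2-q13), Cri-du-chat (5p15) and 1p36 deletion; the
#' coordinates are approximate region spans intended as screening targets,
#' shipped as editable configuration data.
#'
#' @param path catalog TSV (default: the packaged catalog).
#' @return data.frame with attribute `genome_build`.
#' @export
read_syndrome_catalog <- function(path = system.file(
    "extdata", "syndromes_grch37.tsv", package = "nipscnv")) {
  lines <- readLines(path)
  build <- NA_character_
  hdr <- grep("^#genome_build=", lines, value = TRUE)
  if (length(hdr)) build <- sub("^#genome_build=", "", hdr[1])
  df <- utils::read.table(text = lines[!startsWith(lines, "#")],
                          header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("name", "chrom", "start", "end", "expected_state",
                  "min_overlap") %in% names(df)),
            all(df$end > df$start),
            all(df$min_overlap > 0 & df$min_overlap <= 1))
  attr(df, "genome_build") <- build
  df
}

#' Match CNV segments against a syndrome catalog
#'
#' A segment matches a catalog region when the states agree and the overlap
#' covers at least the region's `min_overlap` fraction of the region length;
#' among multiple matches the largest overlap wins. Matched segments are
#' classified `pathogenic_match`, the rest `unmatched`.
#'
#' @param segments segments from [segment_calls()].
#' @param catalog data.frame from [read_syndrome_catalog()].
#' @return `segments` with added `syndrome`, `overlap_fraction` and
#'   `classification` columns.
#' @export
match_syndromes <- function(segments, catalog = read_syndrome_catalog()) {
  sb <- attr(segments, "genome_build")
  cb <- attr(catalog, "genome_build")
  known <- function(b) !is.null(b) && !is.na(b) && b != "synthetic"
  if (known(sb) && known(cb) && !identical(sb, cb))
    stop("genome build mismatch: segments ", sb, " vs catalog ", cb)
  segments$syndrome <- rep(NA_character_, nrow(segments))
  segments$overlap_fraction <- rep(NA_real_, nrow(segments))
  segments$classification <- rep("unmatched", nrow(segments))
  if (!nrow(segments)) return(segments)
  for (i in seq_len(nrow(segments))) {
    cand <- catalog[catalog$chrom == segments$chrom[i] &
                    catalog$expected_state == segments$state[i], ,
                    drop = FALSE]
    if (!nrow(cand)) next
    ov <- pmax(0, pmin(segments$end[i], cand$end) -
                  pmax(segments$start[i], cand$start))
    frac <- ov / (cand$end - cand$start)
    hit <- which(frac >= cand$min_overlap)
    if (!length(hit)) next
    best <- hit[which.max(ov[hit])]
    segments$syndrome[i] <- cand$name[best]
    segments$overlap_fraction[i] <- frac[best]
    segments$classification[i] <- "pathogenic_match"
  }
  segments
}
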