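# Per-sample GC-bias correction. Window counts are under-represented in
# GC-poor and GC-rich regions after PCR; a cubic spline fitted through
# per-GC-bin median counts estimates the bias curve m(gc), and corrected
# read numbers (CRN) are raw counts rescaled to the sample's global
# reference level: CRN_w = raw_w * reference / m(gc_w).

#' Fit a per-sample GC-bias model
#'
#' Usable windows are grouped into GC bins (default width 0.01) and the
#' per-bin median raw count is computed; a cubic smoothing spline (GCV
#' smoothing) is fitted through the (bin centre, median) points, weighted by
#' bin occupancy. With fewer than 10 populated bins the fit falls back to a
#' natural cubic interpolation spline through the medians. The bias curve is
#' only evaluated inside the sample's \[1st, 99th\] GC percentile range;
#' windows outside are clamped (no extrapolation). Medians (not means) keep
#' CNV-carrying windows from bending the curve.
#'
#' @param counts a [sample_counts()].
#' @param windows a `window_map`.
#' @param bin_width GC bin width (default 0.01).
#' @return A `gc_model` with the fitted curve, clip range, global reference
#'   level (median usable-window count) and the bin table (for diagnostics).
#' @export
fit_gc_model <- function(counts, windows, bin_width = 0.01) {
  if (length(counts$raw) != nrow(windows))
    stop("window count mismatch between counts and window map")
  use <- windows$usable & !is.na(windows$gc) & !is.na(counts$raw)
  if (sum(use) < 50)
    stop("need >= 50 usable windows to fit a GC model")
  gc <- windows$gc[use]
  y <- counts$raw[use]
  bin <- round(gc / bin_width)
  bt <- data.frame(
    center = as.numeric(names(table(bin))) * bin_width,
    median = as.numeric(tapply(y, bin, stats::median)),
    n = as.integer(table(bin)))
  if (nrow(bt) < 5)
    stop("insufficient GC spread: fewer than 5 populated GC bins")
  clip <- as.numeric(stats::quantile(gc, c(0.01, 0.99), names = FALSE))
  reference <- stats::median(y)
  if (nrow(bt) >= 10) {
    fit <- stats::smooth.spline(bt$center, bt$median, w = bt$n)
    curve <- function(g) stats::predict(fit, g)$y
    method <- "smoothing_spline_gcv"
  } else {
    fit <- stats::splinefun(bt$center, bt$median, method = "natural")
    curve <- fit
    method <- "interpolating_spline"
  }
  structure(list(curve = curve, method = method, clip = clip,
                 reference = reference, bins = bt, bin_width = bin_width,
                 sample_id = counts$sample_id),
            class = "gc_model")
}

#' Evaluate the fitted GC-bias curve m(gc)
#'
#' @param object a `gc_model`.
#' @param gc GC fractions; values outside the clip range are clamped.
#' @param ... unused.
#' @return Expected raw count at each GC, floored at 5% of the reference
#'   level so corrections stay finite and positive.
#' @export
predict.gc_model <- function(object, gc, ...) {
  g <- pmin(pmax(gc, object$clip[1]), object$clip[2])
  pmax(object$curve(g), 0.05 * object$reference)
}

#' @export
print.gc_model <- function(x, ...) {
  cat(sprintf("GC model (%s): %d bins, clip [%.3f, %.3f], reference %.1f\n",
              x$method, nrow(x$bins), x$clip[1], x$clip[2], x$reference))
  invisible(x)
}

#' Apply GC correction, producing corrected read numbers (CRN)
#'
#' `CRN_w = raw_w * reference / m(clip(gc_w))`. Unusable windows carry `NA`
#' rather than 0 so downstream batch statistics can mask them.
#'
#' @param counts a [sample_counts()].
#' @param model a fitted `gc_model` (defaults to fitting one on `counts`).
#' @param windows a `window_map`.
#' @return A `corrected_counts` object (`sample_id`, `crn`, `model`).
#' @export
apply_gc_correction <- function(counts, model = NULL, windows) {
  if (is.null(model)) model <- fit_gc_model(counts, windows)
  if (length(counts$raw) != nrow(windows))
    stop("window count mismatch between counts and window map")
  m <- predict(model, windows$gc)
  crn <- counts$raw * model$reference / m
  crn[!windows$usable | is.na(windows$gc)] <- NA_real_
  structure(list(sample_id = counts$sample_id, crn = crn, model = model,
                 total_unique_reads = counts$total_unique_reads,
                 chrY_reads = counts$chrY_reads,
                 batch_id = counts$batch_id),
            class = "corrected_counts")
}

#' Full per-sample correction in one call
#'
#' @inheritParams apply_gc_correction
#' @return A `corrected_counts`.
#' @export
gc_correct <- function(counts, windows) {
  apply_gc_correction(counts, fit_gc_model(counts, windows), windows)
}
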