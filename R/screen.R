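# Cohort screening: the central fit. Composes fetal-fraction estimation and
# QC, per-sample GC correction, same-lot batch statistics, HMM copy-number
# decoding with syndrome matching, and the chromosome-level aneuploidy
# Z-test into one classed result.

#' Screening configuration defaults
#'
#' @param baselines chrY [ff_baselines()].
#' @param qc [qc_thresholds()].
#' @param hmm [hmm_params()].
#' @param z_threshold aneuploidy call threshold (default 3).
#' @param min_seg_score CNV segment evidence threshold (default 3.5).
#' @param cnv_chroms chromosomes decoded by the CNV HMM (`NULL` =
#'   autosomes).
#' @return A `screen_config` list.
#' @export
screen_config <- function(baselines = ff_baselines(),
                          qc = qc_thresholds(), hmm = hmm_params(),
                          z_threshold = 3, min_seg_score = 3.5,
                          cnv_chroms = NULL) {
  structure(list(baselines = baselines, qc = qc, hmm = hmm,
                 z_threshold = z_threshold, min_seg_score = min_seg_score,
                 cnv_chroms = cnv_chroms),
            class = "screen_config")
}

#' Screen one sample against prepared batch statistics
#'
#' Composes z-scores (leave-one-out), discretisation, Viterbi decoding,
#' segmentation and syndrome matching for a single sample, attaching the
#' supplied fetal-fraction / QC and aneuploidy results. QC-failed samples
#' are returned with status `"no-call"` and no CNV segments unless
#' `force = TRUE`.
#'
#' @param corrected the sample's `corrected_counts`.
#' @param stats a [batch_stats()] containing the sample.
#' @param windows a `window_map`.
#' @param catalog syndrome catalog (see [read_syndrome_catalog()]).
#' @param config a [screen_config()].
#' @param ff the sample's QC-annotated `ff_estimate` (optional).
#' @param aneuploidy the sample's `aneuploidy_result` (optional).
#' @param force screen despite QC failure.
#' @return A `screen_result`.
#' @export
screen_sample <- function(corrected, stats, windows,
                          catalog = read_syndrome_catalog(),
                          config = screen_config(), ff = NULL,
                          aneuploidy = NULL, force = FALSE) {
  qc_failed <- !is.null(ff) && isFALSE(ff$qc_pass)
  if (qc_failed && !force) {
    warning("sample ", corrected$sample_id,
            " failed QC; returning no-call (use force = TRUE to screen)")
    return(structure(list(sample_id = corrected$sample_id, ff = ff,
                          aneuploidy = aneuploidy,
                          segments = segment_calls(character(0),
                                                   numeric(0),
                                                   windows[0, ]),
                          z = NULL, risk_labels = character(0),
                          status = "no-call"),
                     class = "screen_result"))
  }
  z <- z_scores(corrected, stats)
  path <- decode_cnv(z, windows, params = config$hmm,
                     chroms = config$cnv_chroms)
  segs <- segment_calls(path, z, windows,
                        min_seg_score = config$min_seg_score)
  segs <- match_syndromes(segs, catalog)
  risk <- sprintf("high risk: %s",
                  segs$syndrome[segs$classification == "pathogenic_match"])
  structure(list(sample_id = corrected$sample_id, ff = ff,
                 aneuploidy = aneuploidy, segments = segs, z = z,
                 risk_labels = risk,
                 status = if (qc_failed) "forced" else "screened"),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("sample %s [%s]", x$sample_id, x$status))
  if (!is.null(x$ff) && !is.na(x$ff$ff))
    cat(sprintf(", ff %.2f%%", 100 * x$ff$ff))
  cat("\n")
  if (length(x$risk_labels))
    cat(paste0("  ", x$risk_labels, collapse = "\n"), "\n")
  n_an <- if (!is.null(x$aneuploidy)) nrow(x$aneuploidy$calls) else 0
  cat(sprintf("  %d CNV segment(s), %d aneuploidy call(s)\n",
              nrow(x$segments), n_an))
  invisible(x)
}

#' Screen a cohort of samples
#'
#' The main entry point: takes raw per-window counts for one sequencing lot
#' and returns the full screening result. Steps: chrY fetal-fraction
#' estimation and QC per sample; per-sample GC-bias correction; same-lot
#' batch statistics; per-sample leave-one-out z-scores, HMM decoding,
#' segmentation and syndrome matching; chromosome-level aneuploidy Z-test.
#'
#' @param samples list of [sample_counts()] (one lot).
#' @param windows the `window_map` the counts are aligned to.
#' @param catalog syndrome catalog.
#' @param config a [screen_config()].
#' @param force screen small batches and QC-failed samples.
#' @return A `nips_screen` object: `results` (named list of
#'   `screen_result`), `stats`, `windows`, `config`.
#' @export
screen_cohort <- function(samples, windows,
                          catalog = read_syndrome_catalog(),
                          config = screen_config(), force = FALSE) {
  stopifnot(length(samples) >= 2)
  ffs <- lapply(samples, function(s)
    qc_sample(s, estimate_ff_chry(s, config$baselines,
                                  min_ff = config$qc$min_ff),
              thresholds = config$qc))
  corrected <- lapply(samples, gc_correct, windows = windows)
  stats <- batch_stats(corrected, force = force)
  reps <- lapply(corrected, chromosome_representation, windows = windows)
  aneu <- batch_aneuploidy_z(reps, ff_estimates = ffs,
                             z_threshold = config$z_threshold,
                             min_ff = config$qc$min_ff, force = force)
  results <- lapply(seq_along(samples), function(i)
    screen_sample(corrected[[i]], stats, windows, catalog, config,
                  ff = ffs[[i]], aneuploidy = aneu[[i]], force = force))
  names(results) <- vapply(samples, function(s) s$sample_id, character(1))
  structure(list(results = results, stats = stats, windows = windows,
                 config = config),
            class = "nips_screen")
}

#' @export
print.nips_screen <- function(x, ...) {
  pos <- vapply(x$results, function(r) length(r$risk_labels) > 0, logical(1))
  nc <- vapply(x$results, function(r) r$status == "no-call", logical(1))
  cat(sprintf("cohort screen: %d samples, %d screen-positive, %d no-call\n",
              length(x$results), sum(pos), sum(nc)))
  for (r in x$results[pos])
    cat(sprintf("  %s: %s\n", r$sample_id,
                paste(r$risk_labels, collapse = "; ")))
  invisible(x)
}

#' @export
summary.nips_screen <- function(object, ...) {
  rows <- lapply(object$results, function(r) {
    segs <- r$segments
    hit <- segs[segs$classification == "pathogenic_match", , drop = FALSE]
    data.frame(
      sample_id = r$sample_id,
      ff = if (!is.null(r$ff)) r$ff$ff else NA_real_,
      ff_method = if (!is.null(r$ff)) r$ff$method else NA_character_,
      qc_pass = if (!is.null(r$ff)) r$ff$qc_pass else NA,
      status = r$status,
      n_cnv_segments = nrow(segs),
      n_aneuploidy_calls = if (!is.null(r$aneuploidy))
        nrow(r$aneuploidy$calls) else 0L,
      risk = if (length(r$risk_labels))
        paste(r$risk_labels, collapse = "; ") else "low risk",
      syndromes = if (nrow(hit)) paste(hit$syndrome, collapse = ";")
        else "",
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("summary.nips_screen", "data.frame")
  out
}

#' Collect all pathogenic-match segments of a cohort screen
#'
#' @param screen a `nips_screen`.
#' @param classification keep only this classification (`NULL` for all
#'   segments).
#' @return data.frame of segments with a `sample_id` column.
#' @export
screen_segments <- function(screen, classification = "pathogenic_match") {
  rows <- lapply(screen$results, function(r) {
    s <- r$segments
    if (!nrow(s)) return(NULL)
    s$sample_id <- r$sample_id
    s
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), state = character(),
                      sample_id = character()))
  rownames(out) <- NULL
  if (!is.null(classification))
    out <- out[out$classification == classification, , drop = FALSE]
  out
}
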