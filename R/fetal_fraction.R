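# Fetal fraction from chromosome-Y representation. For a male fetus the
# chrY read proportion rises linearly with the fetal fraction between two
# calibration anchors: the background mismapping level of a purely female
# sample and the proportion a 100% male genome would give. Female-fetus
# estimation (which needs a genome-wide regression model) is out of scope;
# such samples carry method "unavailable".

#' chrY calibration baselines
#'
#' @param b_female chrY read proportion at fetal fraction 0 (maternal
#'   background mismapping). Default 1e-4 for the synthetic genome; real
#'   deployments must calibrate.
#' @param b_male_adult chrY read proportion of a 100% male genome.
#' @return An `ff_baselines` list.
#' @export
ff_baselines <- function(b_female = 1e-4, b_male_adult = 2.1e-3) {
  stopifnot(b_female >= 0, b_female < b_male_adult, b_male_adult <= 1)
  structure(list(b_female = b_female, b_male_adult = b_male_adult),
            class = "ff_baselines")
}

#' QC thresholds for screening
#'
#' @param min_ff minimum fetal fraction at which aneuploidy / CNV calling is
#'   attempted (default 0.035, just below the 1st percentile of the
#'   unenriched cohort distribution).
#' @param min_unique_reads minimum genome-wide unique reads (default 5e6).
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_ff = 0.035, min_unique_reads = 5e6) {
  structure(list(min_ff = min_ff, min_unique_reads = min_unique_reads),
            class = "qc_thresholds")
}

#' Estimate fetal fraction from chrY representation
#'
#' `R_y = chrY_reads / total_unique_reads`;
#' `ff = (R_y - b_female) / (b_male_adult - b_female)`, clamped to \[0, 1\].
#' The estimate is only reported (method `"chrY"`) when `R_y` exceeds the
#' male-fetus decision threshold
#' `b_female + 0.25 * (b_male_adult - b_female) * min_ff`; below it the
#' fetus is presumed female and the method is `"unavailable"`.
#'
#' @param counts a [sample_counts()].
#' @param baselines an [ff_baselines()].
#' @param min_ff the QC fetal-fraction floor entering the decision
#'   threshold.
#' @return An `ff_estimate`: `sample_id`, `ff` (or `NA`), `method`,
#'   `chry_proportion`, and empty QC fields (see [qc_sample()]).
#' @export
estimate_ff_chry <- function(counts, baselines = ff_baselines(),
                             min_ff = 0.035) {
  if (counts$total_unique_reads <= 0) stop("zero total unique reads")
  ry <- counts$chrY_reads / counts$total_unique_reads
  span <- baselines$b_male_adult - baselines$b_female
  male <- ry > baselines$b_female + 0.25 * span * min_ff
  ff <- if (male) min(1, max(0, (ry - baselines$b_female) / span))
        else NA_real_
  structure(list(sample_id = counts$sample_id, ff = ff,
                 method = if (male) "chrY" else "unavailable",
                 chry_proportion = ry, qc_pass = NA, qc_reasons = character()),
            class = "ff_estimate")
}

#' Apply sample QC gates
#'
#' Marks a sample as failing QC with reason `"low_ff"` (fetal fraction below
#' `min_ff`; only applicable when a chrY estimate exists) and/or
#' `"low_depth"` (fewer than `min_unique_reads` genome-wide unique reads).
#' Samples without a fetal-fraction estimate (presumed female fetus) skip
#' the fetal-fraction gate and carry the note `"ff_unavailable"`; depth
#' gating still applies. Downstream CNV and aneuploidy calling refuse
#' qc-failed samples unless forced.
#'
#' @param counts a [sample_counts()].
#' @param ff an `ff_estimate` from [estimate_ff_chry()].
#' @param thresholds a [qc_thresholds()].
#' @return The `ff_estimate` with `qc_pass`, `qc_reasons` and `qc_notes`
#'   populated.
#' @export
qc_sample <- function(counts, ff, thresholds = qc_thresholds()) {
  reasons <- character()
  notes <- character()
  if (ff$method == "chrY") {
    if (ff$ff < thresholds$min_ff) reasons <- c(reasons, "low_ff")
  } else {
    notes <- c(notes, "ff_unavailable")
  }
  if (counts$total_unique_reads < thresholds$min_unique_reads)
    reasons <- c(reasons, "low_depth")
  ff$qc_pass <- length(reasons) == 0L
  ff$qc_reasons <- reasons
  ff$qc_notes <- notes
  ff
}

#' @export
print.ff_estimate <- function(x, ...) {
  cat(sprintf("sample %s: ff %s (method %s), qc %s%s\n", x$sample_id,
              if (is.na(x$ff)) "NA" else sprintf("%.2f%%", 100 * x$ff),
              x$method,
              if (isTRUE(x$qc_pass)) "pass" else if (isFALSE(x$qc_pass))
                "FAIL" else "not assessed",
              if (length(x$qc_reasons))
                paste0(" [", paste(x$qc_reasons, collapse = ","), "]")
              else ""))
  invisible(x)
}
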