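# Chromosome-level aneuploidy screening: per-chromosome representation of
# GC-corrected counts, tested against same-lot leave-one-out batch
# statistics. A trisomy at fetal fraction ff shifts the affected
# chromosome's representation by a factor ~ (1 + ff/2).

#' Per-chromosome representation of corrected counts
#'
#' Fraction of the sample's CRN falling on each chromosome, computed over
#' usable windows only. The denominator defaults to the autosomes: because
#' fetal sex shifts chrX/chrY dosage by ~ff/2, including the sex
#' chromosomes would make every autosomal fraction fetal-sex-dependent and
#' inflate the batch SD. Sex chromosomes present in the map are still
#' reported, as fractions relative to the same autosomal denominator, so
#' their z-scores can be inspected; the denominator fractions sum to 1.
#' Chromosomes whose windows are all unusable are excluded with a warning.
#'
#' @param crn a `corrected_counts`.
#' @param windows a `window_map`.
#' @param chroms denominator chromosomes (default: all non-X/Y in the map).
#' @return A `chrom_representation`: `sample_id`, named `fraction` vector
#'   (denominator chromosomes sum to 1), and `denominator` names.
#' @export
chromosome_representation <- function(crn, windows, chroms = NULL) {
  if (length(crn$crn) != nrow(windows))
    stop("window count mismatch between corrected counts and window map")
  all_chroms <- unique(windows$chrom)
  if (is.null(chroms))
    chroms <- setdiff(all_chroms, c("chrX", "chrY", "X", "Y"))
  chroms <- intersect(all_chroms, chroms)
  ok <- windows$usable & !is.na(crn$crn)
  if (!any(ok & windows$chrom %in% chroms) ||
      sum(crn$crn[ok & windows$chrom %in% chroms]) <= 0)
    stop("no usable signal: corrected counts are all zero or missing")
  lev <- c(chroms, setdiff(all_chroms, chroms))
  sums <- tapply(crn$crn[ok], factor(windows$chrom[ok], levels = lev), sum)
  sums[is.na(sums)] <- 0
  dead <- names(sums)[sums == 0]
  if (length(dead)) {
    warning("chromosome(s) with no usable windows excluded: ",
            paste(dead, collapse = ", "))
    sums <- sums[sums > 0]
    lev <- names(sums)
  }
  denom <- sum(sums[names(sums) %in% chroms])
  structure(list(sample_id = crn$sample_id,
                 fraction = as.numeric(sums) / denom,
                 chrom = names(sums),
                 denominator = intersect(lev, chroms)),
            class = "chrom_representation")
}

#' Batch Z-test for whole-chromosome aneuploidy
#'
#' For each sample s and chromosome c,
#' `z = (f_sc - mean_c) / sd_c` with mean and SD computed over the other
#' samples of the lot (leave-one-out, so a true trisomy does not shrink its
#' own reference). Samples below the fetal-fraction gate are flagged
#' `"no-call"` rather than tested; samples without a chrY fetal-fraction
#' estimate (presumed female) are tested, with the caveat propagated by QC.
#' Calls are made at `|z| >= z_threshold` on the test chromosomes
#' (autosomes by default; X and Y z-scores are reported without karyotype
#' interpretation).
#'
#' @param representations list of [chromosome_representation()] results
#'   sharing the same chromosome set.
#' @param ff_estimates optional list of `ff_estimate` aligned with
#'   `representations` (used for the fetal-fraction gate).
#' @param z_threshold call threshold (default 3).
#' @param min_ff fetal-fraction gate (default 0.035).
#' @param test_chroms chromosomes eligible for calls (default: all except
#'   X/Y).
#' @param force test even with fewer than 8 samples.
#' @return list of `aneuploidy_result`: per-chromosome `z`, `calls`
#'   data.frame (`chrom`, `direction`, `z`), `status` (`"tested"` or
#'   `"no-call"`), `untestable` chromosomes (degenerate batch SD).
#' @export
batch_aneuploidy_z <- function(representations, ff_estimates = NULL,
                               z_threshold = 3, min_ff = 0.035,
                               test_chroms = NULL, force = FALSE) {
  n <- length(representations)
  if (n < 8 && !force)
    stop("batch has fewer than 8 samples; use force = TRUE to override")
  if (n < 3) stop("need at least 3 samples for leave-one-out statistics")
  chroms <- representations[[1]]$chrom
  for (r in representations)
    if (!identical(r$chrom, chroms))
      stop("representations have mismatched chromosome sets")
  if (is.null(test_chroms))
    test_chroms <- setdiff(chroms, c("chrX", "chrY", "X", "Y"))
  f <- do.call(rbind, lapply(representations, function(r) r$fraction))
  colnames(f) <- chroms
  tot <- colSums(f)
  tot2 <- colSums(f^2)
  out <- vector("list", n)
  for (s in seq_len(n)) {
    m <- (tot - f[s, ]) / (n - 1)
    v <- (tot2 - f[s, ]^2 - (n - 1) * m^2) / (n - 2)
    sd <- sqrt(pmax(v, 0))
    z <- ifelse(sd > 0, (f[s, ] - m) / sd, NA_real_)
    names(z) <- chroms
    untestable <- chroms[sd == 0]
    gated <- FALSE
    if (!is.null(ff_estimates)) {
      ff <- ff_estimates[[s]]
      gated <- identical(ff$method, "chrY") && !is.na(ff$ff) &&
        ff$ff < min_ff
    }
    callable <- !gated & chroms %in% test_chroms & !is.na(z) &
      abs(z) >= z_threshold
    calls <- data.frame(
      chrom = chroms[callable],
      direction = ifelse(z[callable] > 0, "gain", "loss"),
      z = as.numeric(z[callable]), stringsAsFactors = FALSE)
    out[[s]] <- structure(
      list(sample_id = representations[[s]]$sample_id, z = z,
           calls = if (gated) calls[0, ] else calls,
           status = if (gated) "no-call" else "tested",
           untestable = untestable, z_threshold = z_threshold),
      class = "aneuploidy_result")
  }
  names(out) <- vapply(out, function(x) x$sample_id, character(1))
  out
}

#' @export
print.aneuploidy_result <- function(x, ...) {
  cat(sprintf("sample %s aneuploidy: status %s, %d call(s)\n", x$sample_id,
              x$status, nrow(x$calls)))
  if (nrow(x$calls))
    print(x$calls, row.names = FALSE)
  invisible(x)
}
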