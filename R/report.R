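# Clinical-style reporting: ISCN-like coordinate strings, cohort
# fetal-fraction summaries, JSON/TSV/BED emission and the YAML-configured
# pipeline runner. Internal coordinates are 0-based half-open; every
# reported coordinate is 1-based inclusive with the underscore separator
# used by microarray reports, e.g. "arr[GRCh37] 7q11.23(72,669,481_74,154,209)x1".

#' Packaged cytoband table (subset)
#'
#' A small table of approximate GRCh37 cytoband spans covering the packaged
#' syndrome regions (config data; segments falling outside it are reported
#' in the chr:start_end fallback form).
#'
#' @param path TSV with `chrom`, `start`, `end` (0-based half-open),
#'   `band`.
#' @return data.frame.
#' @export
read_cytobands <- function(path = system.file(
    "extdata", "cytobands_grch37_subset.tsv", package = "nipscnv")) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, comment.char = "#")
}

band_at <- function(cytobands, chrom, pos0) {
  hit <- cytobands$chrom == chrom & cytobands$start <= pos0 &
    cytobands$end > pos0
  if (any(hit)) cytobands$band[which(hit)[1]] else NA_character_
}

fmt_bp <- function(x) formatC(x, format = "d", big.mark = ",")

#' Format a CNV segment as an ISCN-like string
#'
#' `arr[<build>] <cytoband>(<start>_<end>)x<copy>` with copy number 1 for a
#' loss and 3 for a gain, coordinates 1-based inclusive. The cytoband is
#' looked up in the packaged table; when a segment spans bands the start and
#' end bands are concatenated, and without band coverage the region falls
#' back to `chr:start_end`.
#'
#' @param segment one row of a [segment_calls()] data.frame (internal
#'   0-based half-open coordinates).
#' @param build genome build label (default `"GRCh37"`).
#' @param cytobands cytoband table or `NULL` to force the fallback form.
#' @return Character string.
#' @export
format_iscn <- function(segment, build = "GRCh37",
                        cytobands = read_cytobands()) {
  start1 <- segment$start + 1
  end1 <- segment$end
  copy <- if (segment$state == "loss") 1L else 3L
  chrom_short <- sub("^chr", "", segment$chrom)
  band <- NULL
  if (!is.null(cytobands)) {
    b1 <- band_at(cytobands, segment$chrom, segment$start)
    b2 <- band_at(cytobands, segment$chrom, segment$end - 1)
    if (!is.na(b1) && !is.na(b2))
      band <- if (identical(b1, b2)) paste0(chrom_short, b1)
              else paste0(chrom_short, b1, b2)
  }
  if (is.null(band))
    sprintf("arr[%s] %s:%s_%sx%d", build, segment$chrom, fmt_bp(start1),
            fmt_bp(end1), copy)
  else
    sprintf("arr[%s] %s(%s_%s)x%d", build, band, fmt_bp(start1),
            fmt_bp(end1), copy)
}

#' Parse an ISCN-like coordinate string
#'
#' Inverse of [format_iscn()] for strings such as
#' `"arr[GRCh37] 7q11.23(72,669,481_74,154,209)x1"`; also accepts the
#' chr:start_end fallback form. Coordinates in the string are 1-based
#' inclusive.
#'
#' @param x the string.
#' @return list with `build`, `locus`, `chrom`, `start`, `end` (1-based
#'   inclusive), `copy`, `size_bp` and `size_mb` (2 dp).
#' @export
parse_iscn <- function(x) {
  m <- regmatches(x, regexec(
    "arr\\[([^]]+)\\]\\s*([0-9XYxy]+[pq][0-9.q]*)\\s*\\(([0-9,]+)_([0-9,]+)\\)x([0-9]+)",
    x))[[1]]
  if (length(m) != 6)
    m <- regmatches(x, regexec(
      "arr\\[([^]]+)\\]\\s*((?:chr)?[0-9XY]+):([0-9,]+)_([0-9,]+)x([0-9]+)",
      x))[[1]]
  if (length(m) != 6) stop("cannot parse ISCN string: ", x)
  start <- as.numeric(gsub(",", "", m[4]))
  end <- as.numeric(gsub(",", "", m[5]))
  locus <- sub(":$", "", m[3])
  chrom <- regmatches(locus, regexpr("^(chr)?[0-9XY]+", locus))
  list(build = m[2], locus = locus, chrom = chrom, start = start,
       end = end, copy = as.integer(m[6]), size_bp = end - start + 1,
       size_mb = round((end - start + 1) / 1e6, 2))
}

#' Cohort fetal-fraction summary and two-group comparison
#'
#' Per-group percentiles (1, 25, 50, 75, 99; linear interpolation between
#' order statistics), mean and SD in the layout of a cohort enrichment
#' table, plus a Welch two-sample t-test between the groups.
#'
#' @param group_a,group_b numeric fetal fractions (same units in and out).
#' @param labels group labels.
#' @return list with `table` (data.frame) and `test` (htest).
#' @export
cohort_ff_summary <- function(group_a, group_b,
                              labels = c("group_a", "group_b")) {
  for (g in list(group_a, group_b)) {
    if (length(g) < 2) stop("degenerate group: need n >= 2")
    if (stats::sd(g) == 0) stop("degenerate group: zero variance")
  }
  q <- function(g) stats::quantile(g, c(0.01, 0.25, 0.5, 0.75, 0.99),
                                   names = FALSE)
  tab <- data.frame(group = labels,
                    rbind(q(group_a), q(group_b)),
                    mean = c(mean(group_a), mean(group_b)),
                    sd = c(stats::sd(group_a), stats::sd(group_b)))
  names(tab)[2:6] <- c("p1", "p25", "p50", "p75", "p99")
  tt <- stats::t.test(group_a, group_b)
  list(table = tab, test = tt)
}

# ---- ScreenResult serialization ----------------------------------------

as_plain <- function(r) {
  list(sample_id = r$sample_id,
       status = r$status,
       ff = if (is.null(r$ff)) NULL else list(
         ff = r$ff$ff, method = r$ff$method,
         chry_proportion = r$ff$chry_proportion,
         qc_pass = r$ff$qc_pass, qc_reasons = as.list(r$ff$qc_reasons),
         qc_notes = as.list(r$ff$qc_notes %||% character(0))),
       aneuploidy = if (is.null(r$aneuploidy)) NULL else list(
         z = as.list(r$aneuploidy$z), calls = r$aneuploidy$calls,
         status = r$aneuploidy$status,
         untestable = as.list(r$aneuploidy$untestable),
         z_threshold = r$aneuploidy$z_threshold),
       segments = r$segments,
       risk_labels = as.list(r$risk_labels))
}

#' Write / read a screening result as JSON
#'
#' Lossless round trip of a `screen_result` (fetal fraction and QC,
#' aneuploidy z-scores and calls, CNV segments with syndrome annotation,
#' risk labels) through a JSON file.
#'
#' @param result a `screen_result`.
#' @param path output path.
#' @export
write_screen_json <- function(result, path) {
  jsonlite::write_json(as_plain(result), path, auto_unbox = TRUE,
                       digits = NA, na = "null", null = "null")
  invisible(path)
}

#' @rdname write_screen_json
#' @export
read_screen_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = TRUE)
  ff <- if (!is.null(p$ff)) structure(list(
    sample_id = p$sample_id, ff = p$ff$ff %||% NA_real_,
    method = p$ff$method, chry_proportion = p$ff$chry_proportion,
    qc_pass = p$ff$qc_pass,
    qc_reasons = as.character(unlist(p$ff$qc_reasons)),
    qc_notes = as.character(unlist(p$ff$qc_notes))),
    class = "ff_estimate")
  aneu <- if (!is.null(p$aneuploidy)) {
    calls <- as.data.frame(p$aneuploidy$calls)
    if (!nrow(calls)) calls <- data.frame(chrom = character(),
                                          direction = character(),
                                          z = numeric())
    zr <- p$aneuploidy$z
    z <- if (is.list(zr))
      vapply(zr, function(v) if (is.null(v)) NA_real_ else as.numeric(v),
             numeric(1))
    else { zn <- as.numeric(zr); names(zn) <- names(zr); zn }
    structure(list(sample_id = p$sample_id,
                   z = z,
                   calls = calls, status = p$aneuploidy$status,
                   untestable =
                     as.character(unlist(p$aneuploidy$untestable)),
                   z_threshold = p$aneuploidy$z_threshold),
              class = "aneuploidy_result")
  }
  segs <- as.data.frame(p$segments)
  if (nrow(segs)) {
    for (cn in intersect(c("start", "end", "mean_z", "seg_score",
                           "size_bp", "size_mb", "overlap_fraction"),
                         names(segs)))
      segs[[cn]] <- as.numeric(segs[[cn]])
    if ("n_windows" %in% names(segs))
      segs$n_windows <- as.integer(segs$n_windows)
    for (cn in intersect(c("chrom", "state", "syndrome",
                           "classification"), names(segs)))
      segs[[cn]] <- as.character(segs[[cn]])
  }
  if (!nrow(segs))
    segs <- segment_calls(character(0), numeric(0),
                          new_window_map(data.frame(
                            chrom = character(), start = numeric(),
                            end = numeric(), expected_unique = numeric(),
                            gc = numeric(), usable = logical())))
  structure(list(sample_id = p$sample_id, ff = ff, aneuploidy = aneu,
                 segments = segs, z = NULL,
                 risk_labels = as.character(unlist(p$risk_labels)),
                 status = p$status),
            class = "screen_result")
}

#' Write cohort results as TSV / BED
#'
#' @param screen a `nips_screen`.
#' @param path output path.
#' @export
write_cohort_tsv <- function(screen, path) {
  utils::write.table(summary(screen), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
write_segments_bed <- function(screen, path) {
  segs <- screen_segments(screen, classification = NULL)
  bed <- data.frame(chrom = segs$chrom, start = segs$start, end = segs$end,
                    name = sprintf("%s|%s|%s", segs$sample_id, segs$state,
                                   ifelse(is.na(segs$syndrome), ".",
                                          segs$syndrome)),
                    score = pmin(1000, round(abs(segs$seg_score) * 100)))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- Run configuration --------------------------------------------------

#' Read and validate a YAML run configuration
#'
#' Required keys: `windows`, `counts`, `out_dir`; optional `catalog` (the
#' packaged catalog by default) and parameter blocks `filter`, `qc`,
#' `baselines`, `hmm` (`z_cuts`), `z_threshold`, `min_seg_score`, `seed`,
#' `batch_id`. Path existence is checked up front so a bad configuration
#' fails before any computation; every defaulted parameter is recorded and
#' echoed to the run log.
#'
#' @param path YAML file.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  defaulted <- character(0)
  take <- function(key, default) {
    if (!is.null(y[[key]])) return(y[[key]])
    defaulted <<- c(defaulted, key)
    default
  }
  for (key in c("windows", "counts"))
    if (is.null(y[[key]])) stop("config missing required path: ", key)
  catalog <- take("catalog", system.file("extdata", "syndromes_grch37.tsv",
                                         package = "nipscnv"))
  for (p in c(y$windows, y$counts, catalog))
    if (!file.exists(p)) stop("configured path does not exist: ", p)
  out_dir <- take("out_dir", "nipscnv_out")
  qc <- qc_thresholds(
    min_ff = take("min_ff", 0.035),
    min_unique_reads = take("min_unique_reads", 5e6))
  bl <- ff_baselines(
    b_female = take("b_female", 1e-4),
    b_male_adult = take("b_male_adult", 2.1e-3))
  hmm <- if (!is.null(y$z_cuts)) hmm_params(cuts = y$z_cuts) else {
    defaulted <- c(defaulted, "z_cuts")
    hmm_params()
  }
  cfg <- list(windows = y$windows, counts = y$counts, catalog = catalog,
              out_dir = out_dir,
              screen = screen_config(
                baselines = bl, qc = qc, hmm = hmm,
                z_threshold = take("z_threshold", 3),
                min_seg_score = take("min_seg_score", 3.5)),
              seed = take("seed", 1L),
              batch_id = take("batch_id", "batch1"),
              force = isTRUE(y$force),
              defaulted = defaulted)
  class(cfg) <- "run_config"
  cfg
}

#' Hash the effective configuration
#'
#' MD5 of the canonical JSON serialisation of every effective parameter;
#' changes iff a parameter changes.
#'
#' @param config a `run_config` or `screen_config`.
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  strip <- function(x) {
    if (is.function(x)) return(NULL)
    if (is.list(x)) {
      x <- lapply(x, strip)
      return(x[!vapply(x, is.null, logical(1))])
    }
    x
  }
  canon <- jsonlite::toJSON(strip(unclass(config)), digits = NA,
                            auto_unbox = TRUE, force = TRUE)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(canon), tf)
  unname(tools::md5sum(tf))
}

#' Run the full screening pipeline from a configuration
#'
#' Reads the window map, count matrix and syndrome catalog named by the
#' configuration, screens the cohort, and writes per-sample JSON reports, a
#' cohort summary TSV, a BED5 of all CNV segments and a run log that echoes
#' every defaulted parameter. Deterministic given config + inputs + seed.
#'
#' @param config a `run_config` (see [read_run_config()]) or a YAML path.
#' @return The `nips_screen`, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  set.seed(config$seed)
  windows <- read_window_map(config$windows)
  samples <- read_counts(config$counts)
  catalog <- read_syndrome_catalog(config$catalog)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- c(sprintf("nipscnv run %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
           sprintf("config hash: %s", config_hash(config)),
           sprintf("samples: %d, windows: %d", length(samples),
                   nrow(windows)),
           sprintf("defaulted parameters: %s",
                   if (length(config$defaulted))
                     paste(config$defaulted, collapse = ", ") else "none"))
  screen <- screen_cohort(samples, windows, catalog,
                          config = config$screen, force = config$force)
  for (r in screen$results)
    write_screen_json(r, file.path(config$out_dir,
                                   sprintf("sample_%s.json", r$sample_id)))
  write_cohort_tsv(screen, file.path(config$out_dir, "cohort.tsv"))
  write_segments_bed(screen, file.path(config$out_dir, "segments.bed"))
  nocall <- vapply(screen$results, function(r) r$status == "no-call",
                   logical(1))
  if (any(nocall))
    log <- c(log, sprintf("warning: %d sample(s) no-call after QC: %s",
                          sum(nocall),
                          paste(names(screen$results)[nocall],
                                collapse = ", ")))
  writeLines(log, file.path(config$out_dir, "run.log"))
  invisible(screen)
}
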