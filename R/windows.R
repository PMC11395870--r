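# Genome windows: adjacent intervals each holding a constant expected number
# of uniquely mappable positions, ~1 Mb average length. All internal
# coordinates are 0-based half-open (BED convention); reports convert to
# 1-based inclusive at the formatting boundary.

#' Synthetic genome layouts
#'
#' Returns a genome specification (chromosome names and lengths) used by
#' [uniform_track()] and the cohort simulator. Two layouts are shipped:
#' `"macro"` collapses the 22 autosomes into four macro-chromosomes plus X
#' and Y, scaled to ~3.1 Gb of total window mass (the approximate uniquely
#' mappable autosomal+sex mass of GRCh37); `"ws"` replaces one macro
#' autosome with a chromosome-7-like contig carrying GRCh37-like 7q11.23
#' coordinates, for microdeletion screening experiments.
#'
#' @param layout `"macro"` or `"ws"`.
#' @return A data.frame with columns `chrom` and `length` (bp, multiples of
#'   10 kb).
#' @export
synthetic_genome <- function(layout = c("macro", "ws")) {
  layout <- match.arg(layout)
  spec <- switch(layout,
    macro = data.frame(
      chrom  = c("chrA1", "chrA2", "chrA3", "chrA4", "chrX", "chrY"),
      length = c(800e6, 760e6, 700e6, 620e6, 155e6, 59.2e6)
    ),
    ws = data.frame(
      chrom  = c("chr7", "chrA1", "chrA2", "chrA3", "chrX", "chrY"),
      length = c(158.4e6, 950e6, 950e6, 880e6, 155e6, 59.2e6)
    )
  )
  spec$length <- as.numeric(spec$length)
  attr(spec, "layout") <- layout
  # the ws layout mimics GRCh37 chromosome-7 coordinates, so maps built
  # from it can be matched against the GRCh37 syndrome catalog
  attr(spec, "genome_build") <- if (layout == "ws") "GRCh37" else "synthetic"
  spec
}

#' Default smooth GC profile for synthetic genomes
#'
#' Deterministic position-dependent GC fraction used when building synthetic
#' mappability tracks: a slowly varying curve in roughly \[0.33, 0.51\],
#' mimicking the isochore-scale GC variation that drives coverage bias in
#' PCR-amplified libraries.
#'
#' @param chrom chromosome name (enters a small per-chromosome phase shift).
#' @param mid numeric vector of positions (bp).
#' @return GC fractions in (0, 1).
#' @export
synthetic_gc_profile <- function(chrom, mid) {
  phase <- (utf8ToInt(paste(substr(chrom, 1, 8), collapse = ""))[1] %% 7) / 7
  0.42 + 0.07 * sin(2 * pi * (mid / 37e6 + phase)) +
    0.02 * cos(2 * pi * mid / 7.3e6)
}

#' Build a fully mappable synthetic mappability track
#'
#' Every small bin is fully uniquely mappable (`unique_positions` equals the
#' bin length), with GC either constant or taken from a profile function of
#' `(chrom, bin midpoint)`.
#'
#' @param genome_spec data.frame with columns `chrom`, `length`
#'   (e.g. [synthetic_genome()]).
#' @param bin_size small-bin resolution in bp (default 10 kb); all
#'   chromosome lengths must be multiples of it.
#' @param gc a single GC fraction or a `function(chrom, mid)`.
#' @return A `mappability_track` data.frame with columns `chrom`, `start`,
#'   `end`, `unique_positions`, `gc`.
#' @export
uniform_track <- function(genome_spec, bin_size = 1e4, gc = 0.41) {
  if (is.null(genome_spec) || nrow(genome_spec) == 0L)
    stop("empty genome_spec")
  if (any(genome_spec$length %% bin_size != 0))
    stop("chromosome lengths must be multiples of bin_size")
  pieces <- lapply(seq_len(nrow(genome_spec)), function(i) {
    chrom <- genome_spec$chrom[i]
    n <- genome_spec$length[i] / bin_size
    start <- (seq_len(n) - 1) * bin_size
    mid <- start + bin_size / 2
    g <- if (is.function(gc)) gc(chrom, mid) else rep(gc, n)
    data.frame(chrom = chrom, start = start, end = start + bin_size,
               unique_positions = rep(bin_size, n), gc = g)
  })
  track <- do.call(rbind, pieces)
  rownames(track) <- NULL
  attr(track, "bin_size") <- bin_size
  attr(track, "genome_build") <- attr(genome_spec, "genome_build") %||%
    "synthetic"
  class(track) <- c("mappability_track", "data.frame")
  track
}

new_window_map <- function(df, genome_build = "synthetic",
                           target_avg_len = NA_real_) {
  df$index <- seq_len(nrow(df)) - 1L
  rownames(df) <- NULL
  attr(df, "genome_build") <- genome_build
  attr(df, "target_avg_len") <- target_avg_len
  class(df) <- c("window_map", "data.frame")
  df
}

#' Build constant-quota genome windows from a mappability track
#'
#' Each chromosome is cut into adjacent windows holding (to within one small
#' bin) a constant number of uniquely mappable positions. The per-window
#' quota is `T = total unique positions on the chromosome / round(chromosome
#' length / target_avg_len)`, so poorly mappable regions stretch windows
#' while the expected read count per window stays flat. Windows never cross
#' chromosome boundaries; the last window on a chromosome absorbs the
#' remainder. Per-window GC is the unique-position-weighted mean of the
#' constituent bin GC.
#'
#' @param track a `mappability_track` (see [uniform_track()]).
#' @param target_avg_len target average window length in bp (default 1 Mb);
#'   must be at least 10x the bin size.
#' @return A `window_map` data.frame: `chrom`, `start`, `end`,
#'   `expected_unique`, `gc`, `usable`, `index` (0-based, genome order).
#'   A chromosome with no uniquely mappable positions becomes a single
#'   window flagged unusable.
#' @export
build_windows <- function(track, target_avg_len = 1e6) {
  if (is.null(track) || nrow(track) == 0L) stop("empty mappability track")
  bin_size <- attr(track, "bin_size")
  if (is.null(bin_size)) bin_size <- stats::median(track$end - track$start)
  if (target_avg_len < 10 * bin_size)
    stop("target_avg_len must be >= 10 x bin size")
  chroms <- unique(track$chrom)
  out <- vector("list", length(chroms))
  for (k in seq_along(chroms)) {
    b <- track[track$chrom == chroms[k], , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    chrom_len <- max(b$end) - min(b$start)
    total <- sum(b$unique_positions)
    if (total == 0) {
      out[[k]] <- data.frame(
        chrom = chroms[k], start = min(b$start), end = max(b$end),
        expected_unique = 0, gc = NA_real_, usable = FALSE)
      next
    }
    nwin <- max(1L, as.integer(round(chrom_len / target_avg_len)))
    quota <- total / nwin
    cum <- cumsum(b$unique_positions)
    # a bin belongs to window w while the sum BEFORE it is under w * quota,
    # so the bin that reaches the quota still closes its window
    win <- pmin(floor((cum - b$unique_positions) / quota + 1e-9) + 1L, nwin)
    start <- tapply(b$start, win, min)
    end <- tapply(b$end, win, max)
    eu <- tapply(b$unique_positions, win, sum)
    gw <- vapply(split(seq_len(nrow(b)), win), function(ix) {
      w <- b$unique_positions[ix]
      if (sum(w) == 0) NA_real_ else sum(b$gc[ix] * w) / sum(w)
    }, numeric(1))
    out[[k]] <- data.frame(
      chrom = chroms[k], start = as.numeric(start), end = as.numeric(end),
      expected_unique = as.numeric(eu), gc = as.numeric(gw),
      usable = as.numeric(eu) > 0)
  }
  new_window_map(do.call(rbind, out),
                 genome_build = attr(track, "genome_build") %||% "synthetic",
                 target_avg_len = target_avg_len)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.window_map <- function(x, ...) {
  cat(sprintf("window map: %d windows on %d chromosome(s), build %s\n",
              nrow(x), length(unique(x$chrom)),
              attr(x, "genome_build") %||% "?"))
  cat(sprintf("  mean length %.2f Mb, mean expected unique positions %.0f\n",
              mean(x$end - x$start) / 1e6, mean(x$expected_unique)))
  invisible(x)
}

validate_window_map <- function(map, where = "window map") {
  for (chrom in unique(map$chrom)) {
    m <- map[map$chrom == chrom, , drop = FALSE]
    if (any(m$end <= m$start)) {
      i <- which(m$end <= m$start)[1]
      stop(sprintf("%s: empty window at line %d (%s:%d-%d)", where,
                   which(map$chrom == chrom)[i], chrom, m$start[i], m$end[i]))
    }
    if (nrow(m) > 1) {
      bad <- which(m$start[-1] != m$end[-nrow(m)])
      if (length(bad)) {
        i <- bad[1]
        verb <- if (m$start[i + 1] < m$end[i]) "overlapping" else "non-adjacent"
        stop(sprintf("%s: %s or unsorted windows at line %d (%s:%d)", where,
                     verb, which(map$chrom == chrom)[i + 1], chrom,
                     m$start[i + 1]))
      }
    }
  }
  invisible(map)
}

#' Read / write a window map TSV
#'
#' Lossless round trip through a BED-derived TSV (`chrom`, `start`, `end`,
#' `expected_unique`, `gc`) with a `#genome_build=` header line. Rows must
#' be sorted and adjacent within each chromosome.
#'
#' @param path file path.
#' @return [read_window_map()] returns a `window_map`.
#' @export
read_window_map <- function(path) {
  lines <- readLines(path)
  build <- "synthetic"
  hdr <- grep("^#genome_build=", lines, value = TRUE)
  if (length(hdr)) build <- sub("^#genome_build=", "", hdr[1])
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.table(text = body, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "expected_unique", "gc")
  if (!all(need %in% names(df)))
    stop("window map file missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df$usable <- df$expected_unique > 0
  map <- new_window_map(df[, c(need, "usable")], genome_build = build)
  validate_window_map(map, where = path)
  map
}

#' @rdname read_window_map
#' @param map a `window_map`.
#' @export
write_window_map <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#genome_build=%s",
                     attr(map, "genome_build") %||% "synthetic"), con)
  utils::write.table(
    map[, c("chrom", "start", "end", "expected_unique", "gc")],
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
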