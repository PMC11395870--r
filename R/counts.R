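# Read filtering and per-window counting. "Unique reads" (URs) are the
# alignments surviving the quality / duplicate / mismatch filters; mapping
# quality is the uniqueness proxy (multi-mappers carry MAPQ 0).

#' Alignment filter parameters
#'
#' @param min_mapq minimum mapping quality; MAPQ below this is treated as
#'   non-unique or low quality (default 30).
#' @param max_mismatches maximum edit distance (`NM` tag) for a 50 bp read;
#'   records without an `NM` tag pass this check (permissive).
#' @param drop_duplicates,drop_unmapped,drop_secondary_supplementary flag
#'   filters (all default `TRUE`).
#' @return A `filter_params` list.
#' @export
filter_params <- function(min_mapq = 30L, max_mismatches = 2L,
                          drop_duplicates = TRUE, drop_unmapped = TRUE,
                          drop_secondary_supplementary = TRUE) {
  stopifnot(min_mapq >= 0, max_mismatches >= 0)
  structure(list(min_mapq = as.integer(min_mapq),
                 max_mismatches = as.integer(max_mismatches),
                 drop_duplicates = isTRUE(drop_duplicates),
                 drop_unmapped = isTRUE(drop_unmapped),
                 drop_secondary_supplementary =
                   isTRUE(drop_secondary_supplementary)),
            class = "filter_params")
}

# SAM flag bits
FLAG_PAIRED <- 1L; FLAG_UNMAPPED <- 4L; FLAG_READ2 <- 128L
FLAG_SECONDARY <- 256L; FLAG_DUP <- 1024L; FLAG_SUPPLEMENTARY <- 2048L

has_flag <- function(flag, bit) bitwAnd(as.integer(flag), bit) != 0L

#' Filter alignment records
#'
#' Vectorised filter over a record table with columns `flag`, `mapq` and
#' optionally `nm` (edit distance; `NA` passes). A record is kept iff it is
#' mapped, not duplicate-flagged, not secondary/supplementary, not the
#' second read of a pair (single-end 50 bp reads are assumed; for paired
#' input only read 1 is counted), `mapq >= min_mapq`, and
#' `nm <= max_mismatches`. The reason code names the first failed criterion.
#'
#' @param records data.frame with `flag`, `mapq`, optional `nm`.
#' @param params a [filter_params()].
#' @return data.frame with logical `keep` and character `reason`
#'   (`"pass"`, `"unmapped"`, `"duplicate"`, `"secondary_supplementary"`,
#'   `"read2"`, `"low_mapq"`, `"mismatches"`).
#' @export
filter_alignment <- function(records, params = filter_params()) {
  if (!all(c("flag", "mapq") %in% names(records)))
    stop("records must have 'flag' and 'mapq' columns")
  flag <- as.integer(records$flag)
  if (anyNA(flag)) stop("malformed record: NA flag at line ",
                        which(is.na(flag))[1])
  n <- length(flag)
  nm <- if ("nm" %in% names(records)) records$nm else rep(NA_integer_, n)
  reason <- rep("pass", n)
  mark <- function(cond, code) {
    hit <- cond & reason == "pass"
    reason[hit] <<- code
  }
  if (params$drop_unmapped) mark(has_flag(flag, FLAG_UNMAPPED), "unmapped")
  if (params$drop_duplicates) mark(has_flag(flag, FLAG_DUP), "duplicate")
  if (params$drop_secondary_supplementary)
    mark(has_flag(flag, FLAG_SECONDARY) | has_flag(flag, FLAG_SUPPLEMENTARY),
         "secondary_supplementary")
  mark(has_flag(flag, FLAG_PAIRED) & has_flag(flag, FLAG_READ2), "read2")
  mapq <- as.integer(records$mapq)
  mapq[is.na(mapq)] <- 0L
  mark(mapq < params$min_mapq, "low_mapq")
  mark(!is.na(nm) & nm > params$max_mismatches, "mismatches")
  data.frame(keep = reason == "pass", reason = reason,
             stringsAsFactors = FALSE)
}

#' Read alignment records from a SAM file
#'
#' Thin wrapper over Rsamtools: the text SAM is converted to a temporary BAM
#' and scanned for the fields the filters and counters need.
#'
#' @param path SAM file path.
#' @return data.frame with `rname`, `pos` (1-based leftmost), `mapq`,
#'   `flag`, `nm`.
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stop("SAM file not found: ", path)
  bam <- Rsamtools::asBam(path, destination = tempfile(),
                          overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  p <- Rsamtools::ScanBamParam(what = c("rname", "pos", "mapq", "flag"),
                               tag = "NM")
  r <- Rsamtools::scanBam(bam, param = p)[[1]]
  data.frame(rname = as.character(r$rname), pos = r$pos, mapq = r$mapq,
             flag = r$flag, nm = as.integer(r$tag$NM),
             stringsAsFactors = FALSE)
}

#' Per-sample container of raw window counts
#'
#' @param sample_id sample label.
#' @param raw integer vector of per-window retained-read counts, aligned to
#'   a window map.
#' @param total_unique_reads genome-wide retained reads (includes reads on
#'   contigs absent from the window map).
#' @param chrY_reads retained reads on the Y chromosome.
#' @param batch_id sequencing lot label.
#' @param reported_sex_karyotype optional label.
#' @return A `sample_counts` object.
#' @export
sample_counts <- function(sample_id, raw, total_unique_reads = sum(raw),
                          chrY_reads = 0, batch_id = "batch1",
                          reported_sex_karyotype = NA_character_) {
  stopifnot(all(raw >= 0, na.rm = TRUE), total_unique_reads >= 0,
            chrY_reads >= 0)
  structure(list(sample_id = as.character(sample_id), raw = as.numeric(raw),
                 total_unique_reads = as.numeric(total_unique_reads),
                 chrY_reads = as.numeric(chrY_reads),
                 batch_id = as.character(batch_id),
                 reported_sex_karyotype = reported_sex_karyotype),
            class = "sample_counts")
}

#' @export
print.sample_counts <- function(x, ...) {
  cat(sprintf("sample %s (batch %s): %d windows, %.2f M unique reads, %d chrY\n",
              x$sample_id, x$batch_id, length(x$raw),
              x$total_unique_reads / 1e6, x$chrY_reads))
  invisible(x)
}

chry_aliases <- c("chrY", "Y")

#' Count filtered reads per window
#'
#' Applies [filter_alignment()] and assigns each retained read to the window
#' containing its leftmost aligned base (half-open windows: a read starting
#' exactly on a boundary belongs to the right-hand window). Reads on contigs
#' absent from the window map still count toward `total_unique_reads` (and
#' `chrY_reads` for Y) so that genome-wide QC and fetal-fraction totals are
#' correct.
#'
#' @param alignments a SAM path or a record data.frame (`rname`, `pos`,
#'   `mapq`, `flag`, optional `nm`).
#' @param windows a `window_map`.
#' @param params a [filter_params()].
#' @param sample_id,batch_id labels for the result.
#' @return A [sample_counts()] object.
#' @export
count_sample <- function(alignments, windows, params = filter_params(),
                         sample_id = "sample", batch_id = "batch1") {
  rec <- if (is.character(alignments)) read_sam(alignments) else alignments
  f <- filter_alignment(rec, params)
  rec <- rec[f$keep, , drop = FALSE]
  if (nrow(rec) == 0L) stop("empty sample: no reads pass filters")
  raw <- numeric(nrow(windows))
  pos0 <- rec$pos - 1  # 0-based leftmost base
  for (chrom in unique(rec$rname)) {
    w <- which(windows$chrom == chrom)
    if (!length(w)) next
    r <- which(rec$rname == chrom)
    idx <- findInterval(pos0[r], windows$start[w])
    ok <- idx >= 1 & pos0[r] < windows$end[w][pmax(idx, 1)]
    tab <- table(idx[ok])
    raw[w[as.integer(names(tab))]] <- raw[w[as.integer(names(tab))]] +
      as.numeric(tab)
  }
  sample_counts(sample_id, raw,
                total_unique_reads = nrow(rec),
                chrY_reads = sum(rec$rname %in% chry_aliases),
                batch_id = batch_id)
}

#' Read / write a count matrix TSV
#'
#' One row per window and one column per sample, preceded by a metadata
#' header block (`#sample` lines carrying totals, chrY reads, batch and
#' karyotype labels). The round trip is lossless.
#'
#' @param path file path.
#' @return [read_counts()] returns a list of [sample_counts()].
#' @export
read_counts <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#sample\t")]
  body <- lines[!startsWith(lines, "#")]
  md <- if (length(meta)) {
    utils::read.table(text = meta, sep = "\t", stringsAsFactors = FALSE,
                      comment.char = "",
                      col.names = c("tag", "sample_id", "total", "chry",
                                    "batch", "sex"),
                      colClasses = c("character", "character", "numeric",
                                     "numeric", "character", "character"))
  } else NULL
  df <- utils::read.table(text = body, header = TRUE, sep = "\t",
                          check.names = FALSE)
  if (is.null(md)) return(list())
  out <- lapply(seq_len(nrow(md)), function(i) {
    id <- md$sample_id[i]
    if (!id %in% names(df))
      stop("counts file: no column for sample ", id)
    sample_counts(id, df[[id]], total_unique_reads = md$total[i],
                  chrY_reads = md$chry[i], batch_id = md$batch[i],
                  reported_sex_karyotype =
                    if (is.na(md$sex[i]) || md$sex[i] == ".") NA_character_
                    else md$sex[i])
  })
  names(out) <- md$sample_id
  out
}

#' @rdname read_counts
#' @param samples list of [sample_counts()] with equal window counts.
#' @export
write_counts <- function(samples, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#nipscnv_counts\tv1", con)
  if (length(samples)) {
    nwin <- unique(vapply(samples, function(s) length(s$raw), integer(1)))
    if (length(nwin) != 1L)
      stop("samples have mismatched window counts")
    for (s in samples)
      writeLines(sprintf("#sample\t%s\t%.0f\t%.0f\t%s\t%s", s$sample_id,
                         s$total_unique_reads, s$chrY_reads, s$batch_id,
                         if (is.na(s$reported_sex_karyotype)) "."
                         else s$reported_sex_karyotype), con)
    mat <- data.frame(window_index = seq_len(nwin) - 1L)
    for (s in samples) mat[[s$sample_id]] <- s$raw
    utils::write.table(mat, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    writeLines("window_index", con)
  }
  invisible(path)
}
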