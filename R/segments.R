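#' Build a validated copy-number segment table
#'
#' Internal representation of gain/loss calls: one row per segment with
#' 0-based half-open coordinates.  All wGII and gene-state machinery works on
#' this class.  Most users will call [read_segments()]; this constructor is
#' exposed so that segments assembled in code (e.g. by
#' [simulate_segments()]) go through the same validation.
#'
#' @param df data.frame with columns `sample`, `chrom`, `start`, `end`,
#'   `call` and optionally `copy_number`, `mosaic_fraction`.  Coordinates
#'   must already be 0-based half-open.
#' @param build optional [genome_build()]; when supplied, every segment
#'   chromosome must exist in the build and `end` may not exceed the
#'   chromosome length.
#' @return A `data.frame` of class `segment_table`.
#' @details Validation failures are reported with row indices so offending
#'   records can be located in the source file.  `call` must be `"gain"` or
#'   `"loss"`; when `copy_number` is present it must agree with the call
#'   (gain > 2, loss < 2).  `mosaic_fraction`, when present, must lie in
#'   (0, 1]; mosaic segments are retained at full weight by the downstream
#'   wGII computation (the fraction is metadata).
#' @export
segment_table <- function(df, build = NULL) {
  required <- c("sample", "chrom", "start", "end", "call")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("segment table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  df$sample <- as.character(df$sample)
  df$chrom <- as.character(df$chrom)
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  df$call <- as.character(df$call)
  if (!"copy_number" %in% names(df)) df$copy_number <- rep(NA_real_, nrow(df))
  if (!"mosaic_fraction" %in% names(df))
    df$mosaic_fraction <- rep(NA_real_, nrow(df))

  bad_call <- which(!df$call %in% c("gain", "loss"))
  if (length(bad_call) > 0)
    stop("invalid call (must be 'gain' or 'loss') in row(s): ",
         paste(utils::head(bad_call, 10), collapse = ", "))
  bad_coord <- which(!is.finite(df$start) | !is.finite(df$end) |
                       df$start < 0 | df$end <= df$start)
  if (length(bad_coord) > 0)
    stop("invalid coordinates (need 0 <= start < end) in row(s): ",
         paste(utils::head(bad_coord, 10), collapse = ", "),
         " [samples: ",
         paste(utils::head(unique(df$sample[bad_coord]), 5), collapse = ", "),
         "]")
  cn <- df$copy_number
  bad_cn <- which(!is.na(cn) &
                    ((df$call == "gain" & cn <= 2) |
                       (df$call == "loss" & cn >= 2)))
  if (length(bad_cn) > 0)
    stop("copy_number inconsistent with call (gain => >2, loss => <2) ",
         "in row(s): ", paste(utils::head(bad_cn, 10), collapse = ", "))
  mf <- df$mosaic_fraction
  bad_mf <- which(!is.na(mf) & (mf <= 0 | mf > 1))
  if (length(bad_mf) > 0)
    stop("mosaic_fraction outside (0, 1] in row(s): ",
         paste(utils::head(bad_mf, 10), collapse = ", "))

  if (!is.null(build)) {
    stopifnot(inherits(build, "genome_build"))
    unknown <- setdiff(unique(df$chrom), build$chrom)
    if (length(unknown) > 0)
      stop("segment chromosome(s) absent from genome build: ",
           paste(unknown, collapse = ", "))
    len <- stats::setNames(build$length, build$chrom)
    over <- which(df$end > len[df$chrom])
    if (length(over) > 0)
      stop("segment end exceeds chromosome length in row(s): ",
           paste(utils::head(over, 10), collapse = ", "))
  }
  out <- df[, c("sample", "chrom", "start", "end", "call",
                "copy_number", "mosaic_fraction")]
  rownames(out) <- NULL
  class(out) <- c("segment_table", "data.frame")
  out
}

#' Read copy-number segments from a TSV export
#'
#' Reads a segment file in either of two coordinate dialects and normalises
#' to the internal 0-based half-open convention:
#' \describe{
#'   \item{`chas`}{ChAS-style export, 1-based inclusive coordinates; a row
#'     `(chr1, 1, 100)` denotes the first 100 bases and becomes
#'     `[0, 100)` internally.}
#'   \item{`bed`}{BED-style, already 0-based half-open; taken as is.}
#' }
#'
#' @param path tab-separated file with columns `sample`, `chrom`, `start`,
#'   `end`, `call` and optional `copy_number`, `mosaic_fraction`.
#' @param dialect `"chas"` or `"bed"`.
#' @param build optional [genome_build()] used for validation.
#' @return A [segment_table()].
#' @export
read_segments <- function(path, dialect = c("chas", "bed"), build = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("sample", "chrom", "start", "end", "call")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("segment file '", basename(path), "' lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (dialect == "chas") {
    df$start <- as.numeric(df$start) - 1
  }
  segment_table(df, build = build)
}

#' Write a segment table as BED-dialect TSV
#'
#' @param segments a [segment_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  stopifnot(inherits(segments, "segment_table"))
  utils::write.table(as.data.frame(segments), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Merge altered intervals for one sample
#'
#' Pools gain and loss segments on each chromosome into their set union so
#' that a base covered by several calls (or by both a gain and a loss in a
#' mosaic profile) is counted once.  This is the interval arithmetic behind
#' wGII: the altered length of a chromosome is the summed width of these
#' merged intervals.
#'
#' @param segments a [segment_table()].
#' @param sample sample id to merge; `NULL` is allowed only when the table
#'   holds a single sample.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open, sorted, non-overlapping) and attribute `altered_bp` with the
#'   per-chromosome merged widths (named numeric).
#' @export
merge_altered <- function(segments, sample = NULL) {
  stopifnot(inherits(segments, "segment_table"))
  if (is.null(sample)) {
    ids <- unique(segments$sample)
    if (length(ids) > 1)
      stop("segment table holds ", length(ids),
           " samples; supply `sample`")
    sample <- ids
  }
  seg <- segments[segments$sample %in% sample, , drop = FALSE]
  if (nrow(seg) == 0) {
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE)
    attr(out, "altered_bp") <- stats::setNames(numeric(), character())
    return(out)
  }
  # IRanges is 1-based closed; [start, end) maps to start+1 .. end
  rl <- split(IRanges::IRanges(start = as.integer(seg$start) + 1L,
                               end = as.integer(seg$end)),
              seg$chrom)
  merged <- lapply(rl, IRanges::reduce)
  chrom <- rep(names(merged), times = vapply(merged, length, 0L))
  starts <- unlist(lapply(merged, IRanges::start), use.names = FALSE) - 1
  ends <- unlist(lapply(merged, IRanges::end), use.names = FALSE)
  ord <- order(chrom, starts)
  out <- data.frame(chrom = chrom[ord], start = starts[ord],
                    end = ends[ord], stringsAsFactors = FALSE)
  bp <- vapply(merged, function(ir) sum(as.numeric(IRanges::width(ir))), 0)
  attr(out, "altered_bp") <- bp
  out
}
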