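#' Construct a genome build
#'
#' A genome build is the reference against which copy-number segments are
#' validated and wGII is computed: one row per chromosome with its length in
#' base pairs and a flag marking autosomes.  Only autosomes enter the wGII
#' denominator; sex chromosomes may be present for validation but are ignored
#' by [compute_wgii()].
#'
#' @param chrom character vector of unique chromosome names.
#' @param length integer-like vector of chromosome lengths in base pairs
#'   (all positive).
#' @param autosome logical vector; if `NULL`, chromosomes named
#'   `X`/`Y`/`chrX`/`chrY`/`MT`/`chrM` (case-insensitive) are treated as
#'   non-autosomes and everything else as an autosome.
#' @return A `data.frame` of class `genome_build` with columns `chrom`,
#'   `length`, `autosome`.
#' @examples
#' gb <- genome_build(c("chrA", "chrB"), c(100, 200))
#' @seealso [hs_autosomes()], [read_genome_build()]
#' @export
genome_build <- function(chrom, length, autosome = NULL) {
  chrom <- as.character(chrom)
  if (anyDuplicated(chrom))
    stop("duplicated chromosome names: ",
         paste(unique(chrom[duplicated(chrom)]), collapse = ", "))
  length <- as.numeric(length)
  if (any(!is.finite(length)) || any(length <= 0) || any(length != round(length)))
    stop("chromosome lengths must be positive integers")
  if (is.null(autosome)) {
    autosome <- !grepl("^(chr)?(x|y|m|mt)$", chrom, ignore.case = TRUE)
  }
  autosome <- as.logical(autosome)
  stopifnot(base::length(autosome) == base::length(chrom))
  if (!any(autosome))
    stop("genome build must contain at least one autosome")
  out <- data.frame(chrom = chrom, length = length, autosome = autosome,
                    stringsAsFactors = FALSE)
  class(out) <- c("genome_build", "data.frame")
  out
}

#' Human autosome lengths
#'
#' Convenience build with the 22 human autosome lengths (GRCh38 primary
#' assembly).  Used as the default reference for the synthetic-cohort
#' generators.
#'
#' @param with_sex if `TRUE`, chrX and chrY are appended (flagged as
#'   non-autosomes, so they never enter wGII).
#' @return A `genome_build`.
#' @export
hs_autosomes <- function(with_sex = FALSE) {
  len <- c(248956422, 242193529, 198295559, 190214555, 181538259, 170805979,
           159345973, 145138636, 138394717, 133797422, 135086622, 133275309,
           114364328, 107043718, 101991189,  90338345,  83257441,  80373285,
            58617616,  64444167,  46709983,  50818468)
  chrom <- paste0("chr", 1:22)
  if (with_sex) {
    chrom <- c(chrom, "chrX", "chrY")
    len <- c(len, 156040895, 57227415)
  }
  genome_build(chrom, len)
}

#' Read a genome build from a two-column TSV
#'
#' Expects columns `chrom` and `length` (header optional: a headerless
#' two-column file is accepted), plus an optional logical `autosome` column.
#'
#' @param path path to a tab-separated file.
#' @return A `genome_build`.
#' @export
read_genome_build <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  has_header <- grepl("chrom", first, ignore.case = TRUE)
  df <- utils::read.delim(path, header = has_header,
                          stringsAsFactors = FALSE)
  if (!has_header) {
    names(df)[1:2] <- c("chrom", "length")
  }
  for (col in c("chrom", "length")) {
    if (!col %in% names(df))
      stop("genome build file lacks required column '", col, "'")
  }
  genome_build(df$chrom, df$length,
               autosome = if ("autosome" %in% names(df)) df$autosome else NULL)
}

#' @export
print.genome_build <- function(x, ...) {
  cat("genome build:", nrow(x), "chromosomes (",
      sum(x$autosome), "autosomes ),",
      format(sum(x$length[x$autosome]), big.mark = ","),
      "bp of autosome\n")
  invisible(x)
}
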