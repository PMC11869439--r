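#' Weighted Genome Instability Index (wGII)
#'
#' For each sample, the fraction of each autosome covered by copy-number
#' alterations (gains and losses pooled by set union) is computed and the
#' wGII is the unweighted mean of these per-autosome fractions.  Normalising
#' per chromosome before averaging stops the large chromosomes from
#' dominating the index.  Samples with wGII strictly above `threshold` are
#' labelled CIN+ (chromosomally unstable), the rest CIN-.
#'
#' Autosomes carrying no segments contribute a fraction of 0; the
#' denominator is always the full set of autosomes in `build`, so scores are
#' comparable across samples regardless of which chromosomes happen to carry
#' calls.  Sex chromosomes never enter the index.  Mosaic (subclonal)
#' segments count as altered at full weight.
#'
#' @param segments a [segment_table()] (any number of samples).
#' @param build a [genome_build()]; every segment chromosome must be present.
#' @param threshold CIN+ calling threshold on wGII; the conventional value is
#'   0.2 and the comparison is strict (`wgii > threshold`).
#' @param samples optional character vector forcing the output to cover
#'   exactly these sample ids (samples without segments score 0); default is
#'   the samples present in `segments`.
#' @return A `data.frame` of class `wgii_result` with columns `sample`,
#'   `wgii`, `cin` (factor `CIN+`/`CIN-`), plus attributes
#'   `chrom_fraction` (samples x autosomes matrix of per-chromosome altered
#'   fractions) and `threshold`.
#' @examples
#' gb <- genome_build(c("chrA", "chrB"), c(100, 200))
#' seg <- segment_table(data.frame(
#'   sample = "s1", chrom = c("chrA", "chrB"),
#'   start = c(0, 0), end = c(50, 100),
#'   call = c("gain", "loss")), build = gb)
#' compute_wgii(seg, gb)   # wGII = mean(0.5, 0.5) = 0.5 -> CIN+
#' @export
compute_wgii <- function(segments, build, threshold = 0.2, samples = NULL) {
  stopifnot(inherits(segments, "segment_table"),
            inherits(build, "genome_build"))
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold >= 1)
    stop("threshold must be a single proportion in [0, 1)")
  autos <- build[build$autosome, , drop = FALSE]
  if (nrow(autos) == 0)
    stop("genome build contains no autosomes")
  unknown <- setdiff(unique(segments$chrom), build$chrom)
  if (length(unknown) > 0)
    stop("segment chromosome(s) absent from genome build: ",
         paste(unknown, collapse = ", "))
  if (is.null(samples)) samples <- unique(segments$sample)
  if (length(samples) == 0)
    stop("no samples to score")

  frac <- matrix(0, nrow = length(samples), ncol = nrow(autos),
                 dimnames = list(samples, autos$chrom))
  len <- stats::setNames(autos$length, autos$chrom)
  for (s in samples) {
    bp <- attr(merge_altered(segments, s), "altered_bp")
    bp <- bp[names(bp) %in% autos$chrom]
    if (length(bp) > 0)
      frac[s, names(bp)] <- pmin(1, bp / len[names(bp)])
  }
  wgii <- rowMeans(frac)
  out <- data.frame(sample = samples,
                    wgii = unname(wgii),
                    cin = factor(ifelse(wgii > threshold, "CIN+", "CIN-"),
                                 levels = c("CIN+", "CIN-")),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "chrom_fraction") <- frac
  attr(out, "threshold") <- threshold
  class(out) <- c("wgii_result", "data.frame")
  out
}

#' @export
print.wgii_result <- function(x, ...) {
  cat("wGII for", nrow(x), "sample(s); CIN+ threshold wGII >",
      attr(x, "threshold"), "\n")
  print.data.frame(x, digits = 4, ...)
  invisible(x)
}

#' Read a BED-like gene model
#'
#' @param path TSV with columns `gene`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return data.frame with those columns.
#' @export
read_gene_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("gene", "chrom", "start", "end"), names(df))
  if (length(missing_cols) > 0)
    stop("gene model lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  df
}

#' Gene-level copy states from segment calls
#'
#' Assigns each gene x sample pair an integer copy state: the
#' `copy_number` of the overlapping segment that covers the largest part of
#' the gene, with 2 (diploid) for genes touched by no segment.  Segments
#' without an explicit `copy_number` default to 3 for gains and 1 for
#' losses.  When a gain and a loss cover the gene equally, the loss wins
#' (deterministic, conservative tie-break).
#'
#' @param segments a [segment_table()].
#' @param genes data.frame with columns `gene`, `chrom`, `start`, `end`
#'   (0-based half-open), e.g. from [read_gene_model()].
#' @param build optional [genome_build()]; if given, gene intervals are
#'   checked against chromosome bounds.
#' @return data.frame of class `gene_copy_calls` with columns `gene`,
#'   `sample`, `state` (integer, 2 = diploid), one row per gene x sample.
#' @export
gene_copy_states <- function(segments, genes, build = NULL) {
  stopifnot(inherits(segments, "segment_table"))
  missing_cols <- setdiff(c("gene", "chrom", "start", "end"), names(genes))
  if (length(missing_cols) > 0)
    stop("gene model lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (any(genes$end <= genes$start))
    stop("gene interval with end <= start: ",
         paste(utils::head(genes$gene[genes$end <= genes$start], 5),
               collapse = ", "))
  if (!is.null(build)) {
    len <- stats::setNames(build$length, build$chrom)
    unknown <- setdiff(unique(genes$chrom), build$chrom)
    if (length(unknown) > 0)
      stop("gene chromosome(s) absent from genome build: ",
           paste(unknown, collapse = ", "))
    out_of_bounds <- genes$end > len[genes$chrom] | genes$start < 0
    if (any(out_of_bounds))
      stop("gene interval(s) outside chromosome bounds: ",
           paste(utils::head(genes$gene[out_of_bounds], 5), collapse = ", "))
  }
  samples <- unique(segments$sample)
  cn <- segments$copy_number
  cn[is.na(cn)] <- ifelse(segments$call[is.na(cn)] == "gain", 3, 1)

  gene_gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(start = as.integer(genes$start) + 1L,
                     end = as.integer(genes$end)))
  seg_gr <- GenomicRanges::GRanges(
    segments$chrom,
    IRanges::IRanges(start = as.integer(segments$start) + 1L,
                     end = as.integer(segments$end)))
  hits <- GenomicRanges::findOverlaps(gene_gr, seg_gr)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(gene_gr)[qh], IRanges::ranges(seg_gr)[sh]))

  out <- expand.grid(gene = genes$gene, sample = samples,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$state <- 2L
  if (length(qh) > 0) {
    hit_df <- data.frame(gene_idx = qh,
                         sample = segments$sample[sh],
                         cn = cn[sh],
                         is_loss = segments$call[sh] == "loss",
                         overlap = as.numeric(ov))
    # largest overlap wins; ties prefer loss, then the lowest copy number
    ord <- order(hit_df$gene_idx, hit_df$sample, -hit_df$overlap,
                 !hit_df$is_loss, hit_df$cn)
    hit_df <- hit_df[ord, , drop = FALSE]
    keep <- !duplicated(hit_df[, c("gene_idx", "sample")])
    hit_df <- hit_df[keep, , drop = FALSE]
    key_out <- paste(match(out$gene, genes$gene), out$sample, sep = "\r")
    key_hit <- paste(hit_df$gene_idx, hit_df$sample, sep = "\r")
    idx <- match(key_out, key_hit)
    out$state[!is.na(idx)] <- as.integer(hit_df$cn[idx[!is.na(idx)]])
  }
  class(out) <- c("gene_copy_calls", "data.frame")
  out
}
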