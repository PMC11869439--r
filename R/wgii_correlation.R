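#' Median-normalise and log2-transform a protein abundance matrix
#'
#' Each sample (column) is divided by its own median over non-missing
#' features, then log2-transformed.  After normalisation every sample's
#' median on the log2 scale is exactly 0, which removes per-sample global
#' scale distortions (loading, acquisition) before any between-sample
#' statistic is computed.
#'
#' @param x numeric matrix, features x samples, strictly positive where not
#'   `NA` (raw SWATH areas or similar).
#' @return matrix of the same shape on the log2 scale, median-centred per
#'   sample.
#' @details The median is taken on the log2 scale (for an odd number of
#'   quantified features this is identical to dividing by the linear-scale
#'   median; for an even number it is the geometric midpoint, which keeps
#'   the zero-median property exact in all cases).
#' @export
normalize_protein <- function(x) {
  x <- as.matrix(x)
  if (is.null(colnames(x)) || is.null(rownames(x)))
    stop("matrix must carry feature rownames and sample colnames")
  bad <- which(!is.na(x) & x <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-positive abundance for feature '", rownames(x)[bad[1, 1]],
         "', sample '", colnames(x)[bad[1, 2]],
         "' (", nrow(bad), " offending value(s) in total)")
  lx <- log2(x)
  med <- apply(lx, 2, stats::median, na.rm = TRUE)
  empty <- !is.finite(med)
  if (any(empty))
    stop("sample(s) with no quantified features: ",
         paste(colnames(x)[empty], collapse = ", "))
  sweep(lx, 2, med, "-")
}

#' Per-protein Pearson screen against wGII
#'
#' Correlates each protein's (normalised, log2) abundance profile with the
#' per-sample wGII and reports the Pearson coefficient, its two-sided
#' p-value from the t-transform with n - 2 degrees of freedom, and a
#' selection flag at `p_threshold`.  Missing values are handled
#' pairwise-complete with a minimum-sample floor; proteins with fewer
#' usable pairs, or with constant abundance, are excluded with a warning.
#' BH-adjusted q-values are reported alongside for reference; selection
#' itself is on the raw p-value.
#'
#' @param x normalised log2 matrix, features x samples (see
#'   [normalize_protein()]).
#' @param wgii numeric vector of wGII scores named by sample, or a
#'   `wgii_result`.
#' @param p_threshold selection threshold on the two-sided p (default 0.05).
#' @param min_n minimum number of complete pairs per protein (default 5).
#' @return data.frame of class `correlation_screen` with columns `protein`,
#'   `r`, `p`, `q`, `n`, `selected`, sorted by p.  Attribute `excluded`
#'   lists proteins dropped (too few pairs or constant).
#' @export
pearson_screen <- function(x, wgii, p_threshold = 0.05, min_n = 5) {
  x <- as.matrix(x)
  if (inherits(wgii, "wgii_result"))
    wgii <- stats::setNames(wgii$wgii, wgii$sample)
  if (is.null(names(wgii)))
    stop("wgii must be named by sample id")
  shared <- intersect(colnames(x), names(wgii))
  if (length(shared) < 3)
    stop("fewer than 3 samples shared between matrix and wgii")
  x <- x[, shared, drop = FALSE]
  w <- wgii[shared]
  if (length(unique(w)) < 2)
    stop("wGII is constant across the cohort; correlation undefined")

  m <- nrow(x)
  r <- n_used <- rep(NA_real_, m)
  for (i in seq_len(m)) {
    ok <- !is.na(x[i, ]) & !is.na(w)
    n_used[i] <- sum(ok)
    if (n_used[i] >= max(3, min_n) && stats::sd(x[i, ok]) > 0)
      r[i] <- stats::cor(x[i, ok], w[ok])
  }
  excluded <- rownames(x)[is.na(r)]
  if (length(excluded) > 0)
    warning(length(excluded),
            " protein(s) excluded (constant or < min_n complete pairs)")
  keep <- !is.na(r)
  r <- r[keep]; n_used <- n_used[keep]
  tstat <- r * sqrt((n_used - 2) / (1 - pmin(r^2, 1 - 1e-15)))
  p <- 2 * stats::pt(-abs(tstat), df = n_used - 2)
  out <- data.frame(protein = rownames(x)[keep], r = r, p = p,
                    q = stats::p.adjust(p, "BH"),
                    n = n_used, selected = p < p_threshold,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$protein), ]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  attr(out, "p_threshold") <- p_threshold
  class(out) <- c("correlation_screen", "data.frame")
  out
}

#' @export
print.correlation_screen <- function(x, ...) {
  cat("Pearson wGII screen:", nrow(x), "proteins tested,",
      sum(x$selected), "selected at p <", attr(x, "p_threshold"), "\n")
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 3)
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Overlap between the Pearson-selected and differential protein sets
#'
#' @param pearson_ids ids selected by the Pearson screen.
#' @param differential_ids ids significant in the differential analysis.
#' @return list with `common`, `pearson_only`, `differential_only`
#'   (character vectors) and the corresponding `counts` (named integer).
#' @export
venn_with_integrated <- function(pearson_ids, differential_ids) {
  pearson_ids <- unique(as.character(pearson_ids))
  differential_ids <- unique(as.character(differential_ids))
  common <- intersect(pearson_ids, differential_ids)
  out <- list(common = common,
              pearson_only = setdiff(pearson_ids, differential_ids),
              differential_only = setdiff(differential_ids, pearson_ids))
  out$counts <- c(common = length(out$common),
                  pearson_only = length(out$pearson_only),
                  differential_only = length(out$differential_only))
  out
}

#' Flag mitochondrial proteins from annotation strings or an explicit list
#'
#' A protein is mitochondrial when either of its annotation strings
#' (subcellular location, GO cellular component) contains the substring
#' `mitochondr` (case-insensitive), or when its id appears in an explicit
#' curated list (MitoCarta-style).  Proteins absent from the annotation are
#' returned as `NA` so callers can exclude them from enrichment counts.
#'
#' @param ids protein ids to flag.
#' @param annotation optional data.frame with columns `id` plus one or more
#'   annotation string columns (e.g. `subcellular_location`, `go_cc`).
#' @param mito_list optional character vector of ids to flag regardless of
#'   annotation strings.
#' @return logical vector aligned to `ids` (`NA` = unannotated).
#' @export
annotate_mitochondrial <- function(ids, annotation = NULL, mito_list = NULL) {
  ids <- as.character(ids)
  if (is.null(annotation) && is.null(mito_list))
    stop("supply an annotation table and/or an explicit id list")
  flag <- rep(NA, length(ids))
  if (!is.null(annotation)) {
    if (!"id" %in% names(annotation))
      stop("annotation table lacks an 'id' column")
    str_cols <- setdiff(names(annotation), "id")
    if (length(str_cols) == 0)
      stop("annotation table has no annotation string columns")
    joined <- do.call(paste, c(annotation[str_cols], sep = " "))
    hit <- grepl("mitochondr", joined, ignore.case = TRUE)
    idx <- match(ids, annotation$id)
    flag <- hit[idx]          # NA where unannotated
  }
  if (!is.null(mito_list)) {
    in_list <- ids %in% mito_list
    flag[in_list] <- TRUE
    if (is.null(annotation)) flag[!in_list] <- FALSE
  }
  flag
}

#' One-sided hypergeometric over-representation test
#'
#' Tests whether an annotation (e.g. "mitochondrial") is over-represented in
#' a selection drawn from a population: with `N` population ids of which
#' `K` are annotated, and a selection of `n` ids of which `k` are annotated,
#' the upper-tail p-value is `P(X >= k)` for `X` hypergeometric(N, K, n).
#'
#' @param selection character vector of selected ids (must be a subset of
#'   `population`).
#' @param population character vector of background ids (defaults are the
#'   caller's responsibility; for proteomics use all quantified proteins).
#' @param flags logical annotation flags named by population id, or aligned
#'   to `population`; `NA`-flagged ids are excluded from both N and n.
#' @return object of class `enrichment_result`: list with `N`, `K`, `n`,
#'   `k`, `p`, `odds_ratio` (sample odds ratio of the 2x2 table).
#' @examples
#' pop <- sprintf("p%02d", 1:20)
#' fl <- stats::setNames(rep(c(TRUE, FALSE), each = 10), pop)
#' overrepresentation_test(pop[1:5], pop, fl)  # p = choose(10,5)/choose(20,5)
#' @export
overrepresentation_test <- function(selection, population, flags) {
  selection <- unique(as.character(selection))
  population <- unique(as.character(population))
  if (!all(selection %in% population))
    stop("selection contains id(s) outside the population: ",
         paste(utils::head(setdiff(selection, population), 5),
               collapse = ", "))
  if (!is.null(names(flags))) {
    flags <- flags[population]
  } else if (length(flags) != length(population)) {
    stop("flags must be named by id or aligned to the population")
  }
  keep <- !is.na(flags)
  population <- population[keep]
  flags <- flags[keep]
  selection <- intersect(selection, population)
  N <- length(population)
  K <- sum(flags)
  n <- length(selection)
  k <- sum(flags[match(selection, population)])
  p <- if (n == 0) 1 else stats::phyper(k - 1, K, N - K, n,
                                        lower.tail = FALSE)
  or <- (k * (N - K - n + k)) / max((K - k) * (n - k), .Machine$double.eps)
  structure(list(N = N, K = K, n = n, k = k, p = p, odds_ratio = or),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "over-representation: %d/%d annotated in selection vs %d/%d in population\n",
    x$k, x$n, x$K, x$N))
  cat(sprintf("  hypergeometric P(X >= %d) = %.4g\n", x$k, x$p))
  invisible(x)
}
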