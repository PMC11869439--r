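#' CIN prevalence in a cohort
#'
#' @param wgii a [compute_wgii()] result, or any data.frame with a `cin`
#'   column of `CIN+`/`CIN-` labels.
#' @return percentage of samples labelled CIN+ (0-100).
#' @export
cin_prevalence <- function(wgii) {
  if (!"cin" %in% names(wgii))
    stop("input lacks a 'cin' column")
  if (nrow(wgii) == 0)
    stop("empty cohort: prevalence undefined")
  100 * mean(wgii$cin == "CIN+")
}

#' Organoid-tissue wGII concordance with outlier-robust refit
#'
#' Fits ordinary least squares of organoid (PDO) wGII on matched-tissue
#' wGII, flags pairs whose residual exceeds 2 population standard deviations
#' of the initial fit's residuals, refits once on the remaining pairs, and
#' reports the Pearson correlation and its two-sided p-value from the refit.
#' The removal is single-pass: flag once, refit once.
#'
#' @param pdo numeric vector of organoid wGII values.
#' @param tissue numeric vector of matched tissue wGII values, same length
#'   and order.
#' @param ids optional pair labels (e.g. patient ids); defaults to indices.
#' @param sd_cut residual cut in standard-deviation units (default 2).
#' @return An object of class `concordance_fit`: list with `slope`,
#'   `intercept`, `r`, `p`, `residual_sd` (population SD of the initial
#'   residuals), `outliers` (flagged ids), `n_used`, `n_input`, and the
#'   refit `fit` (an `lm`).
#' @examples
#' set.seed(1)
#' tw <- runif(10, 0, 0.5); pw <- tw + rnorm(10, 0, 0.03)
#' pair_regression(pw, tw)
#' @export
pair_regression <- function(pdo, tissue, ids = NULL, sd_cut = 2) {
  if (length(pdo) != length(tissue))
    stop("pdo and tissue must have equal length")
  if (is.null(ids)) ids <- as.character(seq_along(pdo))
  if (anyDuplicated(ids)) stop("pair ids must be unique")
  keep <- is.finite(pdo) & is.finite(tissue)
  if (any(!keep))
    message("dropping ", sum(!keep), " unmatched/missing pair(s): ",
            paste(ids[!keep], collapse = ", "))
  pdo <- pdo[keep]; tissue <- tissue[keep]; ids <- ids[keep]
  n <- length(pdo)
  if (n < 4) stop("need at least 4 matched pairs, got ", n)

  fit0 <- stats::lm(pdo ~ tissue)
  res <- stats::residuals(fit0)
  res_sd <- sqrt(mean(res^2))        # population SD of residuals
  # small absolute tolerance so numerically exact fits flag nothing
  out_flag <- abs(res) > sd_cut * res_sd + 1e-12
  outliers <- ids[out_flag]
  pdo2 <- pdo[!out_flag]; tissue2 <- tissue[!out_flag]
  if (length(pdo2) < 4)
    stop("fewer than 4 pairs remain after outlier removal; fit degenerate")
  fit1 <- stats::lm(pdo2 ~ tissue2)
  r <- stats::cor(pdo2, tissue2)
  n2 <- length(pdo2)
  tstat <- r * sqrt((n2 - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n2 - 2)
  structure(list(slope = unname(stats::coef(fit1)[2]),
                 intercept = unname(stats::coef(fit1)[1]),
                 r = r, p = p,
                 residual_sd = res_sd,
                 outliers = outliers,
                 n_used = n2, n_input = n,
                 fit = fit1),
            class = "concordance_fit")
}

#' @export
print.concordance_fit <- function(x, ...) {
  cat(sprintf(
    "PDO-tissue wGII concordance: r = %.3f, p = %.3g (n = %d of %d",
    x$r, x$p, x$n_used, x$n_input))
  if (length(x$outliers) > 0)
    cat("; outliers removed: ", paste(x$outliers, collapse = ", "), sep = "")
  cat(")\n")
  cat(sprintf("  slope %.3f, intercept %.3f, residual SD %.4f\n",
              x$slope, x$intercept, x$residual_sd))
  invisible(x)
}

#' Gain/loss frequencies per gene across a cohort
#'
#' Per gene: percentage of samples with copy state > 2 (gain) and with
#' state < 2 (loss); loss frequencies are reported as negative percentages
#' for mirror-plot parity.  Both use the same denominator, the full sample
#' set of `calls`.
#'
#' @param calls a [gene_copy_states()] result (columns `gene`, `sample`,
#'   `state`).
#' @param genes optional gene subset; genes absent from `calls` are skipped
#'   with a warning.
#' @return data.frame with columns `gene`, `gain_pct`, `loss_pct`
#'   (`loss_pct` <= 0).
#' @export
alteration_frequencies <- function(calls, genes = NULL) {
  stopifnot(all(c("gene", "sample", "state") %in% names(calls)))
  if (length(unique(calls$sample)) == 0) stop("no samples in calls")
  if (!is.null(genes)) {
    absent <- setdiff(genes, unique(calls$gene))
    if (length(absent) > 0)
      warning("gene(s) absent from calls, skipped: ",
              paste(absent, collapse = ", "))
    calls <- calls[calls$gene %in% genes, , drop = FALSE]
  }
  n <- length(unique(calls$sample))
  gain <- tapply(calls$state > 2, calls$gene, sum)
  loss <- tapply(calls$state < 2, calls$gene, sum)
  out <- data.frame(gene = names(gain),
                    gain_pct = 100 * as.numeric(gain) / n,
                    loss_pct = -100 * as.numeric(loss) / n,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Venn region counts for named sets
#'
#' Counts, for every combination of membership across the input sets, how
#' many elements fall in exactly that region.  Used to quantify
#' inter-metastasis heterogeneity of gene-level gains/losses, but generic.
#'
#' @param sets named list of >= 2 character vectors over a shared id space.
#' @return named integer vector; names are set names joined by `&` (e.g.
#'   `"A"`, `"A&B"`), covering every non-empty region.  The attribute
#'   `union_size` carries the size of the overall union.
#' @examples
#' overlap_sets(list(M1 = c("A", "B", "C"), M2 = c("B", "C", "D")))
#' @export
overlap_sets <- function(sets) {
  if (!is.list(sets) || length(sets) < 2 || is.null(names(sets)) ||
      any(names(sets) == ""))
    stop("sets must be a named list of at least two character vectors")
  sets <- lapply(sets, unique)
  ids <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, function(s) ids %in% s,
                       logical(length(ids)))
  if (length(ids) == 1) membership <- matrix(membership, nrow = 1,
                                             dimnames = list(NULL, names(sets)))
  region <- apply(membership, 1, function(m)
    paste(names(sets)[m], collapse = "&"))
  counts <- table(region)
  # emit every possible region, zero-filled, in deterministic order
  k <- length(sets)
  combos <- unlist(lapply(seq_len(k), function(i)
    utils::combn(names(sets), i, paste, collapse = "&", simplify = FALSE)))
  out <- stats::setNames(integer(length(combos)), combos)
  out[names(counts)] <- as.integer(counts)
  attr(out, "union_size") <- length(ids)
  out
}
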