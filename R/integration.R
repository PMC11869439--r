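#' Differential protein analysis between CIN+ and CIN- samples
#'
#' Per-feature two-sided Welch t-test on a normalised log2 abundance matrix.
#' The log2 fold change is the difference of group means on the log2 scale
#' (CIN+ minus CIN-).  A feature is called significant when all of
#' `|fold change| >= fc_threshold` (linear scale), `p < p_threshold` and,
#' when peptide counts are available, `peptides >= min_peptides` hold.
#'
#' @param x normalised log2 matrix, features x samples (see
#'   [normalize_protein()]; for RNA, log2 CPM works the same way).
#' @param labels CIN status per sample: `CIN+`/`CIN-` (or logical), named by
#'   sample id or aligned to `colnames(x)`.
#' @param fc_threshold linear-scale fold-change threshold (default 1.5, i.e.
#'   |log2FC| >= log2(1.5)).
#' @param p_threshold p-value threshold (default 0.05).
#' @param peptides optional per-feature peptide counts (named by feature or
#'   aligned to `rownames(x)`).
#' @param min_peptides minimum peptide support (default 2), applied only
#'   when `peptides` is supplied.
#' @return data.frame of class `differential_table` with columns `feature`,
#'   `log2fc`, `t`, `p`, `q` (BH), `direction` (`up`/`down`), `significant`,
#'   and `peptides` when supplied; sorted by p.  All-missing features are
#'   skipped with a warning.
#' @export
differential_protein <- function(x, labels, fc_threshold = 1.5,
                                 p_threshold = 0.05, peptides = NULL,
                                 min_peptides = 2) {
  x <- as.matrix(x)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("matrix must carry feature rownames and sample colnames")
  pos <- cin_positive(labels, colnames(x))
  if (sum(pos) < 2 || sum(!pos) < 2)
    stop("need at least 2 samples per CIN group (got ",
         sum(pos), " CIN+ / ", sum(!pos), " CIN-)")
  empty <- rowSums(!is.na(x)) == 0
  if (any(empty)) {
    warning(sum(empty), " all-missing feature(s) skipped")
    x <- x[!empty, , drop = FALSE]
  }
  w <- row_welch(x, which(pos), which(!pos))
  out <- data.frame(feature = rownames(x),
                    log2fc = w$diff, t = w$t, p = w$p,
                    q = stats::p.adjust(w$p, "BH"),
                    direction = ifelse(w$diff >= 0, "up", "down"),
                    stringsAsFactors = FALSE)
  sig <- abs(out$log2fc) >= log2(fc_threshold) &
    !is.na(out$p) & out$p < p_threshold
  if (!is.null(peptides)) {
    if (!is.null(names(peptides))) {
      pep <- peptides[out$feature]
    } else {
      if (length(peptides) != nrow(x) + sum(empty) &&
          length(peptides) != nrow(x))
        stop("peptides must be named by feature or aligned to the matrix")
      pep <- peptides[match(out$feature, rownames(x))]
    }
    out$peptides <- as.integer(pep)
    sig <- sig & !is.na(pep) & pep >= min_peptides
  }
  out$significant <- sig
  out <- out[order(out$p, out$feature), ]
  rownames(out) <- NULL
  attr(out, "fc_threshold") <- fc_threshold
  attr(out, "p_threshold") <- p_threshold
  class(out) <- c("differential_table", "data.frame")
  out
}

#' @export
print.differential_table <- function(x, ...) {
  up <- sum(x$significant & x$direction == "up")
  dn <- sum(x$significant & x$direction == "down")
  cat("differential analysis:", nrow(x), "features;",
      up + dn, "significant (", up, "up /", dn, "down ) at |FC| >=",
      attr(x, "fc_threshold"), ", p <", attr(x, "p_threshold"), "\n")
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 3)
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Intersect RNA and protein differential lists
#'
#' Computes the set of features significant in both tables (shared gene
#' symbols) and the Pearson correlation of their log2 fold changes over
#' that intersection.
#'
#' @param rna,protein `differential_table` objects (or data.frames with
#'   `feature`, `log2fc`, `significant` columns).
#' @return list with `common` (ids), `r` (Pearson r of matched log2FCs;
#'   `NA` with `r_reason` when fewer than 3 common features), and `counts`
#'   (`common`, `rna_only`, `protein_only`).
#' @export
intersect_omics <- function(rna, protein) {
  for (tb in list(rna, protein))
    if (!all(c("feature", "log2fc", "significant") %in% names(tb)))
      stop("inputs must carry feature, log2fc and significant columns")
  rna_sig <- rna$feature[rna$significant]
  prot_sig <- protein$feature[protein$significant]
  common <- intersect(rna_sig, prot_sig)
  r <- NA_real_
  r_reason <- NULL
  if (length(common) >= 3) {
    fc_rna <- rna$log2fc[match(common, rna$feature)]
    fc_prot <- protein$log2fc[match(common, protein$feature)]
    if (stats::sd(fc_rna) > 0 && stats::sd(fc_prot) > 0) {
      r <- stats::cor(fc_rna, fc_prot)
    } else {
      r_reason <- "constant fold changes in the intersection"
    }
  } else {
    r_reason <- "fewer than 3 common significant features"
  }
  list(common = common, r = r, r_reason = r_reason,
       counts = c(common = length(common),
                  rna_only = length(setdiff(rna_sig, common)),
                  protein_only = length(setdiff(prot_sig, common))))
}

#' Top-n differential signature
#'
#' Extracts the `n` most differentially expressed features under the chosen
#' ranking (p-value ascending by default, or absolute fold change
#' descending), with a deterministic tie-break on feature id, for use as a
#' classification signature.
#'
#' @param table a `differential_table` (or data.frame with `feature`, `p`,
#'   `log2fc`).
#' @param n signature size (default 100); `n = 0` yields an empty signature.
#' @param ranking `"p"` or `"fc"`.
#' @return character vector of feature ids, length `n`.
#' @export
top_n_signature <- function(table, n = 100, ranking = c("p", "fc")) {
  ranking <- match.arg(ranking)
  if (n > nrow(table))
    stop("signature size ", n, " exceeds available features (",
         nrow(table), ")")
  if (n == 0) return(character())
  key <- if (ranking == "p") table$p else -abs(table$log2fc)
  ord <- order(key, table$feature)
  table$feature[ord][seq_len(n)]
}

#' Classify an external cohort by a signature
#'
#' Restricts the matrix to the signature features, z-scores each feature
#' across samples, clusters samples by hierarchical clustering (Euclidean
#' distance, Ward linkage), cuts the tree at 2 clusters, and tests the
#' association between cluster membership and the known labels: Fisher's
#' exact test (two-sided) for 2x2 tables, chi-square otherwise.  The
#' cluster-to-label mapping reported as `accuracy` is the one maximising
#' agreement.
#'
#' @param x abundance/expression matrix, features x samples.
#' @param signature character vector of feature ids.
#' @param labels known class per sample (e.g. CIN+/CIN-), named by sample or
#'   aligned to columns.
#' @return object of class `signature_classification`: list with `clusters`
#'   (named integer), `table` (cluster x label contingency), `p`,
#'   `test` (`"fisher"`, `"chisq"` or `"none"`), `accuracy`,
#'   `features_used`, `features_missing`, and `degenerate` (TRUE when the
#'   cut produced an empty cluster or no informative features, in which
#'   case `p` is `NA`).
#' @export
classify_by_signature <- function(x, signature, labels) {
  x <- as.matrix(x)
  found <- intersect(signature, rownames(x))
  missing_ids <- setdiff(signature, rownames(x))
  if (length(found) < 2)
    stop("fewer than 2 signature features found in matrix; missing: ",
         paste(utils::head(missing_ids, 10), collapse = ", "))
  lab <- if (!is.null(names(labels))) labels[colnames(x)] else labels
  if (length(lab) != ncol(x) || anyNA(lab))
    stop("labels must cover every sample")
  lab <- as.character(lab)
  if (any(table(lab) < 2))
    stop("need at least 2 samples per known label")

  sub <- x[found, , drop = FALSE]
  sds <- apply(sub, 1, stats::sd, na.rm = TRUE)
  informative <- is.finite(sds) & sds > 0
  degenerate <- sum(informative) < 2
  if (!degenerate) {
    z <- (sub[informative, , drop = FALSE] -
            rowMeans(sub[informative, , drop = FALSE], na.rm = TRUE)) /
      sds[informative]
    hc <- stats::hclust(stats::dist(t(z)), method = "ward.D2")
    cl <- stats::cutree(hc, k = 2)
  } else {
    cl <- stats::setNames(rep(1L, ncol(x)), colnames(x))
  }
  tab <- table(cluster = cl, label = lab)
  degenerate <- degenerate || nrow(tab) < 2 || any(rowSums(tab) == 0)
  if (degenerate) {
    p <- NA_real_; test <- "none"; acc <- NA_real_
  } else if (all(dim(tab) == c(2, 2))) {
    p <- stats::fisher.test(tab)$p.value; test <- "fisher"
    acc <- max(sum(diag(tab)), sum(tab[cbind(1:2, 2:1)])) / sum(tab)
  } else {
    p <- suppressWarnings(stats::chisq.test(tab)$p.value); test <- "chisq"
    acc <- sum(apply(tab, 1, max)) / sum(tab)  # majority label per cluster
  }
  structure(list(clusters = cl, table = tab, p = p, test = test,
                 accuracy = acc, features_used = sum(informative),
                 features_missing = missing_ids, degenerate = degenerate),
            class = "signature_classification")
}

#' @export
print.signature_classification <- function(x, ...) {
  cat("signature classification (", x$features_used, "features ):",
      if (x$degenerate) "degenerate - association not computable\n"
      else sprintf("%s p = %.3g, agreement %.1f%%\n",
                   x$test, x$p, 100 * x$accuracy))
  print(x$table)
  invisible(x)
}
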