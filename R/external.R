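#' Compare gene dependency scores between CIN+ and CIN- cell lines
#'
#' Per-gene Welch t-test of dependency scores (more negative = stronger
#' dependence) between CIN+ and CIN- lines, restricted to an optional gene
#' subset (e.g. the wGII-correlated signature).  Reports the effect size
#' (mean CIN+ minus mean CIN-), raw two-sided p and BH-adjusted q, sorted
#' by p — the table behind a dependency volcano plot.
#'
#' @param scores numeric matrix, genes x cell lines.
#' @param labels CIN status per line (`CIN+`/`CIN-`, named or aligned).
#' @param genes optional subset of genes to test; genes absent from the
#'   matrix are reported in the `skipped` attribute and ignored.
#' @return data.frame of class `group_comparison` with columns `feature`,
#'   `effect`, `t`, `p`, `q`; attribute `skipped` holds requested-but-absent
#'   gene ids.
#' @export
dependency_compare <- function(scores, labels, genes = NULL) {
  scores <- as.matrix(scores)
  if (is.null(rownames(scores)) || is.null(colnames(scores)))
    stop("matrix must carry gene rownames and cell-line colnames")
  skipped <- character()
  if (!is.null(genes)) {
    skipped <- setdiff(genes, rownames(scores))
    scores <- scores[intersect(genes, rownames(scores)), , drop = FALSE]
    if (nrow(scores) == 0) stop("none of the requested genes are present")
  }
  pos <- cin_positive(labels, colnames(scores))
  if (sum(pos) < 2 || sum(!pos) < 2)
    stop("need at least 2 cell lines per CIN group")
  w <- row_welch(scores, which(pos), which(!pos))
  out <- data.frame(feature = rownames(scores),
                    effect = w$diff, t = w$t, p = w$p,
                    q = stats::p.adjust(w$p, "BH"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$feature), ]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("CIN+/CIN- group comparison:", nrow(x), "features;",
      sum(!is.na(x$p) & x$p < 0.05), "at p < 0.05\n")
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 3)
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Compare drug-response AUCs between CIN+ and CIN- cell lines
#'
#' Applies the screening filters before any test is computed: compounds
#' with no annotated target, or tested in at most one cell line, are
#' removed.  The surviving compounds are tested as in
#' [dependency_compare()]; a compound is "more effective in CIN+" when its
#' mean AUC is lower in CIN+ lines (negative effect) with p below
#' `p_threshold` (lower AUC = greater drug effect).
#'
#' @param auc numeric matrix, compounds x cell lines (AUC; `NA` for
#'   untested line/compound combinations).
#' @param labels CIN status per line.
#' @param metadata data.frame with columns `compound`, `target`,
#'   `n_lines` (per-compound tested-line count); must cover all compounds.
#' @param p_threshold threshold for the differential-effect call
#'   (default 0.05).
#' @return `group_comparison` data.frame with extra columns `target` and
#'   `more_effective_cin`; attribute `filtered` records the compounds
#'   removed by each rule.
#' @export
drug_compare <- function(auc, labels, metadata, p_threshold = 0.05) {
  auc <- as.matrix(auc)
  if (!all(c("compound", "target", "n_lines") %in% names(metadata)))
    stop("metadata must carry compound, target and n_lines columns")
  uncovered <- setdiff(rownames(auc), metadata$compound)
  if (length(uncovered) > 0)
    stop("metadata missing for compound(s): ",
         paste(utils::head(uncovered, 5), collapse = ", "))
  meta <- metadata[match(rownames(auc), metadata$compound), ]
  no_target <- is.na(meta$target) | trimws(meta$target) == ""
  too_few <- meta$n_lines <= 1
  filtered <- list(no_target = rownames(auc)[no_target],
                   single_line = rownames(auc)[!no_target & too_few])
  keep <- !no_target & !too_few
  if (!any(keep)) stop("no compounds survive the filters")
  res <- dependency_compare(auc[keep, , drop = FALSE], labels)
  res$target <- meta$target[keep][match(res$feature, rownames(auc)[keep])]
  res$more_effective_cin <- !is.na(res$p) & res$p < p_threshold &
    res$effect < 0
  attr(res, "filtered") <- filtered
  attr(res, "p_threshold") <- p_threshold
  res
}

#' Validate the wGII-correlated protein list in an external cohort
#'
#' Restricts an external proteomic cohort (CIN vs MSI labels) to the
#' discovery proteins, runs a per-protein Welch t-test between the label
#' groups, and calls a protein concordant when it is significant and the
#' sign of its external difference (CIN minus MSI) agrees with the sign of
#' its discovery correlation.  The concordant proteins are then used to
#' re-cluster the external cohort (z-score, Euclidean/Ward, 2 clusters) and
#' the cluster-label association is tested by Fisher's exact test.
#'
#' @param x external matrix, proteins x samples (log-scale abundances).
#' @param labels per-sample labels, `CIN` vs `MSI` (MSI proxies CIN-).
#' @param discovery a `correlation_screen` (or data.frame with `protein`,
#'   `r`, `selected`); only selected proteins are looked up.
#' @param p_threshold significance threshold for the external differential
#'   call (default 0.05).
#' @return object of class `external_validation`: list with `tested`
#'   (per-protein table: `protein`, `discovery_r`, `effect`, `p`, `q`,
#'   `significant`, `concordant`), `n_found`, `n_differential`,
#'   `n_concordant`, `classification` (a [classify_by_signature()] result
#'   on the concordant proteins, or `NULL` when fewer than 2).
#' @export
external_signature_validation <- function(x, labels, discovery,
                                          p_threshold = 0.05) {
  x <- as.matrix(x)
  if (!all(c("protein", "r") %in% names(discovery)))
    stop("discovery must carry protein and r columns")
  disc <- discovery
  if ("selected" %in% names(disc)) disc <- disc[disc$selected, , drop = FALSE]
  found <- intersect(disc$protein, rownames(x))
  if (length(found) == 0)
    stop("no discovery proteins found in the external matrix")
  pos <- cin_positive(labels, colnames(x))
  if (sum(pos) < 2 || sum(!pos) < 2)
    stop("need at least 2 samples per label group")
  sub <- x[found, , drop = FALSE]
  w <- row_welch(sub, which(pos), which(!pos))
  disc_r <- disc$r[match(found, disc$protein)]
  significant <- !is.na(w$p) & w$p < p_threshold
  concordant <- significant & sign(w$diff) == sign(disc_r)
  tested <- data.frame(protein = found, discovery_r = disc_r,
                       effect = w$diff, p = w$p,
                       q = stats::p.adjust(w$p, "BH"),
                       significant = significant,
                       concordant = concordant,
                       stringsAsFactors = FALSE)
  classification <- NULL
  conc_ids <- tested$protein[tested$concordant]
  if (length(conc_ids) >= 2)
    classification <- classify_by_signature(x, conc_ids, labels)
  structure(list(tested = tested,
                 n_found = length(found),
                 n_differential = sum(significant),
                 n_concordant = sum(concordant),
                 classification = classification),
            class = "external_validation")
}

#' @export
print.external_validation <- function(x, ...) {
  cat("external cohort validation:", x$n_found, "discovery proteins found;",
      x$n_differential, "differential,", x$n_concordant,
      "concordant in sign\n")
  if (!is.null(x$classification)) {
    cat("clustering on concordant proteins:\n")
    print(x$classification)
  }
  invisible(x)
}
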