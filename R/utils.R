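# Row-wise Welch t machinery shared by the differential, dependency and
# external-validation screens.  Vectorised over features; NA-aware.

row_group_stats <- function(x, idx) {
  xs <- x[, idx, drop = FALSE]
  n <- rowSums(!is.na(xs))
  m <- rowMeans(xs, na.rm = TRUE)
  v <- rowSums((xs - m)^2, na.rm = TRUE) / pmax(n - 1, 1)
  v[n < 2] <- NA_real_
  m[n == 0] <- NA_real_
  list(n = n, mean = m, var = v)
}

# Welch (unequal-variance) t-test per row of `x` between column index sets.
# Returns diff = mean(idx1) - mean(idx2), t, Welch-Satterthwaite df, and a
# two-sided p; rows with fewer than 2 usable values in either group get NA.
row_welch <- function(x, idx1, idx2) {
  g1 <- row_group_stats(x, idx1)
  g2 <- row_group_stats(x, idx2)
  se2 <- g1$var / g1$n + g2$var / g2$n
  tstat <- (g1$mean - g2$mean) / sqrt(se2)
  df <- se2^2 / ((g1$var / g1$n)^2 / (g1$n - 1) +
                   (g2$var / g2$n)^2 / (g2$n - 1))
  p <- 2 * stats::pt(-abs(tstat), df = df)
  bad <- g1$n < 2 | g2$n < 2 | !is.finite(tstat)
  tstat[bad] <- NA_real_; p[bad] <- NA_real_; df[bad] <- NA_real_
  data.frame(diff = g1$mean - g2$mean, t = tstat, df = df, p = p,
             n1 = g1$n, n2 = g2$n)
}

# Normalise CIN labels to a logical "is CIN+" vector aligned to sample ids.
cin_positive <- function(labels, samples) {
  if (!is.null(names(labels))) {
    missing_ids <- setdiff(samples, names(labels))
    if (length(missing_ids) > 0)
      stop("no CIN label for sample(s): ",
           paste(missing_ids, collapse = ", "))
    labels <- labels[samples]
  } else if (length(labels) != length(samples)) {
    stop("labels must be named by sample or match the sample count")
  }
  lab <- as.character(labels)
  pos <- lab %in% c("CIN+", "CIN", "positive", "TRUE", "1")
  neg <- lab %in% c("CIN-", "MSI", "negative", "FALSE", "0")
  if (any(!pos & !neg))
    stop("unrecognised CIN label(s): ",
         paste(unique(lab[!pos & !neg]), collapse = ", "))
  pos
}
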