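# Synthetic-cohort generators.  Every generator seeds its own RNG stream,
# records the planted truth alongside the data, and round-trips through the
# corresponding analysis stage (see the methods vignette for the rationale
# behind each default).

# split `total` into `k` positive integer parts (composition), uniformly
rand_composition <- function(total, k) {
  if (k == 1) return(total)
  cuts <- sort(sample.int(total - 1, k - 1))
  diff(c(0, cuts, total))
}

# cap fractions at 1 and redistribute the excess to uncapped chromosomes
cap_redistribute <- function(f) {
  repeat {
    over <- f > 1
    if (!any(over)) return(f)
    excess <- sum(f[over] - 1)
    f[over] <- 1
    room <- which(f < 1)
    if (length(room) == 0) return(f)
    f[room] <- f[room] + excess * (1 - f[room]) / sum(1 - f[room])
  }
}

#' Simulate copy-number segments with planted wGII
#'
#' For each sample, per-autosome altered fractions are drawn
#' Dirichlet-style and rescaled so that their mean equals the target wGII;
#' non-overlapping gain/loss segments are then placed to cover exactly
#' those fractions (to base-pair resolution).  [compute_wgii()] on the
#' output recovers each target to within 1e-9 on a human-scale build.
#'
#' @param targets numeric vector of target wGII values in `[0, 1]`, named
#'   by sample id.
#' @param build a [genome_build()] (default [hs_autosomes()]).
#' @param seed integer RNG seed.
#' @param max_segments maximum number of segments per chromosome (1-3 by
#'   default; altered chromosomes get a random number up to this).
#' @return list with `segments` (a [segment_table()]) and `truth` (list:
#'   `target` and `realized` wGII per sample, `seed`).
#' @export
simulate_segments <- function(targets, build = hs_autosomes(), seed = 1,
                              max_segments = 3) {
  stopifnot(inherits(build, "genome_build"))
  if (is.null(names(targets))) names(targets) <- sprintf("S%02d", seq_along(targets))
  if (any(!is.finite(targets)) || any(targets < 0) || any(targets > 1))
    stop("wGII targets must lie in [0, 1]")
  set.seed(seed)
  autos <- build[build$autosome, , drop = FALSE]
  L <- autos$length
  C <- nrow(autos)
  rows <- list()
  realized <- stats::setNames(numeric(length(targets)), names(targets))
  for (s in names(targets)) {
    t <- targets[[s]]
    if (t == 0) { realized[s] <- 0; next }
    d <- stats::rgamma(C, shape = 1)
    f <- cap_redistribute(t * C * d / sum(d))
    bp <- round(f * L)
    # absorb the rounding residual so mean(bp / L) hits the target exactly
    resid <- t * C - sum(bp / L)
    for (j in order(L, decreasing = TRUE)) {
      delta <- round(resid * L[j])
      delta <- max(min(delta, L[j] - bp[j]), -bp[j])
      bp[j] <- bp[j] + delta
      resid <- resid - delta / L[j]
      if (abs(resid) * max(L) < 0.5) break
    }
    realized[s] <- mean(bp / L)
    for (j in seq_len(C)) {
      if (bp[j] == 0) next
      k <- sample.int(min(max_segments, bp[j]), 1)
      lens <- rand_composition(bp[j], k)
      free <- L[j] - bp[j]
      cuts <- sort(sample.int(free + 1, k, replace = TRUE) - 1)
      gaps <- diff(c(0, cuts, free))
      starts <- cumsum(c(0, lens[-k])) + cumsum(gaps[seq_len(k)])
      call <- sample(c("gain", "loss"), k, replace = TRUE)
      rows[[length(rows) + 1]] <- data.frame(
        sample = s, chrom = autos$chrom[j],
        start = starts, end = starts + lens, call = call,
        copy_number = ifelse(call == "gain", 3, 1),
        stringsAsFactors = FALSE)
    }
  }
  seg <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(sample = character(), chrom = character(),
               start = numeric(), end = numeric(), call = character(),
               stringsAsFactors = FALSE)
  list(segments = segment_table(seg, build = build),
       truth = list(target = targets, realized = realized, seed = seed))
}

#' Simulate a matched organoid/tissue wGII cohort
#'
#' Draws per-patient latent instability levels, realises organoid (PDO) and
#' tissue wGII as the latent level plus independent Gaussian noise, and
#' plants a configurable number of discordant pairs in which the tissue is
#' CIN- while the organoid carries a high wGII (emulating low
#' tumour-content tissue); these double as regression outliers.
#'
#' @param n_pairs number of matched pairs (default 12).
#' @param n_cin_pairs concordant pairs with a CIN+ latent level (default 8).
#' @param n_discordant discordant pairs (default 1); the remainder are
#'   concordant CIN-.
#' @param sigma_pair Gaussian noise SD added independently to each member
#'   of a pair (default 0.07).
#' @param threshold CIN+ threshold used to record the planted status
#'   (default 0.2).
#' @param seed integer RNG seed.
#' @return list with `pairs` (data.frame: `patient`, `pdo_id`, `tissue_id`,
#'   `pdo_wgii`, `tissue_wgii`) and `truth` (latent levels, planted
#'   discordant patient ids, seed).
#' @export
simulate_paired_cohort <- function(n_pairs = 12, n_cin_pairs = 8,
                                   n_discordant = 1, sigma_pair = 0.07,
                                   threshold = 0.2, seed = 1) {
  if (n_cin_pairs + n_discordant > n_pairs)
    stop("n_cin_pairs + n_discordant exceeds n_pairs")
  set.seed(seed)
  n_neg <- n_pairs - n_cin_pairs - n_discordant
  mu <- c(stats::runif(n_cin_pairs, 0.25, 0.55),
          stats::runif(n_neg, 0.02, 0.12),
          rep(NA_real_, n_discordant))
  patient <- sprintf("P%02d", seq_len(n_pairs))
  clamp <- function(v) pmin(pmax(v, 0.001), 0.98)
  pdo <- clamp(mu + stats::rnorm(n_pairs, 0, sigma_pair))
  tissue <- clamp(mu + stats::rnorm(n_pairs, 0, sigma_pair))
  if (n_discordant > 0) {
    idx <- which(is.na(mu))
    pdo[idx] <- stats::runif(n_discordant, 0.40, 0.55)
    tissue[idx] <- stats::runif(n_discordant, 0.02, 0.08)
  }
  pairs <- data.frame(patient = patient,
                      pdo_id = sprintf("PDO%02d", seq_len(n_pairs)),
                      tissue_id = sprintf("T%02d", seq_len(n_pairs)),
                      pdo_wgii = pdo, tissue_wgii = tissue,
                      stringsAsFactors = FALSE)
  list(pairs = pairs,
       truth = list(latent = stats::setNames(mu, patient),
                    discordant = patient[is.na(mu)],
                    threshold = threshold,
                    pdo_cin = stats::setNames(pdo > threshold, pairs$pdo_id),
                    tissue_cin = stats::setNames(tissue > threshold,
                                                 pairs$tissue_id),
                    seed = seed))
}

#' Simulate a SWATH-like protein abundance matrix
#'
#' Plants two (possibly overlapping) mechanisms on a log2 scale:
#' a wGII-correlated subset (`value = a_i + b_i * (wGII - mean wGII) +
#' noise`, signed slopes) and a CIN-group-shifted subset (`value = a_i +
#' d_i * I[CIN+] + noise`, the differential structure).  Per-sample
#' multiplicative scale factors are applied on the linear scale (so
#' [normalize_protein()] has real work to do) and values go missing
#' completely at random.
#'
#' @param wgii per-sample wGII, named by sample id.
#' @param m total number of proteins (default 1600).
#' @param n_correlated size of the planted wGII-correlated set
#'   (default 147).
#' @param b slope magnitude on the log2 scale per unit wGII (default 2).
#' @param prop_negative fraction of correlated proteins with a negative
#'   slope (default 0.3).
#' @param n_de_up,n_de_down planted group-shifted proteins up/down in CIN+
#'   (defaults 62 and 54).
#' @param de_shift log2 shift magnitude for the group mechanism
#'   (default 1.2).
#' @param n_overlap how many of the shifted proteins also belong to the
#'   correlated set (default 70); these carry both terms with aligned
#'   signs.
#' @param sigma residual noise SD on the log2 scale (default 0.25).
#' @param scale_sd SD of per-sample log2 scale factors (default 0.4).
#' @param missing_rate missing-at-random rate (default 0.05).
#' @param threshold wGII threshold defining the CIN+ group (default 0.2).
#' @param seed integer RNG seed.
#' @return list with `matrix` (linear-scale abundances, proteins x samples,
#'   `NA` = missing), `peptides` (named integer; planted shifted proteins
#'   are guaranteed >= 2), `labels` (CIN status per sample), and `truth`
#'   (ids and signed slopes/shifts of every planted set, the overlap ids,
#'   scale factors, seed).
#' @export
simulate_proteome <- function(wgii, m = 1600, n_correlated = 147, b = 2,
                              prop_negative = 0.3, n_de_up = 62,
                              n_de_down = 54, de_shift = 1.2,
                              n_overlap = 70, sigma = 0.25, scale_sd = 0.4,
                              missing_rate = 0.05, threshold = 0.2,
                              seed = 1, feature_ids = NULL) {
  if (is.null(names(wgii))) stop("wgii must be named by sample id")
  n_de <- n_de_up + n_de_down
  if (n_correlated > m || n_de > m || n_overlap > min(n_correlated, n_de))
    stop("planted set sizes inconsistent with m")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  set.seed(seed)
  n <- length(wgii)
  if (is.null(feature_ids)) feature_ids <- sprintf("PR%04d", seq_len(m))
  stopifnot(length(feature_ids) == m, !anyDuplicated(feature_ids))

  correlated <- sample(feature_ids, n_correlated)
  overlap <- sample(correlated, n_overlap)
  de_pool <- c(overlap, sample(setdiff(feature_ids, correlated),
                               n_de - n_overlap))
  de_up <- sample(de_pool, n_de_up)
  de_down <- setdiff(de_pool, de_up)

  slope <- stats::setNames(
    b * ifelse(stats::runif(n_correlated) < prop_negative, -1, 1),
    correlated)
  # aligned signs for the doubly planted proteins
  shift <- stats::setNames(
    de_shift * ifelse(de_pool %in% de_up, 1, -1), de_pool)
  slope[overlap] <- abs(slope[overlap]) * sign(shift[overlap])

  cin <- wgii > threshold
  baseline <- stats::rnorm(m, mean = 14, sd = 2)
  log2mat <- matrix(baseline, nrow = m, ncol = n,
                    dimnames = list(feature_ids, names(wgii)))
  log2mat <- log2mat + matrix(stats::rnorm(m * n, 0, sigma), m, n)
  wc <- wgii - mean(wgii)
  log2mat[correlated, ] <- log2mat[correlated, ] +
    outer(slope[correlated], wc)
  log2mat[de_pool, ] <- log2mat[de_pool, ] +
    outer(shift[de_pool], as.numeric(cin))

  scale_log2 <- stats::setNames(stats::rnorm(n, 0, scale_sd), names(wgii))
  mat <- 2^sweep(log2mat, 2, scale_log2, "+")
  if (missing_rate > 0)
    mat[stats::runif(m * n) < missing_rate] <- NA
  peptides <- stats::setNames(
    pmax(1L, stats::rpois(m, 4)), feature_ids)
  peptides[de_pool] <- pmax(peptides[de_pool], 2L)

  labels <- stats::setNames(ifelse(cin, "CIN+", "CIN-"), names(wgii))
  list(matrix = mat, peptides = peptides, labels = labels,
       truth = list(correlated = correlated, slope = slope,
                    de_up = de_up, de_down = de_down, shift = shift,
                    overlap = overlap, scale_log2 = scale_log2,
                    sigma = sigma, threshold = threshold, seed = seed))
}

#' Simulate an RNA-seq count matrix with planted differential genes
#'
#' Negative-binomial counts with group-specific means for the planted
#' differentially expressed (DE) genes.  A chosen subset of the planted DE
#' genes can be forced to coincide with a given protein-level DE set (same
#' ids, same sign) so that the RNA-protein intersection recovers a known
#' overlap.
#'
#' @param labels CIN status per sample (`CIN+`/`CIN-`, named).
#' @param g number of genes (default 20000).
#' @param n_de_up,n_de_down planted DE genes up/down in CIN+ (defaults 644
#'   and 373).
#' @param lfc_range range of absolute log2 fold changes for planted genes
#'   (default `c(1.2, 2.5)`).
#' @param overlap_ids optional character vector of gene ids that must be
#'   planted DE (e.g. 15 protein-DE ids); their direction is taken from
#'   `overlap_sign` (named +-1 vector, default +1).
#' @param exclude_ids gene ids that must NOT be planted DE (beyond
#'   `overlap_ids`), e.g. the rest of a protein DE set.
#' @param dispersion NB dispersion (size = 1/dispersion; default 0.1).
#' @param seed integer RNG seed.
#' @param gene_ids optional universe of gene ids (length `g`); generated as
#'   `G00001...` otherwise.  Must contain `overlap_ids` and `exclude_ids`.
#' @return list with `counts` (genes x samples integer matrix) and `truth`
#'   (ids and signed log2FCs of the planted set, seed).
#' @export
simulate_expression <- function(labels, g = 20000, n_de_up = 644,
                                n_de_down = 373, lfc_range = c(1.2, 2.5),
                                overlap_ids = NULL, overlap_sign = NULL,
                                exclude_ids = NULL, dispersion = 0.1,
                                seed = 1, gene_ids = NULL) {
  if (is.null(names(labels))) stop("labels must be named by sample id")
  set.seed(seed)
  if (is.null(gene_ids)) gene_ids <- sprintf("G%05d", seq_len(g))
  stopifnot(length(gene_ids) == g, !anyDuplicated(gene_ids))
  if (!all(overlap_ids %in% gene_ids) || !all(exclude_ids %in% gene_ids))
    stop("overlap/exclude ids must belong to the gene universe")
  if (length(intersect(overlap_ids, exclude_ids)) > 0)
    stop("overlap_ids and exclude_ids intersect: inconsistent overlap request")
  n_de <- n_de_up + n_de_down
  if (length(overlap_ids) > n_de) stop("more overlap ids than planted DE genes")

  free_pool <- setdiff(gene_ids, c(overlap_ids, exclude_ids))
  de_ids <- c(overlap_ids,
              sample(free_pool, n_de - length(overlap_ids)))
  sign_vec <- stats::setNames(
    sample(rep(c(1, -1), c(n_de_up, n_de_down))), de_ids)
  if (!is.null(overlap_sign)) sign_vec[names(overlap_sign)] <- overlap_sign
  lfc <- stats::setNames(
    sign_vec * stats::runif(n_de, lfc_range[1], lfc_range[2]), de_ids)

  n <- length(labels)
  cin <- cin_positive(labels, names(labels))
  mu0 <- 2^stats::rnorm(g, mean = 6, sd = 2)          # baseline means
  names(mu0) <- gene_ids
  mu <- matrix(mu0, nrow = g, ncol = n,
               dimnames = list(gene_ids, names(labels)))
  mu[de_ids, cin] <- mu[de_ids, cin] * 2^lfc[de_ids]
  counts <- matrix(stats::rnbinom(g * n, mu = mu, size = 1 / dispersion),
                   nrow = g, dimnames = dimnames(mu))
  list(counts = counts,
       truth = list(de_up = de_ids[sign_vec > 0],
                    de_down = de_ids[sign_vec < 0],
                    log2fc = lfc, overlap = overlap_ids, seed = seed))
}

#' Stand-in RNA differential table from a count matrix
#'
#' A deliberately simple differential-expression stand-in for synthetic
#' data: per-gene Welch t-test on log2 counts-per-million (prior count 1)
#' between CIN+ and CIN- samples, with the same fold-change/p significance
#' rule as [differential_protein()].  It is not a replacement for a proper
#' count-based DE model on real data (which this package consumes as an
#' input table); it exists so the synthetic pipeline is self-contained.
#'
#' @param counts genes x samples integer matrix.
#' @param labels CIN status per sample.
#' @param fc_threshold,p_threshold significance thresholds (defaults 1.5
#'   and 0.05).
#' @return a `differential_table` (see [differential_protein()]);
#'   zero-count genes are excluded with a warning.
#' @export
rna_differential_standin <- function(counts, labels, fc_threshold = 1.5,
                                     p_threshold = 0.05) {
  counts <- as.matrix(counts)
  zero <- rowSums(counts) == 0
  if (any(zero)) {
    warning(sum(zero), " zero-count gene(s) excluded")
    counts <- counts[!zero, , drop = FALSE]
  }
  cpm <- sweep(counts, 2, colSums(counts), "/") * 1e6
  differential_protein(log2(cpm + 1), labels,
                       fc_threshold = fc_threshold,
                       p_threshold = p_threshold)
}

#' Simulate a gene-dependency score matrix
#'
#' Dependency scores (more negative = stronger dependence) for a panel of
#' cell lines with CIN labels; planted genes carry a mean shift between the
#' CIN+ and CIN- groups.
#'
#' @param genes character vector of gene ids.
#' @param n_cin,n_neg number of CIN+ and CIN- cell lines (defaults 8, 7).
#' @param dependent_ids planted dependent genes (default: first 7 of
#'   `genes`); must be a subset of `genes`.
#' @param effect mean shift (CIN+ minus CIN-) for planted genes; negative =
#'   stronger dependence in CIN+ (default -0.5).
#' @param sigma per-score noise SD (default 0.1).
#' @param seed integer RNG seed.
#' @return list with `scores` (genes x lines), `labels` (named CIN status)
#'   and `truth` (planted ids, effect, seed).
#' @export
simulate_dependencies <- function(genes, n_cin = 8, n_neg = 7,
                                  dependent_ids = NULL, effect = -0.5,
                                  sigma = 0.1, seed = 1) {
  if (!is.finite(effect)) stop("effect must be finite")
  if (n_cin < 2 || n_neg < 2) stop("need at least 2 lines per label")
  set.seed(seed)
  if (is.null(dependent_ids)) dependent_ids <- utils::head(genes, 7)
  if (!all(dependent_ids %in% genes))
    stop("dependent_ids must be a subset of genes")
  lines <- c(sprintf("CL_CIN%02d", seq_len(n_cin)),
             sprintf("CL_NEG%02d", seq_len(n_neg)))
  labels <- stats::setNames(rep(c("CIN+", "CIN-"), c(n_cin, n_neg)), lines)
  base <- stats::rnorm(length(genes), -0.3, 0.3)
  scores <- matrix(base, nrow = length(genes), ncol = length(lines),
                   dimnames = list(genes, lines)) +
    matrix(stats::rnorm(length(genes) * length(lines), 0, sigma),
           length(genes))
  scores[dependent_ids, seq_len(n_cin)] <-
    scores[dependent_ids, seq_len(n_cin)] + effect
  list(scores = scores, labels = labels,
       truth = list(dependent = dependent_ids, effect = effect,
                    sigma = sigma, seed = seed))
}

#' Simulate a drug-response AUC matrix with screening metadata
#'
#' Compound x cell-line AUCs plus the metadata needed by
#' [drug_compare()]'s filters: a fraction of compounds lacks an annotated
#' target and a fraction was tested in a single line.  Planted "effective"
#' compounds have a lower mean AUC in CIN+ lines; planted "resistant"
#' compounds the opposite.
#'
#' @param n_compounds total compounds (default 497).
#' @param n_cin,n_neg cell lines per group (defaults 8, 7).
#' @param n_effective,n_resistant planted compounds with lower/higher AUC
#'   in CIN+ (defaults 15, 11).
#' @param effect AUC shift magnitude for planted compounds (default 1).
#' @param sigma AUC noise SD (default 0.3).
#' @param prop_no_target,prop_single_line fractions of compounds with no
#'   annotated target / tested in one line (defaults 0.2, 0.1); planted
#'   compounds are always annotated and fully tested.
#' @param seed integer RNG seed.
#' @return list with `auc` (compounds x lines, `NA` where untested),
#'   `labels`, `metadata` (compound, target, n_lines) and `truth`.
#' @export
simulate_drug_response <- function(n_compounds = 497, n_cin = 8, n_neg = 7,
                                   n_effective = 15, n_resistant = 11,
                                   effect = 1, sigma = 0.3,
                                   prop_no_target = 0.2,
                                   prop_single_line = 0.1, seed = 1) {
  set.seed(seed)
  compounds <- sprintf("CPD%03d", seq_len(n_compounds))
  lines <- c(sprintf("CL_CIN%02d", seq_len(n_cin)),
             sprintf("CL_NEG%02d", seq_len(n_neg)))
  labels <- stats::setNames(rep(c("CIN+", "CIN-"), c(n_cin, n_neg)), lines)
  n_lines_total <- n_cin + n_neg

  planted_eff <- sample(compounds, n_effective)
  planted_res <- sample(setdiff(compounds, planted_eff), n_resistant)
  planted <- c(planted_eff, planted_res)
  rest <- setdiff(compounds, planted)
  no_target <- sample(rest, round(prop_no_target * n_compounds))
  single_line <- sample(setdiff(rest, no_target),
                        round(prop_single_line * n_compounds))

  base <- stats::rnorm(n_compounds, 10, 1)
  auc <- matrix(base, nrow = n_compounds, ncol = n_lines_total,
                dimnames = list(compounds, lines)) +
    matrix(stats::rnorm(n_compounds * n_lines_total, 0, sigma), n_compounds)
  auc[planted_eff, seq_len(n_cin)] <- auc[planted_eff, seq_len(n_cin)] - effect
  auc[planted_res, seq_len(n_cin)] <- auc[planted_res, seq_len(n_cin)] + effect
  for (cpd in single_line)
    auc[cpd, sample(n_lines_total, n_lines_total - 1)] <- NA

  metadata <- data.frame(
    compound = compounds,
    target = ifelse(compounds %in% no_target, "",
                    paste0("TGT", match(compounds, compounds) %% 97)),
    n_lines = ifelse(compounds %in% single_line, 1L, n_lines_total),
    stringsAsFactors = FALSE)
  list(auc = auc, labels = labels, metadata = metadata,
       truth = list(effective = planted_eff, resistant = planted_res,
                    no_target = no_target, single_line = single_line,
                    effect = effect, seed = seed))
}

#' Simulate an external CIN/MSI proteomic validation cohort
#'
#' Given the discovery screen's signed correlations, plants a chosen number
#' of differential proteins in an external cohort, a chosen subset of which
#' are concordant in sign with the discovery (the rest significant but
#' sign-flipped), on a z-score-like log scale.
#'
#' @param discovery_r named numeric vector of discovery Pearson
#'   coefficients (the selected proteins).
#' @param n_found how many discovery proteins the external cohort quantifies
#'   (default: all).
#' @param n_differential planted differential proteins among those found
#'   (default 44).
#' @param n_concordant planted with the discovery sign (default 30; the
#'   remaining differential proteins are flipped).
#' @param n_cin,n_msi samples per label (defaults 20, 20).
#' @param effect absolute group shift for planted proteins (default 1).
#' @param sigma noise SD (default 0.3).
#' @param seed integer RNG seed.
#' @return list with `matrix` (proteins x samples), `labels`
#'   (`CIN`/`MSI` named), and `truth` (planted concordant/discordant ids,
#'   seed).
#' @export
simulate_external_cohort <- function(discovery_r, n_found = NULL,
                                     n_differential = 44, n_concordant = 30,
                                     n_cin = 20, n_msi = 20, effect = 1,
                                     sigma = 0.3, seed = 1) {
  if (is.null(names(discovery_r))) stop("discovery_r must be named")
  set.seed(seed)
  if (is.null(n_found)) n_found <- length(discovery_r)
  if (n_differential > n_found || n_concordant > n_differential)
    stop("inconsistent planted counts")
  found <- sample(names(discovery_r), n_found)
  differential <- sample(found, n_differential)
  concordant <- sample(differential, n_concordant)
  discordant <- setdiff(differential, concordant)

  samples <- c(sprintf("EXT_CIN%02d", seq_len(n_cin)),
               sprintf("EXT_MSI%02d", seq_len(n_msi)))
  labels <- stats::setNames(rep(c("CIN", "MSI"), c(n_cin, n_msi)), samples)
  mat <- matrix(stats::rnorm(n_found * length(samples), 0, sigma),
                nrow = n_found, dimnames = list(found, samples))
  shift <- stats::setNames(numeric(n_found), found)
  shift[concordant] <- effect * sign(discovery_r[concordant])
  shift[discordant] <- -effect * sign(discovery_r[discordant])
  mat[, seq_len(n_cin)] <- mat[, seq_len(n_cin)] + shift
  list(matrix = mat, labels = labels,
       truth = list(found = found, differential = differential,
                    concordant = concordant, discordant = discordant,
                    seed = seed))
}

#' Simulate a complete study-scale cohort
#'
#' One call producing every dataset of the pipeline at the default study
#' scale - 12 matched organoid/tissue pairs (8 concordant CIN+, 3
#' concordant CIN-, 1 discordant), segment profiles on the human autosomes,
#' a 1600-protein SWATH-like matrix with a 147-protein wGII-correlated set
#' and a 62-up/54-down shifted set overlapping it in 70 ids, a
#' 20000-gene count matrix with 644/373 planted DE genes sharing exactly 15
#' ids with the protein shifted set, a mitochondrial annotation enriched in
#' the correlated set, a 130-gene dependency matrix with 7 planted
#' CIN-dependent genes over 15 cell lines, a 497-compound drug screen and
#' an external CIN/MSI validation cohort (44 differential / 30 concordant
#' planted) - with all ground truth recorded.
#'
#' @param seed integer master seed; each generator receives a sub-seed
#'   derived from it.
#' @param g number of genes in the expression universe (default 20000;
#'   lower it for fast tests).
#' @param m number of proteins (default 1600).
#' @return list with components `build`, `pairs`, `segments`, `wgii`
#'   (recomputed from the segments), `proteome`, `expression`,
#'   `annotation` (data.frame id/subcellular_location/go_cc),
#'   `dependencies`, `drugs`, `external`, and `truth` (per-component truth
#'   lists plus the master seed).
#' @export
simulate_cohort <- function(seed = 1, g = 20000, m = 1600) {
  sub <- function(k) as.integer((as.numeric(seed) * 131 + k) %% 2147483629)
  build <- hs_autosomes()
  paired <- simulate_paired_cohort(seed = sub(1))
  targets <- c(stats::setNames(paired$pairs$pdo_wgii, paired$pairs$pdo_id),
               stats::setNames(paired$pairs$tissue_wgii,
                               paired$pairs$tissue_id))
  seg <- simulate_segments(targets, build = build, seed = sub(2))
  wgii <- compute_wgii(seg$segments, build, samples = names(targets))

  pdo_wgii <- stats::setNames(wgii$wgii, wgii$sample)[paired$pairs$pdo_id]
  gene_ids <- sprintf("G%05d", seq_len(g))
  prot_ids <- sample_protein_ids(gene_ids, m, seed = sub(3))
  prot <- simulate_proteome(pdo_wgii, m = m, seed = sub(4),
                            feature_ids = prot_ids)

  protein_de <- c(prot$truth$de_up, prot$truth$de_down)
  rna_overlap <- sample_overlap_ids(protein_de, 15, seed = sub(5))
  overlap_sign <- sign(prot$truth$shift[rna_overlap])
  expr <- simulate_expression(prot$labels, g = g,
                              overlap_ids = rna_overlap,
                              overlap_sign = overlap_sign,
                              exclude_ids = setdiff(protein_de, rna_overlap),
                              seed = sub(6), gene_ids = gene_ids)

  annotation <- simulate_mito_annotation(prot_ids, prot$truth$correlated,
                                         seed = sub(7))
  dep_genes <- sample_overlap_ids(prot$truth$correlated, 130, seed = sub(8))
  deps <- simulate_dependencies(dep_genes,
                                dependent_ids = sample_overlap_ids(
                                  dep_genes, 7, seed = sub(9)),
                                seed = sub(10))
  drugs <- simulate_drug_response(seed = sub(11))

  screen <- pearson_screen(normalize_protein(prot$matrix), pdo_wgii)
  disc_r <- stats::setNames(screen$r, screen$protein)
  planted_r <- disc_r[intersect(prot$truth$correlated, names(disc_r))]
  external <- simulate_external_cohort(planted_r, seed = sub(12))

  list(build = build, pairs = paired$pairs, segments = seg$segments,
       wgii = wgii, proteome = prot[c("matrix", "peptides", "labels")],
       expression = expr["counts"], annotation = annotation$table,
       dependencies = deps[c("scores", "labels")],
       drugs = drugs[c("auc", "labels", "metadata")],
       external = external[c("matrix", "labels")],
       truth = list(pairs = paired$truth, segments = seg$truth,
                    proteome = prot$truth, expression = expr$truth,
                    annotation = annotation$truth, dependencies = deps$truth,
                    drugs = drugs$truth, external = external$truth,
                    seed = seed))
}

# deterministic helper draws with their own sub-seeds
sample_protein_ids <- function(gene_ids, m, seed) {
  set.seed(seed)
  sample(gene_ids, m)
}

sample_overlap_ids <- function(pool, k, seed) {
  set.seed(seed)
  sample(pool, k)
}

#' Simulate a mitochondrial annotation enriched in a target set
#'
#' Flags proteins as mitochondrial with higher odds inside a target set
#' (e.g. the planted wGII-correlated proteins) than outside, producing a
#' two-column annotation table in the subcellular-location/GO style
#' consumed by [annotate_mitochondrial()].
#'
#' @param ids protein universe.
#' @param enriched_set ids in which the annotation is enriched.
#' @param p_out baseline annotation probability outside the set
#'   (default 0.075).
#' @param odds_ratio enrichment odds ratio inside the set (default 4).
#' @param seed integer RNG seed.
#' @return list with `table` (data.frame `id`, `subcellular_location`,
#'   `go_cc`) and `truth` (flagged ids, parameters, seed).
#' @export
simulate_mito_annotation <- function(ids, enriched_set, p_out = 0.075,
                                     odds_ratio = 4, seed = 1) {
  set.seed(seed)
  odds_in <- odds_ratio * p_out / (1 - p_out)
  p_in <- odds_in / (1 + odds_in)
  p <- ifelse(ids %in% enriched_set, p_in, p_out)
  mito <- stats::runif(length(ids)) < p
  table <- data.frame(
    id = ids,
    subcellular_location = ifelse(mito, "Mitochondrion inner membrane",
                                  "Cytoplasm"),
    go_cc = ifelse(mito, "mitochondrial matrix", "cytosol"),
    stringsAsFactors = FALSE)
  list(table = table,
       truth = list(mitochondrial = ids[mito], p_in = p_in, p_out = p_out,
                    odds_ratio = odds_ratio, seed = seed))
}
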