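test_that("generators are deterministic given their seed", {
  t <- c(a = 0.3, b = 0.05)
  expect_identical(simulate_segments(t, seed = 5), simulate_segments(t, seed = 5))
  w <- setNames(runif(6), sprintf("s%d", 1:6))
  expect_identical(simulate_proteome(w, m = 50, n_correlated = 10,
                                     n_de_up = 3, n_de_down = 3,
                                     n_overlap = 2, seed = 9),
                   simulate_proteome(w, m = 50, n_correlated = 10,
                                     n_de_up = 3, n_de_down = 3,
                                     n_overlap = 2, seed = 9))
  lab <- setNames(rep(c("CIN+", "CIN-"), 3), sprintf("s%d", 1:6))
  expect_identical(simulate_expression(lab, g = 100, n_de_up = 5,
                                       n_de_down = 5, seed = 2),
                   simulate_expression(lab, g = 100, n_de_up = 5,
                                       n_de_down = 5, seed = 2))
  expect_identical(simulate_dependencies(letters, seed = 3),
                   simulate_dependencies(letters, seed = 3))
})

test_that("segment simulation round-trips the planted wGII", {
  build <- hs_autosomes()
  targets <- c(zero = 0, full = 1, mid = 0.37, low = 0.08)
  sim <- simulate_segments(targets, build = build, seed = 11)
  w <- compute_wgii(sim$segments, build, samples = names(targets))
  got <- setNames(w$wgii, w$sample)
  expect_lt(max(abs(got[names(targets)] - targets)), 1e-9)
  expect_equal(unname(got["zero"]), 0)
  expect_equal(unname(got["full"]), 1)
  # full target means every autosome entirely covered
  bp <- attr(merge_altered(sim$segments, "full"), "altered_bp")
  expect_equal(sort(unname(bp)), sort(build$length[build$autosome]))
  expect_error(simulate_segments(c(x = 1.2)), "\\[0, 1\\]")
})

test_that("proteome simulation honours its planted structure", {
  w <- setNames(c(0.05, 0.08, 0.1, 0.4, 0.45, 0.5), sprintf("s%d", 1:6))
  sim <- simulate_proteome(w, m = 200, n_correlated = 40, n_de_up = 10,
                           n_de_down = 10, n_overlap = 5, seed = 12)
  tr <- sim$truth
  expect_length(tr$correlated, 40)
  expect_length(intersect(c(tr$de_up, tr$de_down), tr$correlated), 5)
  expect_true(all(sim$peptides[c(tr$de_up, tr$de_down)] >= 2))
  expect_true(all(is.na(sim$matrix) | sim$matrix > 0))
  expect_error(simulate_proteome(w, m = 10, n_correlated = 20),
               "inconsistent")

  # noiseless limit: every planted protein correlates perfectly (no scale
  # distortion so the log2 matrix is usable directly)
  sim0 <- simulate_proteome(w, m = 50, n_correlated = 10, sigma = 1e-9,
                            n_de_up = 0, n_de_down = 0, n_overlap = 0,
                            missing_rate = 0, scale_sd = 0, seed = 13)
  scr <- suppressWarnings(
    pearson_screen(log2(sim0$matrix), w))
  planted_r <- scr$r[match(intersect(sim0$truth$correlated, scr$protein),
                           scr$protein)]
  expect_true(all(abs(planted_r) > 0.9999))
})

test_that("a null proteome yields type-I-level selection only", {
  w <- setNames(runif(8), sprintf("s%d", 1:8))
  sim <- simulate_proteome(w, m = 2000, n_correlated = 100, b = 0,
                           n_de_up = 0, n_de_down = 0, n_overlap = 0,
                           missing_rate = 0, seed = 14)
  scr <- pearson_screen(normalize_protein(sim$matrix), w)
  expect_lt(abs(mean(scr$selected) - 0.05), 0.02)
})

test_that("expression simulation plants a recoverable overlap", {
  lab <- setNames(rep(c("CIN+", "CIN-"), c(6, 6)), sprintf("s%d", 1:12))
  prot_de <- sprintf("G%05d", 1:40)
  overlap <- prot_de[1:15]
  sim <- simulate_expression(lab, g = 2000, n_de_up = 60, n_de_down = 40,
                             overlap_ids = overlap,
                             exclude_ids = setdiff(prot_de, overlap),
                             seed = 15)
  expect_true(all(overlap %in% c(sim$truth$de_up, sim$truth$de_down)))
  expect_length(intersect(c(sim$truth$de_up, sim$truth$de_down),
                          setdiff(prot_de, overlap)), 0)
  de <- rna_differential_standin(sim$counts, lab)
  planted <- c(sim$truth$de_up, sim$truth$de_down)
  expect_gte(mean(planted %in% de$feature[de$significant]), 0.9)
  # planted direction is recovered
  up_fc <- de$log2fc[match(sim$truth$de_up, de$feature)]
  expect_true(all(up_fc > 0))
  expect_error(simulate_expression(lab, g = 100,
                                   overlap_ids = "G00001",
                                   exclude_ids = "G00001"),
               "inconsistent")
})

test_that("null expression data stay at the type-I level", {
  lab <- setNames(rep(c("CIN+", "CIN-"), c(5, 5)), sprintf("s%d", 1:10))
  sim <- simulate_expression(lab, g = 2000, n_de_up = 0, n_de_down = 0,
                             seed = 16)
  de <- suppressWarnings(rna_differential_standin(sim$counts, lab))
  expect_lt(abs(mean(de$p < 0.05, na.rm = TRUE) - 0.05), 0.02)
  expect_lt(mean(de$significant), 0.05)   # FC filter removes most nulls

  # zero-count genes are excluded with a warning
  counts <- sim$counts
  counts[1:3, ] <- 0L
  expect_warning(rna_differential_standin(counts, lab), "zero-count")
})

test_that("dependency simulation round-trips through the comparison", {
  genes <- sprintf("g%04d", 1:500)
  sim <- simulate_dependencies(genes, dependent_ids = genes[1:7],
                               effect = -0.5, sigma = 0.1, seed = 17)
  res <- dependency_compare(sim$scores, sim$labels)
  hit <- res$feature[!is.na(res$p) & res$p < 0.05 & res$effect < 0]
  expect_true(all(sim$truth$dependent %in% hit))

  # effect 0: recovery stays at the type-I level
  sim0 <- simulate_dependencies(genes, dependent_ids = genes[1:7],
                                effect = 0, sigma = 0.1, seed = 18)
  res0 <- dependency_compare(sim0$scores, sim0$labels)
  expect_lt(mean(res0$p < 0.05, na.rm = TRUE), 0.09)
  expect_error(simulate_dependencies(genes, effect = Inf), "finite")
})

test_that("a single planted dependency among 10000 genes survives BH", {
  genes <- sprintf("g%05d", 1:10000)
  sim <- simulate_dependencies(genes, dependent_ids = "g00042",
                               effect = -0.5, sigma = 0.1, seed = 19)
  res <- dependency_compare(sim$scores, sim$labels)
  expect_lt(res$q[res$feature == "g00042"], 0.05)
  expect_lt(res$effect[res$feature == "g00042"], 0)
})

test_that("planted mitochondrial enrichment is detectable", {
  set.seed(20)
  ids <- sprintf("p%04d", 1:1000)
  target <- sample(ids, 147)
  ann <- simulate_mito_annotation(ids, target, p_out = 0.13,
                                  odds_ratio = 4, seed = 20)
  flags <- annotate_mitochondrial(ids, ann$table)
  expect_setequal(ids[which(flags)], ann$truth$mitochondrial)
  res <- overrepresentation_test(target, ids, setNames(flags, ids))
  expect_lt(res$p, 0.01)
})
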