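# Independent oracles used across the suite.  Each is a brute-force or
# closed-form computation kept deliberately separate from the package's
# implementation path.

# per-base boolean-union wGII oracle for toy genomes (lengths small enough
# to materialise one logical per base)
perbase_wgii <- function(segments, build, sample) {
  autos <- build[build$autosome, , drop = FALSE]
  seg <- segments[segments$sample == sample, , drop = FALSE]
  fracs <- vapply(seq_len(nrow(autos)), function(i) {
    chrom <- autos$chrom[i]
    covered <- logical(autos$length[i])
    rows <- which(seg$chrom == chrom)
    for (r in rows) {
      # 0-based half-open [start, end) -> bases start+1 .. end
      covered[(seg$start[r] + 1):seg$end[r]] <- TRUE
    }
    mean(covered)
  }, 0)
  mean(fracs)
}

# upper-tail hypergeometric by direct enumeration of the support
hyper_upper_enum <- function(N, K, n, k) {
  if (n == 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# two-sided Fisher exact p for a 2x2 table by enumerating all tables with
# the observed margins (sum of probabilities <= observed probability)
fisher2x2_enum <- function(tab) {
  stopifnot(all(dim(tab) == c(2, 2)))
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  support <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- vapply(support, function(a)
    choose(c1, a) * choose(N - c1, r1 - a) / choose(N, r1), 0)
  obs <- probs[support == tab[1, 1]]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# random toy segment table on a toy build (integer coordinates)
random_toy_segments <- function(build, sample = "s1", n_seg = 8) {
  autos <- build[build$autosome, , drop = FALSE]
  idx <- sample.int(nrow(autos), n_seg, replace = TRUE)
  start <- vapply(idx, function(i) sample.int(autos$length[i], 1) - 1, 0)
  end <- vapply(seq_along(idx), function(j)
    start[j] + sample.int(autos$length[idx[j]] - start[j], 1), 0)
  segment_table(data.frame(
    sample = sample, chrom = autos$chrom[idx], start = start, end = end,
    call = sample(c("gain", "loss"), n_seg, replace = TRUE),
    stringsAsFactors = FALSE), build = build)
}

# study-scale synthetic cohort shared by the acceptance tests (generated
# once per test run)
cohort_cache <- local({
  env <- new.env()
  function(seed = 101) {
    key <- paste0("s", seed)
    if (is.null(env[[key]])) env[[key]] <- simulate_cohort(seed = seed)
    env[[key]]
  }
})
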