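---
title: "Methods: wGII scoring and CIN-stratified screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wGII scoring and CIN-stratified screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cinomics)
```

This vignette documents the models and procedures implemented in
`cinomics`, the defaults they ship with, and the design decisions taken
where the methodology left genuine choices open. It states no numbers that
the test suite or `scripts/acceptance.R` do not themselves compute.

## The wGII model

The weighted Genome Instability Index treats a copy-number profile as a set
of gain/loss intervals on a reference genome. For each autosome the altered
fraction is the summed width of the merged intervals divided by the
chromosome length; wGII is the unweighted mean of these 22 fractions, and a
sample is CIN+ when wGII exceeds 0.2.

Decisions behind `compute_wgii()`:

- **Autosomes only, fixed denominator.** Sex chromosomes are excluded
  (their copy state is confounded by sex), and the denominator is always
  the full autosome count of the build, not just chromosomes carrying
  segments — otherwise a sample with a single small alteration on one
  chromosome would score 1 on that chromosome's "mean". Both choices follow
  standard wGII practice and keep scores comparable across samples. The
  `autosome` flag of `genome_build()` makes the inclusion rule explicit and
  overridable.
- **Gains and losses pooled by set union.** A base covered by both a gain
  and a loss call (possible with subclonal/mosaic profiles) counts once.
  The alternative — summing gain and loss lengths independently — can push
  a fraction above 1 and double-counts overlapping calls.
- **Strict threshold.** wGII exactly 0.2 is CIN−, reading "greater than
  0.2" literally. With continuous scores the boundary case is measure-zero;
  the choice only matters for constructed data, and the threshold is an
  argument.
- **Mosaic segments count at full weight.** A subclonal alteration is
  evidence of instability in itself; `mosaic_fraction` is carried as
  metadata but does not down-weight the interval. Callers wanting
  down-weighting can pre-filter.
- **Coordinates.** Internally 0-based half-open; ChAS-style 1-based
  inclusive exports are converted on read (`read_segments(dialect =
  "chas")`). Interval merging and gene overlap run on
  IRanges/GenomicRanges.

Gene-level copy states (`gene_copy_states()`) assign each gene the copy
number of the overlapping segment covering the largest share of the gene,
2 where nothing overlaps, with ties between a gain and a loss resolved to
the loss — deterministic and conservative, since losses are the rarer call
in the cohorts this targets.

## Concordance and prevalence

`pair_regression()` implements the outlier-robust organoid-vs-tissue fit:
one ordinary least-squares pass, flagging of pairs whose residual exceeds
2 population standard deviations of the initial residuals, one refit on the
remainder. The removal is deliberately single-pass — iterating
flag-and-refit can cascade on small cohorts (n = 12 pairs), and the
procedure description reads as a single trimming step. The reported r and
two-sided p come from the refit via the exact t-transform with n − 2
degrees of freedom. A small absolute tolerance (1e-12) keeps numerically
exact fits from flagging machine-epsilon residuals.

`cin_prevalence()` takes an explicit sample set; whether organoids and
tissues are pooled is the caller's decision (the cohort generator's
acceptance path pools all 24 samples).

## Protein screening

Two screens share the normalisation in `normalize_protein()`: log2
transform and per-sample median centring. The median is taken on the log2
scale; for an odd number of quantified features this equals dividing by the
linear-scale median, and for an even number it is the geometric midpoint,
which keeps the per-sample median of the output exactly zero in every case.

- `differential_protein()` — per-feature two-sided Welch t-test between
  CIN+ and CIN− samples. The Welch (unequal-variance) form was chosen
  because proteomic group variances routinely differ and group sizes are
  small and unbalanced; the test is unnamed in typical methods sections,
  so the choice is surfaced here and the thresholds are arguments.
  Significance requires all of: |fold change| ≥ 1.5 (linear scale),
  p < 0.05, and ≥ 2 supporting peptides when peptide counts are supplied.
  BH-adjusted q-values are reported alongside but do not gate
  significance.
- `pearson_screen()` — per-protein Pearson correlation against wGII, with
  p from the t-transform at n − 2 degrees of freedom. Missing protein
  values are handled pairwise-complete with a minimum of 5 complete pairs
  (a floor below which a correlation on so few points is noise); constant
  proteins are excluded with a warning. Selection is on the raw two-sided
  p < 0.05 — not FDR-adjusted — matching the practice of selecting on
  p-value in small discovery cohorts; q is reported for users who want
  control.

The enrichment stage (`overrepresentation_test()`) is the one-sided
upper-tail hypergeometric probability P(X ≥ k), computed with `phyper`.
The default population is the set of quantified proteins, not the genome:
mass-spectrometry detection is biased toward abundant proteins, and a
genome background would manufacture enrichment. Unannotated ids are
excluded from both population and selection counts. Mitochondrial flags
come from a case-insensitive `mitochondr` substring match over the supplied
annotation strings, or an explicit curated list; no live database queries.

## Signature classification

`classify_by_signature()` z-scores each signature feature across samples,
clusters samples by Euclidean distance with Ward linkage, cuts at k = 2,
and tests cluster-vs-label association: Fisher's exact test for 2×2
tables, chi-square otherwise. "Ward linkage" is `hclust(method =
"ward.D2")` — the Ward criterion on raw (not squared) Euclidean distances.
k is fixed at 2 because the question is binary (CIN+ vs CIN−); no
silhouette or gap selection. Constant matrices, or cuts leaving an empty
cluster, are flagged degenerate and return `NA` rather than a p-value.

## External prioritisation

`dependency_compare()` and `drug_compare()` are per-feature Welch t-tests
between CIN+ and CIN− cell lines ("multiple t-tests" in screening
parlance), reporting raw p and BH q. `drug_compare()` applies its filters
*before* any test: compounds with no annotated target, or tested in at most
one line, never reach a p-value — so the multiplicity burden reflects only
testable compounds. "More effective in CIN+" means lower mean AUC in CIN+
with p < 0.05. `external_signature_validation()` calls a discovery protein
concordant in an external CIN/MSI cohort when it is differential there and
the sign of its CIN-minus-MSI difference matches the sign of its discovery
correlation; the concordant set then re-clusters the external cohort
through the same classification machinery.

## What the synthetic cohort emulates

`simulate_cohort()` generates, from one seed, a cohort at the scale of a
typical PDO CIN study: 12 matched organoid/tissue pairs (8 concordant
CIN+, 3 concordant CIN−, 1 discordant pair with a CIN− tissue and a
high-wGII organoid, emulating low tumour content and doubling as the
planted regression outlier — with pair noise SD 0.07 this realises a
concordance around r ≈ 0.87 and a pooled CIN+ prevalence near 70%);
segment profiles on the 22 human autosomes whose recomputed wGII
round-trips the planted targets to 1e-9; a 1600-protein abundance matrix
with a 147-protein wGII-correlated set (log2 slope 2 per unit wGII, noise
SD 0.25, 30% negative slopes), a 62-up/54-down group-shifted set (log2
shift 1.2) overlapping the correlated set in 70 ids, per-sample scale
distortions (log2 SD 0.4) and 5% missingness; a 20000-gene
negative-binomial count matrix (dispersion 0.1) with 644/373 planted DE
genes sharing exactly 15 ids with the protein shifted set; a mitochondrial
annotation planted at odds ratio 4 in the correlated set; a 130-gene
dependency matrix over 15 cell lines with 7 planted CIN-dependent genes
(shift −0.5, noise 0.1); a 497-compound drug screen with 15 planted
CIN+-effective and 11 CIN+-resistant compounds behind the no-target and
single-line filters; and an external CIN/MSI cohort planting 44
differential discovery proteins of which 30 are sign-concordant.

What it does **not** emulate: segmentation error and breakpoint
uncertainty; correlated missingness (real SWATH missingness is
abundance-dependent); protein–protein abundance correlation; count-model
misspecification that a DESeq2-class analysis would absorb;
batch structure. Passing tests therefore demonstrate that the statistical
machinery recovers known structure under its own assumptions — not that
those assumptions hold in any real cohort.

The RNA differential stand-in (`rna_differential_standin()`) is a Welch
t-test on log2 counts-per-million with the same |FC|/p significance rule as
the protein screen. On synthetic data with strong planted effects this
recovers the planted sets; on real counts a dedicated count model should be
used and its output consumed as the input table — the stand-in exists so
the synthetic pipeline is self-contained, and at a raw p < 0.05 threshold
its significant set includes null genes at the type-I rate.

## Numerical choices and test design

- Exact wGII round-trips are achieved by drawing per-autosome fractions
  Dirichlet-style, rescaling to the target mean, rounding to integer base
  pairs and absorbing the rounding residual on the largest chromosomes;
  on ~1e8-bp chromosomes the residual is below 1e-9.
- Every generator seeds its own RNG stream and records the seed in its
  truth object; outputs are byte-identical across re-runs with the same
  seed.
- The planted-recovery property for the Pearson screen is parameterised by
  the signal-to-noise ratio b·sd(wGII)/σ. A per-unit-wGII reading of the
  slope is not scale-free (the same b means different detectability
  depending on the wGII spread), so the recovery guarantee — at least 90%
  of planted proteins selected at SNR 1.5 with n = 8 samples and a
  CIN-cohort-like bimodal wGII design — is stated and tested in SNR terms.
  The recovery simulations plant 400 proteins among 8000 (a 5% planted
  fraction) so that the Monte-Carlo error of the estimated recovery rate is
  near 1% and median centring is not perturbed by the planted mass.
- Type-I calibration tests use 3000 null features per run (standard error
  ~0.4% on a 5% rate); permutation agreement uses 10,000 shuffles at
  n = 8. Problem sizes throughout (2000-gene expression fixtures,
  500-gene dependency panels) are chosen so the full suite runs in well
  under a minute while keeping Monte-Carlo error well inside the asserted
  bands.

## Known limitations

- wGII is computed from total copy-number calls; allele-specific events
  (copy-neutral LOH) are invisible to it, and no ploidy correction is
  attempted.
- The CIN+ threshold of 0.2 is a convention, not an estimated cut; cohorts
  with different platforms or segmentation stringency may need their own.
- Selection on raw p-values (both screens) trades false positives for
  sensitivity in small cohorts; the reported q-values are the
  multiplicity-aware alternative.
- The package consumes dependency/drug matrices as plain labelled
  matrices; database versioning, gene-id harmonisation and MSI inference
  are the caller's responsibility.
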