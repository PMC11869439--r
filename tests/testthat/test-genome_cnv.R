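toy_build <- genome_build(c("chrA", "chrB"), c(100, 200))

write_seg_tsv <- function(df) {
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("read_segments normalises ChAS and BED coordinate conventions", {
  chas <- write_seg_tsv(data.frame(sample = "s1", chrom = "chrA",
                                   start = 1, end = 100, call = "gain"))
  bed <- write_seg_tsv(data.frame(sample = "s1", chrom = "chrA",
                                  start = 0, end = 100, call = "gain"))
  seg_chas <- read_segments(chas, "chas", build = toy_build)
  seg_bed <- read_segments(bed, "bed", build = toy_build)
  expect_equal(seg_chas$start, 0)
  expect_equal(seg_chas$end, 100)
  expect_equal(as.data.frame(seg_chas), as.data.frame(seg_bed))
})

test_that("segment validation reports offending rows and columns", {
  bad <- write_seg_tsv(data.frame(sample = c("s1", "s2"),
                                  chrom = "chrA",
                                  start = c(0, 50), end = c(10, 40),
                                  call = "gain"))
  expect_error(read_segments(bad, "bed"), "row\\(s\\): 2.*s2")
  nocol <- write_seg_tsv(data.frame(sample = "s1", chrom = "chrA",
                                    start = 0, stop = 10, call = "gain"))
  expect_error(read_segments(nocol, "bed"), "end")
  expect_error(
    segment_table(data.frame(sample = "s1", chrom = "chrZ", start = 0,
                             end = 10, call = "gain"), build = toy_build),
    "chrZ")
  expect_error(
    segment_table(data.frame(sample = "s1", chrom = "chrA", start = 0,
                             end = 10, call = "loss", copy_number = 3)),
    "inconsistent")
})

test_that("merge_altered pools overlapping gain/loss calls by set union", {
  seg <- segment_table(data.frame(
    sample = "s1", chrom = "chrA",
    start = c(0, 40), end = c(50, 80),
    call = c("gain", "gain")), build = toy_build)
  m <- merge_altered(seg)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(0, 80))
  expect_equal(unname(attr(m, "altered_bp")["chrA"]), 80)

  seg2 <- segment_table(data.frame(
    sample = "s1", chrom = "chrA",
    start = c(0, 20), end = c(10, 30),
    call = c("gain", "loss")), build = toy_build)
  m2 <- merge_altered(seg2)
  expect_equal(nrow(m2), 2)
  expect_equal(sum(attr(m2, "altered_bp")), 20)

  empty <- segment_table(data.frame(sample = character(), chrom = character(),
                                    start = numeric(), end = numeric(),
                                    call = character()))
  expect_equal(sum(attr(merge_altered(empty, sample = "sX"), "altered_bp")), 0)
})

test_that("compute_wgii matches hand arithmetic and handles edge cases", {
  # toy: gain chrA [0,50), loss chrB [0,100) -> a = (0.5, 0.5)
  seg <- segment_table(data.frame(
    sample = "s1", chrom = c("chrA", "chrB"),
    start = c(0, 0), end = c(50, 100),
    call = c("gain", "loss")), build = toy_build)
  w <- compute_wgii(seg, toy_build)
  expect_equal(w$wgii, 0.5)
  expect_equal(as.character(w$cin), "CIN+")

  # no alterations -> 0, CIN-
  w0 <- compute_wgii(seg, toy_build, samples = c("s1", "none"))
  expect_equal(w0$wgii[w0$sample == "none"], 0)
  expect_equal(as.character(w0$cin[w0$sample == "none"]), "CIN-")

  # saturation: every autosome fully gained -> 1, CIN+
  segf <- segment_table(data.frame(
    sample = "sf", chrom = c("chrA", "chrB"), start = 0, end = c(100, 200),
    call = "gain"), build = toy_build)
  wf <- compute_wgii(segf, toy_build)
  expect_equal(wf$wgii, 1)
  expect_equal(as.character(wf$cin), "CIN+")

  # strict threshold: wGII exactly at the cutoff is CIN-
  seg02 <- segment_table(data.frame(
    sample = "s2", chrom = c("chrA", "chrB"), start = 0, end = c(20, 40),
    call = "gain"), build = toy_build)
  w02 <- compute_wgii(seg02, toy_build)
  expect_equal(w02$wgii, 0.2)
  expect_equal(as.character(w02$cin), "CIN-")

  expect_error(compute_wgii(segment_table(data.frame(
    sample = "s", chrom = "chrZ", start = 0, end = 5, call = "gain")),
    toy_build), "chrZ")
  expect_error(genome_build("chrX", 100, autosome = FALSE), "autosome")
})

test_that("sex chromosomes are excluded from the wGII denominator", {
  gb <- genome_build(c("chr1", "chrX"), c(100, 100))
  seg <- segment_table(data.frame(
    sample = "s1", chrom = c("chr1", "chrX"), start = 0, end = c(50, 100),
    call = "gain"), build = gb)
  expect_equal(compute_wgii(seg, gb)$wgii, 0.5)
})

test_that("wGII is invariant to segment splitting and monotone in additions", {
  set.seed(42)
  for (rep in 1:10) {
    seg <- random_toy_segments(toy_build)
    w <- compute_wgii(seg, toy_build)$wgii
    # split every segment at an interior point into abutting halves
    mids <- floor((seg$start + seg$end) / 2)
    splittable <- mids > seg$start & mids < seg$end
    split_df <- rbind(
      data.frame(sample = seg$sample, chrom = seg$chrom,
                 start = seg$start,
                 end = ifelse(splittable, mids, seg$end),
                 call = seg$call),
      data.frame(sample = seg$sample[splittable],
                 chrom = seg$chrom[splittable],
                 start = mids[splittable], end = seg$end[splittable],
                 call = seg$call[splittable]))
    w_split <- compute_wgii(segment_table(split_df, build = toy_build),
                            toy_build)$wgii
    expect_identical(w, w_split)
    # adding an interval can only increase the score
    extra <- rbind(as.data.frame(seg)[, 1:5],
                   data.frame(sample = "s1", chrom = "chrB",
                              start = 150, end = 190, call = "loss"))
    w_extra <- compute_wgii(segment_table(extra, build = toy_build),
                            toy_build)$wgii
    expect_gte(w_extra, w)
  }
})

test_that("compute_wgii equals the per-base boolean-union oracle", {
  set.seed(7)
  builds <- list(toy_build,
                 genome_build(paste0("c", 1:5), c(37, 101, 64, 250, 11)))
  for (build in builds) {
    for (rep in 1:10) {
      seg <- random_toy_segments(build, n_seg = sample(1:12, 1))
      expect_equal(compute_wgii(seg, build)$wgii,
                   perbase_wgii(seg, build, "s1"))
    }
  }
})

test_that("gene_copy_states assigns the dominant overlapping copy state", {
  genes <- data.frame(gene = c("g_in_gain", "g_none", "g_half_loss",
                               "g_tie"),
                      chrom = "chrA",
                      start = c(10, 90, 30, 50),
                      end = c(20, 95, 50, 70))
  seg <- segment_table(data.frame(
    sample = "s1", chrom = "chrA",
    start = c(5, 30, 50, 60), end = c(25, 40, 60, 70),
    call = c("gain", "loss", "gain", "loss"),
    copy_number = c(3, 1, 3, 1)), build = toy_build)
  calls <- gene_copy_states(seg, genes, build = toy_build)
  st <- setNames(calls$state, calls$gene)
  expect_equal(unname(st["g_in_gain"]), 3L)    # fully inside CN=3 gain
  expect_equal(unname(st["g_none"]), 2L)       # diploid default
  expect_equal(unname(st["g_half_loss"]), 1L)  # loss covers largest fraction
  expect_equal(unname(st["g_tie"]), 1L)        # equal gain/loss -> loss

  # rows without copy_number default to 3 (gain) / 1 (loss)
  seg2 <- segment_table(data.frame(sample = "s1", chrom = "chrA",
                                   start = 0, end = 100, call = "gain"))
  calls2 <- gene_copy_states(seg2, genes[1, ])
  expect_equal(calls2$state, 3L)

  expect_error(
    gene_copy_states(seg, data.frame(gene = "g", chrom = "chrA",
                                     start = 50, end = 150),
                     build = toy_build),
    "outside chromosome bounds")
})
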