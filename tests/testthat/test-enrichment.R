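# Fisher tail, region enrichment against the genome background, CLIP
# region summaries and metagene profiles.

test_that("one-tailed Fisher matches enumeration on hand-checked tables", {
  expect_equal(fisher_one_tailed(matrix(c(0, 10, 0, 10), 2, byrow = TRUE)), 1)
  expect_equal(fisher_one_tailed(matrix(c(5, 0, 0, 5), 2, byrow = TRUE)),
               1 / 252, tolerance = 1e-12)
  # enumeration-verified value (also equals stats::fisher.test "greater")
  expect_equal(fisher_one_tailed(matrix(c(5, 0, 5, 5), 2, byrow = TRUE)),
               252 / 3003, tolerance = 1e-12)
  expect_error(fisher_one_tailed(matrix(c(-1, 0, 0, 5), 2)), "non-negative")
})

test_that("Fisher tail equals fisher.test(greater) on random tables", {
  set.seed(50)
  for (i in 1:50) {
    tab <- matrix(sample(0:25, 4, replace = TRUE), 2)
    expect_equal(fisher_one_tailed(tab),
                 stats::fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
})

test_that("region enrichment ratio is peak fraction over genome fraction", {
  # one 1000-bp single-exon gene on a 10 kb chromosome, no windows: exon
  # covers 10% of the genome (minus the 2 single-base TSS/TES windows)
  genes <- mk_gene("g1", "chr1", 1000, c(1000), integer(0))
  cfg <- region_config(promoter_upstream = 0, promoter_downstream = 0,
                       tts_upstream = 0, tts_downstream = 0, utr_proxy = 0)
  set.seed(51)
  inside <- tibble::tibble(chrom = "chr1",
                           start = sample(1050:1900, 30), end = NA)
  outside <- tibble::tibble(chrom = "chr1",
                            start = sample(3000:9000, 70), end = NA)
  pk <- dplyr::bind_rows(inside, outside) |> dplyr::mutate(end = start + 20)
  res <- region_enrichment(pk, genes, c(chr1 = 10000), cfg)
  exon <- res[res$region == "exon", ]
  expect_equal(exon$n_peaks_in, 30)
  expect_equal(exon$peak_fraction, 0.3)
  expect_equal(exon$enrichment_ratio,
               0.3 / exon$genome_fraction)
  expect_equal(sum(res$peak_fraction), 1, tolerance = 1e-12)
  expect_true(all(res$pvalue > 0 & res$pvalue <= 1))
})

test_that("enrichment p-values reproduce the hypergeometric tail on the tile table", {
  genes <- mk_gene("g1", "chr1", 1000, c(1000), integer(0))
  cfg <- region_config(promoter_upstream = 0, promoter_downstream = 0,
                       tts_upstream = 0, tts_downstream = 0, utr_proxy = 0)
  pk <- tibble::tibble(chrom = "chr1", start = c(1100, 1300, 5000),
                       end = c(1200, 1400, 5100))
  res <- region_enrichment(pk, genes, c(chr1 = 10000), cfg)
  # tile width = median peak width = 100 -> 100 tiles; tile midpoints in
  # the exon: tiles starting 1000..1900 have midpoints 1050..1950, and the
  # two single-base TSS/TES windows claim none of those midpoints except
  # none (tss base 1000 and tes base 1999 are not midpoints), so b = 10
  exon <- res[res$region == "exon", ]
  expect_equal(exon$pvalue, bf_fisher(2, 1, 10, 90), tolerance = 1e-12)
})

test_that("CLIP region summary reports counts, fractions and mean enrichment", {
  genes <- toy_genes()
  cfg <- region_config()
  # three peaks in gA's first intron ([5500, 6000)), fc 2/4/6
  pk <- tibble::tibble(
    chrom = "chr1", start = c(5600, 5700, 5800), end = c(5660, 5760, 5860),
    name = c("c1", "c2", "c3"), score = 0, strand = ".",
    fold_enrichment = c(2, 4, 6), neg_log10_p = 5, neg_log10_q = -1,
    summit = -1L, assay = "clip"
  )
  res <- clip_region_enrichment(pk, genes, cfg)
  expect_equal(nrow(res), 1)
  expect_equal(res$region, "intron")
  expect_equal(res$n_peaks, 3)
  expect_equal(res$peak_fraction, 1)
  expect_equal(res$mean_fold_enrichment, 4)
  expect_equal(res$mean_log2_fc, mean(log2(c(2, 4, 6))))
})

test_that("metaprofile of a constant track is flat at the constant", {
  track <- tibble::tibble(chrom = "chr1", start = 0, end = 50000, value = 3.5)
  anchors <- tibble::tibble(chrom = "chr1", start = c(20000, 30000),
                            end = c(20200, 30200))
  mp <- metaprofile(anchors, track, half_window = 3000, bin_width = 50)
  expect_equal(nrow(mp), 120)
  expect_true(all(abs(mp$mean_depth - 3.5) < 1e-12))
  expect_equal(attr(mp, "n_anchors"), 2)
  expect_equal(mp$offset[1], -2975)
  expect_equal(mp$offset[120], 2975)
})

test_that("a single 50-bp pulse lands in the centre bin only", {
  anchors <- tibble::tibble(chrom = "chr1", start = 10000, end = 10200)
  mid <- 10100
  track <- tibble::tibble(chrom = "chr1", start = mid - 25, end = mid + 25,
                          value = 10)
  mp <- metaprofile(anchors, track, half_window = 3000, bin_width = 50)
  expect_equal(sum(mp$mean_depth > 0), 2)  # pulse straddles two 50-bp bins
  expect_equal(sum(mp$mean_depth) * 50, 10 * 50)  # mass conserved
})

test_that("metaprofile is linear in the track and matches per-base averaging", {
  set.seed(52)
  track <- tibble::tibble(
    chrom = "chr1",
    start = seq(0, 49750, by = 250), end = seq(250, 50000, by = 250),
    value = round(runif(200, 0, 5), 3)
  )
  anchors <- tibble::tibble(
    chrom = "chr1", start = sample(2000:40000, 100), end = NA
  ) |> dplyr::mutate(end = start + 150)
  mp <- metaprofile(anchors, track, half_window = 300, bin_width = 50)
  oracle <- bf_metaprofile(anchors, track, 300, 50)
  expect_equal(mp$mean_depth, oracle, tolerance = 1e-12)

  scaled <- track |> dplyr::mutate(value = value * 4)
  mp4 <- metaprofile(anchors, scaled, half_window = 300, bin_width = 50)
  expect_equal(mp4$mean_depth, 4 * mp$mean_depth, tolerance = 1e-12)
})

test_that("off-chromosome window positions contribute zero depth", {
  track <- tibble::tibble(chrom = "chr1", start = 0, end = 1000, value = 2)
  anchors <- tibble::tibble(chrom = "chr1", start = 0, end = 100)  # mid 50
  mp <- metaprofile(anchors, track, half_window = 300, bin_width = 50)
  # window [-250, 350): the 5 leading bins overlap negative coordinates
  expect_equal(mp$mean_depth[1], 0)   # [-250, -200) fully off-chromosome
  expect_equal(mp$mean_depth[12], 2)  # [300, 350) fully covered
  expect_error(metaprofile(anchors, track, half_window = 300, bin_width = 70),
               "divide")
})

test_that("summit anchoring shifts the profile when summits are present", {
  track <- tibble::tibble(chrom = "chr1", start = 500, end = 510, value = 5)
  anchors <- tibble::tibble(chrom = "chr1", start = 400, end = 1000,
                            summit = 105L)  # summit at 505, midpoint at 700
  mp_mid <- metaprofile(anchors, track, half_window = 100, bin_width = 10)
  mp_sum <- metaprofile(anchors, track, half_window = 100, bin_width = 10,
                        anchor = "summit")
  expect_equal(sum(mp_sum$mean_depth[mp_sum$offset %in% c(-5, 5)] > 0), 2)
  expect_false(identical(mp_mid$mean_depth, mp_sum$mean_depth))
})
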