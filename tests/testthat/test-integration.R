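# Gene classification, target sets, contrast overlaps, Jaccard and the
# ChIP-CLIP distance profile.

deg_row <- function(gene_id, log2fc) {
  tibble::tibble(gene_id = gene_id, base_mean = 10, log2fc = log2fc,
                 pvalue = 1e-4, padj = 1e-3,
                 direction = ifelse(log2fc > 0, "up", "down"))
}

as_row <- function(gene_id, delta_psi, event_type = "SE", chrom = "chr1",
                   start = 100, end = 200) {
  tibble::tibble(event_id = paste0(event_type, "_", gene_id, "_", start),
                 gene_id = gene_id, event_type = event_type, chrom = chrom,
                 start = start, end = end, strand = "+",
                 delta_psi = delta_psi, pvalue = 1e-4, fdr = 1e-3,
                 direction = ifelse(delta_psi > 0, "inclusion_up",
                                    "inclusion_down"))
}

clip_peak <- function(chrom, start, end) {
  tibble::tibble(chrom = chrom, start = start, end = end,
                 name = paste0("c", start), score = 0, strand = ".",
                 fold_enrichment = 8, neg_log10_p = 5, neg_log10_q = -1,
                 summit = -1L, assay = "clip")
}

test_that("genes partition into DEG-only / AS-only / Both with subgroups", {
  deg <- dplyr::bind_rows(deg_row("A", -2), deg_row("B", -1.5))
  as_ev <- dplyr::bind_rows(as_row("B", 0.3), as_row("C", -0.2))
  got <- classify_genes(deg, as_ev, universe = c("A", "B", "C", "D"))
  expect_equal(got$group[match(c("A", "B", "C", "D"), got$gene_id)],
               c("DEG_only", "Both", "AS_only", "none"))
  # B: down-regulated with increased inclusion -> subgroup 1
  expect_equal(got$subgroup[got$gene_id == "B"], 1L)
  expect_true(is.na(got$subgroup[got$gene_id == "A"]))

  # disjoint layers -> no Both genes
  got2 <- classify_genes(deg_row("A", 1), as_row("B", 0.1), c("A", "B"))
  expect_equal(sum(got2$group == "Both"), 0)
})

test_that("mixed inclusion directions block the subgroup and the partition identities hold", {
  deg <- deg_row("A", 2)
  as_ev <- dplyr::bind_rows(as_row("A", 0.3, start = 100, end = 200),
                            as_row("A", -0.3, start = 400, end = 500),
                            as_row("B", 0.2))
  got <- classify_genes(deg, as_ev, universe = c("A", "B"))
  a <- got[got$gene_id == "A", ]
  expect_equal(a$group, "Both")
  expect_equal(a$as_direction, "mixed")
  expect_true(is.na(a$subgroup))

  n_deg <- length(unique(deg$gene_id))
  n_as <- length(unique(as_ev$gene_id))
  expect_equal(sum(got$group == "DEG_only") + sum(got$group == "Both"), n_deg)
  expect_equal(sum(got$group == "AS_only") + sum(got$group == "Both"), n_as)

  expect_warning(classify_genes(deg_row("Z", 1), as_ev[0, ], c("A", "B")),
                 "absent from the universe")
})

test_that("all four subgroups map as direction combinations", {
  deg <- dplyr::bind_rows(deg_row("s1", -2), deg_row("s2", -2),
                          deg_row("s3", 2), deg_row("s4", 2))
  as_ev <- dplyr::bind_rows(as_row("s1", 0.3), as_row("s2", -0.3),
                            as_row("s3", 0.3), as_row("s4", -0.3))
  got <- classify_genes(deg, as_ev, paste0("s", 1:4))
  expect_equal(got$subgroup[match(paste0("s", 1:4), got$gene_id)], 1:4)
})

test_that("transcriptional targets are DEGs with a distance-0 peak", {
  genes <- toy_genes()
  deg <- dplyr::bind_rows(deg_row("gA", -2), deg_row("gB", 1))
  pk <- random_peaks(1, "chr1", 1e4)[0, ]
  expect_equal(transcriptional_targets(deg, pk, genes), character())
  # one peak in gA's promoter
  pk1 <- tibble::tibble(chrom = "chr1", start = 4400, end = 4600)
  expect_equal(transcriptional_targets(deg, pk1, genes), "gA")
  # region whitelist: the same peak is rejected if only exonic evidence counts
  expect_equal(transcriptional_targets(deg, pk1, genes, regions = "exon"),
               character())
})

test_that("event-peak matching respects half-open adjacency and the window", {
  ev <- as_row("G", 0.3, start = 100, end = 200)
  expect_equal(splicing_targets(ev, clip_peak("chr1", 150, 160))$gene_ids, "G")
  # peak starting exactly at the segment end does not match at window 0
  miss <- splicing_targets(ev, clip_peak("chr1", 200, 300))
  expect_equal(nrow(miss$events), 0)
  expect_equal(miss$gene_ids, character())
  # ... but does with a 1-bp window
  expect_equal(splicing_targets(ev, clip_peak("chr1", 200, 300),
                                window = 1)$gene_ids, "G")
  # different chromosome never matches
  expect_equal(splicing_targets(ev, clip_peak("chr2", 150, 160))$gene_ids,
               character())
})

test_that("contrast overlap labels concordance in both modes", {
  kd <- dplyr::bind_rows(deg_row("A", -1), deg_row("B", 2))
  pma <- dplyr::bind_rows(deg_row("A", -0.5), deg_row("B", -1), deg_row("C", 1))
  ov <- differentiation_overlap(kd, pma, "genes")
  expect_setequal(ov$gene_id, c("A", "B"))
  expect_equal(ov$concordant[ov$gene_id == "A"], TRUE)
  expect_equal(ov$concordant[ov$gene_id == "B"], FALSE)
  expect_equal(nrow(differentiation_overlap(kd, pma[0, ], "genes")), 0)

  kd_ev <- dplyr::bind_rows(as_row("A", 0.3), as_row("B", 0.2, start = 300))
  pma_ev <- dplyr::bind_rows(as_row("A", -0.4),
                             as_row("B", 0.2, start = 999))  # different segment
  ove <- differentiation_overlap(kd_ev, pma_ev, "events")
  expect_equal(ove$gene_id, "A")
  expect_false(ove$concordant)
})

test_that("jaccard has the subset identity and symmetric bounds", {
  expect_equal(jaccard(c("a", "b"), c("b", "c")), 1 / 3)
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard(character(), character()), 0)
  set.seed(60)
  for (i in 1:20) {
    a <- sample(letters, sample(0:15, 1))
    b <- sample(letters, sample(0:15, 1))
    expect_equal(jaccard(a, b), jaccard(b, a))
    expect_gte(jaccard(a, b), 0)
    expect_lte(jaccard(a, b), 1)
    if (length(a) > 0) expect_equal(jaccard(a, union(a, b)),
                                    length(unique(a)) / length(union(a, b)))
  }
})

test_that("target-set chains nest and co-regulation is the exact intersection", {
  b <- shared_bundle()
  r <- shared_report()
  ts <- r$target_sets
  expect_true(all(ts$co_regulated %in% ts$diff_transcriptional))
  expect_true(all(ts$co_regulated %in% ts$diff_splicing))
  expect_true(all(ts$diff_transcriptional %in% ts$transcriptional))
  expect_true(all(ts$diff_splicing %in% ts$splicing))
  expect_setequal(ts$co_regulated,
                  intersect(ts$diff_transcriptional, ts$diff_splicing))
  ev <- co_regulated_genes(ts, r$deg_kd_sig, r$deg_pma_sig)
  expect_equal(ev$gene_id, ts$co_regulated)
  expect_true(all(!is.na(ev$log2fc_kd)))
  # concordance restriction: kd and differentiation signs agree
  expect_true(all(sign(ev$log2fc_kd) == sign(ev$log2fc_pma)))
})

test_that("distance bins follow the overlap/gap rules on hand cases", {
  chip <- tibble::tibble(chrom = "chr1", start = c(100, 0, 0),
                         end = c(200, 100, 100))
  chip$chrom[3] <- "chr2"
  clip <- dplyr::bind_rows(clip_peak("chr1", 150, 250),
                           clip_peak("chr1", 7100, 7200))
  prof <- chip_clip_distance_profile(chip[1, ], clip)
  expect_equal(prof$count[prof$bin == "overlap"], 1)
  # ChIP [0,100) vs nearest CLIP [7100,7200): gap 7000 -> 5-10 kb bin
  prof2 <- chip_clip_distance_profile(chip[2, ], clip[2, ])
  expect_equal(prof2$count[prof2$bin == "kb5_10"], 1)
  # no CLIP peak on chr2 -> beyond-10kb bin
  prof3 <- chip_clip_distance_profile(chip, clip)
  expect_equal(prof3$count[prof3$bin == "gt_10kb"], 1)
  expect_equal(sum(prof3$fraction), 1, tolerance = 1e-12)
  expect_error(chip_clip_distance_profile(chip[0, ], clip), "empty")
})

test_that("distance profile equals the all-pairs scan and is monotone under CLIP supersets", {
  set.seed(61)
  chip <- random_peaks(300, c("chr1", "chr2"), 2e6)
  clip <- random_peaks(300, c("chr1", "chr2"), 2e6)
  prof <- chip_clip_distance_profile(chip, clip)
  oracle <- table(factor(bf_distance_bins(chip, clip),
                         levels = c("overlap", "lt_5kb", "kb5_10", "gt_10kb")))
  expect_equal(prof$count, as.integer(oracle))
  expect_equal(sum(prof$fraction), 1, tolerance = 1e-12)

  # adding CLIP peaks can only move ChIP peaks to nearer bins
  bigger <- dplyr::bind_rows(clip, random_peaks(200, c("chr1", "chr2"), 2e6))
  prof_big <- chip_clip_distance_profile(chip, bigger)
  cum_small <- cumsum(prof$count)
  cum_big <- cumsum(prof_big$count)
  expect_true(all(cum_big >= cum_small))
})
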