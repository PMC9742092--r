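# Region classification: priority scheme, midpoint rule, nearest-gene
# assignment and exact genome composition, each checked against a
# brute-force per-base oracle.

test_that("positions classify into the expected region classes", {
  genes <- toy_genes()
  cfg <- region_config()
  got <- classify_positions(
    tibble::tibble(chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
                   pos = c(4500, 5700, 5300, 15000, 1100)),
    genes, cfg
  )
  # 4500 is inside (tss - 1000, tss + 100) of gA; 5700 in the gap between
  # gA's first two exons; 5300 inside exon 1 (past the promoter and the
  # 5' proxy); 15000 in no gene or window; 1100 in gC's 5' UTR proxy zone
  # but still claimed by gC's promoter (+100 downstream), so exon wins only
  # beyond it.
  expect_equal(got$region,
               c("promoter", "intron", "exon", "intergenic", "promoter"))
  expect_equal(got$gene_id, c("gA", "gA", "gA", NA, "gC"))
})

test_that("priority resolves overlaps deterministically and intergenic has no gene", {
  genes <- toy_genes()
  cfg <- region_config()
  # within the promoter window (tss..tss+100) the 5' proxy zone is claimed
  # by the higher-priority promoter label
  got <- classify_positions(tibble::tibble(chrom = "chr1", pos = 5050),
                            genes, cfg)
  expect_equal(got$region, "promoter")
  # beyond promoter (+100) the proxy applies: positions 5101..5199
  got2 <- classify_positions(tibble::tibble(chrom = "chr1", pos = 5150),
                             genes, cfg)
  expect_equal(got2$region, "five_prime_utr_proxy")
  # repeated calls are identical (pure function)
  pts <- tibble::tibble(chrom = rep("chr1", 50), pos = seq(4000, 8900, 100))
  expect_identical(classify_positions(pts, genes, cfg),
                   classify_positions(pts, genes, cfg))
  # unknown chromosome warns and falls through to intergenic
  expect_warning(
    got3 <- classify_positions(tibble::tibble(chrom = "chrUn", pos = 5),
                               genes, cfg),
    "intergenic"
  )
  expect_equal(got3$region, "intergenic")
})

test_that("classification agrees with the brute-force per-base oracle", {
  dir <- withr::local_tempdir()
  simulate_bundle(small_sim_cfg(11), dir)
  genes <- read_gtf(file.path(dir, "genome.gtf"))
  cfg <- region_config()
  set.seed(42)
  pts <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 2000, replace = TRUE),
                        pos = floor(runif(2000, 0, 6e5)))
  got <- classify_positions(pts, genes, cfg)
  oracle <- bf_classify(pts, genes, cfg)
  expect_equal(got$region, oracle$region)
  expect_equal(got$gene_id, oracle$gene_id)
})

test_that("peaks are classified by their midpoint", {
  genes <- toy_genes()
  cfg <- region_config()
  pk <- tibble::tibble(chrom = "chr1", start = c(4400, 5400), end = c(4600, 5600))
  got <- classify_peaks(pk, genes, cfg)
  expect_equal(got$midpoint, c(4500, 5500))
  # [5400, 5600) spans gA's exon1/intron1 boundary at 5500; midpoint 5500
  # is the first intron base
  expect_equal(got$region, c("promoter", "intron"))
})

test_that("nearest_gene distances are zero in the hull and signed TSS offsets outside", {
  genes <- toy_genes()
  cfg <- region_config()
  pk <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr1", "chr3"),
    start = c(4999, 2700, 12000, 10),
    end = c(5001, 2800, 12002, 20)
  )
  got <- nearest_gene(pk, genes, cfg)
  # midpoint exactly at gA's tss
  expect_equal(got$distance[1], 0)
  expect_equal(got$gene_id[1], "gA")
  # 2750 is 2250 bp 5' of gA's tss, outside the hull (which starts at 4000)
  expect_equal(got$distance[2], -2250)
  # 12001 sits between gA (hull [4000, 8000)) and gB (- strand, hull
  # [19000, 22600)): |d| to gA's tss is 7001, to gB's tss (21599) is 9598
  expect_equal(got$gene_id[3], "gA")
  expect_equal(got$distance[3], 7001)
  # chromosome with no gene
  expect_true(is.na(got$gene_id[4]))
  expect_equal(got$distance[4], Inf)
})

test_that("nearest_gene agrees with a brute-force scan on random peaks", {
  dir <- withr::local_tempdir()
  simulate_bundle(small_sim_cfg(12), dir)
  genes <- read_gtf(file.path(dir, "genome.gtf"))
  cfg <- region_config()
  set.seed(99)
  pk <- random_peaks(500, c("chr1", "chr2"), 6e5)
  got <- nearest_gene(pk, genes, cfg)
  for (i in seq_len(nrow(pk))) {
    o <- bf_nearest_one(pk$chrom[i], got$midpoint[i], genes, cfg)
    expect_identical(got$gene_id[i], o$gene_id)
    expect_equal(got$distance[i], o$distance)
  }
})

test_that("genome composition is exact on a hand-computable annotation", {
  genes <- mk_gene("g1", "chr1", 1000, c(1000), integer(0))
  cfg <- region_config(promoter_upstream = 0, promoter_downstream = 0,
                       tts_upstream = 0, tts_downstream = 0, utr_proxy = 0)
  comp <- genome_region_composition(genes, c(chr1 = 10000), cfg)
  # zero-width windows still claim the single TSS/TES base each
  expect_equal(comp$bp[comp$region == "promoter"], 1)
  expect_equal(comp$bp[comp$region == "tts"], 1)
  expect_equal(comp$bp[comp$region == "exon"], 998)
  expect_equal(comp$bp[comp$region == "intergenic"], 9000)
  expect_equal(sum(comp$fraction), 1)

  empty <- genome_region_composition(toy_genes()[0, ], c(chr1 = 5000),
                                     region_config())
  expect_equal(empty$fraction[empty$region == "intergenic"], 1)
})

test_that("composition equals a per-base brute-force scan on a small chromosome", {
  genes <- dplyr::bind_rows(
    mk_gene("gX", "chr1", 2000, c(300, 200), c(400), "+"),
    mk_gene("gY", "chr1", 3500, c(250, 250), c(500), "-")  # overlaps gX's TTS zone
  )
  cfg <- region_config(utr_proxy = 150)
  L <- 8000
  comp <- genome_region_composition(genes, c(chr1 = L), cfg)
  oracle <- bf_classify(tibble::tibble(chrom = "chr1", pos = 0:(L - 1)),
                        genes, cfg)
  tab <- table(factor(oracle$region, levels = region_levels()))
  expect_equal(comp$bp, as.numeric(tab))
})

test_that("region fractions always sum to one across random configurations", {
  genes <- toy_genes()
  set.seed(7)
  for (i in 1:20) {
    cfg <- region_config(
      promoter_upstream = sample(0:3000, 1),
      promoter_downstream = sample(0:500, 1),
      tts_upstream = sample(0:500, 1),
      tts_downstream = sample(0:3000, 1),
      utr_proxy = sample(0:400, 1)
    )
    comp <- genome_region_composition(genes, toy_sizes(), cfg)
    expect_equal(sum(comp$fraction), 1, tolerance = 1e-12)
    expect_true(all(comp$bp >= 0))
  }
})
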