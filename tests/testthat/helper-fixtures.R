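# Shared fixtures and independent brute-force oracles. The oracles
# re-derive every quantity from first principles (plain loops and choose()
# arithmetic) and never call the implementation paths they check.

mk_gene <- function(gene_id, chrom, start, exon_widths, intron_widths,
                    strand = "+", gene_name = toupper(gene_id)) {
  stopifnot(length(intron_widths) == length(exon_widths) - 1)
  starts <- start + cumsum(c(0, head(exon_widths, -1) + intron_widths))
  ex <- tibble::tibble(start = starts, end = starts + exon_widths)
  tibble::tibble(
    gene_id = gene_id, gene_name = gene_name, chrom = chrom,
    start = start, end = max(ex$end), strand = strand,
    tss = if (strand == "-") max(ex$end) - 1 else start,
    tes = if (strand == "-") start else max(ex$end) - 1,
    n_exons = length(exon_widths), exons = list(ex)
  )
}

# Three genes on two chromosomes; gA has tss = 5000 on the + strand.
toy_genes <- function() {
  dplyr::bind_rows(
    mk_gene("gA", "chr1", 5000, c(500, 500, 200), c(500, 300), "+"),
    mk_gene("gB", "chr1", 20000, c(300, 300), c(1000), "-"),
    mk_gene("gC", "chr2", 1000, c(400, 200, 300), c(600, 800), "+")
  )
}

toy_sizes <- function() c(chr1 = 30000, chr2 = 10000)

# Deterministic, dense annotation in which every occupied region class
# covers >= 10% of the genome (under grid_cfg()), so that ratio bounds on
# uniformly placed peaks are multi-sigma. All genes on the + strand, laid
# on a regular 40 kb grid.
grid_annotation <- function(n_per_chrom = 25, chrom_len = 1e6, n_chroms = 2) {
  rows <- list()
  k <- 0
  for (ci in seq_len(n_chroms)) {
    for (j in seq_len(n_per_chrom)) {
      k <- k + 1
      slot <- (j - 1) * (chrom_len / n_per_chrom)
      rows[[k]] <- mk_gene(sprintf("grid%03d", k), paste0("chr", ci),
                           slot + 8000, rep(1500, 8), rep(1700, 7))
    }
  }
  dplyr::bind_rows(rows)
}

grid_cfg <- function() {
  region_config(promoter_upstream = 2000, promoter_downstream = 2000,
                tts_upstream = 2000, tts_downstream = 2000, utr_proxy = 0)
}

grid_sizes <- function(n_chroms = 2, chrom_len = 1e6) {
  stats::setNames(rep(chrom_len, n_chroms), paste0("chr", seq_len(n_chroms)))
}

# A compact simulation configuration for tests that need many replicates.
small_sim_cfg <- function(seed, noise_sd = 0) {
  sim_config(seed = seed, n_genes = 120, chrom_length = 6e5,
             n_trans_targets = 15, n_splice_targets = 12, n_co_regulated = 5,
             n_chip_decoys = 80, n_clip_decoys = 80, n_pma_only_deg = 12,
             n_pma_only_splice = 8, noise_sd = noise_sd)
}

# Default-configuration bundle shared across test files (simulated once).
.fixture_cache <- new.env(parent = emptyenv())

shared_bundle <- function() {
  if (is.null(.fixture_cache$bundle)) {
    dir <- file.path(tempdir(), "chipclipr-default-bundle")
    manifest <- simulate_bundle(sim_config(seed = 1), dir)
    .fixture_cache$bundle <- list(dir = dir, manifest = manifest)
  }
  .fixture_cache$bundle
}

shared_report <- function() {
  if (is.null(.fixture_cache$report)) {
    b <- shared_bundle()
    .fixture_cache$report <- suppressMessages(run_integration(b$dir))
  }
  .fixture_cache$report
}

## ---- brute-force oracles --------------------------------------------------

# Per-position region scan over every gene and window, vectorized over the
# genes of the position's chromosome.
bf_classify_one <- function(chrom, pos, genes, cfg) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  best <- list(region = "intergenic", gene_id = NA_character_)
  if (nrow(g) == 0) return(best)
  plus <- g$strand != "-"
  in_prom <- ifelse(plus,
    pos >= g$tss - cfg$promoter_upstream & pos <= g$tss + cfg$promoter_downstream,
    pos >= g$tss - cfg$promoter_downstream & pos <= g$tss + cfg$promoter_upstream)
  in_tts <- ifelse(plus,
    pos >= g$tes - cfg$tts_upstream & pos <= g$tes + cfg$tts_downstream,
    pos >= g$tes - cfg$tts_downstream & pos <= g$tes + cfg$tts_upstream)
  u <- cfg$utr_proxy
  if (u > 0) {
    in5 <- ifelse(plus,
      pos >= g$start & pos < pmin(g$start + u, g$end),
      pos >= pmax(g$end - u, g$start) & pos < g$end)
    in3 <- ifelse(plus,
      pos >= pmax(g$end - u, g$start) & pos < g$end,
      pos >= g$start & pos < pmin(g$start + u, g$end))
  } else {
    in5 <- in3 <- rep(FALSE, nrow(g))
  }
  in_exon <- vapply(g$exons, function(ex) any(ex$start <= pos & pos < ex$end),
                    logical(1))
  in_intron <- (pos >= g$start & pos < g$end) & !in_exon
  cand <- rbind(in_prom, in_tts, in5, in3, in_exon, in_intron)
  labels <- c("promoter", "tts", "five_prime_utr_proxy",
              "three_prime_utr_proxy", "exon", "intron")
  hits <- which(cand, arr.ind = TRUE)
  if (nrow(hits) == 0) return(best)
  ord <- order(hits[, "row"], g$gene_id[hits[, "col"]])[1]
  list(region = labels[hits[ord, "row"]], gene_id = g$gene_id[hits[ord, "col"]])
}

bf_classify <- function(positions, genes, cfg) {
  res <- lapply(seq_len(nrow(positions)), function(i) {
    bf_classify_one(positions$chrom[i], positions$pos[i], genes, cfg)
  })
  tibble::tibble(
    region = vapply(res, `[[`, "", "region"),
    gene_id = vapply(res, `[[`, "", "gene_id")
  )
}

bf_nearest_one <- function(chrom, mid, genes, cfg) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (nrow(g) == 0) return(list(gene_id = NA_character_, distance = Inf))
  plus <- g$strand != "-"
  hull_lo <- ifelse(plus, g$start - cfg$promoter_upstream,
                    g$start - cfg$tts_downstream)
  hull_hi <- ifelse(plus, g$end + cfg$tts_downstream,
                    g$end + cfg$promoter_upstream)
  inside <- hull_lo <= mid & mid < hull_hi
  if (any(inside)) {
    return(list(gene_id = min(g$gene_id[inside]), distance = 0))
  }
  d <- ifelse(plus, mid - g$tss, g$tss - mid)
  ord <- order(abs(d), g$gene_id)[1]
  list(gene_id = g$gene_id[ord], distance = d[ord])
}

# Exhaustive hypergeometric tail by direct choose() arithmetic.
bf_fisher <- function(a, b, c2, d) {
  r1 <- a + b; c1 <- a + c2; n <- a + b + c2 + d
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  xs <- xs[xs >= a]
  if (length(xs) == 0) return(0)
  sum(vapply(xs, function(x) {
    choose(r1, x) * choose(n - r1, c1 - x) / choose(n, c1)
  }, numeric(1)))
}

# Per-base depth of a bedGraph step function at one position.
bf_depth_at <- function(track, chrom, pos) {
  sel <- track$chrom == chrom & track$start <= pos & pos < track$end
  if (any(sel)) sum(track$value[sel]) else 0
}

bf_metaprofile <- function(anchors, track, half_window, bin_width) {
  mids <- floor((anchors$start + anchors$end) / 2)
  offsets <- seq(-half_window, half_window - 1)
  depth <- matrix(0, nrow = nrow(anchors), ncol = length(offsets))
  for (i in seq_len(nrow(anchors))) {
    for (j in seq_along(offsets)) {
      depth[i, j] <- bf_depth_at(track, anchors$chrom[i], mids[i] + offsets[j])
    }
  }
  per_base <- colMeans(depth)
  n_bins <- (2 * half_window) / bin_width
  vapply(seq_len(n_bins), function(b) {
    mean(per_base[((b - 1) * bin_width + 1):(b * bin_width)])
  }, numeric(1))
}

# All-pairs nearest-CLIP scan with the same bin semantics as the contract:
# overlap needs >= 1 shared bp; gap 0 without shared bp is lt_5kb.
bf_distance_bins <- function(chip, clip) {
  vapply(seq_len(nrow(chip)), function(i) {
    same <- clip[clip$chrom == chip$chrom[i], , drop = FALSE]
    if (nrow(same) == 0) return("gt_10kb")
    shared <- pmin(chip$end[i], same$end) - pmax(chip$start[i], same$start)
    if (any(shared >= 1)) return("overlap")
    gap <- min(pmax(chip$start[i], same$start) - pmin(chip$end[i], same$end))
    if (gap <= 5000) "lt_5kb" else if (gap <= 10000) "kb5_10" else "gt_10kb"
  }, character(1))
}

random_peaks <- function(n, chroms, chrom_len, width_range = c(50, 400)) {
  w <- sample(width_range[1]:width_range[2], n, replace = TRUE)
  s <- floor(runif(n, 0, chrom_len - max(width_range)))
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = s, end = s + w,
    name = sprintf("p%05d", seq_len(n)), score = 0, strand = ".",
    fold_enrichment = runif(n, 1, 10), neg_log10_p = runif(n, 0, 6),
    neg_log10_q = -1, summit = -1L, assay = "chip"
  )
}
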