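# Synthetic data generator: a complete, self-consistent toy bundle
# (annotation, ChIP/CLIP peaks, coverage tracks, expression and splicing
# tables for a knockdown and a differentiation contrast) with a
# machine-readable truth manifest. The manifest records both the planted
# roles and the downstream sets expected from the written files, the latter
# computed by the generator's own independent bookkeeping (plain scans of
# the emitted tables) so it can serve as an oracle for the pipeline.

#' Simulation configuration
#'
#' Defaults describe a compact two-chromosome genome dense enough to
#' exercise every region class, with planted transcriptional targets
#' (promoter ChIP peaks on differentially expressed genes), splicing
#' targets (significant splicing events covered by high-enrichment CLIP
#' peaks) and a co-regulated subset present in both pools and shared with
#' the differentiation contrast. Non-target rows follow the null: uniform
#' p-values, near-zero effect sizes; decoy peaks sit at or below the
#' fold-enrichment cutoff so the CLIP filter removes them.
#'
#' `noise_sd` is the coefficient-of-variation of the planted effect sizes:
#' a target's realized effect is `nominal * (1 + N(0, noise_sd))`, and its
#' p-value is coupled to the realized relative magnitude `r` as `10^(-u *
#' r)` with `u ~ U(4, 8)`, so at `noise_sd = 0` target p-values are at most
#' 1e-4 and as noise grows targets increasingly fail the significance
#' filters.
#'
#' @param seed Integer seed; one seed yields one byte-identical bundle.
#' @param n_chroms,chrom_length Number of chromosomes and their common
#'   length (bp).
#' @param n_genes Number of non-overlapping single-transcript genes.
#' @param exons_per_gene Inclusive integer range of exon counts.
#' @param n_trans_targets,n_splice_targets,n_co_regulated Planted target
#'   pool sizes; the co-regulated genes are drawn from both pools.
#' @param pma_overlap_fraction Fraction of each knockdown target pool also
#'   planted (concordantly) in the differentiation contrast.
#' @param effect_log2fc,effect_dpsi Nominal effect sizes of planted
#'   expression and splicing targets.
#' @param clip_fc_true,clip_fc_decoy IP/input fold enrichment of true and
#'   decoy CLIP peaks.
#' @param noise_sd Relative effect-size noise (see above).
#' @param n_chip_decoys,n_clip_decoys Decoy peak counts.
#' @param n_pma_only_deg,n_pma_only_splice Differentiation-only planted
#'   targets, so the contrast overlap is a proper subset in both
#'   directions.
#' @param null_event_fraction Fraction of non-target genes given one null
#'   (non-significant) splicing event per contrast.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chroms = 2, chrom_length = 2e6,
                       n_genes = 500, exons_per_gene = c(3, 8),
                       n_trans_targets = 40, n_splice_targets = 30,
                       n_co_regulated = 10, pma_overlap_fraction = 0.6,
                       effect_log2fc = 2.0, effect_dpsi = 0.3,
                       clip_fc_true = 8, clip_fc_decoy = 2, noise_sd = 0,
                       n_chip_decoys = 300, n_clip_decoys = 300,
                       n_pma_only_deg = 30, n_pma_only_splice = 20,
                       null_event_fraction = 0.4) {
  if (n_co_regulated > min(n_trans_targets, n_splice_targets)) {
    abort("n_co_regulated must not exceed either target pool size")
  }
  if (pma_overlap_fraction < 0 || pma_overlap_fraction > 1 ||
      null_event_fraction < 0 || null_event_fraction > 1) {
    abort("Fractions must lie in [0, 1]")
  }
  structure(
    list(seed = as.integer(seed), n_chroms = n_chroms,
         chrom_length = chrom_length, n_genes = n_genes,
         exons_per_gene = exons_per_gene,
         n_trans_targets = n_trans_targets,
         n_splice_targets = n_splice_targets,
         n_co_regulated = n_co_regulated,
         pma_overlap_fraction = pma_overlap_fraction,
         effect_log2fc = effect_log2fc, effect_dpsi = effect_dpsi,
         clip_fc_true = clip_fc_true, clip_fc_decoy = clip_fc_decoy,
         noise_sd = noise_sd, n_chip_decoys = n_chip_decoys,
         n_clip_decoys = n_clip_decoys, n_pma_only_deg = n_pma_only_deg,
         n_pma_only_splice = n_pma_only_splice,
         null_event_fraction = null_event_fraction),
    class = "sim_config"
  )
}

EVENT_TYPES <- c("SE", "MXE", "A3SS", "A5SS", "RI")
EVENT_TYPE_WEIGHTS <- c(SE = 0.5, MXE = 0.1, A3SS = 0.15, A5SS = 0.1,
                        RI = 0.15)

sim_genes <- function(cfg) {
  per_chrom <- ceiling(cfg$n_genes / cfg$n_chroms)
  rows <- list()
  gi <- 0
  for (ci in seq_len(cfg$n_chroms)) {
    chrom <- paste0("chr", ci)
    n_here <- min(per_chrom, cfg$n_genes - (ci - 1) * per_chrom)
    if (n_here <= 0) next
    n_ex <- sample(seq(cfg$exons_per_gene[1], cfg$exons_per_gene[2]),
                   n_here, replace = TRUE)
    ex_w <- purrr::map(n_ex, function(k) sample(100:300, k, replace = TRUE))
    in_w <- purrr::map(n_ex, function(k) sample(300:1500, k - 1, replace = TRUE))
    glen <- purrr::map2_dbl(ex_w, in_w, function(e, i) sum(e) + sum(i))
    min_gap <- 2200
    needed <- sum(glen) + (n_here + 1) * min_gap
    if (needed > cfg$chrom_length) {
      abort(paste0("Cannot place ", n_here, " genes without overlap on a ",
                   format_bp(cfg$chrom_length),
                   " bp chromosome; increase chrom_length"))
    }
    slack <- cfg$chrom_length - needed
    w <- runif(n_here + 1)
    extra <- floor(slack * w / sum(w))
    gaps <- min_gap + extra
    pos <- 0
    for (k in seq_len(n_here)) {
      pos <- pos + gaps[k]
      gi <- gi + 1
      starts <- pos + cumsum(c(0, head(ex_w[[k]], -1) + in_w[[k]]))
      ex <- tibble(start = starts, end = starts + ex_w[[k]])
      strand <- sample(c("+", "-"), 1)
      rows[[gi]] <- tibble(
        gene_id = sprintf("g%04d", gi),
        gene_name = sprintf("GENE%04d", gi),
        chrom = chrom, start = pos, end = pos + glen[k], strand = strand,
        tss = if (strand == "-") pos + glen[k] - 1 else pos,
        tes = if (strand == "-") pos else pos + glen[k] - 1,
        n_exons = n_ex[k], exons = list(ex)
      )
      pos <- pos + glen[k]
    }
  }
  bind_rows(rows) |> arrange(.data$chrom, .data$start, .data$gene_id)
}

# Draw one planted effect: realized = nominal * (1 + N(0, noise_sd)), with
# the p-value coupled to the realized relative magnitude.
draw_effect <- function(n, nominal, noise_sd) {
  sgn <- sample(c(-1, 1), n, replace = TRUE)
  realized <- nominal * (1 + rnorm(n, 0, noise_sd))
  r <- pmax(0, abs(realized) / nominal)
  p <- pmax(10^(-runif(n, 4, 8) * r), 1e-300)
  tibble(value = sgn * abs(realized), pvalue = pmin(p, 1))
}

# sample() flattens a length-1 vector into 1:n; always pick from the set
sample_one <- function(v) v[sample.int(length(v), 1)]

pick_event <- function(gene, used_exons = integer()) {
  ex <- gene$exons[[1]]
  n <- nrow(ex)
  repeat {
    type <- sample(EVENT_TYPES, 1, prob = EVENT_TYPE_WEIGHTS)
    if (type == "MXE" && n < 4) next
    i <- if (type == "MXE") sample_one(2:(n - 2)) else sample_one(2:(n - 1))
    ext <- 100
    seg <- switch(type,
      SE = c(ex$start[i], ex$end[i]),
      MXE = c(ex$start[i], ex$end[i]),
      A5SS = c(ex$start[i], ex$end[i] + ext),
      A3SS = c(ex$start[i] - ext, ex$end[i]),
      RI = c(ex$start[i], ex$end[i + 1])
    )
    # bp interval in which a planted CLIP peak lands in the intended class
    clip_zone <- switch(type,
      SE = c(ex$start[i], ex$end[i]),
      MXE = c(ex$start[i], ex$end[i]),
      A5SS = c(ex$start[i], ex$end[i]),
      A3SS = c(ex$start[i], ex$end[i]),
      RI = c(ex$end[i] + 5, ex$start[i + 1] - 5)
    )
    clip_class <- if (type == "RI") "intron" else "exon"
    return(list(type = type, seg_start = seg[1], seg_end = seg[2],
                clip_zone = clip_zone, clip_class = clip_class,
                exon_index = i))
  }
}

sim_events_layer <- function(genes, target_ids, shared_from = NULL, cfg,
                             null_pool) {
  rows <- list()
  k <- 0
  for (gid in target_ids) {
    k <- k + 1
    if (!is.null(shared_from) && gid %in% names(shared_from)) {
      base <- shared_from[[gid]]
      eff <- draw_effect(1, cfg$effect_dpsi, cfg$noise_sd)
      dpsi <- base$dpsi_sign * abs(eff$value)
      rows[[k]] <- tibble(
        gene_id = gid, event_type = base$type,
        seg_start = base$seg_start, seg_end = base$seg_end,
        exon_index = base$exon_index,
        delta_psi = max(-0.95, min(0.95, dpsi)),
        pvalue = eff$pvalue, planted = TRUE,
        clip_zone_start = base$clip_zone[1], clip_zone_end = base$clip_zone[2],
        clip_class = base$clip_class
      )
    } else {
      g <- genes[genes$gene_id == gid, ]
      ev <- pick_event(g)
      eff <- draw_effect(1, cfg$effect_dpsi, cfg$noise_sd)
      rows[[k]] <- tibble(
        gene_id = gid, event_type = ev$type,
        seg_start = ev$seg_start, seg_end = ev$seg_end,
        exon_index = ev$exon_index,
        delta_psi = max(-0.95, min(0.95, eff$value)),
        pvalue = eff$pvalue, planted = TRUE,
        clip_zone_start = ev$clip_zone[1], clip_zone_end = ev$clip_zone[2],
        clip_class = ev$clip_class
      )
    }
  }
  for (gid in null_pool) {
    k <- k + 1
    g <- genes[genes$gene_id == gid, ]
    ev <- pick_event(g)
    rows[[k]] <- tibble(
      gene_id = gid, event_type = ev$type,
      seg_start = ev$seg_start, seg_end = ev$seg_end,
      exon_index = ev$exon_index,
      delta_psi = sample(c(-1, 1), 1) * runif(1, 0, 0.049),
      pvalue = runif(1), planted = FALSE,
      clip_zone_start = ev$clip_zone[1], clip_zone_end = ev$clip_zone[2],
      clip_class = ev$clip_class
    )
  }
  ev <- bind_rows(rows)
  if (nrow(ev) == 0) return(ev)
  gidx <- match(ev$gene_id, genes$gene_id)
  ev$chrom <- genes$chrom[gidx]
  ev$strand <- genes$strand[gidx]
  # per-type row ids and BH FDR, as the upstream engine would report
  ev <- ev |>
    group_by(.data$event_type) |>
    mutate(row_id = row_number(),
           fdr = stats::p.adjust(.data$pvalue, method = "BH")) |>
    ungroup()
  ev
}

write_deg_file <- function(deg, path) {
  out <- tibble(
    gene_id = deg$gene_id,
    baseMean = round(deg$base_mean, 3),
    log2FoldChange = signif(deg$log2fc, 8),
    pvalue = signif(deg$pvalue, 8),
    padj = signif(deg$padj, 8)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

write_rmats_files <- function(ev, genes, dir, stem) {
  for (tt in EVENT_TYPES) {
    sub <- ev[ev$event_type == tt, , drop = FALSE]
    seg <- RMATS_SEGMENT_COLS[[tt]]
    base <- tibble(
      ID = if (nrow(sub)) sub$row_id else integer(),
      GeneID = if (nrow(sub)) sub$gene_id else character(),
      geneSymbol = if (nrow(sub)) {
        genes$gene_name[match(sub$gene_id, genes$gene_id)]
      } else character(),
      chr = if (nrow(sub)) sub$chrom else character(),
      strand = if (nrow(sub)) sub$strand else character()
    )
    base[[seg[1]]] <- if (nrow(sub)) format_bp(sub$seg_start) else character()
    base[[seg[2]]] <- if (nrow(sub)) format_bp(sub$seg_end) else character()
    if (tt == "MXE") {
      nxt <- purrr::map2(sub$gene_id, sub$exon_index, function(gid, i) {
        ex <- genes$exons[[match(gid, genes$gene_id)]]
        c(ex$start[i + 1], ex$end[i + 1])
      })
      base[["2ndExonStart_0base"]] <- if (nrow(sub)) {
        format_bp(purrr::map_dbl(nxt, 1))
      } else character()
      base[["2ndExonEnd"]] <- if (nrow(sub)) {
        format_bp(purrr::map_dbl(nxt, 2))
      } else character()
    }
    base$PValue <- if (nrow(sub)) signif(sub$pvalue, 8) else numeric()
    base$FDR <- if (nrow(sub)) signif(sub$fdr, 8) else numeric()
    base$IncLevelDifference <- if (nrow(sub)) signif(sub$delta_psi, 8) else numeric()
    readr::write_tsv(base, file.path(dir, paste0(stem, tt, ".tsv")),
                     progress = FALSE)
  }
  invisible(dir)
}

gaussian_bump_track <- function(chroms, chrom_length, centres_by_chrom,
                                amp, sd = 150, halo = 600, step = 10) {
  rows <- list()
  for (chrom in chroms) {
    centres <- centres_by_chrom[[chrom]]
    if (is.null(centres) || length(centres) == 0) {
      rows[[chrom]] <- tibble(chrom = chrom, start = 0, end = chrom_length,
                              value = 1)
      next
    }
    win <- IRanges::reduce(IRanges::IRanges(
      start = pmax(0, centres - halo) + 1,
      end = pmin(chrom_length, centres + halo)
    ))
    tile_rows <- purrr::map(seq_along(win), function(j) {
      s <- IRanges::start(win)[j] - 1
      e <- IRanges::end(win)[j]
      starts <- seq(s, e - 1, by = step)
      ends <- pmin(starts + step, e)
      mids <- (starts + ends) / 2
      val <- 1 + colSums(amp * exp(-outer(centres, mids, "-")^2 / (2 * sd^2)))
      tibble(chrom = chrom, start = starts, end = ends, value = round(val, 4))
    })
    tiles <- bind_rows(tile_rows)
    gaps_ir <- IRanges::gaps(win, start = 1, end = chrom_length)
    gaps <- tibble(chrom = chrom, start = IRanges::start(gaps_ir) - 1,
                   end = IRanges::end(gaps_ir), value = 1)
    rows[[chrom]] <- bind_rows(tiles, gaps) |> arrange(.data$start)
  }
  bind_rows(rows)
}

#' Generate a synthetic data bundle with a truth manifest
#'
#' Writes a complete input bundle for the pipeline into `outdir`:
#' `genome.gtf`, `chrom.sizes`, `chip_peaks.narrowPeak`,
#' `clip_peaks.narrowPeak`, `h3k27ac.bedGraph`, `polII.bedGraph`,
#' `deg_kd.tsv`, `deg_pma.tsv`, per-type splicing tables
#' `as_kd_<TYPE>.tsv` / `as_pma_<TYPE>.tsv`, and `truth.json`. The same
#' seed and configuration always produce a byte-identical bundle.
#'
#' The manifest (`truth.json`, also returned) carries the planted roles
#' (target pools, peak truth, event truth) and, under `$expected`, the
#' downstream significant sets and counts implied by the written files,
#' recomputed by the generator's own bookkeeping scans. Chance-significant
#' null rows (uniform p-values below the cutoff) are part of `$expected`
#' but not of the planted pools.
#'
#' @param cfg A [sim_config()].
#' @param outdir Output directory, created if needed.
#' @return The manifest, invisibly, as a nested list.
#' @export
simulate_bundle <- function(cfg = sim_config(), outdir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(cfg$seed)

  genes <- sim_genes(cfg)
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  chrom_sizes <- setNames(rep(cfg$chrom_length, cfg$n_chroms), chroms)

  ## -- roles ---------------------------------------------------------------
  ids <- genes$gene_id
  co_reg <- sort(sample(ids, cfg$n_co_regulated))
  trans_targets <- sort(c(co_reg,
    sample(setdiff(ids, co_reg), cfg$n_trans_targets - cfg$n_co_regulated)))
  splice_targets <- sort(c(co_reg,
    sample(setdiff(ids, trans_targets),
           cfg$n_splice_targets - cfg$n_co_regulated)))

  n_shared_trans <- max(cfg$n_co_regulated,
                        round(cfg$pma_overlap_fraction * cfg$n_trans_targets))
  pma_shared_trans <- sort(c(co_reg,
    sample(setdiff(trans_targets, co_reg),
           n_shared_trans - cfg$n_co_regulated)))
  n_shared_splice <- max(cfg$n_co_regulated,
                         round(cfg$pma_overlap_fraction * cfg$n_splice_targets))
  pma_shared_splice <- sort(c(co_reg,
    sample(setdiff(splice_targets, co_reg),
           n_shared_splice - cfg$n_co_regulated)))

  non_targets <- setdiff(ids, union(trans_targets, splice_targets))
  pma_only_deg <- sort(sample(non_targets, cfg$n_pma_only_deg))
  pma_only_splice <- sort(sample(setdiff(non_targets, pma_only_deg),
                                 cfg$n_pma_only_splice))

  ## -- expression tables ---------------------------------------------------
  base_mean <- exp(rnorm(cfg$n_genes, 5, 1.2))
  kd_sign <- setNames(sample(c(-1, 1), length(trans_targets), replace = TRUE),
                      trans_targets)
  deg_kd <- tibble(gene_id = ids, base_mean = base_mean,
                   log2fc = rnorm(cfg$n_genes, 0, 0.2),
                   pvalue = runif(cfg$n_genes))
  eff <- draw_effect(length(trans_targets), cfg$effect_log2fc, cfg$noise_sd)
  ti <- match(trans_targets, ids)
  deg_kd$log2fc[ti] <- as.numeric(kd_sign) * abs(eff$value)
  deg_kd$pvalue[ti] <- eff$pvalue
  deg_kd$padj <- stats::p.adjust(deg_kd$pvalue, method = "BH")

  pma_sig_genes <- c(pma_shared_trans, pma_only_deg)
  deg_pma <- tibble(gene_id = ids, base_mean = base_mean,
                    log2fc = rnorm(cfg$n_genes, 0, 0.2),
                    pvalue = runif(cfg$n_genes))
  eff_p <- draw_effect(length(pma_sig_genes), cfg$effect_log2fc, cfg$noise_sd)
  pi_ <- match(pma_sig_genes, ids)
  pma_sign <- ifelse(pma_sig_genes %in% pma_shared_trans,
                     as.numeric(kd_sign[pma_sig_genes]),
                     sample(c(-1, 1), length(pma_sig_genes), replace = TRUE))
  deg_pma$log2fc[pi_] <- pma_sign * abs(eff_p$value)
  deg_pma$pvalue[pi_] <- eff_p$pvalue
  deg_pma$padj <- stats::p.adjust(deg_pma$pvalue, method = "BH")

  ## -- splicing tables and CLIP peaks --------------------------------------
  null_pool_kd <- sample(setdiff(ids, splice_targets),
    round(cfg$null_event_fraction * (cfg$n_genes - cfg$n_splice_targets)))
  ev_kd <- sim_events_layer(genes, splice_targets, NULL, cfg, null_pool_kd)

  shared_base <- ev_kd |> filter(.data$gene_id %in% pma_shared_splice)
  shared_from <- setNames(purrr::pmap(shared_base, function(gene_id, event_type,
      seg_start, seg_end, exon_index, delta_psi, clip_zone_start,
      clip_zone_end, clip_class, ...) {
    list(type = event_type, seg_start = seg_start, seg_end = seg_end,
         exon_index = exon_index, dpsi_sign = sign(delta_psi),
         clip_zone = c(clip_zone_start, clip_zone_end),
         clip_class = clip_class)
  }), shared_base$gene_id)
  null_pool_pma <- sample(
    setdiff(ids, c(pma_shared_splice, pma_only_splice)),
    round(cfg$null_event_fraction *
            (cfg$n_genes - n_shared_splice - cfg$n_pma_only_splice)))
  ev_pma <- sim_events_layer(genes, c(pma_shared_splice, pma_only_splice),
                             shared_from, cfg, null_pool_pma)

  # true CLIP peaks inside the planted knockdown event segments
  planted_ev <- ev_kd |> filter(.data$planted)
  clip_true <- purrr::pmap(planted_ev, function(gene_id, chrom,
      clip_zone_start, clip_zone_end, clip_class, ...) {
    w <- 60
    lo <- clip_zone_start
    hi <- max(lo + 1, clip_zone_end - w)
    s <- floor(runif(1, lo, hi))
    tibble(chrom = chrom, start = s, end = s + w, gene_id = gene_id,
           true_peak = TRUE, planted_class = clip_class)
  }) |> bind_rows()
  clip_decoy <- tibble(
    chrom = sample(chroms, cfg$n_clip_decoys, replace = TRUE),
    start = floor(runif(cfg$n_clip_decoys, 0, cfg$chrom_length - 60))
  ) |>
    mutate(end = .data$start + 60, gene_id = NA_character_,
           true_peak = FALSE, planted_class = NA_character_)
  clip_all <- bind_rows(clip_true, clip_decoy) |>
    mutate(
      name = sprintf("clip_%04d", row_number()),
      score = 0,
      strand = ".",
      fold_enrichment = if_else(.data$true_peak, cfg$clip_fc_true,
                                cfg$clip_fc_decoy),
      neg_log10_p = round(if_else(.data$true_peak, runif(n(), 4, 6),
                                  runif(n(), 0, 6)), 4),
      neg_log10_q = -1, summit = -1L, assay = "clip"
    )

  ## -- ChIP peaks ----------------------------------------------------------
  cfg_regions <- region_config()
  tgt <- genes[match(trans_targets, genes$gene_id), ]
  offset <- sample(200:800, nrow(tgt), replace = TRUE)
  chip_mid <- ifelse(tgt$strand == "-", tgt$tss + offset, tgt$tss - offset)
  chip_true <- tibble(
    chrom = tgt$chrom, start = chip_mid - 100, end = chip_mid + 100,
    gene_id = tgt$gene_id, true_peak = TRUE, planted_class = "promoter"
  )
  prom_hull <- tibble(
    chrom = tgt$chrom,
    start = ifelse(tgt$strand == "-", tgt$tss - cfg_regions$promoter_downstream,
                   tgt$tss - cfg_regions$promoter_upstream) - 200,
    end = ifelse(tgt$strand == "-", tgt$tss + cfg_regions$promoter_upstream,
                 tgt$tss + cfg_regions$promoter_downstream) + 201
  )
  n_dec <- cfg$n_chip_decoys
  dec_chrom <- character(0); dec_mid <- numeric(0)
  while (length(dec_mid) < n_dec) {
    m <- n_dec - length(dec_mid)
    cand_chrom <- sample(chroms, m * 2, replace = TRUE)
    cand_mid <- floor(runif(m * 2, 150, cfg$chrom_length - 150))
    in_prom <- purrr::map2_lgl(cand_chrom, cand_mid, function(cc, mm) {
      any(prom_hull$chrom == cc & prom_hull$start <= mm & mm < prom_hull$end)
    })
    dec_chrom <- c(dec_chrom, cand_chrom[!in_prom])
    dec_mid <- c(dec_mid, cand_mid[!in_prom])
  }
  dec_chrom <- dec_chrom[seq_len(n_dec)]
  dec_mid <- dec_mid[seq_len(n_dec)]
  chip_decoy <- tibble(chrom = dec_chrom, start = dec_mid - 100,
                       end = dec_mid + 100, gene_id = NA_character_,
                       true_peak = FALSE, planted_class = NA_character_)
  chip_all <- bind_rows(chip_true, chip_decoy) |>
    mutate(
      name = sprintf("chip_%04d", row_number()),
      score = 0, strand = ".",
      fold_enrichment = round(runif(n(), 5, 15), 3),
      neg_log10_p = round(runif(n(), 3, 6), 4),
      neg_log10_q = -1, summit = -1L, assay = "chip"
    )

  ## -- coverage tracks -----------------------------------------------------
  true_mids <- split(floor((chip_true$start + chip_true$end) / 2),
                     chip_true$chrom)
  h3k27ac <- gaussian_bump_track(chroms, cfg$chrom_length, true_mids, amp = 10)
  polii <- gaussian_bump_track(chroms, cfg$chrom_length, true_mids, amp = 6)

  ## -- write the bundle ----------------------------------------------------
  write_gtf(genes, file.path(outdir, "genome.gtf"))
  readr::write_tsv(tibble(chrom = chroms, size = cfg$chrom_length),
                   file.path(outdir, "chrom.sizes"), col_names = FALSE,
                   progress = FALSE)
  write_narrowpeak(chip_all, file.path(outdir, "chip_peaks.narrowPeak"))
  write_narrowpeak(clip_all, file.path(outdir, "clip_peaks.narrowPeak"))
  write_bedgraph(h3k27ac, file.path(outdir, "h3k27ac.bedGraph"))
  write_bedgraph(polii, file.path(outdir, "polII.bedGraph"))
  write_deg_file(deg_kd, file.path(outdir, "deg_kd.tsv"))
  write_deg_file(deg_pma, file.path(outdir, "deg_pma.tsv"))
  write_rmats_files(ev_kd, genes, outdir, "as_kd_")
  write_rmats_files(ev_pma, genes, outdir, "as_pma_")

  ## -- bookkeeping: expected downstream sets -------------------------------
  expected <- bookkeeping_expected(genes, deg_kd, deg_pma, ev_kd, ev_pma,
                                   clip_all, chip_all, cfg_regions)

  manifest <- list(
    config = unclass(cfg),
    genes = list(
      trans_targets = trans_targets,
      splice_targets = splice_targets,
      co_regulated = co_reg,
      pma_shared_trans = pma_shared_trans,
      pma_shared_splice = pma_shared_splice,
      pma_only_deg = pma_only_deg,
      pma_only_splice = pma_only_splice
    ),
    peaks = list(
      chip = chip_all |> select("name", "true_peak", "planted_class",
                                "gene_id"),
      clip = clip_all |> select("name", "true_peak", "planted_class",
                                "gene_id")
    ),
    events = list(
      kd = ev_kd |> mutate(event_id = paste0(.data$event_type, "_",
                                             .data$row_id)) |>
        select("event_id", "gene_id", "event_type", "chrom",
               start = "seg_start", end = "seg_end", "delta_psi", "pvalue",
               "fdr", "planted"),
      pma = ev_pma |> mutate(event_id = paste0(.data$event_type, "_",
                                               .data$row_id)) |>
        select("event_id", "gene_id", "event_type", "chrom",
               start = "seg_start", end = "seg_end", "delta_psi", "pvalue",
               "fdr", "planted")
    ),
    expected = expected
  )
  jsonlite::write_json(manifest, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(manifest)
}

# Independent re-derivation of the downstream sets from the generator's
# in-memory tables: plain vector scans and interval checks, no pipeline
# calls. This is the oracle against which pipeline recovery is compared.
bookkeeping_expected <- function(genes, deg_kd, deg_pma, ev_kd, ev_pma,
                                 clip_all, chip_all, cfg_regions) {
  deg_sig <- function(d) {
    keep <- d$pvalue < 0.05 & abs(d$log2fc) > 0
    tibble(gene_id = d$gene_id[keep],
           direction = ifelse(d$log2fc[keep] > 0, "up", "down"))
  }
  as_sig <- function(ev) {
    keep <- abs(ev$delta_psi) > 0.05 & ev$pvalue < 0.05 & ev$fdr < 0.1
    ev[keep, , drop = FALSE]
  }
  kd_deg <- deg_sig(deg_kd)
  pma_deg <- deg_sig(deg_pma)
  kd_as <- as_sig(ev_kd)
  pma_as <- as_sig(ev_pma)

  clip_sig <- clip_all[clip_all$neg_log10_p > 3 & clip_all$fold_enrichment > 4, ]
  # event matched iff a surviving CLIP peak shares >= 1 bp with the segment
  matched <- logical(nrow(kd_as))
  for (i in seq_len(nrow(kd_as))) {
    same <- clip_sig$chrom == kd_as$chrom[i]
    matched[i] <- any(same & clip_sig$start < kd_as$seg_end[i] &
                        kd_as$seg_start[i] < clip_sig$end)
  }
  splice_genes <- sort(unique(kd_as$gene_id[matched]))

  # bound gene: a ChIP peak midpoint within body or promoter/TTS windows
  plus <- genes$strand != "-"
  hull_start <- ifelse(plus, genes$start - cfg_regions$promoter_upstream,
                       genes$start - cfg_regions$tts_downstream)
  hull_end <- ifelse(plus, genes$end + cfg_regions$tts_downstream,
                     genes$end + cfg_regions$promoter_upstream)
  mids <- floor((chip_all$start + chip_all$end) / 2)
  bound <- purrr::map_lgl(seq_len(nrow(genes)), function(g) {
    any(chip_all$chrom == genes$chrom[g] & mids >= hull_start[g] &
          mids < hull_end[g])
  })
  chip_bound <- sort(genes$gene_id[bound])
  trans <- sort(intersect(unique(kd_deg$gene_id), chip_bound))

  kd_dir <- setNames(kd_deg$direction, kd_deg$gene_id)
  shared_deg <- intersect(unique(kd_deg$gene_id), unique(pma_deg$gene_id))
  pma_dir <- setNames(pma_deg$direction, pma_deg$gene_id)
  concordant <- shared_deg[kd_dir[shared_deg] == pma_dir[shared_deg]]
  diff_trans <- sort(intersect(trans, concordant))

  key <- function(ev) paste(ev$gene_id, ev$event_type, ev$chrom,
                            ev$seg_start, ev$seg_end)
  shared_ev <- intersect(key(kd_as), key(pma_as))
  diff_splice <- sort(unique(
    kd_as$gene_id[matched & key(kd_as) %in% shared_ev]))

  as_genes <- sort(unique(kd_as$gene_id))
  deg_genes <- sort(unique(kd_deg$gene_id))
  both <- intersect(deg_genes, as_genes)
  gene_dir <- vapply(both, function(g) {
    d <- unique(ifelse(kd_as$delta_psi[kd_as$gene_id == g] > 0,
                       "inclusion_up", "inclusion_down"))
    if (length(d) == 1) d else "mixed"
  }, character(1))
  sub_counts <- c(
    sum(kd_dir[both] == "down" & gene_dir == "inclusion_up"),
    sum(kd_dir[both] == "down" & gene_dir == "inclusion_down"),
    sum(kd_dir[both] == "up" & gene_dir == "inclusion_up"),
    sum(kd_dir[both] == "up" & gene_dir == "inclusion_down")
  )

  list(
    deg_kd_genes = deg_genes,
    deg_pma_genes = sort(unique(pma_deg$gene_id)),
    as_kd_genes = as_genes,
    as_kd_events = length(unique(key(kd_as))),
    as_pma_genes = sort(unique(pma_as$gene_id)),
    clip_sig_peaks = sort(clip_sig$name),
    chip_bound_genes = chip_bound,
    transcriptional_targets = trans,
    splicing_targets = splice_genes,
    shared_deg_genes = sort(shared_deg),
    concordant_deg_genes = sort(concordant),
    shared_event_count = length(shared_ev),
    diff_transcriptional = diff_trans,
    diff_splicing = diff_splice,
    co_regulated = sort(intersect(diff_trans, diff_splice)),
    group_counts = list(
      DEG_only = length(setdiff(deg_genes, as_genes)),
      AS_only = length(setdiff(as_genes, deg_genes)),
      Both = length(both),
      none = nrow(genes) - length(union(deg_genes, as_genes))
    ),
    subgroup_counts = as.list(setNames(sub_counts, paste0("subgroup_", 1:4)))
  )
}
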