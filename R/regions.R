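# Classification of positions and peaks into genomic region classes.
#
# Every base is assigned exactly one label by a deterministic priority:
# promoter > tts > five_prime_utr_proxy > three_prime_utr_proxy > exon >
# intron > intergenic. Ties between genes contributing the same-priority
# label are broken by lexicographic gene_id, so classification is a pure
# function of (position, annotation, config).

#' Region window configuration
#'
#' Window sizes (bp) used to derive promoter, transcription-termination-site
#' and UTR-proxy regions from a gene model. Windows are expressed relative
#' to the direction of transcription: `promoter_upstream = 1000,
#' promoter_downstream = 100` means the promoter covers -1000..+100 around
#' the TSS. Annotations without explicit UTR features get fixed-width UTR
#' proxies of `utr_proxy` bp at each transcript end; set `utr_proxy = 0` to
#' disable the UTR classes.
#'
#' @param promoter_upstream,promoter_downstream Promoter window around the
#'   TSS, bp.
#' @param tts_upstream,tts_downstream Termination-site window around the
#'   TES, bp.
#' @param utr_proxy Width of the UTR proxy at each transcript end, bp.
#' @return A list of class `region_config`.
#' @export
region_config <- function(promoter_upstream = 1000, promoter_downstream = 100,
                          tts_upstream = 100, tts_downstream = 1000,
                          utr_proxy = 200) {
  vals <- c(promoter_upstream, promoter_downstream, tts_upstream,
            tts_downstream, utr_proxy)
  if (any(vals < 0)) abort("All region windows must be >= 0")
  structure(
    list(
      promoter_upstream = promoter_upstream,
      promoter_downstream = promoter_downstream,
      tts_upstream = tts_upstream,
      tts_downstream = tts_downstream,
      utr_proxy = utr_proxy
    ),
    class = "region_config"
  )
}

# One interval per (gene, region label), 0-based half-open, start clipped at
# 0. Intron rows are the gaps between consecutive exons. Strand "." is
# treated as "+" for window orientation.
region_index <- function(genes, cfg = region_config()) {
  if (nrow(genes) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  region = character(), gene_id = character(),
                  priority = integer()))
  }
  plus <- genes$strand != "-"
  tss <- genes$tss
  tes <- genes$tes

  prom_start <- ifelse(plus, tss - cfg$promoter_upstream, tss - cfg$promoter_downstream)
  prom_end   <- ifelse(plus, tss + cfg$promoter_downstream + 1, tss + cfg$promoter_upstream + 1)
  tts_start  <- ifelse(plus, tes - cfg$tts_upstream, tes - cfg$tts_downstream)
  tts_end    <- ifelse(plus, tes + cfg$tts_downstream + 1, tes + cfg$tts_upstream + 1)

  u <- cfg$utr_proxy
  five_start  <- ifelse(plus, genes$start, pmax(genes$end - u, genes$start))
  five_end    <- ifelse(plus, pmin(genes$start + u, genes$end), genes$end)
  three_start <- ifelse(plus, pmax(genes$end - u, genes$start), genes$start)
  three_end   <- ifelse(plus, genes$end, pmin(genes$start + u, genes$end))

  windows <- bind_rows(
    tibble(chrom = genes$chrom, start = prom_start, end = prom_end,
           region = "promoter", gene_id = genes$gene_id),
    tibble(chrom = genes$chrom, start = tts_start, end = tts_end,
           region = "tts", gene_id = genes$gene_id),
    if (u > 0) tibble(chrom = genes$chrom, start = five_start, end = five_end,
                      region = "five_prime_utr_proxy", gene_id = genes$gene_id),
    if (u > 0) tibble(chrom = genes$chrom, start = three_start, end = three_end,
                      region = "three_prime_utr_proxy", gene_id = genes$gene_id)
  )

  exon_tbl <- genes |>
    select("gene_id", "chrom", "exons") |>
    tidyr::unnest("exons") |>
    mutate(region = "exon")
  intron_src <- genes |> filter(.data$n_exons > 1)
  intron_tbl <- if (nrow(intron_src) == 0) NULL else {
    intron_src |>
      select("gene_id", "chrom", "exons") |>
      mutate(gaps = purrr::map(.data$exons, function(ex) {
        tibble(start = ex$end[-nrow(ex)], end = ex$start[-1])
      })) |>
      select("gene_id", "chrom", "gaps") |>
      tidyr::unnest("gaps") |>
      filter(.data$end > .data$start) |>
      mutate(region = "intron")
  }

  idx <- bind_rows(windows, exon_tbl, intron_tbl) |>
    mutate(start = pmax(.data$start, 0)) |>
    filter(.data$end > .data$start) |>
    mutate(priority = match(.data$region, REGION_LEVELS)) |>
    select("chrom", "start", "end", "region", "gene_id", "priority") |>
    arrange(.data$chrom, .data$start, .data$priority, .data$gene_id)
  idx
}

index_granges <- function(idx, seqlevels) {
  GenomicRanges::GRanges(
    seqnames = factor(idx$chrom, levels = seqlevels),
    ranges = IRanges::IRanges(start = idx$start + 1, end = idx$end)
  )
}

#' Classify genomic positions into region classes
#'
#' Assigns each (chrom, pos) query exactly one region label and, for genic
#' labels, the owning gene. When a position falls in windows of several
#' genes or classes, the promoter > tts > 5'UTR proxy > 3'UTR proxy > exon >
#' intron priority decides, and ties between genes at equal priority go to
#' the lexicographically smaller `gene_id`. Positions in no gene and no
#' window are `intergenic` with `gene_id = NA`; positions on chromosomes
#' absent from the annotation are intergenic with a warning.
#'
#' @param positions Tibble with columns `chrom` and `pos` (0-based bp).
#' @param genes Gene-model table from [read_gtf()].
#' @param cfg A [region_config()].
#' @return `positions` with `region` and `gene_id` columns appended.
#' @export
classify_positions <- function(positions, genes, cfg = region_config()) {
  stopifnot(all(c("chrom", "pos") %in% names(positions)))
  idx <- region_index(genes, cfg)
  out <- positions |> mutate(region = "intergenic", gene_id = NA_character_)
  if (nrow(positions) == 0) return(out)
  known <- unique(genes$chrom)
  if (length(setdiff(unique(positions$chrom), known)) > 0 && nrow(genes) > 0) {
    warn("Positions on chromosomes absent from the annotation were classified as intergenic")
  }
  if (nrow(idx) == 0) return(out)
  seqlevels <- union(known, unique(positions$chrom))
  q <- GenomicRanges::GRanges(
    seqnames = factor(positions$chrom, levels = seqlevels),
    ranges = IRanges::IRanges(start = positions$pos + 1, width = 1)
  )
  hits <- GenomicRanges::findOverlaps(q, index_granges(idx, seqlevels))
  if (length(hits) > 0) {
    h <- tibble(
      q = S4Vectors::queryHits(hits),
      priority = idx$priority[S4Vectors::subjectHits(hits)],
      region = idx$region[S4Vectors::subjectHits(hits)],
      gene_id = idx$gene_id[S4Vectors::subjectHits(hits)]
    ) |>
      arrange(.data$q, .data$priority, .data$gene_id) |>
      distinct(.data$q, .keep_all = TRUE)
    out$region[h$q] <- h$region
    out$gene_id[h$q] <- h$gene_id
  }
  out
}

#' Classify peaks into region classes by their midpoint
#'
#' A peak is assigned the label of its midpoint, `floor((start + end) / 2)`,
#' so each peak gets exactly one label and region percentages over a peak
#' set sum to 100.
#'
#' @param peaks Peak tibble with `chrom`, `start`, `end` (plus any other
#'   columns, preserved).
#' @inheritParams classify_positions
#' @return `peaks` with `midpoint`, `region` and `gene_id` columns appended.
#' @export
classify_peaks <- function(peaks, genes, cfg = region_config()) {
  mid <- floor((peaks$start + peaks$end) / 2)
  cls <- classify_positions(tibble(chrom = peaks$chrom, pos = mid), genes, cfg)
  peaks |> mutate(midpoint = mid, region = cls$region, gene_id = cls$gene_id)
}

# Strand-aware extents of the "bound" hull: gene body plus promoter and TTS
# windows, which are contiguous with the body.
binding_hull <- function(genes, cfg) {
  plus <- genes$strand != "-"
  tibble(
    chrom = genes$chrom,
    gene_id = genes$gene_id,
    start = pmax(0, ifelse(plus, genes$start - cfg$promoter_upstream,
                           genes$start - cfg$tts_downstream)),
    end = ifelse(plus, genes$end + cfg$tts_downstream,
                 genes$end + cfg$promoter_upstream)
  )
}

#' Assign each peak to its nearest gene
#'
#' Distance is 0 when the peak midpoint lies within the gene body or its
#' promoter/TTS windows; otherwise it is the signed midpoint-to-TSS
#' distance, negative upstream of the TSS in the direction of transcription.
#' Ties go to the lexicographically smaller `gene_id`. Peaks on chromosomes
#' with no gene get `gene_id = NA` and infinite distance.
#'
#' @inheritParams classify_peaks
#' @return `peaks` with `midpoint`, `gene_id` and `distance` columns
#'   appended.
#' @export
nearest_gene <- function(peaks, genes, cfg = region_config()) {
  mid <- floor((peaks$start + peaks$end) / 2)
  n <- nrow(peaks)
  gene_id <- rep(NA_character_, n)
  distance <- rep(Inf, n)
  if (n > 0 && nrow(genes) > 0) {
    hull <- binding_hull(genes, cfg)
    by_chrom <- split(seq_len(nrow(genes)), genes$chrom)
    for (i in seq_len(n)) {
      gi <- by_chrom[[peaks$chrom[i]]]
      if (is.null(gi)) next
      inside <- gi[hull$start[gi] <= mid[i] & mid[i] < hull$end[gi]]
      if (length(inside)) {
        gene_id[i] <- min(genes$gene_id[inside])
        distance[i] <- 0
      } else {
        plus <- genes$strand[gi] != "-"
        d <- ifelse(plus, mid[i] - genes$tss[gi], genes$tss[gi] - mid[i])
        ord <- order(abs(d), genes$gene_id[gi])[1]
        gene_id[i] <- genes$gene_id[gi][ord]
        distance[i] <- d[ord]
      }
    }
  }
  peaks |> mutate(midpoint = mid, gene_id = gene_id, distance = distance)
}

#' Genome-wide region composition
#'
#' Exact per-base accounting of how much of the genome each region class
#' covers under the priority scheme, by interval arithmetic (no sampling).
#' The returned fractions sum to 1.
#'
#' @inheritParams classify_positions
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp),
#'   covering every chromosome in the annotation.
#' @return Tibble with columns `region`, `bp`, `fraction`, one row per
#'   region class in priority order.
#' @export
genome_region_composition <- function(genes, chrom_sizes,
                                      cfg = region_config()) {
  missing_chroms <- setdiff(unique(genes$chrom), names(chrom_sizes))
  if (length(missing_chroms)) {
    abort(paste0("Annotation chromosomes absent from chrom_sizes: ",
                 paste(missing_chroms, collapse = ", ")))
  }
  if (nrow(genes) > 0 &&
      any(genes$end > chrom_sizes[genes$chrom] | genes$start < 0)) {
    abort("Gene interval outside chromosome bounds")
  }
  idx <- region_index(genes, cfg)
  total <- sum(chrom_sizes)
  bp <- setNames(numeric(length(REGION_LEVELS)), REGION_LEVELS)
  for (chrom in names(chrom_sizes)) {
    L <- chrom_sizes[[chrom]]
    sub <- idx[idx$chrom == chrom, ]
    claimed <- IRanges::IRanges()
    for (label in setdiff(REGION_LEVELS, "intergenic")) {
      rows <- sub[sub$region == label, ]
      if (nrow(rows) == 0) next
      ir <- IRanges::reduce(IRanges::IRanges(
        start = pmax(rows$start, 0) + 1,
        end = pmin(rows$end, L)
      ))
      free <- IRanges::setdiff(ir, claimed)
      bp[label] <- bp[label] + sum(IRanges::width(free))
      claimed <- IRanges::union(claimed, free)
    }
    bp["intergenic"] <- bp["intergenic"] + L - sum(IRanges::width(claimed))
  }
  tibble(region = REGION_LEVELS, bp = as.numeric(bp),
         fraction = as.numeric(bp) / total)
}
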