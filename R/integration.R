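# Combining the filtered evidence layers: gene classification into
# expression/splicing groups, ChIP- and CLIP-derived direct-target sets,
# knockdown-vs-differentiation overlaps, co-occupancy (Jaccard) statistics,
# ChIP-CLIP peak distance profiles, and the final co-regulated gene list.

as_direction_per_gene <- function(as_sig) {
  if (nrow(as_sig) == 0) {
    return(tibble(gene_id = character(), as_direction = character()))
  }
  as_sig |>
    group_by(.data$gene_id) |>
    summarise(as_direction = {
      d <- unique(.data$direction)
      if (length(d) == 1) d else "mixed"
    }, .groups = "drop")
}

SUBGROUP_MAP <- data.frame(
  deg_direction = c("down", "down", "up", "up"),
  as_direction = c("inclusion_up", "inclusion_down",
                   "inclusion_up", "inclusion_down"),
  subgroup = 1:4
)

#' Classify genes by expression and splicing evidence
#'
#' Partitions genes into the four groups `DEG_only` (differentially
#' expressed, no significant splicing change), `AS_only` (spliced, not
#' differentially expressed), `Both`, and `none`. Genes in `Both` whose
#' splicing events all share one inclusion direction get a subgroup 1-4:
#' 1 = down-regulated with increased inclusion, 2 = down-regulated with
#' decreased inclusion, 3 = up-regulated with increased inclusion, 4 =
#' up-regulated with decreased inclusion. Genes with significant events of
#' both inclusion signs are `mixed` and get no subgroup.
#'
#' @param deg_sig Filtered expression table from [filter_deg()] (one row
#'   per gene; the first row wins if a gene is duplicated).
#' @param as_sig Filtered splicing events from [filter_as()].
#' @param universe Character vector of all annotated gene ids.
#' @return Tibble with one row per gene in the union of `universe` and the
#'   evidence layers: `gene_id`, `group`, `subgroup`, `deg_direction`,
#'   `as_direction`.
#' @export
classify_genes <- function(deg_sig, as_sig, universe) {
  deg_genes <- deg_sig |> distinct(.data$gene_id, .keep_all = TRUE)
  extra <- setdiff(deg_genes$gene_id, universe)
  if (length(extra)) {
    warn(paste0(length(extra),
                " differentially expressed gene(s) absent from the universe; retained"))
  }
  as_dir <- as_direction_per_gene(as_sig)
  all_genes <- sort(unique(c(universe, deg_genes$gene_id, as_dir$gene_id)))
  tibble(gene_id = all_genes) |>
    left_join(deg_genes |> select("gene_id", deg_direction = "direction"),
              by = "gene_id") |>
    left_join(as_dir, by = "gene_id") |>
    mutate(
      deg_direction = coalesce(.data$deg_direction, "none"),
      as_direction = coalesce(.data$as_direction, "none"),
      group = case_when(
        .data$deg_direction != "none" & .data$as_direction != "none" ~ "Both",
        .data$deg_direction != "none" ~ "DEG_only",
        .data$as_direction != "none" ~ "AS_only",
        TRUE ~ "none"
      )
    ) |>
    left_join(SUBGROUP_MAP, by = c("deg_direction", "as_direction")) |>
    mutate(subgroup = if_else(.data$group == "Both", .data$subgroup,
                              NA_integer_)) |>
    select("gene_id", "group", "subgroup", "deg_direction", "as_direction")
}

#' Genes bound by at least one peak
#'
#' A gene counts as bound when a peak midpoint lies in its gene body or
#' promoter/TTS window ([nearest_gene()] distance 0). An optional region
#' whitelist (e.g. `c("promoter")`) restricts the evidence to peaks whose
#' midpoint region class is listed.
#'
#' @inheritParams classify_peaks
#' @param regions Optional character vector of region classes to accept as
#'   binding evidence; `NULL` accepts any distance-0 peak.
#' @return Sorted character vector of bound gene ids.
#' @export
bound_genes <- function(peaks, genes, cfg = region_config(), regions = NULL) {
  if (nrow(peaks) == 0) return(character())
  if (!is.null(regions)) {
    labelled <- classify_peaks(peaks, genes, cfg)
    peaks <- peaks[labelled$region %in% regions, , drop = FALSE]
    if (nrow(peaks) == 0) return(character())
  }
  assigned <- nearest_gene(peaks, genes, cfg)
  sort(unique(assigned$gene_id[assigned$distance == 0 &
                                 !is.na(assigned$gene_id)]))
}

#' Transcriptional target genes (differential expression and ChIP binding)
#'
#' Intersects the significant differentially expressed genes with the
#' ChIP-bound genes.
#'
#' @inheritParams classify_genes
#' @param chip_peaks ChIP peak tibble.
#' @inheritParams bound_genes
#' @return Sorted character vector of gene ids.
#' @export
transcriptional_targets <- function(deg_sig, chip_peaks, genes,
                                    cfg = region_config(), regions = NULL) {
  sort(intersect(unique(deg_sig$gene_id),
                 bound_genes(chip_peaks, genes, cfg, regions)))
}

#' Splicing target genes (differential splicing and CLIP binding)
#'
#' Matches each significant splicing event against the significant CLIP
#' peaks: an event is matched when a peak shares at least 1 bp with the
#' event's alternative segment extended by `window` bp on each side
#' (half-open arithmetic, so a peak starting exactly at the segment end
#' does not match at `window = 0`).
#'
#' @param as_sig Filtered splicing events from [filter_as()].
#' @param clip_sig Filtered CLIP peaks from [filter_clip_peaks()].
#' @param window Extension of the event segment on each side, bp.
#' @return A list with `events` (the matched event rows, with an
#'   `n_clip_peaks` column) and `gene_ids` (sorted distinct genes of the
#'   matched events).
#' @export
splicing_targets <- function(as_sig, clip_sig, window = 0) {
  if (nrow(as_sig) == 0 || nrow(clip_sig) == 0) {
    return(list(events = as_sig[0, , drop = FALSE], gene_ids = character()))
  }
  seqlevels <- union(unique(as_sig$chrom), unique(clip_sig$chrom))
  ev <- GenomicRanges::GRanges(
    seqnames = factor(as_sig$chrom, levels = seqlevels),
    ranges = IRanges::IRanges(start = pmax(0, as_sig$start - window) + 1,
                              end = as_sig$end + window)
  )
  pk <- GenomicRanges::GRanges(
    seqnames = factor(clip_sig$chrom, levels = seqlevels),
    ranges = IRanges::IRanges(start = clip_sig$start + 1, end = clip_sig$end)
  )
  hits <- GenomicRanges::findOverlaps(ev, pk, minoverlap = 1)
  n_hits <- tabulate(S4Vectors::queryHits(hits), nbins = nrow(as_sig))
  matched <- as_sig[n_hits > 0, , drop = FALSE] |>
    mutate(n_clip_peaks = n_hits[n_hits > 0])
  list(events = matched, gene_ids = sort(unique(matched$gene_id)))
}

#' Overlap of knockdown and differentiation layers
#'
#' In `"genes"` mode, intersects two filtered differential-expression
#' layers by gene and labels each shared gene concordant (same log2FC sign
#' in both contrasts) or discordant. In `"events"` mode, intersects two
#' filtered splicing layers keyed by (gene, event type, segment interval)
#' exact match, with concordance on the dPSI sign.
#'
#' @param kd_layer,pma_layer Filtered tables from [filter_deg()] (genes
#'   mode) or [filter_as()] (events mode).
#' @param mode `"genes"` or `"events"`.
#' @return Tibble of the shared records with per-contrast effect columns
#'   and a logical `concordant`.
#' @export
differentiation_overlap <- function(kd_layer, pma_layer,
                                    mode = c("genes", "events")) {
  mode <- match.arg(mode)
  if (mode == "genes") {
    kd <- kd_layer |> distinct(.data$gene_id, .keep_all = TRUE)
    pma <- pma_layer |> distinct(.data$gene_id, .keep_all = TRUE)
    inner_join(
      kd |> select("gene_id", log2fc_kd = "log2fc"),
      pma |> select("gene_id", log2fc_pma = "log2fc"),
      by = "gene_id"
    ) |>
      mutate(concordant = sign(.data$log2fc_kd) == sign(.data$log2fc_pma))
  } else {
    key <- c("gene_id", "event_type", "chrom", "start", "end")
    inner_join(
      kd_layer |> select(all_of(key), event_id_kd = "event_id",
                         delta_psi_kd = "delta_psi"),
      pma_layer |> select(all_of(key), event_id_pma = "event_id",
                          delta_psi_pma = "delta_psi"),
      by = key
    ) |>
      mutate(concordant = sign(.data$delta_psi_kd) == sign(.data$delta_psi_pma))
  }
}

#' Jaccard index of two gene sets
#'
#' `|A intersect B| / |A union B|`; defined as 0 when both sets are empty.
#'
#' @param set_a,set_b Character vectors (duplicates ignored).
#' @return Numeric scalar in \[0, 1\].
#' @export
jaccard <- function(set_a, set_b) {
  u <- length(union(set_a, set_b))
  if (u == 0) return(0)
  length(intersect(set_a, set_b)) / u
}

#' Assemble the full target-set hierarchy
#'
#' Builds, from the filtered layers of both contrasts, the transcriptional
#' targets (knockdown DEGs that are ChIP-bound), the splicing targets
#' (knockdown splicing events overlapped by significant CLIP peaks,
#' collapsed to genes), their restrictions to the differentiation contrast
#' (transcriptional targets whose gene is a concordant shared DEG; splicing
#' targets whose matched event is also a shared differential splicing
#' event), and the final co-regulated set, the intersection of the two
#' restricted sets.
#'
#' @param deg_kd_sig,deg_pma_sig Filtered expression tables for the
#'   knockdown and differentiation contrasts.
#' @param as_kd_sig,as_pma_sig Filtered splicing events for the two
#'   contrasts; `as_pma_sig` may be `NULL` to skip the differentiation
#'   restriction on the splicing side.
#' @param chip_peaks ChIP peaks; `clip_sig` filtered CLIP peaks.
#' @inheritParams classify_positions
#' @inheritParams bound_genes
#' @inheritParams splicing_targets
#' @return A list of class `target_sets`: gene-id vectors
#'   `transcriptional`, `splicing`, `diff_transcriptional`,
#'   `diff_splicing`, `co_regulated`, plus evidence tables
#'   `splicing_events`, `shared_deg`, `shared_events`.
#' @export
target_sets <- function(deg_kd_sig, as_kd_sig, chip_peaks, clip_sig, genes,
                        deg_pma_sig = NULL, as_pma_sig = NULL,
                        cfg = region_config(), regions = NULL, window = 0) {
  transcriptional <- transcriptional_targets(deg_kd_sig, chip_peaks, genes,
                                             cfg, regions)
  splice <- splicing_targets(as_kd_sig, clip_sig, window)

  shared_deg <- if (!is.null(deg_pma_sig)) {
    differentiation_overlap(deg_kd_sig, deg_pma_sig, "genes")
  } else NULL
  diff_transcriptional <- if (!is.null(shared_deg)) {
    sort(intersect(transcriptional,
                   shared_deg$gene_id[shared_deg$concordant]))
  } else character()

  shared_events <- if (!is.null(as_pma_sig)) {
    differentiation_overlap(as_kd_sig, as_pma_sig, "events")
  } else NULL
  diff_splicing <- if (!is.null(shared_events) && nrow(splice$events) > 0) {
    shared_matched <- semi_join(
      splice$events, shared_events,
      by = c("gene_id", "event_type", "chrom", "start", "end")
    )
    sort(unique(shared_matched$gene_id))
  } else character()

  structure(
    list(
      transcriptional = transcriptional,
      splicing = splice$gene_ids,
      diff_transcriptional = diff_transcriptional,
      diff_splicing = diff_splicing,
      co_regulated = sort(intersect(diff_transcriptional, diff_splicing)),
      splicing_events = splice$events,
      shared_deg = shared_deg,
      shared_events = shared_events
    ),
    class = "target_sets"
  )
}

#' Co-regulated genes with their supporting evidence
#'
#' The intersection of the differentiation-restricted transcriptional and
#' splicing target sets, emitted with the evidence rows backing each gene.
#'
#' @param ts A [target_sets()] object.
#' @param deg_kd_sig,deg_pma_sig Filtered expression tables (optional, for
#'   evidence columns).
#' @return Tibble with one row per co-regulated gene: `gene_id`, the
#'   knockdown and differentiation log2 fold changes when supplied, and the
#'   number of matched splicing events.
#' @export
co_regulated_genes <- function(ts, deg_kd_sig = NULL, deg_pma_sig = NULL) {
  stopifnot(inherits(ts, "target_sets"))
  out <- tibble(gene_id = ts$co_regulated)
  if (!is.null(deg_kd_sig)) {
    out <- left_join(out,
                     deg_kd_sig |> distinct(.data$gene_id, .keep_all = TRUE) |>
                       select("gene_id", log2fc_kd = "log2fc"),
                     by = "gene_id")
  }
  if (!is.null(deg_pma_sig)) {
    out <- left_join(out,
                     deg_pma_sig |> distinct(.data$gene_id, .keep_all = TRUE) |>
                       select("gene_id", log2fc_pma = "log2fc"),
                     by = "gene_id")
  }
  if (nrow(ts$splicing_events) > 0) {
    ev_count <- ts$splicing_events |> count(.data$gene_id, name = "n_events")
    out <- left_join(out, ev_count, by = "gene_id")
  }
  out
}

DISTANCE_BINS <- c("overlap", "lt_5kb", "kb5_10", "gt_10kb")

#' ChIP-to-CLIP peak distance profile
#'
#' For each ChIP peak, finds the nearest CLIP peak on the same chromosome
#' and bins the edge-to-edge gap: `overlap` (at least 1 shared bp),
#' `lt_5kb` (gap of 0-5000 bp, including half-open adjacency), `kb5_10`
#' (5-10 kb) and `gt_10kb` (beyond 10 kb, including ChIP peaks whose
#' chromosome carries no CLIP peak). An optional `gene_subset` restricts
#' both peak sets to peaks bound to those genes (distance 0 under
#' [nearest_gene()]).
#'
#' @param chip_peaks,clip_peaks Peak tibbles; `chip_peaks` must be
#'   non-empty after any restriction.
#' @param gene_subset Optional character vector of gene ids.
#' @param genes,cfg Annotation and region config; required when
#'   `gene_subset` is used.
#' @return Tibble of class `distance_profile` with columns `bin`, `count`,
#'   `fraction`; fractions sum to 1 over the ChIP peaks.
#' @export
chip_clip_distance_profile <- function(chip_peaks, clip_peaks,
                                       gene_subset = NULL, genes = NULL,
                                       cfg = region_config()) {
  if (!is.null(gene_subset)) {
    if (is.null(genes)) abort("gene_subset restriction requires `genes`")
    restrict <- function(p) {
      a <- nearest_gene(p, genes, cfg)
      p[a$distance == 0 & a$gene_id %in% gene_subset, , drop = FALSE]
    }
    chip_peaks <- restrict(chip_peaks)
    clip_peaks <- restrict(clip_peaks)
  }
  if (nrow(chip_peaks) == 0) {
    abort("Distance profile undefined for an empty ChIP peak set")
  }
  bin <- rep("gt_10kb", nrow(chip_peaks))
  if (nrow(clip_peaks) > 0) {
    seqlevels <- union(unique(chip_peaks$chrom), unique(clip_peaks$chrom))
    gr_chip <- GenomicRanges::GRanges(
      seqnames = factor(chip_peaks$chrom, levels = seqlevels),
      ranges = IRanges::IRanges(start = chip_peaks$start + 1,
                                end = chip_peaks$end)
    )
    gr_clip <- GenomicRanges::GRanges(
      seqnames = factor(clip_peaks$chrom, levels = seqlevels),
      ranges = IRanges::IRanges(start = clip_peaks$start + 1,
                                end = clip_peaks$end)
    )
    ov <- GenomicRanges::findOverlaps(gr_chip, gr_clip, minoverlap = 1)
    overlapping <- unique(S4Vectors::queryHits(ov))
    d2n <- GenomicRanges::distanceToNearest(gr_chip, gr_clip)
    gap <- rep(NA_real_, nrow(chip_peaks))
    gap[S4Vectors::queryHits(d2n)] <- S4Vectors::mcols(d2n)$distance
    bin <- case_when(
      seq_along(bin) %in% overlapping ~ "overlap",
      is.na(gap) ~ "gt_10kb",
      gap <= 5000 ~ "lt_5kb",
      gap <= 10000 ~ "kb5_10",
      TRUE ~ "gt_10kb"
    )
  }
  counts <- table(factor(bin, levels = DISTANCE_BINS))
  res <- tibble(
    bin = DISTANCE_BINS,
    count = as.integer(counts),
    fraction = as.integer(counts) / nrow(chip_peaks)
  )
  new_result(res, "distance_profile")
}
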