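# End-to-end run over a bundle directory: read every layer, apply the
# significance filters, and assemble every statistic the integration
# computes into one report object. The reporter only collects module
# outputs; it does no arithmetic of its own beyond formatting.

BUNDLE_FILES <- list(
  gtf = "genome.gtf", chrom_sizes = "chrom.sizes",
  chip = "chip_peaks.narrowPeak", clip = "clip_peaks.narrowPeak",
  h3k27ac = "h3k27ac.bedGraph", polii = "polII.bedGraph",
  deg_kd = "deg_kd.tsv", deg_pma = "deg_pma.tsv"
)

#' Run the full integration pipeline over a bundle directory
#'
#' Expects the file layout written by [simulate_bundle()]: annotation and
#' chromosome sizes, ChIP and CLIP narrowPeak files, coverage tracks, and
#' expression/splicing tables for the knockdown contrast and (optionally)
#' the differentiation contrast. Missing optional layers degrade
#' gracefully: without CLIP peaks the splicing-target sections are `NULL`,
#' without the differentiation tables the co-regulation sections are
#' `NULL`.
#'
#' @param dir Bundle directory.
#' @param thresholds A [filter_thresholds()].
#' @param cfg A [region_config()].
#' @param window Event-to-peak matching window, bp (see
#'   [splicing_targets()]).
#' @param regions Optional region whitelist for ChIP binding evidence (see
#'   [bound_genes()]).
#' @return A list of class `coreg_report`; see [write_report()] for the
#'   serialized layout.
#' @export
run_integration <- function(dir, thresholds = filter_thresholds(),
                            cfg = region_config(), window = 0,
                            regions = NULL) {
  path <- function(key) file.path(dir, BUNDLE_FILES[[key]])
  has <- function(key) file.exists(path(key))
  if (!has("gtf") || !has("chrom_sizes")) {
    abort(paste0("Bundle at ", dir, " must contain ", BUNDLE_FILES$gtf,
                 " and ", BUNDLE_FILES$chrom_sizes))
  }
  genes <- read_gtf(path("gtf"))
  chrom_sizes <- read_chrom_sizes(path("chrom_sizes"))

  deg_kd <- read_deg_table(path("deg_kd"))
  as_kd <- read_rmats_bundle(dir, "as_kd_")
  chip <- if (has("chip")) read_narrowpeak(path("chip"), "chip") else NULL
  clip <- if (has("clip")) read_narrowpeak(path("clip"), "clip") else NULL
  deg_pma <- if (has("deg_pma")) read_deg_table(path("deg_pma")) else NULL
  as_pma <- if (file.exists(file.path(dir, "as_pma_SE.tsv"))) {
    read_rmats_bundle(dir, "as_pma_")
  } else NULL

  deg_kd_sig <- filter_deg(deg_kd, thresholds)
  as_kd_sig <- filter_as(as_kd, thresholds)
  deg_pma_sig <- if (!is.null(deg_pma)) filter_deg(deg_pma, thresholds)
  as_pma_sig <- if (!is.null(as_pma)) filter_as(as_pma, thresholds)
  clip_sig <- if (!is.null(clip)) filter_clip_peaks(clip, thresholds)

  composition <- genome_region_composition(genes, chrom_sizes, cfg)
  chip_enrich <- if (!is.null(chip) && nrow(chip) > 0) {
    region_enrichment(chip, genes, chrom_sizes, cfg)
  }
  clip_enrich <- if (!is.null(clip_sig) && nrow(clip_sig) > 0) {
    clip_region_enrichment(clip_sig, genes, cfg)
  }

  profiles <- list()
  if (!is.null(chip) && nrow(chip) > 0) {
    for (key in c("h3k27ac", "polii")) {
      if (has(key)) {
        profiles[[key]] <- metaprofile(chip, read_bedgraph(path(key)))
      }
    }
  }

  classification <- classify_genes(deg_kd_sig, as_kd_sig, genes$gene_id)
  group_counts <- classification |> count(.data$group, name = "n")
  subgroup_counts <- classification |>
    filter(!is.na(.data$subgroup)) |>
    count(.data$subgroup, name = "n")

  ts <- if (!is.null(chip) && !is.null(clip_sig)) {
    target_sets(deg_kd_sig, as_kd_sig, chip, clip_sig, genes,
                deg_pma_sig, as_pma_sig, cfg, regions, window)
  } else NULL

  jaccard_by_group <- distance_by_group <- NULL
  if (!is.null(chip) && !is.null(clip_sig)) {
    chip_genes_all <- bound_genes(chip, genes, cfg)
    clip_genes_all <- bound_genes(clip_sig, genes, cfg)
    groups <- list(
      Total = classification$gene_id,
      DEG_only = classification$gene_id[classification$group == "DEG_only"],
      AS_only = classification$gene_id[classification$group == "AS_only"],
      Both = classification$gene_id[classification$group == "Both"]
    )
    jaccard_by_group <- purrr::imap(groups, function(g, nm) {
      a <- intersect(chip_genes_all, g)
      b <- intersect(clip_genes_all, g)
      tibble(group = nm, n_chip_genes = length(a), n_clip_genes = length(b),
             n_co_occupied = length(intersect(a, b)),
             jaccard = jaccard(a, b))
    }) |> bind_rows()
    distance_by_group <- purrr::imap(groups, function(g, nm) {
      prof <- tryCatch(
        chip_clip_distance_profile(chip, clip_sig, gene_subset = g,
                                   genes = genes, cfg = cfg),
        error = function(e) NULL
      )
      if (is.null(prof)) return(NULL)
      prof |> mutate(group = nm, .before = 1)
    }) |> bind_rows()
  }

  structure(list(
    dir = dir,
    thresholds = thresholds,
    region_config = cfg,
    n_genes = nrow(genes),
    counts = list(
      deg_kd_total = nrow(deg_kd), deg_kd_sig = nrow(deg_kd_sig),
      deg_kd_up = sum(deg_kd_sig$direction == "up"),
      deg_kd_down = sum(deg_kd_sig$direction == "down"),
      as_kd_total = nrow(as_kd), as_kd_sig = nrow(as_kd_sig),
      as_kd_sig_genes = length(unique(as_kd_sig$gene_id)),
      deg_pma_sig = if (!is.null(deg_pma_sig)) nrow(deg_pma_sig),
      as_pma_sig = if (!is.null(as_pma_sig)) nrow(as_pma_sig),
      as_pma_sig_genes = if (!is.null(as_pma_sig)) {
        length(unique(as_pma_sig$gene_id))
      },
      chip_peaks = if (!is.null(chip)) nrow(chip),
      clip_peaks_total = if (!is.null(clip)) nrow(clip),
      clip_peaks_sig = if (!is.null(clip_sig)) nrow(clip_sig)
    ),
    region_composition = composition,
    chip_region_enrichment = chip_enrich,
    clip_region_enrichment = clip_enrich,
    metaprofiles = profiles,
    classification = classification,
    group_counts = group_counts,
    subgroup_counts = subgroup_counts,
    jaccard_by_group = jaccard_by_group,
    distance_by_group = distance_by_group,
    target_sets = ts,
    co_regulated = if (!is.null(ts)) {
      co_regulated_genes(ts, deg_kd_sig, deg_pma_sig)
    },
    deg_kd_sig = deg_kd_sig,
    as_kd_sig = as_kd_sig,
    deg_pma_sig = deg_pma_sig,
    as_pma_sig = as_pma_sig,
    clip_sig = clip_sig
  ), class = "coreg_report")
}

#' @export
print.coreg_report <- function(x, ...) {
  cat("<coreg_report>\n")
  cat("  genes:", x$n_genes, "\n")
  cat("  significant DEGs (knockdown):", x$counts$deg_kd_sig,
      sprintf("(%d up / %d down)\n", x$counts$deg_kd_up, x$counts$deg_kd_down))
  cat("  significant splicing events (knockdown):", x$counts$as_kd_sig,
      "in", x$counts$as_kd_sig_genes, "genes\n")
  if (!is.null(x$target_sets)) {
    cat("  transcriptional targets:", length(x$target_sets$transcriptional), "\n")
    cat("  splicing targets:", length(x$target_sets$splicing), "\n")
    cat("  co-regulated genes:", length(x$target_sets$co_regulated), "\n")
  }
  invisible(x)
}

report_json_payload <- function(report) {
  ts <- report$target_sets
  list(
    counts = report$counts,
    region_composition = report$region_composition,
    chip_region_enrichment = report$chip_region_enrichment,
    clip_region_enrichment = report$clip_region_enrichment,
    metaprofiles = purrr::map(report$metaprofiles, function(p) {
      list(n_anchors = attr(p, "n_anchors"), offset = p$offset,
           mean_depth = p$mean_depth)
    }),
    group_counts = report$group_counts,
    subgroup_counts = report$subgroup_counts,
    jaccard_by_group = report$jaccard_by_group,
    distance_by_group = report$distance_by_group,
    target_sets = if (!is.null(ts)) {
      list(
        transcriptional = ts$transcriptional,
        splicing = ts$splicing,
        diff_transcriptional = ts$diff_transcriptional,
        diff_splicing = ts$diff_splicing,
        co_regulated = ts$co_regulated
      )
    } else "empty"
  )
}

#' Serialize a pipeline report to disk
#'
#' Writes `report.json` (every statistic in the report, nested by section)
#' plus per-section TSVs, plain-text gene lists (one id per line) for each
#' target set, and a BED6 file of the CLIP-matched splicing event segments.
#' Output is a pure function of the report: two identical runs produce
#' byte-identical files.
#'
#' @param report A `coreg_report` from [run_integration()].
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "coreg_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report_json_payload(report),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, null = "null",
                       pretty = TRUE)
  tsvs <- list(
    region_composition = report$region_composition,
    chip_region_enrichment = report$chip_region_enrichment,
    clip_region_enrichment = report$clip_region_enrichment,
    classification = report$classification,
    jaccard_by_group = report$jaccard_by_group,
    distance_by_group = report$distance_by_group,
    co_regulated = report$co_regulated
  )
  for (nm in names(tsvs)) {
    if (!is.null(tsvs[[nm]])) {
      readr::write_tsv(tsvs[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       progress = FALSE)
    }
  }
  ts <- report$target_sets
  if (!is.null(ts)) {
    for (nm in c("transcriptional", "splicing", "diff_transcriptional",
                 "diff_splicing", "co_regulated")) {
      readr::write_lines(ts[[nm]], file.path(dir, paste0("genes_", nm, ".txt")))
    }
    if (nrow(ts$splicing_events) > 0) {
      write_bed6(ts$splicing_events |>
                   mutate(name = .data$event_id, score = 0),
                 file.path(dir, "matched_events.bed"))
    }
  }
  invisible(dir)
}

#' Validate a bundle directory
#'
#' Attempts to parse every recognized file in the bundle and reports, per
#' file, whether it parsed, its row count, and the first error message if
#' not.
#'
#' @param dir Bundle directory.
#' @return Tibble with columns `file`, `present`, `ok`, `n_rows`, `error`.
#' @export
validate_bundle <- function(dir) {
  readers <- list(
    genome.gtf = function(p) nrow(read_gtf(p)),
    chrom.sizes = function(p) length(read_chrom_sizes(p)),
    chip_peaks.narrowPeak = function(p) nrow(read_narrowpeak(p, "chip")),
    clip_peaks.narrowPeak = function(p) nrow(read_narrowpeak(p, "clip")),
    h3k27ac.bedGraph = function(p) nrow(read_bedgraph(p)),
    polII.bedGraph = function(p) nrow(read_bedgraph(p)),
    deg_kd.tsv = function(p) nrow(read_deg_table(p)),
    deg_pma.tsv = function(p) nrow(read_deg_table(p))
  )
  for (tt in EVENT_TYPES) {
    for (stem in c("as_kd_", "as_pma_")) {
      f <- paste0(stem, tt, ".tsv")
      local({
        tt_ <- tt
        readers[[f]] <<- function(p) nrow(read_rmats_table(p, tt_))
      })
    }
  }
  purrr::imap(readers, function(fn, file) {
    p <- file.path(dir, file)
    if (!file.exists(p)) {
      return(tibble(file = file, present = FALSE, ok = NA, n_rows = NA_integer_,
                    error = NA_character_))
    }
    res <- tryCatch(
      tibble(file = file, present = TRUE, ok = TRUE,
             n_rows = as.integer(fn(p)), error = NA_character_),
      error = function(e) tibble(file = file, present = TRUE, ok = FALSE,
                                 n_rows = NA_integer_,
                                 error = conditionMessage(e))
    )
    res
  }) |> bind_rows()
}

#' Tidy a pipeline report into a per-gene table
#'
#' Broom-style `tidy()` method: one row per gene, with its
#' expression/splicing group, subgroup and directions, plus logical
#' membership flags for each target set.
#'
#' @param x A `coreg_report`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.coreg_report <- function(x, ...) {
  out <- x$classification
  ts <- x$target_sets
  if (!is.null(ts)) {
    out <- out |>
      mutate(
        transcriptional_target = .data$gene_id %in% ts$transcriptional,
        splicing_target = .data$gene_id %in% ts$splicing,
        co_regulated = .data$gene_id %in% ts$co_regulated
      )
  }
  out
}

#' One-row summary of a pipeline report
#'
#' Broom-style `glance()` method: filter survivor counts, group sizes and
#' target-set sizes in one row.
#'
#' @inheritParams tidy.coreg_report
#' @return A one-row tibble.
#' @export
glance.coreg_report <- function(x, ...) {
  gc <- setNames(as.list(x$group_counts$n),
                 paste0("n_", x$group_counts$group))
  ts <- x$target_sets
  as_tibble(c(
    list(
      n_genes = x$n_genes,
      n_deg_sig = x$counts$deg_kd_sig,
      n_as_sig_events = x$counts$as_kd_sig,
      n_as_sig_genes = x$counts$as_kd_sig_genes
    ),
    gc,
    if (!is.null(ts)) list(
      n_transcriptional = length(ts$transcriptional),
      n_splicing = length(ts$splicing),
      n_diff_transcriptional = length(ts$diff_transcriptional),
      n_diff_splicing = length(ts$diff_splicing),
      n_co_regulated = length(ts$co_regulated)
    )
  ))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
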