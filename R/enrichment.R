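# Region-composition enrichment of peak sets against the genome background,
# region-level CLIP fold-enrichment summaries, and metagene signal profiles
# around peak anchors.

#' One-tailed Fisher's exact test (alternative: greater)
#'
#' Exact upper-tail probability P(X >= a11) for a 2x2 contingency table
#' under the hypergeometric distribution fixed at the table's margins.
#'
#' @param counts 2x2 matrix (or length-4 vector, row-major) of non-negative
#'   integer counts.
#' @return p-value in (0, 1].
#' @export
fisher_one_tailed <- function(counts) {
  x <- as.numeric(counts)
  if (length(x) != 4) abort("Expected a 2x2 table")
  if (any(x < 0) || any(is.na(x))) abort("Counts must be non-negative integers")
  if (is.matrix(counts)) {
    a <- counts[1, 1]; b <- counts[1, 2]; c2 <- counts[2, 1]; d <- counts[2, 2]
  } else {
    a <- x[1]; b <- x[2]; c2 <- x[3]; d <- x[4]
  }
  # X ~ Hypergeometric(white = a + b, black = c2 + d, drawn = a + c2)
  phyper(a - 1, a + b, c2 + d, a + c2, lower.tail = FALSE)
}

classify_tile_midpoints <- function(genes, cfg, chrom_sizes, tile_width) {
  tiles <- purrr::imap(as.list(chrom_sizes), function(L, chrom) {
    starts <- seq(0, L - 1, by = tile_width)
    tibble(chrom = chrom,
           pos = pmin(starts + floor(tile_width / 2), L - 1))
  }) |> bind_rows()
  classify_positions(tiles, genes, cfg)
}

#' Region enrichment of a peak set against the genome background
#'
#' Classifies each peak by its midpoint, then contrasts the per-region peak
#' counts with the genomic abundance of each region class. The enrichment
#' ratio is (fraction of peaks in the region) / (fraction of genome bp in
#' the region, from exact interval arithmetic). The one-tailed Fisher
#' p-value uses a discretized background so both margins are counts: the
#' genome is divided into tiles of width equal to the median peak width
#' (rounded up, minimum 1), each tile classified by its midpoint, giving the
#' 2x2 table \[\[peaks in region, peaks elsewhere\], \[tiles in region,
#' tiles elsewhere\]\].
#'
#' @param peaks Peak tibble (any assay); must be non-empty.
#' @inheritParams genome_region_composition
#' @return Tibble of class `clip_region_enrichment`-style with one row per
#'   region class: `region`, `n_peaks_in`, `n_peaks_out`, `genome_fraction`,
#'   `peak_fraction`, `enrichment_ratio`, `pvalue`. Peak fractions sum to 1.
#' @export
region_enrichment <- function(peaks, genes, chrom_sizes,
                              cfg = region_config()) {
  if (nrow(peaks) == 0) abort("region_enrichment() needs at least one peak")
  comp <- genome_region_composition(genes, chrom_sizes, cfg)
  labelled <- classify_peaks(peaks, genes, cfg)
  N <- nrow(labelled)
  k <- table(factor(labelled$region, levels = REGION_LEVELS))

  W <- max(1, ceiling(median(peaks$end - peaks$start)))
  tiles <- classify_tile_midpoints(genes, cfg, chrom_sizes, W)
  b <- table(factor(tiles$region, levels = REGION_LEVELS))
  B <- nrow(tiles)

  res <- tibble(
    region = REGION_LEVELS,
    n_peaks_in = as.integer(k),
    n_peaks_out = N - as.integer(k),
    genome_fraction = comp$fraction[match(REGION_LEVELS, comp$region)],
    peak_fraction = as.integer(k) / N
  ) |>
    mutate(
      enrichment_ratio = .data$peak_fraction / .data$genome_fraction,
      pvalue = purrr::map2_dbl(
        as.integer(k), as.integer(b),
        function(ki, bi) fisher_one_tailed(c(ki, N - ki, bi, B - bi))
      )
    )
  if (any(res$genome_fraction == 0 & res$n_peaks_in > 0)) {
    warn("Peaks found in region class(es) with zero genomic extent; enrichment ratio is infinite")
  }
  new_result(res, "region_enrichment_tbl")
}

#' Region-level CLIP fold-enrichment summary
#'
#' Groups CLIP peaks by their midpoint region class and summarises the
#' IP-vs-input fold enrichment per region: peak count, fraction of all
#' peaks, arithmetic mean fold enrichment and mean log2 fold enrichment.
#' Region classes with no peaks are absent from the output.
#'
#' @param clip_peaks CLIP peak tibble carrying `fold_enrichment`.
#' @inheritParams classify_positions
#' @return Tibble with columns `region`, `n_peaks`, `peak_fraction`,
#'   `mean_fold_enrichment`, `mean_log2_fc`.
#' @export
clip_region_enrichment <- function(clip_peaks, genes, cfg = region_config()) {
  labelled <- classify_peaks(clip_peaks, genes, cfg)
  res <- labelled |>
    count(region = factor(.data$region, levels = REGION_LEVELS),
          name = "n_peaks") |>
    mutate(
      region = as.character(.data$region),
      peak_fraction = .data$n_peaks / sum(.data$n_peaks)
    )
  fc <- labelled |>
    group_by(region = .data$region) |>
    summarise(mean_fold_enrichment = mean(.data$fold_enrichment),
              mean_log2_fc = mean(log2(.data$fold_enrichment)),
              .groups = "drop")
  res <- left_join(res, fc, by = "region") |>
    arrange(match(.data$region, REGION_LEVELS))
  new_result(res, "clip_region_tbl")
}

track_coverage <- function(track) {
  if (nrow(track) == 0) return(list())
  gr <- GenomicRanges::GRanges(
    seqnames = track$chrom,
    ranges = IRanges::IRanges(start = track$start + 1, end = track$end)
  )
  as.list(GenomicRanges::coverage(gr, weight = track$value))
}

# Depth vector over 0-based half-open [from, to) on one chromosome,
# zero-padded outside the covered extent.
window_depth <- function(cov_rle, from, to) {
  n <- to - from
  out <- numeric(n)
  if (is.null(cov_rle)) return(out)
  len <- length(cov_rle)
  lo <- max(from, 0)
  hi <- min(to, len)
  if (hi > lo) {
    out[(lo - from + 1):(hi - from)] <-
      as.numeric(S4Vectors::window(cov_rle, start = lo + 1, end = hi))
  }
  out
}

#' Metagene signal profile around peak anchors
#'
#' Averages a per-base coverage track in fixed-width bins over a window
#' centred on each anchor peak (by default its midpoint; optionally its
#' narrowPeak summit when the `summit` column is present and non-negative).
#' Profiles are peak-centric and strand-agnostic: no orientation flipping is
#' applied. Window positions off the covered extent of the track contribute
#' depth 0 and the anchor is retained.
#'
#' @param anchors Non-empty peak tibble (`chrom`, `start`, `end`, and
#'   `summit` if `anchor = "summit"`).
#' @param track Coverage tibble from [read_bedgraph()].
#' @param half_window Half-width of the window around each anchor, bp.
#' @param bin_width Bin width, bp; must divide `2 * half_window`.
#' @param anchor `"midpoint"` or `"summit"`.
#' @return Tibble of class `meta_profile` with columns `offset` (bin centre
#'   relative to the anchor, bp) and `mean_depth`; the anchor count is in
#'   attribute `n_anchors`.
#' @export
metaprofile <- function(anchors, track, half_window = 3000, bin_width = 50,
                        anchor = c("midpoint", "summit")) {
  anchor <- match.arg(anchor)
  if (nrow(anchors) == 0) abort("metaprofile() needs at least one anchor")
  if ((2 * half_window) %% bin_width != 0) {
    abort("bin_width must divide 2 * half_window")
  }
  centres <- floor((anchors$start + anchors$end) / 2)
  if (anchor == "summit") {
    if (is.null(anchors$summit)) abort("anchor = \"summit\" needs a summit column")
    has_summit <- !is.na(anchors$summit) & anchors$summit >= 0
    centres[has_summit] <- anchors$start[has_summit] + anchors$summit[has_summit]
  }
  cov <- track_coverage(track)
  width <- 2 * half_window
  total <- numeric(width)
  for (i in seq_along(centres)) {
    total <- total + window_depth(cov[[anchors$chrom[i]]],
                                  centres[i] - half_window,
                                  centres[i] + half_window)
  }
  per_base <- total / length(centres)
  n_bins <- width / bin_width
  binned <- colMeans(matrix(per_base, nrow = bin_width, ncol = n_bins))
  res <- tibble(
    offset = seq(-half_window + bin_width / 2, half_window - bin_width / 2,
                 by = bin_width),
    mean_depth = binned
  )
  attr(res, "n_anchors") <- length(centres)
  new_result(res, "meta_profile")
}

new_result <- function(x, subclass) {
  class(x) <- c(subclass, class(tibble()))
  x
}
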