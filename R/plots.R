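# ggplot2 views of the result tables. Thin layers: every number plotted
# comes straight from a result tibble.

#' Plot region enrichment of a peak set
#'
#' Side-by-side bars of the peak fraction and the genome fraction per
#' region class, annotated with the enrichment ratio.
#'
#' @param x A `region_enrichment_tbl` from [region_enrichment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_region_enrichment <- function(x, ...) {
  df <- tibble(
    region = factor(rep(x$region, 2), levels = REGION_LEVELS),
    fraction = c(x$peak_fraction, x$genome_fraction),
    set = rep(c("peaks", "genome"), each = nrow(x))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$fraction,
                                   fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "fraction", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname plot_region_enrichment
#' @param object A `region_enrichment_tbl`.
#' @export
autoplot.region_enrichment_tbl <- function(object, ...) {
  plot_region_enrichment(object, ...)
}

#' Plot a metagene signal profile
#'
#' Mean track depth per bin against the offset from the anchor.
#'
#' @param x A `meta_profile` from [metaprofile()], or a named list of them
#'   (drawn as one line per track).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_metaprofile <- function(x, ...) {
  if (inherits(x, "meta_profile")) x <- list(signal = x)
  df <- purrr::imap(x, function(p, nm) {
    tibble(track = nm, offset = p$offset, mean_depth = p$mean_depth)
  }) |> bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$mean_depth,
                                   colour = .data$track)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance from peak (bp)", y = "mean depth",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_metaprofile
#' @param object A `meta_profile`.
#' @export
autoplot.meta_profile <- function(object, ...) plot_metaprofile(object, ...)

#' Plot a ChIP-to-CLIP distance profile
#'
#' Fraction of ChIP peaks per distance bin; accepts the per-group table
#' from [run_integration()] (faceted by group) or a single
#' [chip_clip_distance_profile()] result.
#'
#' @param x A `distance_profile` tibble, optionally with a `group` column.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_distance_profile <- function(x, ...) {
  df <- x |> mutate(bin = factor(.data$bin, levels = DISTANCE_BINS))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$fraction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "nearest CLIP peak", y = "fraction of ChIP peaks") +
    ggplot2::theme_minimal()
  if ("group" %in% names(df)) p <- p + ggplot2::facet_wrap(~group)
  p
}

#' @rdname plot_distance_profile
#' @param object A `distance_profile`.
#' @export
autoplot.distance_profile <- function(object, ...) {
  plot_distance_profile(object, ...)
}

#' Plot gene group and subgroup sizes
#'
#' Bar chart of the DEG-only / AS-only / Both partition from a
#' classification table.
#'
#' @param classification Output of [classify_genes()].
#' @return A ggplot object.
#' @export
plot_gene_groups <- function(classification) {
  df <- classification |>
    filter(.data$group != "none") |>
    count(group = factor(.data$group,
                         levels = c("DEG_only", "AS_only", "Both")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "genes") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
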