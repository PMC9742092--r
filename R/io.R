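# File readers and writers for the formats the pipeline consumes.
# Internal convention: 0-based half-open coordinates everywhere. GTF is
# converted on read/write; BED-family formats pass through unchanged.

gtf_attr <- function(attributes, key) {
  m <- stringr::str_match(attributes, paste0(key, ' "([^"]*)"'))
  m[, 2]
}

#' Read gene models from a GTF file
#'
#' Parses an Ensembl-dialect GTF (1-based inclusive coordinates, `gene_id`
#' and optionally `gene_name` attributes) into a gene-model table. Exon
#' features are grouped per gene; a `gene` feature line, when present, sets
#' the gene span, otherwise the span is the exon hull. Coordinates are
#' converted to 0-based half-open.
#'
#' @param path Path to a GTF file.
#' @return A tibble with one row per gene, sorted by (chrom, start, gene_id):
#'   columns `gene_id`, `gene_name`, `chrom`, `start`, `end`, `strand`,
#'   `tss`, `tes`, `n_exons`, and `exons`, a list-column of tibbles with
#'   `start`/`end` (0-based half-open, sorted, non-overlapping). `tss` is the
#'   strand-aware 5' end and `tes` the strand-aware 3' end, both as single
#'   base positions.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) abort(paste0("GTF file not found: ", path))
  lines <- readr::read_lines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  if (!any(keep)) return(empty_gene_table())
  idx <- which(keep)
  fields <- stringr::str_split(lines[idx], "\t")
  nf <- lengths(fields)
  if (any(nf != 9)) {
    bad <- idx[which(nf != 9)[1]]
    abort(paste0("Malformed GTF line ", bad, ": expected 9 tab-separated fields, got ",
                 nf[which(nf != 9)[1]]))
  }
  mat <- do.call(rbind, fields)
  start1 <- suppressWarnings(as.numeric(mat[, 4]))
  end1 <- suppressWarnings(as.numeric(mat[, 5]))
  if (anyNA(start1) || anyNA(end1)) {
    bad <- idx[which(is.na(start1) | is.na(end1))[1]]
    abort(paste0("Malformed GTF line ", bad, ": non-numeric coordinates"))
  }
  feat <- tibble(
    chrom = mat[, 1], feature = mat[, 3],
    start = start1 - 1, end = end1,            # to 0-based half-open
    strand = mat[, 7],
    gene_id = gtf_attr(mat[, 9], "gene_id"),
    gene_name = gtf_attr(mat[, 9], "gene_name"),
    line = idx
  )
  if (anyNA(feat$gene_id)) {
    abort(paste0("Malformed GTF line ", feat$line[which(is.na(feat$gene_id))[1]],
                 ": missing gene_id attribute"))
  }
  if (any(feat$end <= feat$start)) {
    abort(paste0("Invalid interval at GTF line ",
                 feat$line[which(feat$end <= feat$start)[1]],
                 ": end <= start after 0-based conversion"))
  }

  exons <- feat |>
    filter(.data$feature == "exon") |>
    arrange(.data$gene_id, .data$start)
  gene_lines <- feat |> filter(.data$feature == "gene")
  used <- bind_rows(exons, gene_lines)
  if (nrow(used) == 0) return(empty_gene_table())

  per_gene <- used |>
    group_by(.data$gene_id) |>
    summarise(
      chrom = .data$chrom[1],
      strand = .data$strand[1],
      gene_name = {
        nm <- .data$gene_name[!is.na(.data$gene_name)]
        if (length(nm)) nm[1] else .data$gene_id[1]
      },
      exons = {
        is_exon <- .data$feature == "exon"
        ex_start <- .data$start[is_exon]
        ex_end <- .data$end[is_exon]
        list(tibble(start = ex_start, end = ex_end))
      },
      start = min(.data$start),
      end = max(.data$end),
      .groups = "drop"
    )
  genes <- per_gene |>
    mutate(
      tss = if_else(.data$strand == "-", .data$end - 1, .data$start),
      tes = if_else(.data$strand == "-", .data$start, .data$end - 1),
      n_exons = purrr::map_int(.data$exons, nrow)
    ) |>
    select("gene_id", "gene_name", "chrom", "start", "end", "strand",
           "tss", "tes", "n_exons", "exons") |>
    arrange(.data$chrom, .data$start, .data$gene_id)
  validate_gene_table(genes)
  genes
}

empty_gene_table <- function() {
  tibble(
    gene_id = character(), gene_name = character(), chrom = character(),
    start = numeric(), end = numeric(), strand = character(),
    tss = numeric(), tes = numeric(), n_exons = integer(), exons = list()
  )
}

validate_gene_table <- function(genes) {
  for (i in seq_len(nrow(genes))) {
    ex <- genes$exons[[i]]
    if (nrow(ex) == 0) next
    if (any(ex$start < genes$start[i]) || any(ex$end > genes$end[i])) {
      abort(paste0("Gene ", genes$gene_id[i], ": exon outside gene interval"))
    }
    if (nrow(ex) > 1 && any(ex$start[-1] < ex$end[-nrow(ex)])) {
      abort(paste0("Gene ", genes$gene_id[i], ": overlapping exons"))
    }
  }
  invisible(genes)
}

#' Write gene models to a GTF file
#'
#' Inverse of [read_gtf()]: emits one `gene` line and one `exon` line per
#' exon for each gene, converting back to 1-based inclusive coordinates.
#'
#' @param genes Gene-model tibble as returned by [read_gtf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  rows <- purrr::pmap(genes, function(gene_id, gene_name, chrom, start, end,
                                      strand, tss, tes, n_exons, exons, ...) {
    attrs <- sprintf('gene_id "%s"; gene_name "%s";', gene_id, gene_name)
    gene_line <- paste(chrom, "chipclipr", "gene", format_bp(start + 1),
                       format_bp(end), ".", strand, ".", attrs, sep = "\t")
    if (nrow(exons)) {
      exon_lines <- paste(chrom, "chipclipr", "exon", format_bp(exons$start + 1),
                          format_bp(exons$end), ".", strand, ".", attrs, sep = "\t")
    } else exon_lines <- character()
    c(gene_line, exon_lines)
  })
  readr::write_lines(unlist(rows), path)
  invisible(path)
}

format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read and write BED6 interval files
#'
#' BED6 is 0-based half-open; coordinates pass through unchanged.
#'
#' @param path File path.
#' @return `read_bed6()`: a tibble with columns `chrom`, `start`, `end`,
#'   `name`, `score`, `strand`.
#' @export
read_bed6 <- function(path) {
  readr::read_tsv(path,
    col_names = c("chrom", "start", "end", "name", "score", "strand"),
    col_types = "ciicdc", progress = FALSE
  ) |> as_tibble()
}

#' @rdname read_bed6
#' @param x Tibble with at least `chrom`, `start`, `end`; missing `name`,
#'   `score`, `strand` columns are filled with ".", 0, ".".
#' @export
write_bed6 <- function(x, path) {
  out <- tibble(
    chrom = x$chrom, start = x$start, end = x$end,
    name = x$name %||% ".", score = x$score %||% 0,
    strand = x$strand %||% "."
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

NARROWPEAK_COLS <- c("chrom", "start", "end", "name", "score", "strand",
                     "signal_value", "p_value", "q_value", "summit")

#' Read a narrowPeak file
#'
#' Ten-column BED extension: `signalValue` carries the IP/input fold
#' enrichment, `pValue`/`qValue` are -log10 transformed, `peak` is the
#' summit offset from `start` (-1 when absent).
#'
#' @param path File path.
#' @param assay Either `"chip"` or `"clip"`; recorded in an `assay` column so
#'   downstream filters can refuse the wrong peak type.
#' @return Tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, `fold_enrichment`, `neg_log10_p`, `neg_log10_q`, `summit`,
#'   `assay`.
#' @export
read_narrowpeak <- function(path, assay = c("chip", "clip")) {
  assay <- match.arg(assay)
  x <- readr::read_tsv(path, col_names = NARROWPEAK_COLS,
                       col_types = "ciicdcdddi", progress = FALSE)
  bad <- which(x$end <= x$start)
  if (length(bad)) {
    abort(paste0("Invalid peak at ", path, " line ", bad[1], ": end <= start"))
  }
  x |>
    transmute(
      .data$chrom, .data$start, .data$end, .data$name, .data$score,
      .data$strand,
      fold_enrichment = .data$signal_value,
      neg_log10_p = .data$p_value,
      neg_log10_q = .data$q_value,
      .data$summit,
      assay = assay
    )
}

#' @rdname read_narrowpeak
#' @param peaks Peak tibble as returned by `read_narrowpeak()`.
#' @export
write_narrowpeak <- function(peaks, path) {
  out <- tibble(
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    name = peaks$name, score = peaks$score, strand = peaks$strand,
    signal_value = peaks$fold_enrichment, p_value = peaks$neg_log10_p,
    q_value = peaks$neg_log10_q %||% -1, summit = peaks$summit %||% -1L
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' Four-column, 0-based half-open step function. Intervals not covered by
#' any record have depth 0.
#'
#' @param path File path.
#' @return Tibble with columns `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                  col_types = "ciid", comment = "track", progress = FALSE) |>
    as_tibble()
}

#' @rdname read_bedgraph
#' @param track Tibble with `chrom`, `start`, `end`, `value`.
#' @export
write_bedgraph <- function(track, path) {
  readr::write_tsv(track[, c("chrom", "start", "end", "value")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a chrom.sizes file
#'
#' @param path Two-column file: chromosome name, length in bp.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "size"), col_types = "cd",
                       progress = FALSE)
  setNames(x$size, x$chrom)
}

#' Read a DESeq2-style differential expression table
#'
#' Expects a TSV with header columns `gene_id`, `baseMean`,
#' `log2FoldChange`, `pvalue`, `padj`; `"NA"` is allowed in the statistics
#' columns. Row order is preserved.
#'
#' @param path File path.
#' @return Tibble with columns `gene_id`, `base_mean`, `log2fc`, `pvalue`,
#'   `padj`.
#' @export
read_deg_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  need <- c("gene_id", "baseMean", "log2FoldChange", "pvalue", "padj")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    abort(paste0("Differential-expression table ", path,
                 " is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  tibble(
    gene_id = x$gene_id,
    base_mean = as.numeric(x$baseMean),
    log2fc = suppressWarnings(as.numeric(x$log2FoldChange)),
    pvalue = suppressWarnings(as.numeric(x$pvalue)),
    padj = suppressWarnings(as.numeric(x$padj))
  )
}

# Per-event-type names of the columns delimiting the alternative segment,
# as printed in rMATS v4 *.MATS.JC.txt headers.
RMATS_SEGMENT_COLS <- list(
  SE   = c("exonStart_0base", "exonEnd"),
  MXE  = c("1stExonStart_0base", "1stExonEnd"),
  A3SS = c("longExonStart_0base", "longExonEnd"),
  A5SS = c("longExonStart_0base", "longExonEnd"),
  RI   = c("riExonStart_0base", "riExonEnd")
)

#' Read an rMATS-style differential splicing table
#'
#' Reads one per-type rMATS v4 output table (`SE`, `MXE`, `A3SS`, `A5SS`,
#' `RI`) and maps the per-type coordinate columns to a single alternative
#' segment: the cassette exon for SE, the first alternative exon for MXE,
#' the long exon for A5SS/A3SS and the retained-intron span for RI. rMATS
#' starts are already 0-based and are preserved.
#'
#' `delta_psi` is the `IncLevelDifference` column. rMATS reports
#' Psi(sample1) - Psi(sample2); the caller is responsible for having run
#' rMATS with the condition as sample 1 so that the sign convention is
#' Psi(condition) - Psi(control).
#'
#' @param path File path.
#' @param event_type One of `"SE"`, `"MXE"`, `"A3SS"`, `"A5SS"`, `"RI"`.
#' @return Tibble with columns `event_id`, `gene_id`, `event_type`, `chrom`,
#'   `start`, `end`, `strand`, `delta_psi`, `pvalue`, `fdr`.
#' @export
read_rmats_table <- function(path, event_type) {
  if (!event_type %in% names(RMATS_SEGMENT_COLS)) {
    abort(paste0("Unknown splicing event type: ", event_type))
  }
  x <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  seg <- RMATS_SEGMENT_COLS[[event_type]]
  need <- c("ID", "GeneID", "chr", "strand", seg,
            "PValue", "FDR", "IncLevelDifference")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    abort(paste0("Splicing table ", path, " is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(x) == 0) return(empty_event_table())
  tibble(
    event_id = paste0(event_type, "_", x$ID),
    gene_id = x$GeneID,
    event_type = event_type,
    chrom = x$chr,
    start = as.numeric(x[[seg[1]]]),
    end = as.numeric(x[[seg[2]]]),
    strand = x$strand,
    delta_psi = suppressWarnings(as.numeric(x$IncLevelDifference)),
    pvalue = suppressWarnings(as.numeric(x$PValue)),
    fdr = suppressWarnings(as.numeric(x$FDR))
  )
}

empty_event_table <- function() {
  tibble(
    event_id = character(), gene_id = character(), event_type = character(),
    chrom = character(), start = numeric(), end = numeric(),
    strand = character(), delta_psi = numeric(), pvalue = numeric(),
    fdr = numeric()
  )
}

#' Read all five event types of a contrast
#'
#' Convenience wrapper over [read_rmats_table()] for a bundle where the five
#' per-type tables share a filename stem, e.g. `as_kd_SE.tsv`.
#'
#' @param dir Directory holding the tables.
#' @param stem Filename stem; files are `<stem><type>.tsv`.
#' @param types Event types to read (files absent for a listed type are an
#'   error; restrict `types` to skip them).
#' @return One tibble of events, all types row-bound.
#' @export
read_rmats_bundle <- function(dir, stem, types = names(RMATS_SEGMENT_COLS)) {
  purrr::map(types, function(tt) {
    read_rmats_table(file.path(dir, paste0(stem, tt, ".tsv")), tt)
  }) |> bind_rows()
}
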