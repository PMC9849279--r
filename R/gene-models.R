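#' Gene models: genes, TSSs and first introns
#'
#' A lightweight container for gene structures: a `genes` tibble
#' (`gene_id`, `chrom`, `start`, `end`, `strand`, `tss`) and an `exons`
#' tibble (`gene_id`, `chrom`, `start`, `end`, `exon_rank` in transcription
#' order). The TSS is the 0-based first transcribed base: `start` for `+`
#' genes and `end - 1` for `-` genes.
#'
#' @param genes Tibble with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @param exons Tibble with `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open genomic coordinates).
#' @return An object of class `wr_genes`.
#' @export
gene_models <- function(genes, exons) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in% names(genes)),
            all(genes$strand %in% c("+", "-")),
            all(c("gene_id", "chrom", "start", "end") %in% names(exons)))
  check_intervals(genes)
  check_intervals(exons)
  genes <- genes |>
    mutate(tss = ifelse(.data$strand == "+", .data$start, .data$end - 1L)) |>
    arrange(.data$chrom, .data$start)
  # transcription order: genomic order for '+', reversed for '-'
  exons <- exons |>
    left_join(genes[, c("gene_id", "strand")], by = "gene_id") |>
    group_by(.data$gene_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(exon_rank = if (.data$strand[1] == "+") row_number()
           else rev(row_number())) |>
    ungroup() |>
    arrange(.data$gene_id, .data$exon_rank) |>
    select("gene_id", "chrom", "start", "end", "exon_rank")
  # exons must not overlap within a gene
  bad <- exons |>
    group_by(.data$gene_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    summarise(ov = any(.data$start[-1] < .data$end[-n()]), .groups = "drop")
  if (any(bad$ov)) stop("overlapping exons within a gene", call. = FALSE)
  structure(list(genes = genes, exons = exons), class = "wr_genes")
}

#' @export
print.wr_genes <- function(x, ...) {
  cat("<wr_genes> ", nrow(x$genes), " genes, ", nrow(x$exons), " exons\n",
      sep = "")
  invisible(x)
}

#' First introns of multi-exon genes
#'
#' The first intron is the gap between the first and second exon in
#' transcription order; genes with fewer than two exons are absent from the
#' result.
#'
#' @param gm A [gene_models()] object.
#' @return Tibble `gene_id`, `chrom`, `start`, `end` (0-based half-open).
#' @export
first_introns <- function(gm) {
  stopifnot(inherits(gm, "wr_genes"))
  ex <- gm$exons |> filter(.data$exon_rank <= 2L)
  multi <- ex |>
    group_by(.data$gene_id) |>
    filter(n() == 2L) |>
    arrange(.data$exon_rank, .by_group = TRUE) |>
    summarise(
      chrom = .data$chrom[1],
      # intron = genomic gap between the two exons
      lo = min(.data$end[1], .data$end[2]),
      hi = max(.data$start[1], .data$start[2]),
      .groups = "drop"
    )
  tibble(gene_id = multi$gene_id, chrom = multi$chrom,
         start = as.integer(multi$lo), end = as.integer(multi$hi))
}
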