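#' @import tibble
#' @importFrom dplyr arrange mutate filter select group_by summarise ungroup
#'   left_join bind_rows n desc row_number
#' @importFrom rlang .data
NULL

# All public tables use the BED convention: `start` is 0-based inclusive,
# `end` is exclusive. IRanges/GenomicRanges (1-based closed) are used purely
# as a compute backend behind the two converters below.

#' Build an interval tibble
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors; 0-based half-open coordinates.
#' @param strand Optional strand vector in `+`, `-`, `.`.
#' @param ... Further columns recycled alongside.
#' @return A tibble with at least `chrom`, `start`, `end`.
#' @examples
#' intervals("chr1", 0, 100)
#' @export
intervals <- function(chrom, start, end, strand = NULL, ...) {
  tbl <- tibble(chrom = as.character(chrom),
                start = as.integer(start),
                end = as.integer(end), ...)
  if (!is.null(strand)) tbl$strand <- as.character(strand)
  check_intervals(tbl)
  tbl
}

check_intervals <- function(tbl) {
  stopifnot(all(c("chrom", "start", "end") %in% names(tbl)))
  if (nrow(tbl) == 0) return(invisible(tbl))
  if (any(is.na(tbl$chrom)) || any(!nzchar(tbl$chrom))) {
    stop("chrom must be non-empty", call. = FALSE)
  }
  if (any(tbl$start < 0)) stop("start must be >= 0", call. = FALSE)
  if (any(tbl$end <= tbl$start)) stop("end must be > start", call. = FALSE)
  invisible(tbl)
}

#' Convert an interval tibble to GRanges (internal backend)
#' @noRd
gr_from_tbl <- function(tbl) {
  strand <- if ("strand" %in% names(tbl)) {
    ifelse(tbl$strand %in% c("+", "-"), tbl$strand, "*")
  } else "*"
  GenomicRanges::GRanges(
    seqnames = tbl$chrom,
    ranges = IRanges::IRanges(start = tbl$start + 1L, end = tbl$end),
    strand = strand
  )
}

#' @noRd
tbl_from_gr <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' Do two intervals overlap?
#'
#' Half-open semantics: touching intervals (`end == start`) do not overlap.
#' Vectorised over pairs.
#'
#' @param a,b Interval tibbles (recycled to equal length).
#' @return Logical vector.
#' @examples
#' interval_overlap(intervals("chr1", 0, 10), intervals("chr1", 10, 20))
#' @export
interval_overlap <- function(a, b) {
  check_intervals(a); check_intervals(b)
  n <- max(nrow(a), nrow(b))
  idx_a <- rep_len(seq_len(nrow(a)), n)
  idx_b <- rep_len(seq_len(nrow(b)), n)
  a$chrom[idx_a] == b$chrom[idx_b] &
    a$start[idx_a] < b$end[idx_b] &
    b$start[idx_b] < a$end[idx_a]
}

#' Signed distance from a peak summit to a TSS
#'
#' Distance measured in the transcription orientation of the gene: negative
#' values are upstream of the TSS, positive downstream, and 0 means the
#' summit sits on the TSS base itself.
#'
#' @param summit_pos Absolute 0-based summit positions.
#' @param tss 0-based TSS base positions.
#' @param strand Gene strands (`+` or `-`).
#' @return Integer vector of signed distances in bp.
#' @examples
#' signed_tss_distance(950, 1000, "+")  # -50, upstream
#' @export
signed_tss_distance <- function(summit_pos, tss, strand) {
  stopifnot(all(strand %in% c("+", "-")))
  ifelse(strand == "+",
         as.integer(summit_pos) - as.integer(tss),
         as.integer(tss) - as.integer(summit_pos))
}

#' Signed summit-to-TSS distance between peak and gene tables
#'
#' @param peaks Peak tibble with `chrom`, `start`, `summit` (offset from
#'   start).
#' @param genes Gene tibble with `chrom`, `tss`, `strand` (one row, or as
#'   many rows as `peaks`).
#' @return Integer vector; errors if any pair sits on different chromosomes.
#' @export
peak_tss_distance <- function(peaks, genes) {
  n <- max(nrow(peaks), nrow(genes))
  ip <- rep_len(seq_len(nrow(peaks)), n)
  ig <- rep_len(seq_len(nrow(genes)), n)
  if (any(peaks$chrom[ip] != genes$chrom[ig])) {
    stop("peak and gene on different chromosomes", call. = FALSE)
  }
  signed_tss_distance(peaks$start[ip] + peaks$summit[ip],
                      genes$tss[ig], genes$strand[ig])
}

#' Merge peaks across samples
#'
#' Peaks whose intervals overlap (or whose gap is smaller than `max_gap`) on
#' the same chromosome are unioned transitively. Sample and assay evidence
#' are set unions; the merged summit is the summit of the highest-scoring
#' constituent (leftmost on ties); the merged score is the maximum.
#'
#' With the default `max_gap = 0` only literally overlapping peaks merge;
#' touching peaks stay separate, matching [interval_overlap()].
#'
#' @param peaks Peak tibble with columns `chrom`, `start`, `end`, `summit`,
#'   `score`, `sample_evidence`, `assay_evidence` (the evidence columns are
#'   comma-separated sets).
#' @param max_gap Maximum half-open gap (bp) across which peaks still merge.
#' @return Merged peak tibble sorted by (chrom, start).
#' @export
merge_peaks <- function(peaks, max_gap = 0L) {
  cols <- c("chrom", "start", "end", "summit", "score",
            "sample_evidence", "assay_evidence")
  stopifnot(all(cols %in% names(peaks)))
  if (nrow(peaks) == 0) return(peaks[, cols])
  check_intervals(peaks)
  gr <- gr_from_tbl(peaks)
  merged <- GenomicRanges::reduce(gr, min.gapwidth = max_gap,
                                  ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(gr, merged, maxgap = max_gap - 1L,
                                      ignore.strand = TRUE)
  grp <- integer(nrow(peaks))
  grp[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)
  out <- tbl_from_gr(merged)
  peaks$.grp <- grp
  peaks$.summit_abs <- peaks$start + peaks$summit
  agg <- peaks |>
    group_by(.data$.grp) |>
    summarise(
      .summit_abs = .data$.summit_abs[order(-.data$score, .data$.summit_abs)][1],
      score = max(.data$score),
      sample_evidence = evidence_union(.data$sample_evidence),
      assay_evidence = evidence_union(.data$assay_evidence),
      .groups = "drop"
    ) |>
    arrange(.data$.grp)
  stopifnot(identical(agg$.grp, seq_len(nrow(out))))
  out$summit <- as.integer(agg$.summit_abs - out$start)
  out$score <- agg$score
  out$sample_evidence <- agg$sample_evidence
  out$assay_evidence <- agg$assay_evidence
  arrange(out, .data$chrom, .data$start)
}

#' Union of comma-separated evidence sets
#' @noRd
evidence_union <- function(x) {
  paste(sort(unique(unlist(strsplit(x[nzchar(x)], ",", fixed = TRUE)))),
        collapse = ",")
}

#' Number of members in a comma-separated evidence set
#' @noRd
evidence_size <- function(x) {
  lengths(strsplit(x, ",", fixed = TRUE)) * nzchar(x)
}

evidence_has <- function(x, member) {
  vapply(strsplit(x, ",", fixed = TRUE), function(s) member %in% s, logical(1))
}
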