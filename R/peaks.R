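#' Keep nucleosome-free-region fragments
#'
#' Retains fragments whose insert size (end - start) does not exceed the
#' configured maximum; input order is preserved.
#'
#' @param frags Fragment tibble (`chrom`, `start`, `end`).
#' @param cfg [analysis_config()]; `nfr_max_insert` is used (default 100 bp,
#'   boundary inclusive).
#' @return Filtered fragment tibble.
#' @export
filter_nfr <- function(frags, cfg = analysis_config()) {
  check_intervals(frags)
  frags[frags$end - frags$start <= cfg$nfr_max_insert, , drop = FALSE]
}

#' Shift Tn5 cut sites
#'
#' Plus-strand cut sites move +4 bp and minus-strand sites -5 bp to centre
#' the signal on the transposase insertion point; shifted positions are
#' clipped at 0.
#'
#' @param pos Integer vector of 0-based cut positions.
#' @param strand Strand vector (`+` or `-`).
#' @param cfg [analysis_config()].
#' @return Integer vector of shifted positions.
#' @examples
#' tn5_shift(c(100, 100), c("+", "-"))  # 104, 95
#' @export
tn5_shift <- function(pos, strand, cfg = analysis_config()) {
  stopifnot(all(strand %in% c("+", "-")))
  shift <- ifelse(strand == "+", cfg$tn5_shift_plus, cfg$tn5_shift_minus)
  pmax(0L, as.integer(pos) + as.integer(shift))
}

#' Call peaks from fragment intervals
#'
#' A windowed Poisson caller in the MACS2 mould: fragment midpoints are
#' counted in sliding windows, each window's count is tested against a local
#' Poisson rate (the largest of the genome-wide rate and rates over the
#' configured local spans), p-values are BH-adjusted genome-wide, and
#' significant windows are merged. Merged candidate regions are trimmed to
#' the span where per-base fragment coverage stays above
#' `peak_trim_frac` of the regional maximum; the summit is the leftmost
#' coverage maximum.
#'
#' @param frags Fragment tibble (`chrom`, `start`, `end`), already
#'   NFR-filtered and shifted.
#' @param genome_sizes Named integer vector of chromosome lengths.
#' @param cfg [analysis_config()].
#' @param sample_id Sample label recorded in `sample_evidence`.
#' @param assay Assay label recorded in `assay_evidence` (default "ATAC").
#' @return Peak tibble `chrom`, `start`, `end`, `summit`, `score`
#'   (-log10 of the best window q-value), `sample_evidence`,
#'   `assay_evidence`, sorted and non-overlapping.
#' @export
call_peaks <- function(frags, genome_sizes, cfg = analysis_config(),
                       sample_id = "sample", assay = "ATAC") {
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  summit = integer(), score = numeric(),
                  sample_evidence = character(), assay_evidence = character())
  if (nrow(frags) == 0) return(empty)
  check_intervals(frags)
  missing_chrom <- setdiff(unique(frags$chrom), names(genome_sizes))
  if (length(missing_chrom) > 0) {
    stop("missing chromosome size for: ",
         paste(missing_chrom, collapse = ", "), call. = FALSE)
  }
  w <- cfg$peak_window
  step <- cfg$peak_step
  genome_len <- sum(as.numeric(genome_sizes))
  rate_genome <- nrow(frags) / genome_len

  mids <- floor((frags$start + frags$end) / 2)
  win <- list()
  for (chrom in names(genome_sizes)) {
    len <- genome_sizes[[chrom]]
    if (len < w) next
    ws <- seq(0L, len - w, by = step)
    m <- sort(mids[frags$chrom == chrom])
    cnt <- findInterval(ws + w - 1L, m) - findInterval(ws - 1L, m)
    lam <- rate_genome * w
    for (span in cfg$peak_local_bg) {
      ctr <- ws + w / 2
      lo <- pmax(0, ctr - span / 2)
      hi <- pmin(len, ctr + span / 2)
      local_cnt <- findInterval(hi - 1, m) - findInterval(lo - 1, m)
      lam <- pmax(lam, local_cnt / (hi - lo) * w)
    }
    win[[chrom]] <- tibble(chrom = chrom, start = ws, end = ws + w,
                           count = cnt, lambda = lam)
  }
  if (length(win) == 0) return(empty)
  win <- bind_rows(win)
  win$p <- stats::ppois(win$count - 1L, win$lambda, lower.tail = FALSE)
  win$q <- stats::p.adjust(win$p, method = "BH")
  sig <- win[win$q < cfg$peak_qvalue & win$count > 0, , drop = FALSE]
  if (nrow(sig) == 0) return(empty)

  gr <- gr_from_tbl(sig)
  merged <- GenomicRanges::reduce(gr, min.gapwidth = 1L, ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(gr, merged, ignore.strand = TRUE)
  best_q <- vapply(seq_along(merged), function(i) {
    min(sig$q[S4Vectors::queryHits(hits)[S4Vectors::subjectHits(hits) == i]])
  }, numeric(1))
  cand <- tbl_from_gr(merged)
  cand$score <- -log10(pmax(best_q, 1e-300))

  out <- vector("list", nrow(cand))
  for (chrom in unique(cand$chrom)) {
    cov <- IRanges::coverage(
      IRanges::IRanges(start = frags$start[frags$chrom == chrom] + 1L,
                       end = frags$end[frags$chrom == chrom]),
      width = genome_sizes[[chrom]]
    )
    idx <- which(cand$chrom == chrom)
    for (i in idx) {
      seg <- as.integer(S4Vectors::window(cov, start = cand$start[i] + 1L,
                                          end = cand$end[i]))
      mx <- max(seg)
      if (mx == 0) next
      keep <- which(seg >= cfg$peak_trim_frac * mx)
      lo <- cand$start[i] + keep[1] - 1L
      hi <- cand$start[i] + keep[length(keep)]
      summit_abs <- cand$start[i] + which.max(seg) - 1L
      summit_abs <- min(max(summit_abs, lo), hi - 1L)
      out[[i]] <- tibble(chrom = chrom, start = as.integer(lo),
                         end = as.integer(hi),
                         summit = as.integer(summit_abs - lo),
                         score = cand$score[i],
                         sample_evidence = sample_id,
                         assay_evidence = assay)
    }
  }
  out <- bind_rows(out[!vapply(out, is.null, logical(1))])
  if (nrow(out) == 0) return(empty)
  arrange(out, .data$chrom, .data$start)
}
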