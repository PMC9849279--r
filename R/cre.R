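CRE_CLASSES <- c("CP", "PP", "FI", "Pro", "Dis")

#' Keep peaks supported by enough samples
#'
#' @param merged Merged peak tibble with a `sample_evidence` column
#'   (comma-separated sample identifiers).
#' @param cfg [analysis_config()]; `min_sample_evidence` is used (default 2).
#' @return Filtered peak tibble.
#' @export
evidence_filter <- function(merged, cfg = analysis_config()) {
  stopifnot("sample_evidence" %in% names(merged))
  merged[evidence_size(merged$sample_evidence) >= cfg$min_sample_evidence, ,
         drop = FALSE]
}

#' Assign each peak to its closest gene by summit-to-TSS distance
#'
#' The gene minimising the absolute signed summit-to-TSS distance wins;
#' ties break to the lexicographically smallest `gene_id`. Peaks on
#' chromosomes without genes are reported and dropped.
#'
#' @param peaks Peak tibble with `chrom`, `start`, `summit`.
#' @param gm A [gene_models()] object.
#' @return `peaks` with `gene_id` and `signed_distance` columns added;
#'   peaks with no gene on their chromosome are removed (with a warning).
#' @export
assign_closest_gene <- function(peaks, gm) {
  stopifnot(inherits(gm, "wr_genes"))
  if (nrow(peaks) == 0) {
    peaks$gene_id <- character(0)
    peaks$signed_distance <- integer(0)
    return(peaks)
  }
  genes <- gm$genes
  gene_id <- character(nrow(peaks))
  dist <- integer(nrow(peaks))
  ok <- logical(nrow(peaks))
  for (chrom in unique(peaks$chrom)) {
    ip <- which(peaks$chrom == chrom)
    g <- genes[genes$chrom == chrom, , drop = FALSE]
    if (nrow(g) == 0) next
    g <- g[order(g$gene_id), , drop = FALSE]  # tie-break by gene_id
    summit_abs <- peaks$start[ip] + peaks$summit[ip]
    d <- outer(summit_abs, g$tss, "-")  # peaks x genes, '+' orientation
    d <- sweep(d, 2, ifelse(g$strand == "+", 1L, -1L), "*")
    best <- apply(abs(d), 1, which.min)  # first (smallest gene_id) on ties
    gene_id[ip] <- g$gene_id[best]
    dist[ip] <- d[cbind(seq_along(ip), best)]
    ok[ip] <- TRUE
  }
  if (any(!ok)) {
    warning(sum(!ok), " peak(s) on chromosomes without genes were dropped")
  }
  out <- peaks[ok, , drop = FALSE]
  out$gene_id <- gene_id[ok]
  out$signed_distance <- dist[ok]
  out
}

#' Classify a peak into a cis-regulatory-element class
#'
#' Peaks with only ATAC evidence are promoter candidates: a core promoter
#' (CP) lies strictly less than `cp_max_upstream` bp upstream of the TSS,
#' a proximal promoter (PP) between the bounds of `pp_upstream_range`
#' (inclusive; the shared 100 bp boundary belongs to PP). Peaks with ChIP
#' evidence are enhancer candidates: first-intron (FI) when the summit
#' falls in the assigned gene's first intron, otherwise proximal (Pro)
#' within `pro_max_dist` of the TSS or distal (Dis) out to `dis_max_dist`.
#' Anything else is `unannotated`.
#'
#' @param signed_distance Signed summit-to-TSS distance (negative =
#'   upstream).
#' @param has_chip Logical; does the peak carry ChIP (H3K27ac) evidence?
#' @param in_first_intron Logical; does the summit overlap the assigned
#'   gene's first intron?
#' @param cfg [analysis_config()].
#' @return Character vector over `CP`, `PP`, `FI`, `Pro`, `Dis`,
#'   `unannotated`.
#' @export
classify_cre <- function(signed_distance, has_chip, in_first_intron,
                         cfg = analysis_config()) {
  n <- max(length(signed_distance), length(has_chip),
           length(in_first_intron))
  d <- rep_len(signed_distance, n)
  chip <- rep_len(as.logical(has_chip), n)
  fi <- rep_len(as.logical(in_first_intron), n)
  out <- rep("unannotated", n)
  # ATAC-only: upstream promoter classes
  cp <- !chip & d > -cfg$cp_max_upstream & d < 0
  pp <- !chip & d >= -cfg$pp_upstream_range[2] & d <= -cfg$pp_upstream_range[1]
  out[cp] <- "CP"
  out[pp] <- "PP"
  # ChIP evidence: enhancer classes, first intron takes precedence
  out[chip & fi] <- "FI"
  pro <- chip & !fi & abs(d) <= cfg$pro_max_dist
  dis <- chip & !fi & abs(d) > cfg$pro_max_dist & abs(d) <= cfg$dis_max_dist
  out[pro] <- "Pro"
  out[dis] <- "Dis"
  out
}

#' Annotate merged peaks into CRE classes
#'
#' Applies the evidence filter, assigns each surviving peak to its closest
#' gene, tests the summit for first-intron overlap, and classifies the
#' peak. Peaks classified `unannotated` are kept in the output so the
#' caller can report them.
#'
#' @param merged Merged peak tibble (from [merge_peaks()]).
#' @param gm A [gene_models()] object.
#' @param cfg [analysis_config()].
#' @return CRE annotation tibble with `region` key, coordinates, `summit`,
#'   `cre_class`, `gene_id`, `signed_distance`, `first_intron_overlap`,
#'   `n_sample_evidence`, `assay_evidence`.
#' @export
annotate_cres <- function(merged, gm, cfg = analysis_config()) {
  kept <- evidence_filter(merged, cfg)
  kept <- assign_closest_gene(kept, gm)
  if (nrow(kept) == 0) {
    return(tibble(region = character(), chrom = character(),
                  start = integer(), end = integer(), summit = integer(),
                  cre_class = character(), gene_id = character(),
                  signed_distance = integer(),
                  first_intron_overlap = logical(),
                  n_sample_evidence = integer(),
                  assay_evidence = character()))
  }
  fi <- first_introns(gm)
  summit_abs <- kept$start + kept$summit
  fi_idx <- match(kept$gene_id, fi$gene_id)
  in_fi <- !is.na(fi_idx) &
    summit_abs >= fi$start[fi_idx] & summit_abs < fi$end[fi_idx]
  in_fi[is.na(in_fi)] <- FALSE
  has_chip <- evidence_has(kept$assay_evidence, "CHIP")
  cls <- classify_cre(kept$signed_distance, has_chip, in_fi, cfg)
  tibble(
    region = region_keys(kept),
    chrom = kept$chrom, start = kept$start, end = kept$end,
    summit = kept$summit,
    cre_class = cls,
    gene_id = kept$gene_id,
    signed_distance = kept$signed_distance,
    first_intron_overlap = in_fi,
    n_sample_evidence = evidence_size(kept$sample_evidence),
    assay_evidence = kept$assay_evidence
  )
}
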