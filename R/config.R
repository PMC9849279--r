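#' Analysis configuration
#'
#' Collects every numeric threshold used across the pipeline in a single
#' validated object, so that each stage reads its cutoffs from one place.
#'
#' @param nfr_max_insert Maximum fragment (insert) size in bp kept when
#'   selecting nucleosome-free-region fragments (default 100).
#' @param tn5_shift_plus Shift applied to plus-strand Tn5 cut sites, bp
#'   (default +4).
#' @param tn5_shift_minus Shift applied to minus-strand Tn5 cut sites, bp
#'   (default -5).
#' @param acr_fdr FDR cutoff for pole-specific accessible chromatin regions
#'   (default 0.05).
#' @param acr_fc Linear fold-change cutoff for pole-specific ACRs (default 2;
#'   interpreted as |log2 fold change| > log2(acr_fc)).
#' @param cp_max_upstream Core promoters lie strictly less than this many bp
#'   upstream of a TSS (default 100).
#' @param pp_upstream_range Proximal promoters lie between these upstream
#'   distances (bp) from a TSS, inclusive (default c(100, 500)).
#' @param pro_max_dist Proximal enhancers lie within this absolute distance of
#'   a TSS (default 2000).
#' @param dis_max_dist Distal enhancers lie between `pro_max_dist` and this
#'   absolute distance of a TSS (default 10000).
#' @param min_sample_evidence Minimum number of samples a merged peak must be
#'   called in to enter CRE annotation (default 2).
#' @param motif_adj_p Adjusted p-value cutoff for motif over-representation
#'   (default 0.05).
#' @param motif_scan_p Per-window match p-value cutoff for PWM scanning
#'   (default 1e-4).
#' @param de_fdr FDR cutoff for differential expression (default 0.05).
#' @param de_lfc log2 fold-change cutoff for differential expression
#'   (default 0.5).
#' @param cpm_min Counts-per-million threshold for the expression filter
#'   (default 1).
#' @param peak_window,peak_step Window width and step (bp) for the sliding
#'   Poisson peak caller (defaults 150 and 50).
#' @param peak_qvalue BH-adjusted q-value cutoff for significant windows
#'   (default 0.05).
#' @param peak_local_bg Spans (bp) over which local Poisson rates are
#'   estimated; the largest of the genome-wide and these local rates is used
#'   (default c(5000, 10000)).
#' @param peak_trim_frac When refining peak boundaries, positions with
#'   coverage below this fraction of the peak maximum are trimmed
#'   (default 0.25).
#' @param min_chip_mean Minimum mean normalized H3K27ac count for a region to
#'   count as carrying ChIP evidence (default 20).
#' @param rng_seed Integer seed controlling every stochastic step
#'   (default 1).
#'
#' @return A list with class `"wr_config"`.
#' @examples
#' cfg <- analysis_config()
#' cfg$nfr_max_insert
#' @export
analysis_config <- function(nfr_max_insert = 100,
                            tn5_shift_plus = 4L,
                            tn5_shift_minus = -5L,
                            acr_fdr = 0.05,
                            acr_fc = 2,
                            cp_max_upstream = 100,
                            pp_upstream_range = c(100, 500),
                            pro_max_dist = 2000,
                            dis_max_dist = 10000,
                            min_sample_evidence = 2L,
                            motif_adj_p = 0.05,
                            motif_scan_p = 1e-4,
                            de_fdr = 0.05,
                            de_lfc = 0.5,
                            cpm_min = 1,
                            peak_window = 150L,
                            peak_step = 50L,
                            peak_qvalue = 0.05,
                            peak_local_bg = c(5000, 10000),
                            peak_trim_frac = 0.25,
                            min_chip_mean = 20,
                            rng_seed = 1L) {
  cfg <- list(
    nfr_max_insert = nfr_max_insert,
    tn5_shift_plus = as.integer(tn5_shift_plus),
    tn5_shift_minus = as.integer(tn5_shift_minus),
    acr_fdr = acr_fdr,
    acr_fc = acr_fc,
    cp_max_upstream = cp_max_upstream,
    pp_upstream_range = pp_upstream_range,
    pro_max_dist = pro_max_dist,
    dis_max_dist = dis_max_dist,
    min_sample_evidence = as.integer(min_sample_evidence),
    motif_adj_p = motif_adj_p,
    motif_scan_p = motif_scan_p,
    de_fdr = de_fdr,
    de_lfc = de_lfc,
    cpm_min = cpm_min,
    peak_window = as.integer(peak_window),
    peak_step = as.integer(peak_step),
    peak_qvalue = peak_qvalue,
    peak_local_bg = peak_local_bg,
    peak_trim_frac = peak_trim_frac,
    min_chip_mean = min_chip_mean,
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "wr_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "wr_config"))
  pos <- c(
    "nfr_max_insert", "acr_fdr", "acr_fc", "cp_max_upstream",
    "pro_max_dist", "dis_max_dist", "min_sample_evidence", "motif_adj_p",
    "motif_scan_p", "de_fdr", "de_lfc", "cpm_min", "peak_window",
    "peak_step", "peak_qvalue", "peak_trim_frac"
  )
  for (nm in pos) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || cfg[[nm]] <= 0) {
      stop("config field '", nm, "' must be a single positive number", call. = FALSE)
    }
  }
  if (length(cfg$pp_upstream_range) != 2 ||
      cfg$pp_upstream_range[1] >= cfg$pp_upstream_range[2]) {
    stop("pp_upstream_range must be an increasing pair of distances", call. = FALSE)
  }
  if (cfg$cp_max_upstream > cfg$pp_upstream_range[1]) {
    stop("cp_max_upstream must not exceed the lower proximal-promoter bound",
         call. = FALSE)
  }
  if (cfg$pro_max_dist >= cfg$dis_max_dist) {
    stop("pro_max_dist must be smaller than dis_max_dist", call. = FALSE)
  }
  if (any(cfg$peak_local_bg <= 0)) {
    stop("peak_local_bg spans must be positive", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.wr_config <- function(x, ...) {
  cat("<wr_config>\n")
  flat <- vapply(x, function(v) paste(format(v), collapse = ", "), character(1))
  cat(paste0("  ", format(names(flat)), " : ", flat, collapse = "\n"), "\n")
  invisible(x)
}
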