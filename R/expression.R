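#' Counts per million
#' @param counts Gene x sample count matrix.
#' @param lib_sizes Optional named library sizes; defaults to column sums.
#' @return Matrix of CPM values.
#' @export
cpm <- function(counts, lib_sizes = NULL) {
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  sweep(counts, 2, lib_sizes, "/") * 1e6
}

#' Filter lowly expressed genes by CPM
#'
#' Keeps genes whose CPM reaches `cpm_min` in at least as many samples as
#' the smallest group.
#'
#' @param counts Gene x sample count matrix with gene rownames.
#' @param groups Character vector of group labels, one per column.
#' @param cfg [analysis_config()]; `cpm_min` is used (default 1).
#' @return Filtered count matrix.
#' @export
cpm_filter <- function(counts, groups, cfg = analysis_config()) {
  if (nrow(counts) == 0) return(counts)
  stopifnot(length(groups) == ncol(counts))
  min_group <- min(table(groups))
  keep <- rowSums(cpm(counts) >= cfg$cpm_min) >= min_group
  counts[keep, , drop = FALSE]
}

# Newton solve of trigamma(x) = y (vectorised), for the prior df fit
trigamma_inverse <- function(y) {
  out <- rep(Inf, length(y))
  pos <- which(y > 1e-8)
  if (length(pos) == 0) return(out)
  x <- 0.5 + 1 / y[pos]
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y[pos]) / psigamma(x, 2)
    x <- x + dif
    if (max(abs(dif / x)) < 1e-8) break
  }
  out[pos] <- x
  out
}

#' Moderated t-test for differential expression on log2-CPM
#'
#' An empirical-Bayes moderated two-group t-test: per-gene log2-CPM values
#' (0.5-count offset) are compared between groups, and the per-gene
#' variance is shrunk toward a prior estimated by method of moments across
#' genes. With prior degrees of freedom `d0` and prior variance `s0^2`, the
#' posterior variance is `(d0 s0^2 + d s^2) / (d0 + d)` and the moderated t
#' has `d0 + d` degrees of freedom. Significance requires
#' `q < de_fdr` and `|log2fc| > de_lfc`.
#'
#' @param counts Gene x sample count matrix (CPM-filtered), gene rownames.
#' @param group_a,group_b Character vectors of column names (at least two
#'   replicates each).
#' @param cfg [analysis_config()].
#' @param prior_df Override for the prior degrees of freedom (e.g. `Inf`
#'   forces complete pooling to the prior variance); `NULL` (default)
#'   estimates it from the data.
#' @return Tibble `gene_id`, `mean_cpm`, `log2fc` (B over A),
#'   `moderated_t`, `df`, `p`, `q`, `significant`.
#' @export
moderated_de_test <- function(counts, group_a, group_b,
                              cfg = analysis_config(), prior_df = NULL) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 replicates", call. = FALSE)
  }
  stopifnot(all(c(group_a, group_b) %in% colnames(counts)),
            !is.null(rownames(counts)))
  cols <- c(group_a, group_b)
  lib <- colSums(counts)[cols]
  logcpm <- log2(sweep(counts[, cols, drop = FALSE] + 0.5, 2, lib + 1, "/")
                 * 1e6)
  A <- logcpm[, group_a, drop = FALSE]
  B <- logcpm[, group_b, drop = FALSE]
  na <- length(group_a); nb <- length(group_b)
  d <- na + nb - 2
  mA <- rowMeans(A); mB <- rowMeans(B)
  s2 <- (apply(A, 1, stats::var) * (na - 1) +
           apply(B, 1, stats::var) * (nb - 1)) / d

  # method-of-moments fit of the scaled inverse-chi-square prior
  z <- log(pmax(s2, 1e-12))
  e <- z - digamma(d / 2) + log(d / 2)
  d0 <- if (!is.null(prior_df)) prior_df else {
    resid_var <- stats::var(e) - trigamma(d / 2)
    if (is.na(resid_var) || resid_var <= 0) Inf
    else 2 * trigamma_inverse(resid_var)
  }
  s0_sq <- if (is.infinite(d0) || d0 == 0) {
    exp(mean(e))
  } else {
    exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }

  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2))
             else if (d0 == 0) s2
             else (d0 * s0_sq + d * s2) / (d0 + d)
  se <- sqrt(s2_post * (1 / na + 1 / nb))
  tstat <- (mB - mA) / se
  df_total <- d0 + d
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  q <- stats::p.adjust(p, method = "BH")
  lfc <- mB - mA

  tibble(
    gene_id = rownames(counts),
    mean_cpm = unname(rowMeans(cpm(counts[, cols, drop = FALSE]))),
    log2fc = unname(lfc),
    moderated_t = unname(tstat),
    df = df_total,
    p = unname(p),
    q = unname(q),
    significant = unname(q < cfg$de_fdr & abs(lfc) > cfg$de_lfc)
  )
}

#' Integrate differential expression with motif-based gene sets
#'
#' Collects the downregulated gene set (significant with negative fold
#' change) and its intersections with TCF-in-enhancer, TCF-in-promoter and
#' FoxG motif gene sets plus any number of external gene lists. Gene
#' identifiers can be harmonised through an optional two-column mapping
#' (`from`, `to`); unmappable identifiers are excluded and counted.
#'
#' @param de Result of [moderated_de_test()].
#' @param tcf_enhancer_genes,tcf_promoter_genes,foxg_genes Character gene
#'   sets from [genes_with_motif()].
#' @param external_lists Named list of character gene sets.
#' @param id_map Optional tibble with `from`, `to` columns applied to the
#'   external lists.
#' @return List with `downregulated`, `tcf_enhancer_down`,
#'   `tcf_promoter_down`, `foxg_down`, `external` (named list of
#'   intersections), `counts` (named integer summary) and `n_unmapped`.
#' @export
integrate_targets <- function(de, tcf_enhancer_genes,
                              tcf_promoter_genes = character(),
                              foxg_genes = character(),
                              external_lists = list(),
                              id_map = NULL) {
  down <- sort(de$gene_id[de$significant & de$log2fc < 0])
  n_unmapped <- 0L
  if (!is.null(id_map)) {
    stopifnot(all(c("from", "to") %in% names(id_map)))
    external_lists <- lapply(external_lists, function(g) {
      mapped <- id_map$to[match(g, id_map$from)]
      n_unmapped <<- n_unmapped + sum(is.na(mapped))
      mapped[!is.na(mapped)]
    })
  }
  external <- lapply(external_lists, function(g) intersect(down, sort(g)))
  out <- list(
    downregulated = down,
    tcf_enhancer_down = intersect(down, tcf_enhancer_genes),
    tcf_promoter_down = intersect(down, tcf_promoter_genes),
    foxg_down = intersect(down, foxg_genes),
    external = external,
    n_unmapped = n_unmapped
  )
  out$counts <- c(
    n_downregulated = length(down),
    n_tcf_enhancer_down = length(out$tcf_enhancer_down),
    n_tcf_promoter_down = length(out$tcf_promoter_down),
    n_foxg_down = length(out$foxg_down),
    vapply(external, length, integer(1))
  )
  out
}
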