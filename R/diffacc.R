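#' Negative-binomial Wald test for differential accessibility
#'
#' Counts are scaled to effective library size, a per-region negative
#' binomial dispersion is estimated by method of moments and regularised
#' toward a monotone trend on the mean, and a Wald test is performed on the
#' log2 fold change of group B over group A. P-values are BH-adjusted
#' across regions. The NB parameterisation is mean `m` with dispersion
#' `alpha` and variance `m + alpha * m^2`.
#'
#' @param counts Integer matrix, regions x samples, with region rownames.
#' @param group_a,group_b Character vectors of column names (at least two
#'   replicates each).
#' @param lib_sizes Optional named per-sample library sizes (genome-wide
#'   totals); when absent, effective sizes are estimated from the matrix by
#'   the median-of-ratios method, which is robust to a minority of truly
#'   differential regions.
#' @return Tibble `region`, `mean_a`, `mean_b`, `log2fc` (B over A),
#'   `dispersion`, `p`, `q`, `positive_a`, `positive_b` (replicates with
#'   raw count > 0).
#' @export
nb_diff_test <- function(counts, group_a, group_b, lib_sizes = NULL) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 replicates", call. = FALSE)
  }
  stopifnot(all(c(group_a, group_b) %in% colnames(counts)))
  cols <- c(group_a, group_b)
  if (is.null(lib_sizes)) {
    sf <- median_of_ratios(counts[, cols, drop = FALSE])
  } else {
    stopifnot(all(cols %in% names(lib_sizes)))
    lib_sizes <- lib_sizes[cols]
    if (any(lib_sizes <= 0)) {
      stop("library sizes must be positive", call. = FALSE)
    }
    sf <- lib_sizes / exp(mean(log(lib_sizes)))
  }
  norm <- sweep(counts[, cols, drop = FALSE], 2, sf, "/")
  na <- length(group_a); nb <- length(group_b)
  A <- norm[, group_a, drop = FALSE]
  B <- norm[, group_b, drop = FALSE]
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- apply(A, 1, stats::var); vB <- apply(B, 1, stats::var)
  s2 <- (vA * (na - 1) + vB * (nb - 1)) / (na + nb - 2)
  mbar <- (mA * na + mB * nb) / (na + nb)
  # method-of-moments: E[s2] = m + alpha m^2; the denominator uses the
  # unbiased estimate of m^2 (mbar^2 - var(mbar)) to avoid downward bias
  msq <- pmax(mbar^2 - s2 / (na + nb), mbar)
  alpha_mom <- pmax((s2 - mbar) / pmax(msq, 1e-8), 0)

  alpha <- fit_dispersion_trend(mbar, alpha_mom)

  pseudo <- 0.5
  lfc <- log2((mB + pseudo) / (mA + pseudo))
  # delta-method variance of the log2 ratio, evaluated at the pooled mean:
  # using the common mean decouples the variance estimate from the observed
  # fold change, which keeps the Wald statistic calibrated at small n
  m0 <- pmax(mbar, pseudo)
  ln2sq <- log(2)^2
  vl <- (m0 + alpha * m0^2) / (m0^2 * ln2sq) * (1 / na + 1 / nb)
  z <- lfc / sqrt(vl)
  p <- 2 * stats::pnorm(-abs(z))

  allzero <- rowSums(counts[, cols, drop = FALSE]) == 0
  p[allzero] <- 1
  lfc[allzero] <- 0

  tibble(
    region = rownames(counts),
    mean_a = unname(mA), mean_b = unname(mB),
    log2fc = unname(lfc),
    dispersion = unname(alpha),
    p = unname(p),
    q = unname(stats::p.adjust(p, method = "BH")),
    positive_a = unname(rowSums(counts[, group_a, drop = FALSE] > 0)),
    positive_b = unname(rowSums(counts[, group_b, drop = FALSE] > 0))
  )
}

# DESeq-style size factors: median across regions of the ratio to the
# per-region geometric mean, normalised to geometric mean 1
median_of_ratios <- function(m) {
  logs <- log(m)
  logs[!is.finite(logs)] <- NA
  ref <- rowMeans(logs)
  usable <- is.finite(ref)
  if (!any(usable)) return(rep(1, ncol(m)))
  lsf <- apply(logs[usable, , drop = FALSE] - ref[usable], 2,
               stats::median, na.rm = TRUE)
  sf <- exp(lsf - mean(lsf))
  sf[!is.finite(sf) | sf <= 0] <- 1
  sf
}

# Trended, monotone-regularised dispersion: lowess of the method-of-moments
# estimates on log mean, constrained to be non-increasing in the mean.
# With few regions the pooled (count-weighted) estimate is used instead.
fit_dispersion_trend <- function(mbar, alpha_mom) {
  n <- length(mbar)
  informative <- mbar > 1
  if (n < 50 || sum(informative) < 25) {
    pooled <- if (any(informative)) {
      sum(alpha_mom[informative] * mbar[informative]) /
        sum(mbar[informative])
    } else 0
    return(rep(max(pooled, 1e-8), n))
  }
  lx <- log(mbar + 1)
  # iter = 0: the MoM estimates are strongly right-skewed, and the robust
  # iterations would track a trimmed mean and underestimate the dispersion
  fit <- stats::lowess(lx[informative], alpha_mom[informative], f = 0.5,
                       iter = 0)
  # interpolate the smooth onto all regions
  trend <- stats::approx(fit$x, fit$y, xout = lx, rule = 2,
                         ties = mean)$y
  # monotone non-increasing in mean: isotonic regression on -trend vs lx
  ord <- order(lx)
  iso <- stats::isoreg(lx[ord], -trend[ord])
  trend[ord] <- -iso$yf
  pmax(trend, 1e-8)
}

#' Select pole-specific accessible chromatin regions
#'
#' Regions significant at the ACR FDR with an absolute log2 fold change
#' above `log2(acr_fc)` are partitioned by sign: negative fold changes
#' (higher in group A) go to the first set, positive (higher in group B) to
#' the second. For the anterior-vs-posterior comparison with A = anterior,
#' the sets are anterior- and posterior-specific ACRs.
#'
#' @param diff Result of [nb_diff_test()].
#' @param cfg [analysis_config()]; `acr_fdr` and `acr_fc` are used.
#' @return List with elements `a_specific` and `b_specific` (tibbles).
#' @export
select_pole_acrs <- function(diff, cfg = analysis_config()) {
  lfc_cut <- log2(cfg$acr_fc)
  sig <- diff[diff$q < cfg$acr_fdr & abs(diff$log2fc) > lfc_cut, ,
              drop = FALSE]
  list(
    a_specific = sig[sig$log2fc < 0, , drop = FALSE],
    b_specific = sig[sig$log2fc > 0, , drop = FALSE]
  )
}

#' Split ACRs into putative enhancers and promoter-like elements
#'
#' ACRs are crossmatched against H3K27ac ChIP signal: regions where the
#' ATAC-vs-ChIP comparison is significant (ATAC excess over the enhancer
#' mark) are assumed promoter-like; non-significant regions that carry ChIP
#' evidence are marked putative enhancers. Non-significant regions without
#' ChIP evidence fall in neither set and are returned separately.
#'
#' @param acrs Tibble of ACRs with a `region` column.
#' @param chip_diff [nb_diff_test()] result on the same regions comparing
#'   ATAC samples (group A) against H3K27ac samples (group B).
#' @param chip_evidence Character vector of region keys carrying ChIP
#'   evidence.
#' @param q_cut Significance cutoff for the crossmatch (default 0.05).
#' @return List `putative_enhancers`, `promoter_like`, `unassigned`.
#' @export
split_enhancer_promoter <- function(acrs, chip_diff, chip_evidence,
                                    q_cut = 0.05) {
  if (nrow(acrs) == 0) {
    return(list(putative_enhancers = acrs, promoter_like = acrs,
                unassigned = acrs))
  }
  missing <- setdiff(acrs$region, chip_diff$region)
  if (length(missing) > 0) {
    stop("regions missing from ChIP crossmatch: ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  }
  q <- chip_diff$q[match(acrs$region, chip_diff$region)]
  significant <- q < q_cut
  has_chip <- acrs$region %in% chip_evidence
  list(
    putative_enhancers = acrs[!significant & has_chip, , drop = FALSE],
    promoter_like = acrs[significant, , drop = FALSE],
    unassigned = acrs[!significant & !has_chip, , drop = FALSE]
  )
}

ACCESSIBILITY_STATES <- c("ACCESSIBLE", "MORE_ACCESSIBLE", "LESS_ACCESSIBLE",
                          "NON_ACCESSIBLE", "UNCLASSIFIED")

#' Classify the RNAi "second round" accessibility state
#'
#' Decision table over the second-round differential result for a region
#' (wild-type pole samples vs RNAi samples) and the number of replicates
#' with positive raw counts in each group:
#'
#' * not significant and both RNAi replicates positive: `ACCESSIBLE`
#' * significant, both groups fully positive, fold change above the
#'   wild type: `MORE_ACCESSIBLE`
#' * significant, both groups fully positive, fold change below the
#'   wild type: `LESS_ACCESSIBLE`
#' * significant, wild type fully positive, fewer than two positive RNAi
#'   replicates: `NON_ACCESSIBLE`
#' * anything else: `UNCLASSIFIED`
#'
#' @param significant Logical; second-round q-value below the cutoff.
#' @param log2fc log2 fold change of RNAi over wild type.
#' @param wt_positive,rnai_positive Number of replicates (0-2) with raw
#'   count > 0 in the wild-type and RNAi groups.
#' @return Character vector of states (vectorised over inputs).
#' @export
classify_rnai_state <- function(significant, log2fc, wt_positive,
                                rnai_positive) {
  n <- max(length(significant), length(log2fc), length(wt_positive),
           length(rnai_positive))
  significant <- rep_len(as.logical(significant), n)
  log2fc <- rep_len(log2fc, n)
  wt_positive <- rep_len(as.integer(wt_positive), n)
  rnai_positive <- rep_len(as.integer(rnai_positive), n)
  if (any(!wt_positive %in% 0:2) || any(!rnai_positive %in% 0:2)) {
    stop("replicate positivity counts must be 0, 1 or 2", call. = FALSE)
  }
  state <- rep("UNCLASSIFIED", n)
  state[!significant & rnai_positive == 2L] <- "ACCESSIBLE"
  both <- significant & wt_positive == 2L & rnai_positive == 2L
  state[both & log2fc > 0] <- "MORE_ACCESSIBLE"
  state[both & log2fc < 0] <- "LESS_ACCESSIBLE"
  state[significant & wt_positive == 2L & rnai_positive < 2L] <-
    "NON_ACCESSIBLE"
  state
}

#' Apply the second-round classifier to a differential result
#'
#' @param diff [nb_diff_test()] result where group A holds the wild-type
#'   pole replicates and group B the RNAi replicates.
#' @param q_cut Significance cutoff (default 0.05).
#' @return Tibble `region`, `state`.
#' @export
second_round_states <- function(diff, q_cut = 0.05) {
  tibble(
    region = diff$region,
    state = classify_rnai_state(diff$q < q_cut, diff$log2fc,
                                diff$positive_a, diff$positive_b)
  )
}

#' Summarise accessibility states as fractions
#'
#' Fractions are taken over classified regions and sum to 1; the number of
#' `UNCLASSIFIED` regions is reported separately.
#'
#' @param states Character vector of states from [classify_rnai_state()].
#' @return List with `fractions` (named numeric over the four classified
#'   states present), `n_classified` and `n_unclassified`.
#' @export
summarize_states <- function(states) {
  if (length(states) == 0) stop("no states to summarise", call. = FALSE)
  stopifnot(all(states %in% ACCESSIBILITY_STATES))
  classified <- states[states != "UNCLASSIFIED"]
  frac <- if (length(classified) > 0) {
    tab <- table(factor(classified, levels = ACCESSIBILITY_STATES[1:4]))
    as.numeric(tab) / length(classified)
  } else rep(0, 4)
  list(
    fractions = stats::setNames(frac, ACCESSIBILITY_STATES[1:4]),
    n_classified = length(classified),
    n_unclassified = sum(states == "UNCLASSIFIED")
  )
}
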