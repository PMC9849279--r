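null_rna <- function(n, seed, reps = 3, meanlog = log(300), disp = 0.02) {
  withr::with_seed(seed, {
    mu <- stats::rlnorm(n, meanlog, 0.8)
    m <- matrix(stats::rnbinom(n * 2 * reps, mu = rep(mu, 2 * reps),
                               size = 1 / disp), n, 2 * reps)
    dimnames(m) <- list(sprintf("g%05d", seq_len(n)),
                        c(paste0("a", seq_len(reps)),
                          paste0("b", seq_len(reps))))
    m
  })
}

test_that("CPM filter removes genes below 1 CPM in too many samples", {
  counts <- matrix(c(5, 5, 5, 5,
                     4000, 3000, 4000, 5000), 2, 4, byrow = TRUE,
                   dimnames = list(c("low", "high"),
                                   c("a1", "a2", "b1", "b2")))
  # library size ~ 1e4 -> "low" is ~500 CPM; scale libs up via a third gene
  counts <- rbind(counts, big = c(1e7, 1e7, 1e7, 1e7))
  out <- cpm_filter(counts, c("A", "A", "B", "B"))
  expect_true("high" %in% rownames(out))
  expect_false("low" %in% rownames(out))  # ~0.5 CPM everywhere
  expect_equal(nrow(cpm_filter(counts[0, , drop = FALSE],
                               c("A", "A", "B", "B"))), 0)
})

test_that("moderated t is calibrated on a null simulation", {
  cnt <- null_rna(10000, seed = 1)
  de <- moderated_de_test(cnt, c("a1", "a2", "a3"), c("b1", "b2", "b3"))
  expect_gt(mean(de$p < 0.05), 0.04)
  expect_lt(mean(de$p < 0.05), 0.06)
  expect_true(all(de$q >= de$p - 1e-12))
})

test_that("planted downregulation is detected with high sensitivity", {
  withr::with_seed(2, {
    n <- 2000
    mu <- stats::rlnorm(n, log(300), 0.8)
    fc <- rep(1, n); fc[1:100] <- 0.5  # log2fc = -1
    cnt <- cbind(
      matrix(stats::rnbinom(n * 3, mu = rep(mu, 3), size = 50), n, 3),
      matrix(stats::rnbinom(n * 3, mu = rep(mu * fc, 3), size = 50), n, 3))
    dimnames(cnt) <- list(sprintf("g%04d", 1:n),
                          c("a1", "a2", "a3", "b1", "b2", "b3"))
    de <- moderated_de_test(cnt, c("a1", "a2", "a3"), c("b1", "b2", "b3"))
    hit <- de$significant & de$log2fc < 0
    expect_gt(mean(hit[1:100]), 0.8)
    expect_lt(mean(hit[-(1:100)]), 0.01)
  })
})

test_that("forcing infinite prior df reproduces the pooled-variance z-test", {
  cnt <- null_rna(500, seed = 7)
  de_inf <- moderated_de_test(cnt, c("a1", "a2", "a3"), c("b1", "b2", "b3"),
                              prior_df = Inf)
  expect_true(all(is.infinite(de_inf$df)))
  # all genes share one variance: the common-variance estimate is the
  # bias-corrected geometric mean of the per-gene variances (df = 4)
  lib <- colSums(cnt)
  logcpm <- log2(sweep(cnt + 0.5, 2, lib + 1, "/") * 1e6)
  delta <- rowMeans(logcpm[, 4:6]) - rowMeans(logcpm[, 1:3])
  s2 <- (apply(logcpm[, 1:3], 1, var) + apply(logcpm[, 4:6], 1, var)) / 2
  s0 <- exp(mean(log(s2)) - digamma(2) + log(2))
  z <- delta / sqrt(s0 * (2 / 3))
  expect_equal(de_inf$moderated_t, unname(z), tolerance = 1e-8)
  expect_equal(de_inf$p, unname(2 * pnorm(-abs(z))), tolerance = 1e-8)
})

test_that("moderated t lies between the raw t and the prior-variance z", {
  cnt <- null_rna(500, seed = 8)
  de <- moderated_de_test(cnt, c("a1", "a2", "a3"), c("b1", "b2", "b3"))
  de0 <- moderated_de_test(cnt, c("a1", "a2", "a3"), c("b1", "b2", "b3"),
                           prior_df = 0)  # no shrinkage: raw t
  deI <- moderated_de_test(cnt, c("a1", "a2", "a3"), c("b1", "b2", "b3"),
                           prior_df = Inf)
  lo <- pmin(abs(de0$moderated_t), abs(deI$moderated_t))
  hi <- pmax(abs(de0$moderated_t), abs(deI$moderated_t))
  expect_true(all(abs(de$moderated_t) >= lo - 1e-9))
  expect_true(all(abs(de$moderated_t) <= hi + 1e-9))
})

test_that("moderated t is invariant to sample order and library scaling", {
  cnt <- null_rna(300, seed = 9)
  de1 <- moderated_de_test(cnt, c("a1", "a2", "a3"), c("b1", "b2", "b3"))
  de2 <- moderated_de_test(cnt[, c(6:4, 3:1)], c("a3", "a2", "a1"),
                           c("b3", "b2", "b1"))
  expect_equal(de1$moderated_t, de2$moderated_t)
  de3 <- moderated_de_test(cnt * 4L, c("a1", "a2", "a3"),
                           c("b1", "b2", "b3"))
  expect_equal(de1$log2fc, de3$log2fc, tolerance = 0.02)
})

test_that("moderated t agrees with limma's empirical Bayes machinery", {
  skip_if_not_installed("limma")
  cnt <- null_rna(1000, seed = 10)
  de <- moderated_de_test(cnt, c("a1", "a2", "a3"), c("b1", "b2", "b3"))
  lib <- colSums(cnt)
  logcpm <- log2(sweep(cnt + 0.5, 2, lib + 1, "/") * 1e6)
  design <- cbind(1, rep(c(0, 1), each = 3))
  fit <- limma::eBayes(limma::lmFit(logcpm, design))
  expect_equal(de$moderated_t, unname(fit$t[, 2]), tolerance = 0.02)
  expect_gt(cor(de$p, fit$p.value[, 2]), 0.999)
})

test_that("target integration intersects gene sets as reported", {
  de <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4"),
    log2fc = c(-2, -1, 2, -1.5),
    significant = c(TRUE, TRUE, TRUE, FALSE))
  rep <- integrate_targets(de, tcf_enhancer_genes = c("g1", "g3"),
                           tcf_promoter_genes = "g9",
                           foxg_genes = c("g2"),
                           external_lists = list(wound = c("g1", "g2")))
  expect_equal(rep$downregulated, c("g1", "g2"))
  expect_equal(rep$tcf_enhancer_down, "g1")   # g3 is upregulated
  expect_equal(rep$tcf_promoter_down, character(0))
  expect_equal(rep$foxg_down, "g2")
  expect_equal(rep$external$wound, c("g1", "g2"))
  expect_equal(unname(rep$counts["n_downregulated"]), 2L)
  # disjoint sets give empty intersections
  rep2 <- integrate_targets(de, tcf_enhancer_genes = "gX")
  expect_equal(rep2$tcf_enhancer_down, character(0))
  # unmappable external identifiers are excluded and counted
  rep3 <- integrate_targets(de, tcf_enhancer_genes = "g1",
                            external_lists = list(ext = c("G1", "G9")),
                            id_map = tibble::tibble(from = "G1", to = "g1"))
  expect_equal(rep3$external$ext, "g1")
  expect_equal(rep3$n_unmapped, 1L)
})
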