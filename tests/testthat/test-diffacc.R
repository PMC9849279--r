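make_null_counts <- function(n, seed, mulog = log(100), disp = 0.1) {
  withr::with_seed(seed, {
    mu <- stats::rlnorm(n, mulog, 1)
    matrix(stats::rnbinom(n * 4, mu = rep(mu, 4), size = 1 / disp), n, 4,
           dimnames = list(sprintf("chr1:%d-%d", (1:n) * 100,
                                   (1:n) * 100 + 50),
                           c("a1", "a2", "b1", "b2")))
  })
}

test_that("NB test is calibrated on a null simulation", {
  cnt <- make_null_counts(5000, seed = 1)
  d <- nb_diff_test(cnt, c("a1", "a2"), c("b1", "b2"))
  expect_gt(mean(d$p < 0.05), 0.03)
  expect_lt(mean(d$p < 0.05), 0.07)
  expect_true(all(d$q >= d$p - 1e-12))
})

test_that("NB test flags a clear single-region difference", {
  cnt <- rbind(matrix(c(0, 0, 50, 60), 1,
                      dimnames = list("chr1:0-100",
                                      c("a1", "a2", "b1", "b2"))),
               make_null_counts(200, seed = 3))
  d <- nb_diff_test(cnt, c("a1", "a2"), c("b1", "b2"),
                    lib_sizes = c(a1 = 1e5, a2 = 1e5, b1 = 1e5, b2 = 1e5))
  r1 <- d[d$region == "chr1:0-100", ]
  expect_lt(r1$q, 0.05)
  expect_gt(r1$log2fc, 1)
  expect_equal(r1$positive_a, 0)
  expect_equal(r1$positive_b, 2)
})

test_that("NB test handles degenerate input and bad groups", {
  cnt <- matrix(0L, 2, 4, dimnames = list(c("r1", "r2"),
                                          c("a1", "a2", "b1", "b2")))
  cnt[2, ] <- c(5L, 6L, 7L, 8L)
  d <- nb_diff_test(cnt, c("a1", "a2"), c("b1", "b2"))
  expect_equal(d$p[d$region == "r1"], 1)
  expect_equal(d$log2fc[d$region == "r1"], 0)
  expect_error(nb_diff_test(cnt, "a1", c("b1", "b2")), "2 replicates")
})

test_that("NB p-values are invariant to relabeling replicates within groups", {
  cnt <- make_null_counts(500, seed = 5)
  d1 <- nb_diff_test(cnt, c("a1", "a2"), c("b1", "b2"))
  d2 <- nb_diff_test(cnt, c("a2", "a1"), c("b2", "b1"))
  expect_equal(d1$p, d2$p)
  expect_equal(d1$log2fc, d2$log2fc)
})

test_that("NB test agrees with DESeq2 on strong effects", {
  skip_if_not_installed("DESeq2")
  withr::with_seed(9, {
    n <- 300
    mu <- stats::rlnorm(n, log(150), 0.7)
    fc <- rep(1, n); fc[1:30] <- 6
    cnt <- cbind(
      matrix(stats::rnbinom(n * 2, mu = rep(mu, 2), size = 10), n, 2),
      matrix(stats::rnbinom(n * 2, mu = rep(mu * fc, 2), size = 10), n, 2))
    dimnames(cnt) <- list(sprintf("r%d", 1:n), c("a1", "a2", "b1", "b2"))
    d <- nb_diff_test(cnt, c("a1", "a2"), c("b1", "b2"))
    dds <- DESeq2::DESeqDataSetFromMatrix(
      cnt, data.frame(cond = factor(c("A", "A", "B", "B"))), ~cond)
    dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
    res <- DESeq2::results(dds)
    ours <- d$q < 0.05 & abs(d$log2fc) > 1
    theirs <- !is.na(res$padj) & res$padj < 0.05 & abs(res$log2FoldChange) > 1
    # the planted regions must be found by both routes
    expect_gt(mean(ours[1:30]), 0.9)
    expect_gt(mean(theirs[1:30]), 0.9)
    # overall decisions agree closely
    expect_gt(mean(ours == theirs), 0.95)
    # effect sizes agree on the planted regions
    expect_lt(median(abs(d$log2fc[1:30] - res$log2FoldChange[1:30])), 0.3)
  })
})

test_that("pole-specific ACR selection applies both cutoffs with sign", {
  diff <- tibble::tibble(
    region = c("r1", "r2", "r3", "r4"),
    log2fc = c(1.5, 0.5, 3, -2),
    q = c(0.04, 0.04, 0.06, 0.01),
    p = q / 2, mean_a = 10, mean_b = 10, dispersion = 0.1,
    positive_a = 2, positive_b = 2
  )
  sel <- select_pole_acrs(diff)
  expect_equal(sel$b_specific$region, "r1")  # q ok, fc ok, positive sign
  expect_equal(sel$a_specific$region, "r4")
  expect_false("r2" %in% c(sel$a_specific$region, sel$b_specific$region))
  expect_false("r3" %in% c(sel$a_specific$region, sel$b_specific$region))
})

test_that("enhancer/promoter split follows the ChIP crossmatch", {
  acrs <- tibble::tibble(region = c("r1", "r2", "r3"))
  chip_diff <- tibble::tibble(region = c("r1", "r2", "r3"),
                              q = c(0.5, 0.001, 0.6))
  out <- split_enhancer_promoter(acrs, chip_diff,
                                 chip_evidence = c("r1"))
  expect_equal(out$putative_enhancers$region, "r1")  # balanced, has ChIP
  expect_equal(out$promoter_like$region, "r2")       # ATAC excess
  expect_equal(out$unassigned$region, "r3")
  expect_error(split_enhancer_promoter(tibble::tibble(region = "rX"),
                                       chip_diff, "r1"), "missing")
  empty <- split_enhancer_promoter(acrs[0, ], chip_diff, "r1")
  expect_equal(nrow(empty$putative_enhancers), 0)
  expect_equal(nrow(empty$promoter_like), 0)
})

test_that("the RNAi state classifier matches a hand-enumerated truth table", {
  # independent oracle: direct transcription of the decision rules,
  # enumerated cell by cell
  oracle <- function(sig, wt, rn, lfc) {
    if (!sig && rn == 2) return("ACCESSIBLE")
    if (sig && wt == 2 && rn == 2 && lfc > 0) return("MORE_ACCESSIBLE")
    if (sig && wt == 2 && rn == 2 && lfc < 0) return("LESS_ACCESSIBLE")
    if (sig && wt == 2 && rn < 2) return("NON_ACCESSIBLE")
    "UNCLASSIFIED"
  }
  grid <- expand.grid(sig = c(TRUE, FALSE), wt = 0:2, rn = 0:2,
                      lfc = c(-1.5, 1.5))
  got <- classify_rnai_state(grid$sig, grid$lfc, grid$wt, grid$rn)
  want <- mapply(oracle, grid$sig, grid$wt, grid$rn, grid$lfc)
  expect_equal(got, unname(want))
  expect_error(classify_rnai_state(TRUE, 1, 3, 2), "positivity")
})

test_that("state fractions sum to one and report unclassified separately", {
  expect_equal(summarize_states(rep("ACCESSIBLE", 4))$fractions[["ACCESSIBLE"]],
               1)
  s <- summarize_states(c("ACCESSIBLE", "MORE_ACCESSIBLE",
                          "LESS_ACCESSIBLE", "NON_ACCESSIBLE",
                          "UNCLASSIFIED"))
  expect_equal(unname(s$fractions), rep(0.25, 4))
  expect_equal(s$n_unclassified, 1)
  expect_equal(sum(s$fractions), 1)
  expect_error(summarize_states(character(0)), "no states")
})

test_that("second-round states recover the planted RNAi truth", {
  sim <- default_sim()
  el <- sim$truth$elements
  keys <- region_keys(el)
  enh <- el$true_class %in% c("FI", "Pro", "Dis")
  for (pole in c("anterior", "posterior")) {
    rows <- which(enh & el$pole == pole)
    wt <- if (pole == "anterior") c("wt_ant_1", "wt_ant_2")
          else c("wt_post_1", "wt_post_2")
    rnai <- if (pole == "anterior") c("notum_ant_1", "notum_ant_2")
            else c("wnt1_post_1", "wnt1_post_2")
    truth_col <- if (pole == "anterior") el$rnai_state_notum
                 else el$rnai_state_wnt1
    d <- nb_diff_test(sim$atac$counts[keys[rows], ], wt, rnai,
                      lib_sizes = sim$atac$lib_sizes)
    st <- second_round_states(d)
    truth <- truth_col[rows]
    sumr <- summarize_states(st$state)
    truth_frac <- prop.table(table(factor(truth,
                                          levels = names(sumr$fractions))))
    expect_lt(max(abs(sumr$fractions - as.numeric(truth_frac))), 0.05)
    expect_gt(mean(st$state == truth), 0.9)
  }
})
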