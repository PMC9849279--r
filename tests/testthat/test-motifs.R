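sym_bg <- c(0.325, 0.175, 0.175, 0.325)

test_that("score threshold matches exhaustive k-mer enumeration", {
  withr::with_seed(31, {
    for (w in c(4L, 6L, 8L)) {
      counts <- matrix(stats::rpois(4 * w, 20) + 1, w, 4)
      pwm <- pwm_matrix("m", counts, background = sym_bg)
      # exhaustive oracle over all 4^w words, on the same 1/1000-bit
      # discretisation grid the DP uses (the grid makes the null exact)
      words <- as.matrix(expand.grid(rep(list(1:4), w)))
      binned <- round(pwm$score / 0.001) * 0.001
      sc <- rowSums(matrix(binned[cbind(rep(1:w, each = nrow(words)),
                                        as.vector(words))],
                           nrow(words), w))
      pr <- exp(rowSums(matrix(log(sym_bg)[as.vector(words)],
                               nrow(words), w)))
      sc <- round(sc, 3)
      ord <- order(sc, decreasing = TRUE)
      scs <- sc[ord]
      cum <- cumsum(pr[ord])
      runs <- rle(scs)
      tail_distinct <- cum[cumsum(runs$lengths)]
      for (p_cut in c(1e-3, 1e-2)) {
        thr <- score_threshold(pwm, p_cut)
        # the smallest score with tail probability <= p_cut sits one bin
        # above the largest achievable score whose tail still exceeds it
        exact <- runs$values[min(which(tail_distinct > p_cut))] + 0.001
        expect_lt(abs(thr - exact), 0.0015)  # within one bin
        # both thresholds admit exactly the same achievable words
        expect_equal(sc >= thr - 1e-9, sc >= exact - 5e-4)
      }
    }
  })
})

test_that("threshold limits behave as documented", {
  pwm <- pwm_matrix("m", matrix(c(90, 4, 3, 3), 4, 4, byrow = TRUE),
                    background = rep(0.25, 4))
  # p_cut = 1 admits everything: threshold is the minimum attainable score
  thr1 <- score_threshold(pwm, 1)
  worst <- sum(apply(pwm$score, 1, min))
  expect_lt(abs(thr1 - worst), 0.005)
  # uniform PWM scores 0 everywhere; at p_cut = 1 the threshold is <= 0
  unif <- pwm_matrix("u", matrix(25, 6, 4), background = rep(0.25, 4))
  expect_lte(score_threshold(unif, 1), 1e-9)
  expect_true(all(abs(unif$score) < 1e-12))
})

test_that("degenerate PWMs are rejected", {
  counts <- matrix(10, 5, 4)
  counts[3, ] <- c(10, 0, 0, 10)
  expect_error(pwm_matrix("bad", counts, pseudocount = 0), "degenerate")
})

test_that("scanning finds a planted consensus and is strand-symmetric", {
  withr::with_seed(33, {
    pfm <- default_motifs()$FOXG_SYN
    pwm <- pwm_matrix("FOXG_SYN", pfm, background = sym_bg)
    w <- nrow(pfm)
    consensus <- paste(c("A", "C", "G", "T")[apply(pfm, 1, which.max)],
                       collapse = "")
    seq <- paste0(substr(random_dna(10), 1, 10), consensus, random_dna(300))
    hits <- scan_pwm(seq, pwm)
    expect_true(any(hits$start == 10 & hits$end == 10 + w &
                      hits$strand == "+"))
    expect_true(all(hits$p <= 1e-4))
    # reverse complement: same number of hits, mirrored, flipped strand
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    hits_rc <- scan_pwm(rc, pwm)
    expect_equal(nrow(hits_rc), nrow(hits))
    L <- nchar(seq)
    expect_setequal(L - hits$end, hits_rc$start[order(hits_rc$start)])
    # sequences shorter than the motif yield no hits; N never matches
    expect_equal(nrow(scan_pwm("ACGT", pwm)), 0)
    withN <- paste0(substr(seq, 1, 12), "N", substr(seq, 14, nchar(seq)))
    expect_false(any(scan_pwm(withN, pwm)$start == 10))
  })
})

test_that("scan equals brute-force window scoring on random sequences", {
  withr::with_seed(34, {
    pwms <- lapply(names(default_motifs()), function(id) {
      pwm_matrix(id, default_motifs()[[id]], background = sym_bg)
    })
    for (rep in 1:5) {
      seq <- random_dna(1000)
      for (pwm in pwms) {
        thr <- score_threshold(pwm, 1e-3)
        hits <- scan_pwm(seq, pwm, p_cut = 1e-3)
        bf <- brute_force_scan(seq, pwm, function(s) thr)
        expect_equal(nrow(hits), nrow(bf))
        if (nrow(bf) > 0) {
          key_a <- paste(hits$start, hits$strand)
          key_b <- paste(bf$start, bf$strand)
          expect_setequal(key_a, key_b)
          expect_equal(sort(round(hits$score, 6)), sort(round(bf$score, 6)))
        }
      }
    }
  })
})

test_that("planted motif enrichment is detected and absent motifs are not", {
  withr::with_seed(35, {
    genome <- c(chr1 = random_dna(60000))
    pfms <- default_motifs()
    pwm_t <- pwm_matrix("TCF_SYN", pfms$TCF_SYN, background = sym_bg)
    pwm_h <- pwm_matrix("HOX_SYN", pfms$HOX_SYN, background = sym_bg)
    consensus <- "CCTTTGTACGA"
    # plant the TCF consensus in 80% of 30 targets
    starts <- seq(1000, 59000, by = 2000)[1:30]
    for (i in 1:24) {
      substr(genome[["chr1"]], starts[i] + 20, starts[i] + 19 +
               nchar(consensus)) <- consensus
    }
    target <- intervals("chr1", starts, starts + 200)
    tab <- motif_enrichment(target, genome, list(pwm_t, pwm_h),
                            background_n = 300, seed = 5)
    expect_true(tab$significant[tab$motif_id == "TCF_SYN"])
    expect_lt(tab$adj_p[tab$motif_id == "TCF_SYN"], 1e-6)
    expect_false(tab$significant[tab$motif_id == "HOX_SYN"])
    expect_error(motif_enrichment(target[0, ], genome, list(pwm_t)),
                 "empty")
    expect_error(motif_enrichment(target, genome, list(pwm_t),
                                  background_n = 50), "10x")
  })
})

test_that("enrichment is calibrated when targets are background draws", {
  withr::with_seed(36, {
    genome <- c(chr1 = random_dna(50000))
    pwm <- pwm_matrix("HOX_SYN", default_motifs()$HOX_SYN,
                      background = sym_bg)
    flags <- vapply(1:100, function(s) {
      starts <- sample(0:(50000 - 120), 15)
      target <- intervals("chr1", starts, starts + 120)
      tab <- motif_enrichment(target, genome, list(pwm),
                              background_n = 150, seed = 10000 + s)
      tab$significant[1]
    }, logical(1))
    expect_lte(mean(flags), 0.05)
  })
})

test_that("gene-level motif routing respects compartments", {
  annos <- tibble::tibble(
    region = c("r1", "r2", "r3"),
    gene_id = c("gA", "gA", "gB"),
    cre_class = c("Dis", "CP", "Pro"))
  hits <- tibble::tibble(
    region = c("r1", "r2", "r3"),
    motif_id = c("TCF", "TCF", "FOXG"),
    start = 1L, end = 11L, strand = "+", score = 10, p = 1e-5)
  expect_equal(genes_with_motif(annos, hits, "TCF", "enhancer"), "gA")
  expect_equal(genes_with_motif(annos, hits, "TCF", "promoter"), "gA")
  expect_equal(genes_with_motif(annos, hits, "FOXG", "enhancer"), "gB")
  expect_equal(genes_with_motif(annos, hits, "FOXG", "promoter"),
               character(0))
  expect_equal(genes_with_motif(annos, hits, "TCF", "either"), "gA")
  expect_error(genes_with_motif(annos, hits, "NOPE"), "unknown motif")
})

test_that("FoxG ratio categories follow the ratio rules and scale invariance", {
  ca <- tibble::tibble(gene_id = c("g1", "g1", "g2", "g3"),
                       motif_id = c("FOXG", "HOX", "HOX", "FOXG"),
                       n = c(3L, 7L, 5L, 2L))
  cp <- tibble::tibble(gene_id = c("g2", "g3", "g4"),
                       motif_id = c("FOXG", "FOXG", "HOX"),
                       n = c(2L, 1L, 4L))
  out <- foxg_ratio_categories(ca, cp, "FOXG")
  lookup <- function(g) out$category[out$gene_id == g]
  expect_equal(lookup("g1"), "A_to_0")     # 0.3 anterior, 0 posterior
  expect_equal(lookup("g2"), "ZERO_to_P")
  expect_equal(lookup("g3"), "SIMILAR")
  expect_equal(lookup("g4"), "NONE")
  expect_equal(out$ratio_anterior[out$gene_id == "g1"], 0.3)
  # doubling all counts leaves categories unchanged
  ca2 <- dplyr::mutate(ca, n = n * 2L)
  cp2 <- dplyr::mutate(cp, n = n * 2L)
  expect_equal(foxg_ratio_categories(ca2, cp2, "FOXG")$category,
               out$category)
})
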