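test_that("the generator is byte-identical under the same seed", {
  p <- small_params()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_regenome(simulate_regenome(p), d1)
  write_regenome(simulate_regenome(p), d2)
  files <- list.files(d1)
  expect_true(length(files) > 10)
  expect_setequal(files, list.files(d2))
  for (f in files) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 label = f)
  }
  # a different seed changes counts but keeps the layout statistics
  p2 <- small_params(); p2$seed <- 43L
  s2 <- simulate_genome(p2)
  s1 <- simulate_genome(p)
  expect_equal(nrow(s1$truth$elements), nrow(s2$truth$elements))
  expect_false(identical(s1$genome, s2$genome))
})

test_that("ledger construction invariants hold", {
  sim <- small_sim()
  el <- sim$truth$elements
  # every element maps to exactly one existing gene
  expect_true(all(el$gene_id %in% sim$gm$genes$gene_id))
  # FI elements lie inside the first intron of their gene
  fi <- first_introns(sim$gm)
  fi_el <- el[el$true_class == "FI", ]
  m <- match(fi_el$gene_id, fi$gene_id)
  expect_true(all(!is.na(m)))
  expect_true(all(fi_el$start >= fi$start[m] & fi_el$end <= fi$end[m]))
  # planted motif offsets lie inside their element
  inst <- sim$truth$motif_instances
  ei <- match(inst$element_id, el$element_id)
  widths <- vapply(sim$motifs, nrow, integer(1))[inst$motif_id]
  expect_true(all(inst$offset >= 0))
  expect_true(all(el$start[ei] + inst$offset + widths <= el$end[ei]))
  # CP elements sit within 100 bp upstream of their gene's TSS
  cp <- el[el$true_class == "CP", ]
  g <- sim$gm$genes[match(cp$gene_id, sim$gm$genes$gene_id), ]
  mid <- (cp$start + cp$end) %/% 2
  d <- signed_tss_distance(mid, g$tss, g$strand)
  expect_true(all(d > -100 & d < 0))
})

test_that("re-scanning the emitted genome recovers planted motifs", {
  sim <- default_sim()
  el <- sim$truth$elements
  bg <- genome_background(sim$genome)
  pwms <- lapply(names(sim$motifs), function(id) {
    pwm_matrix(id, sim$motifs[[id]], bg)
  })
  names(pwms) <- names(sim$motifs)
  hits <- scan_regions(el, sim$genome, pwms)
  inst <- sim$truth$motif_instances
  ei <- match(inst$element_id, el$element_id)
  keys <- region_keys(el)
  found <- mapply(function(mid, s, r) {
    any(hits$motif_id == mid & hits$start == s & hits$region == r)
  }, inst$motif_id, el$start[ei] + inst$offset, keys[ei])
  expect_gte(mean(found), 0.95)
})

test_that("ATAC count means implement depth x openness", {
  sim <- default_sim()
  p <- sim$params
  el <- sim$truth$elements
  keys <- region_keys(el)
  cnt <- sim$atac$counts
  wt_ant <- cnt[, c("wt_ant_1", "wt_ant_2")]
  open_rows <- el$pole %in% c("anterior", "shared")
  # >= 1000 pooled draws from open elements: mean within 5% of depth
  draws <- as.vector(wt_ant[open_rows, ])
  expect_gt(length(draws), 200)
  expect_lt(abs(mean(draws) - p$fragment_depth) / p$fragment_depth, 0.05)
  closed <- as.vector(wt_ant[el$pole == "posterior", ])
  expect_lt(abs(mean(closed) - p$fragment_depth / p$rnai_effect) /
              (p$fragment_depth / p$rnai_effect), 0.15)
  # NON_ACCESSIBLE elements draw from the noise floor under their RNAi
  non <- el$rnai_state_notum == "NON_ACCESSIBLE" & el$pole == "anterior"
  notum <- cnt[non, c("notum_ant_1", "notum_ant_2")]
  expect_lt(mean(notum), 0.5)
  # zero-depth, zero-noise parameters give an all-zero matrix
  p0 <- small_params(fragment_depth = 0, noise_count_mean = 0,
                     frag_noise_per_kb = 0)
  sim0 <- simulate_genome(p0)
  atac0 <- simulate_atac_counts(sim0)
  expect_true(all(atac0$counts == 0))
  expect_true(all(vapply(atac0$fragments, nrow, integer(1)) == 0))
})

test_that("ChIP signal is restricted to enhancer-class elements", {
  sim <- default_sim()
  p <- sim$params
  el <- sim$truth$elements
  cnt <- sim$chip$counts
  floor_mean <- p$fragment_depth / p$open_vs_closed_ratio
  # CP elements sit at the background floor in all ChIP samples
  cp <- el$true_class == "CP"
  expect_lt(mean(cnt[cp, ]), 2.5 * floor_mean)
  # posterior Dis elements reach depth in posterior ChIP samples
  dis_post <- el$true_class == "Dis" & el$pole == "posterior"
  post_mean <- mean(cnt[dis_post, c("chip_post_1", "chip_post_2")])
  expect_lt(abs(post_mean - p$fragment_depth) / p$fragment_depth, 0.15)
  # cross-table: high ChIP signal identifies exactly the active enhancers
  enh <- el$true_class %in% c("FI", "Pro", "Dis")
  hot <- rowMeans(cnt) > p$fragment_depth / 4
  expect_gt(mean(hot == enh), 0.95)
})

test_that("RNA-seq planting matches the requested fold change", {
  sim <- default_sim()
  rna <- sim$rna
  de <- sim$truth$de_genes
  ctrl <- rowMeans(rna$counts[de$gene_id, paste0("ctrl_", 1:3)])
  wnt1 <- rowMeans(rna$counts[de$gene_id, paste0("wnt1_", 1:3)])
  emp_lfc <- mean(log2(wnt1 + 0.5) - log2(ctrl + 0.5))
  expect_lt(abs(emp_lfc - de$log2fc[1]), 0.15)
  # a null generator plants nothing
  pnull <- small_params(de_lfc_planted = 0)
  simnull <- simulate_genome(pnull)
  rnanull <- simulate_rnaseq(simnull)
  g <- simnull$truth$de_genes$gene_id
  lfc0 <- mean(log2(rowMeans(rnanull$counts[g, 4:6]) + 0.5) -
                 log2(rowMeans(rnanull$counts[g, 1:3]) + 0.5))
  expect_lt(abs(lfc0), 0.15)
  # seeded determinism of the RNA stage alone
  expect_identical(simulate_rnaseq(simnull)$counts, rnanull$counts)
})

test_that("infeasible packing is rejected", {
  expect_error(sim_params(genome_length = 1e5, n_genes = 200),
               "infeasible")
})
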