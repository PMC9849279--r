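# Shared fixtures, built once per test run and cached.

# the default synthetic regulome (study conditions, seed 1)
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_regenome(sim_params())
    cache
  }
})

# a small regulome for cheap structural tests
small_params <- function(...) {
  sim_params(genome_length = 4e5, n_chrom = 2L, n_genes = 40L,
             n_secondary_cp = 4L, n_de_genes = 8L, n_tcf_genes = 6L,
             seed = 42L, ...)
}

small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_regenome(small_params())
    cache
  }
})

# build a peak tibble row-by-row
peak_tbl <- function(chrom, start, end, summit = NULL, score = 1,
                     sample_evidence = "s1", assay_evidence = "ATAC") {
  n <- length(start)
  tibble::tibble(
    chrom = rep_len(chrom, n), start = as.integer(start),
    end = as.integer(end),
    summit = as.integer(if (is.null(summit)) (end - start) %/% 2
                        else summit),
    score = rep_len(score, n),
    sample_evidence = rep_len(sample_evidence, n),
    assay_evidence = rep_len(assay_evidence, n)
  )
}

# a two-exon '+' gene for CRE decision-table sweeps
two_exon_gene <- function(tss = 20000L, strand = "+") {
  if (strand == "+") {
    genes <- tibble::tibble(gene_id = "gA", chrom = "chr1", start = tss,
                            end = tss + 3000L, strand = "+")
    exons <- tibble::tibble(gene_id = "gA", chrom = "chr1",
                            start = c(tss, tss + 1200L),
                            end = c(tss + 200L, tss + 3000L))
  } else {
    genes <- tibble::tibble(gene_id = "gA", chrom = "chr1",
                            start = tss - 2999L, end = tss + 1L,
                            strand = "-")
    exons <- tibble::tibble(gene_id = "gA", chrom = "chr1",
                            start = c(tss - 199L, tss - 2999L),
                            end = c(tss + 1L, tss - 1199L))
  }
  gene_models(genes, exons)
}

# two full default pipeline runs (seed 1), shared by the acceptance and
# pipeline tests
pipeline_runs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir1 <- file.path(tempdir(), "wr_run_a")
      dir2 <- file.path(tempdir(), "wr_run_b")
      res1 <- run_pipeline(dir1, seed = 1, quiet = TRUE)
      res2 <- run_pipeline(dir2, seed = 1, quiet = TRUE)
      cache <<- list(dir1 = dir1, dir2 = dir2, res1 = res1, res2 = res2)
    }
    cache
  }
})

random_dna <- function(n, prob = c(0.325, 0.175, 0.175, 0.325)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# brute-force PWM scoring straight from the definition: every window is
# scored by direct position-by-position matrix lookup (via embed()), the
# minus strand by scoring the reverse-complemented sequence and mapping
# window starts back to forward coordinates
brute_force_scan <- function(seq, pwm, threshold_fun) {
  w <- nrow(pwm$score)
  L <- nchar(seq)
  score_all <- function(s) {
    codes <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
    n <- length(codes) - w + 1
    if (n < 1) return(numeric(0))
    M <- t(embed(codes, w)[, w:1, drop = FALSE])  # w x n window codes
    sc <- colSums(matrix(pwm$score[cbind(rep(seq_len(w), n),
                                         as.vector(M))], w, n))
    sc[colSums(is.na(M)) > 0] <- -Inf
    sc
  }
  fwd <- score_all(seq)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  rev_sc <- score_all(rc)
  fi <- which(fwd >= threshold_fun("+"))
  ri <- which(rev_sc >= threshold_fun("-"))
  out <- rbind(
    data.frame(start = fi - 1L, strand = rep("+", length(fi)),
               score = fwd[fi]),
    data.frame(start = L - w - (ri - 1L), strand = rep("-", length(ri)),
               score = rev_sc[ri])
  )
  out[is.finite(out$score), , drop = FALSE]
}
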