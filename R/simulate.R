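#' Parameters for the synthetic wound regulome
#'
#' Defaults describe a desk-scale regulome: a 2 Mb genome over four
#' chromosomes at 35% GC, 200 multi-exon genes laid out in 10 kb
#' territories, one planted cis-regulatory element per gene cycling through
#' the five CRE classes (plus a handful of secondary core promoters), and
#' the four-condition wound design (wild-type anterior/posterior wounds and
#' notum/wnt1 RNAi wounds, two ATAC replicates each, two H3K27ac replicates
#' per pole).
#'
#' Accessibility is parameterised as a multiplier of `fragment_depth`:
#' an open element has multiplier 1, the silent pole of a pole-specific
#' element `1/rnai_effect`, and RNAi states map to multipliers
#' (`ACCESSIBLE` 1, `MORE_ACCESSIBLE` 4, `LESS_ACCESSIBLE` 0.25,
#' `NON_ACCESSIBLE` 0, plus the count noise floor).
#'
#' @param genome_length Total genome size in bp (default 2e6).
#' @param n_chrom Number of chromosomes (default 4).
#' @param gc GC content of the background sequence (default 0.35).
#' @param n_genes Number of genes (default 200).
#' @param fragment_depth Mean fragments per open element per sample
#'   (default 200).
#' @param nb_dispersion NB dispersion of ATAC/ChIP counts: variance is
#'   `m + alpha m^2` (default 0.1).
#' @param open_vs_closed_ratio Open-element signal over the ChIP/fragment
#'   background floor (default 20).
#' @param rnai_effect Linear fold between the accessible and silent pole of
#'   a pole-specific element; this is the planted pole effect that RNAi
#'   flips (default 8).
#' @param noise_count_mean Background mean added to every region count, so
#'   deeply closed regions still occasionally record a read (default 0.1).
#' @param frag_noise_per_kb Genome-wide background fragments per kb in the
#'   per-sample fragment tracks (default 5).
#' @param own_state_probs Probabilities of the RNAi accessibility states
#'   (ACCESSIBLE, MORE, LESS, NON) for elements of the pole the RNAi
#'   perturbs; 1 minus the ACCESSIBLE mass is the flip fraction (default
#'   0.85).
#' @param opp_state_probs State probabilities for elements of the opposite
#'   pole, which mostly open when the wound polarity flips.
#' @param promoter_width,enhancer_width Width ranges (bp) of planted
#'   promoter- and enhancer-class elements.
#' @param frag_len_range Fragment length range, nucleosome-free scale
#'   (default 40-100 bp).
#' @param replicates ATAC/ChIP replicates per condition (default 2).
#' @param n_secondary_cp Number of enhancer-class genes that also receive a
#'   shared core-promoter element (default 10).
#' @param foxg_fraction Fraction of pole-specific enhancer-class elements
#'   carrying planted FoxG motifs (default 0.6).
#' @param n_de_genes Genes downregulated under wnt1 RNAi (default 30).
#' @param n_tcf_genes Of the DE genes, how many carry a TCF motif in their
#'   enhancer element (default 25); 5 of these also get a TCF motif in a
#'   secondary promoter.
#' @param de_lfc_planted Planted log2 fold change of DE genes under wnt1
#'   RNAi (default -1).
#' @param rna_replicates RNA-seq replicates per arm (default 3).
#' @param rna_dispersion NB dispersion of RNA-seq counts (default 0.02).
#' @param rna_baseline_meanlog,rna_baseline_sdlog Log-normal baseline
#'   expression across genes (defaults log(300) and 0.8).
#' @param seed Master seed (default 1).
#' @return A list with class `wr_sim_params`.
#' @export
sim_params <- function(genome_length = 2e6,
                       n_chrom = 4L,
                       gc = 0.35,
                       n_genes = 200L,
                       fragment_depth = 200,
                       nb_dispersion = 0.1,
                       open_vs_closed_ratio = 20,
                       rnai_effect = 8,
                       noise_count_mean = 0.1,
                       frag_noise_per_kb = 5,
                       own_state_probs = c(ACCESSIBLE = 0.15,
                                           MORE_ACCESSIBLE = 0,
                                           LESS_ACCESSIBLE = 0.25,
                                           NON_ACCESSIBLE = 0.60),
                       opp_state_probs = c(ACCESSIBLE = 0.80,
                                           MORE_ACCESSIBLE = 0.10,
                                           LESS_ACCESSIBLE = 0.05,
                                           NON_ACCESSIBLE = 0.05),
                       promoter_width = c(150L, 200L),
                       enhancer_width = c(350L, 450L),
                       frag_len_range = c(40L, 100L),
                       replicates = 2L,
                       n_secondary_cp = 10L,
                       foxg_fraction = 0.6,
                       n_de_genes = 30L,
                       n_tcf_genes = 25L,
                       de_lfc_planted = -1,
                       rna_replicates = 3L,
                       rna_dispersion = 0.02,
                       rna_baseline_meanlog = log(300),
                       rna_baseline_sdlog = 0.8,
                       seed = 1L) {
  p <- as.list(environment())
  stopifnot(p$replicates >= 2, p$n_genes > 0, p$genome_length > 0,
            abs(sum(own_state_probs) - 1) < 1e-9,
            abs(sum(opp_state_probs) - 1) < 1e-9,
            p$n_tcf_genes <= p$n_de_genes)
  p$chrom_len <- as.integer(genome_length / n_chrom)
  p$tile <- as.integer(genome_length / n_genes)
  if (p$tile < 10000L) {
    stop("infeasible packing: need at least 10 kb of genome per gene",
         call. = FALSE)
  }
  class(p) <- "wr_sim_params"
  p
}

# accessibility multipliers implementing the planted RNAi states; MORE and
# LESS are symmetric four-fold changes around the open level
STATE_MULT <- c(ACCESSIBLE = 1, MORE_ACCESSIBLE = 4,
                LESS_ACCESSIBLE = 0.25, NON_ACCESSIBLE = 0)

#' Built-in synthetic motif library
#'
#' Three synthetic position frequency matrices standing in for the TCF,
#' FoxG/forkhead and homeobox motif families used throughout the package's
#' simulations. They are constructed (not downloaded) matrices, strongly
#' informative with degenerate W (A/T) positions.
#'
#' @return Named list of `width x 4` count matrices (A, C, G, T columns).
#' @export
default_motifs <- function() {
  make_pfm <- function(consensus) {
    letters <- strsplit(consensus, "")[[1]]
    m <- matrix(2, nrow = length(letters), ncol = 4,
                dimnames = list(NULL, DNA))
    for (j in seq_along(letters)) {
      if (letters[j] == "W") {
        m[j, ] <- c(147, 3, 3, 147)
      } else if (letters[j] == "S") {
        m[j, ] <- c(3, 147, 147, 3)
      } else {
        m[j, letters[j]] <- 294
      }
    }
    m
  }
  # consensus choices keep enough G/C content that, at the AT-rich genome
  # background, a planted instance with one sampling mismatch still clears
  # the 1e-4 exact-null threshold
  list(
    TCF_SYN = make_pfm("CCTTTGWWCGA"),
    FOXG_SYN = make_pfm("TGTTTACWCA"),
    HOX_SYN = make_pfm("GCTAATTAGCW")
  )
}

#' Simulate the synthetic genome, gene models and truth ledger
#'
#' Generates i.i.d. background sequence at the configured GC, places one
#' multi-exon gene per 10 kb territory, plants one CRE per gene (classes
#' cycling CP, PP, FI, Pro, Dis) at positions consistent with the
#' annotation rules (core promoters centred 50 bp upstream of the TSS,
#' first-intron elements inside intron 1, distal elements 2.5-4.3 kb from
#' the TSS), embeds motif instances sampled from the PWM rows at recorded
#' offsets, and assigns each element a pole and per-RNAi accessibility
#' state. Fully deterministic under `params$seed`.
#'
#' @param params A [sim_params()] object.
#' @return List with `genome` (named character vector), `gm`
#'   ([gene_models()]), `motifs` (count matrices), and `truth` — the ledger
#'   with `elements`, `motif_instances`, `de_genes` tibbles and `gene_ids`.
#' @export
simulate_genome <- function(params = sim_params()) {
  stopifnot(inherits(params, "wr_sim_params"))
  with_seed(derive_seed(params$seed, 1L), simulate_genome_impl(params))
}

simulate_genome_impl <- function(p) {
  chroms <- paste0("chr", seq_len(p$n_chrom))
  base_prob <- c(A = (1 - p$gc) / 2, C = p$gc / 2, G = p$gc / 2,
                 T = (1 - p$gc) / 2)
  genome <- vapply(chroms, function(ch) {
    paste(sample(DNA, p$chrom_len, replace = TRUE, prob = base_prob),
          collapse = "")
  }, character(1))

  tiles_per_chrom <- p$chrom_len %/% p$tile
  if (tiles_per_chrom * p$n_chrom < p$n_genes) {
    stop("infeasible packing: too many genes for the genome length",
         call. = FALSE)
  }
  classes <- rep(CRE_CLASSES, length.out = p$n_genes)

  genes <- vector("list", p$n_genes)
  exons <- vector("list", p$n_genes)
  elements <- vector("list", p$n_genes)
  for (i in seq_len(p$n_genes)) {
    chrom <- chroms[((i - 1L) %/% tiles_per_chrom) + 1L]
    t0 <- ((i - 1L) %% tiles_per_chrom) * p$tile
    strand <- sample(c("+", "-"), 1)
    gid <- sprintf("g%03d", i)

    e1 <- sample(150:300, 1)
    i1 <- sample(900:1400, 1)
    n_exon <- sample(2:5, 1)
    lens <- c(e1, i1)
    for (k in seq_len(n_exon - 1L)) {
      lens <- c(lens, sample(150:400, 1))            # exon k+1
      if (k < n_exon - 1L) lens <- c(lens, sample(300:800, 1))  # intron
      if (sum(lens) > 4300) { lens <- lens[seq_len(2 * k + 1)]; break }
    }
    glen <- sum(lens)
    # transcription-order blocks alternate exon, intron, exon, ...
    starts_rel <- cumsum(c(0, lens[-length(lens)]))
    exon_rel <- cbind(starts_rel, starts_rel + lens)[seq(1, length(lens),
                                                         by = 2), ,
                                                     drop = FALSE]
    if (strand == "+") {
      tss <- t0 + 4800L
      gstart <- tss; gend <- tss + glen
      ex <- tibble(gene_id = gid, chrom = chrom,
                   start = as.integer(tss + exon_rel[, 1]),
                   end = as.integer(tss + exon_rel[, 2]))
    } else {
      tss <- t0 + 5200L
      gend <- tss + 1L; gstart <- gend - glen
      ex <- tibble(gene_id = gid, chrom = chrom,
                   start = as.integer(gend - exon_rel[, 2]),
                   end = as.integer(gend - exon_rel[, 1]))
    }
    genes[[i]] <- tibble(gene_id = gid, chrom = chrom,
                         start = as.integer(gstart), end = as.integer(gend),
                         strand = strand)
    exons[[i]] <- ex

    cls <- classes[i]
    w <- if (cls %in% c("CP", "PP")) {
      sample(p$promoter_width[1]:p$promoter_width[2], 1)
    } else {
      sample(p$enhancer_width[1]:p$enhancer_width[2], 1)
    }
    mid <- switch(cls,
      CP = place_upstream(tss, strand, -50L),
      PP = place_upstream(tss, strand, -300L),
      Pro = place_upstream(tss, strand, -sample(700:1800, 1)),
      Dis = place_upstream(tss, strand, -sample(2500:4300, 1)),
      FI = {
        # centre of the first intron in genomic coordinates
        if (strand == "+") tss + e1 + as.integer(i1 / 2)
        else tss - e1 - as.integer(i1 / 2)
      })
    pole <- sample(c("anterior", "posterior", "shared"), 1,
                   prob = c(0.4, 0.4, 0.2))
    elements[[i]] <- tibble(
      element_id = sprintf("el_%03d", i),
      chrom = chrom,
      start = as.integer(mid - w %/% 2),
      end = as.integer(mid - w %/% 2 + w),
      true_class = cls, gene_id = gid, pole = pole
    )
  }
  genes <- bind_rows(genes)
  exons <- bind_rows(exons)
  elements <- bind_rows(elements)
  gm <- gene_models(genes, exons)

  # secondary shared core promoters on a few enhancer-class genes
  enh_genes <- elements$gene_id[elements$true_class %in% c("FI", "Pro", "Dis")]
  sec_genes <- sort(sample_vec(unique(enh_genes), p$n_secondary_cp))
  sec <- lapply(seq_along(sec_genes), function(k) {
    g <- gm$genes[gm$genes$gene_id == sec_genes[k], ]
    w <- sample(p$promoter_width[1]:p$promoter_width[2], 1)
    mid <- place_upstream(g$tss, g$strand, -50L)
    tibble(element_id = sprintf("el_sec_%02d", k), chrom = g$chrom,
           start = as.integer(mid - w %/% 2),
           end = as.integer(mid - w %/% 2 + w),
           true_class = "CP", gene_id = g$gene_id, pole = "shared")
  })
  elements <- bind_rows(elements, bind_rows(sec))

  # RNAi accessibility states per perturbation, relative to the pole where
  # the element is open in the wild type
  draw_state <- function(probs, n) {
    sample(names(STATE_MULT), n, replace = TRUE, prob = probs)
  }
  n_el <- nrow(elements)
  st_notum <- rep("ACCESSIBLE", n_el)
  st_wnt1 <- rep("ACCESSIBLE", n_el)
  ant <- elements$pole == "anterior"
  post <- elements$pole == "posterior"
  st_notum[ant] <- draw_state(p$own_state_probs, sum(ant))
  st_notum[post] <- draw_state(p$opp_state_probs, sum(post))
  st_wnt1[post] <- draw_state(p$own_state_probs, sum(post))
  st_wnt1[ant] <- draw_state(p$opp_state_probs, sum(ant))
  elements$rnai_state_notum <- st_notum
  elements$rnai_state_wnt1 <- st_wnt1

  # DE genes: posterior program genes with enhancer-class elements,
  # downregulated when wnt1 is silenced
  post_enh <- elements |>
    filter(.data$true_class %in% c("FI", "Pro", "Dis"),
           .data$pole == "posterior", !duplicated(.data$gene_id))
  n_de <- min(p$n_de_genes, nrow(post_enh))
  de_gene_ids <- sort(sample_vec(post_enh$gene_id, n_de))
  tcf_gene_ids <- sort(sample_vec(de_gene_ids, min(p$n_tcf_genes, n_de)))
  de_genes <- tibble(gene_id = de_gene_ids, log2fc = p$de_lfc_planted)

  # motif planting plan
  motifs <- default_motifs()
  widths <- vapply(motifs, nrow, integer(1))
  enh_rows <- which(elements$true_class %in% c("FI", "Pro", "Dis"))
  foxg_rows <- unlist(lapply(c("anterior", "posterior"), function(pl) {
    rows <- enh_rows[elements$pole[enh_rows] == pl]
    sample_vec(rows, round(p$foxg_fraction * length(rows)))
  }))
  tcf_enh_rows <- which(elements$gene_id %in% tcf_gene_ids &
                          elements$true_class %in% c("FI", "Pro", "Dis"))
  # a few TCF genes also get the motif in their secondary promoter
  sec_tcf_genes <- intersect(sec_genes, tcf_gene_ids)
  tcf_prom_rows <- which(elements$gene_id %in% sec_tcf_genes &
                           elements$true_class == "CP" &
                           grepl("^el_sec", elements$element_id))

  plan <- lapply(seq_len(n_el), function(i) {
    ids <- c("HOX_SYN", "HOX_SYN")
    if (i %in% foxg_rows) ids <- c(ids, "FOXG_SYN", "FOXG_SYN")
    if (i %in% tcf_enh_rows || i %in% tcf_prom_rows) {
      ids <- c(ids, "TCF_SYN", "TCF_SYN")
    }
    ids
  })

  inst <- vector("list", n_el)
  for (i in seq_len(n_el)) {
    ids <- plan[[i]]
    w_el <- elements$end[i] - elements$start[i]
    # one motif per equal slot keeps instances disjoint
    slot <- w_el %/% length(ids)
    offs <- integer(length(ids))
    for (k in seq_along(ids)) {
      wk <- widths[[ids[k]]]
      lo <- (k - 1L) * slot
      hi <- k * slot - wk
      offs[k] <- if (hi <= lo) lo else sample(lo:hi, 1)
    }
    inst[[i]] <- tibble(element_id = elements$element_id[i],
                        motif_id = ids, offset = offs,
                        strand = sample(c("+", "-"), length(ids),
                                        replace = TRUE))
  }
  inst <- bind_rows(inst)

  # embed sampled motif instances into the genome sequence
  el_idx <- match(inst$element_id, elements$element_id)
  for (r in seq_len(nrow(inst))) {
    m <- motifs[[inst$motif_id[r]]]
    probs <- m / rowSums(m)
    letters <- vapply(seq_len(nrow(m)), function(j) {
      sample(DNA, 1, prob = probs[j, ])
    }, character(1))
    s <- paste(letters, collapse = "")
    if (inst$strand[r] == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    i <- el_idx[r]
    pos <- elements$start[i] + inst$offset[r]
    ch <- elements$chrom[i]
    substr(genome[[ch]], pos + 1L, pos + nchar(s)) <- s
  }

  truth <- list(
    elements = elements,
    motif_instances = inst,
    de_genes = de_genes,
    tcf_promoter_genes = sec_tcf_genes,
    gene_ids = sort(genes$gene_id)
  )
  list(genome = genome, gm = gm, motifs = motifs, truth = truth,
       params = p)
}

# size-safe sampling without the scalar-x expansion of sample()
sample_vec <- function(x, size) x[sample.int(length(x), size)]

# upstream position: negative d means upstream in transcription orientation
place_upstream <- function(tss, strand, d) {
  as.integer(if (strand == "+") tss + d else tss - d)
}

# accessibility multiplier of an element in a condition
openness <- function(elements, condition, rnai_effect) {
  closed <- 1 / rnai_effect
  switch(condition,
    wt_ant = ifelse(elements$pole == "posterior", closed, 1),
    wt_post = ifelse(elements$pole == "anterior", closed, 1),
    notum_ant = STATE_MULT[elements$rnai_state_notum],
    wnt1_post = STATE_MULT[elements$rnai_state_wnt1],
    stop("unknown condition: ", condition)
  )
}

atac_sample_sheet <- function(replicates) {
  conds <- c("wt_ant", "wt_post", "notum_ant", "wnt1_post")
  tibble(
    sample_id = paste0(rep(conds, each = replicates), "_",
                       rep(seq_len(replicates), times = length(conds))),
    condition = rep(conds, each = replicates),
    replicate = rep(seq_len(replicates), times = length(conds)),
    assay = "ATAC"
  )
}

chip_sample_sheet <- function(replicates) {
  conds <- c("chip_ant", "chip_post")
  tibble(
    sample_id = paste0(rep(conds, each = replicates), "_",
                       rep(seq_len(replicates), times = length(conds))),
    condition = rep(conds, each = replicates),
    replicate = rep(seq_len(replicates), times = length(conds)),
    assay = "CHIP"
  )
}

#' Simulate ATAC region counts and per-sample fragment tracks
#'
#' Region counts are negative binomial with mean
#' `fragment_depth x openness + noise_count_mean`, where openness encodes
#' the wild-type pole pattern and the ledger's RNAi states. Fragment tracks
#' place the counted fragments inside their elements (centres drawn from a
#' half-uniform, half-Beta(4,4) mixture so peaks have defined summits) on
#' top of a uniform genome-wide background. Deterministic under the seed.
#'
#' @param sim Result of [simulate_genome()].
#' @return List `counts` (regions x samples integer matrix keyed
#'   `chrom:start-end`), `samples` (sample sheet tibble), `lib_sizes`,
#'   `fragments` (named list of per-sample fragment tibbles).
#' @export
simulate_atac_counts <- function(sim) {
  p <- sim$params
  with_seed(derive_seed(p$seed, 2L), {
    el <- sim$truth$elements
    samples <- atac_sample_sheet(p$replicates)
    keys <- region_keys(el)
    counts <- matrix(0L, nrow(el), nrow(samples),
                     dimnames = list(keys, samples$sample_id))
    frags <- vector("list", nrow(samples))
    names(frags) <- samples$sample_id
    noise_n_mean <- p$frag_noise_per_kb * p$genome_length / 1000
    chrom_names <- names(sim$genome)
    for (s in seq_len(nrow(samples))) {
      mult <- openness(el, samples$condition[s], p$rnai_effect)
      mu <- p$fragment_depth * mult + p$noise_count_mean
      counts[, s] <- stats::rnbinom(nrow(el), mu = mu,
                                    size = 1 / p$nb_dispersion)
      # signal fragments: counted fragments placed inside their element
      n_sig <- counts[, s]
      el_rep <- rep(seq_len(nrow(el)), n_sig)
      wds <- (el$end - el$start)[el_rep]
      mix <- stats::runif(length(el_rep)) < 0.5
      relpos <- ifelse(mix, stats::runif(length(el_rep)),
                       stats::rbeta(length(el_rep), 4, 4))
      ctr <- el$start[el_rep] + relpos * wds
      len <- sample(p$frag_len_range[1]:p$frag_len_range[2],
                    length(el_rep), replace = TRUE)
      sig <- tibble(chrom = el$chrom[el_rep],
                    start = pmax(0L, as.integer(round(ctr - len / 2))),
                    len = len)
      # background fragments scattered over the genome
      n_noise <- stats::rpois(1, noise_n_mean)
      bg_chrom <- sample(chrom_names, n_noise, replace = TRUE)
      bg_len <- sample(p$frag_len_range[1]:p$frag_len_range[2], n_noise,
                       replace = TRUE)
      bg_start <- floor(stats::runif(n_noise) * (p$chrom_len - bg_len))
      bg <- tibble(chrom = bg_chrom, start = as.integer(bg_start),
                   len = bg_len)
      all <- bind_rows(sig, bg)
      all$end <- pmin(all$start + all$len, p$chrom_len)
      frags[[s]] <- arrange(
        tibble(chrom = all$chrom, start = all$start, end = all$end),
        .data$chrom, .data$start, .data$end)
    }
    lib <- colSums(counts) + round(noise_n_mean)
    list(counts = counts, samples = samples,
         lib_sizes = stats::setNames(lib, samples$sample_id),
         fragments = frags)
  })
}

#' Simulate H3K27ac ChIP region counts
#'
#' Enhancer-class elements (FI, Pro, Dis) carry ChIP signal at
#' `fragment_depth` in the pole where they are active (both poles for
#' shared elements); promoter-class elements and inactive poles sit at the
#' background floor `fragment_depth / open_vs_closed_ratio`.
#'
#' @param sim Result of [simulate_genome()].
#' @return List `counts`, `samples`, `lib_sizes`.
#' @export
simulate_chip_counts <- function(sim) {
  p <- sim$params
  with_seed(derive_seed(p$seed, 3L), {
    el <- sim$truth$elements
    samples <- chip_sample_sheet(p$replicates)
    keys <- region_keys(el)
    floor_mean <- p$fragment_depth / p$open_vs_closed_ratio
    enh <- el$true_class %in% c("FI", "Pro", "Dis")
    counts <- matrix(0L, nrow(el), nrow(samples),
                     dimnames = list(keys, samples$sample_id))
    for (s in seq_len(nrow(samples))) {
      pole_here <- if (samples$condition[s] == "chip_ant") "anterior"
                   else "posterior"
      active <- enh & (el$pole == pole_here | el$pole == "shared")
      mu <- ifelse(active, p$fragment_depth, floor_mean)
      counts[, s] <- stats::rnbinom(nrow(el), mu = mu,
                                    size = 1 / p$nb_dispersion)
    }
    list(counts = counts, samples = samples,
         lib_sizes = stats::setNames(colSums(counts), samples$sample_id))
  })
}

#' Simulate the wnt1 RNAi RNA-seq experiment
#'
#' Baseline expression is log-normal across genes; ledger DE genes have
#' their mean multiplied by `2^de_lfc_planted` in the wnt1 RNAi arm.
#' Counts are negative binomial with the RNA-seq dispersion.
#'
#' @param sim Result of [simulate_genome()].
#' @return List `counts` (genes x samples), `samples` (sample sheet).
#' @export
simulate_rnaseq <- function(sim) {
  p <- sim$params
  with_seed(derive_seed(p$seed, 4L), {
    gene_ids <- sim$truth$gene_ids
    base <- stats::rlnorm(length(gene_ids), p$rna_baseline_meanlog,
                          p$rna_baseline_sdlog)
    names(base) <- gene_ids
    samples <- tibble(
      sample_id = c(paste0("ctrl_", seq_len(p$rna_replicates)),
                    paste0("wnt1_", seq_len(p$rna_replicates))),
      condition = rep(c("ctrl", "wnt1"), each = p$rna_replicates)
    )
    fc <- rep(1, length(gene_ids))
    de_idx <- match(sim$truth$de_genes$gene_id, gene_ids)
    counts <- matrix(0L, length(gene_ids), nrow(samples),
                     dimnames = list(gene_ids, samples$sample_id))
    for (s in seq_len(nrow(samples))) {
      mu <- base
      if (samples$condition[s] == "wnt1") {
        mu[de_idx] <- mu[de_idx] * 2^sim$truth$de_genes$log2fc
      }
      counts[, s] <- stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / p$rna_dispersion)
    }
    list(counts = counts, samples = samples)
  })
}

#' Generate the full synthetic wound regulome
#'
#' Runs [simulate_genome()], [simulate_atac_counts()],
#' [simulate_chip_counts()] and [simulate_rnaseq()] under one parameter
#' set.
#'
#' @param params A [sim_params()] object.
#' @return List `genome`, `gm`, `motifs`, `truth`, `params`, `atac`,
#'   `chip`, `rna`.
#' @export
simulate_regenome <- function(params = sim_params()) {
  sim <- simulate_genome(params)
  sim$atac <- simulate_atac_counts(sim)
  sim$chip <- simulate_chip_counts(sim)
  sim$rna <- simulate_rnaseq(sim)
  sim
}

#' Write a simulated regulome to disk
#'
#' Emits `genome.fa`, `genes.gff3`, `truth.json`, `motifs.jaspar`,
#' per-sample `fragments_<sample>.bed`, `atac_counts.tsv`,
#' `chip_counts.tsv`, `rna_counts.tsv` and the two sample sheets.
#'
#' @param sim Result of [simulate_regenome()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_regenome <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  write_genome_fasta(sim$genome, fp("genome.fa"))
  write_gff3_genes(sim$gm, fp("genes.gff3"))
  write_jaspar(sim$motifs, fp("motifs.jaspar"))
  truth <- sim$truth
  jsonlite::write_json(
    list(elements = truth$elements, motif_instances = truth$motif_instances,
         de_genes = truth$de_genes,
         tcf_promoter_genes = truth$tcf_promoter_genes,
         gene_ids = truth$gene_ids),
    fp("truth.json"), dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  write_count_table(sim$atac$counts, fp("atac_counts.tsv"))
  write_count_table(sim$chip$counts, fp("chip_counts.tsv"))
  write_count_table(sim$rna$counts, fp("rna_counts.tsv"))
  write_plain_tsv(sim$atac$samples, fp("samples_atac.tsv"))
  write_plain_tsv(sim$chip$samples, fp("samples_chip.tsv"))
  write_plain_tsv(sim$rna$samples, fp("samples_rna.tsv"))
  for (s in names(sim$atac$fragments)) {
    write_bed6(sim$atac$fragments[[s]], fp(sprintf("fragments_%s.bed", s)))
  }
  invisible(dir)
}
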