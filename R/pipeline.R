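#' Run the wound-regulome pipeline end to end
#'
#' Orchestrates the stages `simulate` (or ingest of existing files),
#' `peaks`, `merge`, `acr`, `split`, `states`, `cre`, `motifs`, `de` and
#' `integrate`. Every stage reads its inputs from, and writes its outputs
#' to, files under `outdir`, so a completed run can be resumed and audited;
#' a JSON manifest records the configuration, seed, per-file digests and
#' timestamps.
#'
#' @param outdir Output directory.
#' @param cfg [analysis_config()].
#' @param params [sim_params()] describing the synthetic regulome.
#' @param seed Master seed; overrides `params$seed` when given.
#' @param resume If `TRUE`, stages whose output files already exist are
#'   skipped.
#' @param quiet Suppress per-stage log lines.
#' @return Invisibly, a list with the manifest and the in-memory stage
#'   results (`acrs`, `splits`, `states`, `annos`, `enrichment`,
#'   `foxg`, `de`, `integration`).
#' @export
run_pipeline <- function(outdir, cfg = analysis_config(),
                         params = sim_params(), seed = NULL,
                         resume = FALSE, quiet = FALSE) {
  validate_config(cfg)
  if (!is.null(seed)) {
    params$seed <- as.integer(seed)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  data_dir <- file.path(outdir, "data")
  res_dir <- file.path(outdir, "results")
  dir.create(res_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(stage, msg) {
    if (!quiet) message(sprintf("[%s] %s", stage, msg))
  }
  stage_done <- function(files) resume && all(file.exists(files))

  # ---- stage: simulate -----------------------------------------------------
  sim_files <- file.path(data_dir, c("genome.fa", "genes.gff3", "truth.json",
                                     "atac_counts.tsv", "chip_counts.tsv",
                                     "rna_counts.tsv", "motifs.jaspar"))
  if (!stage_done(sim_files)) {
    log_stage("simulate", sprintf("generating synthetic regulome (seed %d)",
                                  params$seed))
    sim <- simulate_regenome(params)
    write_regenome(sim, data_dir)
  } else {
    log_stage("simulate", "outputs present, skipped")
  }
  genome <- read_genome_fasta(file.path(data_dir, "genome.fa"))
  gm <- read_gff3_genes(file.path(data_dir, "genes.gff3"))
  atac_counts <- read_count_table(file.path(data_dir, "atac_counts.tsv"))
  chip_counts <- read_count_table(file.path(data_dir, "chip_counts.tsv"))
  rna_counts <- read_count_table(file.path(data_dir, "rna_counts.tsv"))
  atac_samples <- read_tsv(file.path(data_dir, "samples_atac.tsv"),
                           show_col_types = FALSE)
  chip_samples <- read_tsv(file.path(data_dir, "samples_chip.tsv"),
                           show_col_types = FALSE)
  rna_samples <- read_tsv(file.path(data_dir, "samples_rna.tsv"),
                          show_col_types = FALSE)
  pfms <- read_jaspar(file.path(data_dir, "motifs.jaspar"))
  genome_sizes <- vapply(genome, nchar, integer(1))

  cols_of <- function(samples, cond) samples$sample_id[samples$condition == cond]

  # ---- stage: peaks --------------------------------------------------------
  peak_files <- file.path(res_dir,
                          sprintf("peaks_%s.narrowPeak",
                                  atac_samples$sample_id))
  if (!stage_done(peak_files)) {
    log_stage("peaks", "calling per-sample peaks")
    for (i in seq_len(nrow(atac_samples))) {
      sid <- atac_samples$sample_id[i]
      frags <- read_bed6(file.path(data_dir,
                                   sprintf("fragments_%s.bed", sid)))
      frags <- filter_nfr(frags, cfg)
      pk <- call_peaks(frags, genome_sizes, cfg, sample_id = sid)
      write_narrowpeak(pk, peak_files[i])
    }
  } else log_stage("peaks", "outputs present, skipped")

  # ---- stage: merge --------------------------------------------------------
  merged_file <- file.path(res_dir, "merged_peaks.tsv")
  if (!stage_done(merged_file)) {
    log_stage("merge", "merging peaks across samples")
    per_sample <- lapply(seq_len(nrow(atac_samples)), function(i) {
      pk <- read_narrowpeak(peak_files[i])
      tibble(chrom = pk$chrom, start = pk$start, end = pk$end,
             summit = pk$summit, score = pk$qvalue,
             sample_evidence = atac_samples$sample_id[i],
             assay_evidence = "ATAC")
    })
    merged <- merge_peaks(bind_rows(per_sample))
    # ChIP evidence: merged peaks overlapping a region whose normalised
    # H3K27ac mean reaches the configured floor in either pole
    chip_regions <- parse_region_keys(rownames(chip_counts))
    chip_norm <- sweep(chip_counts, 2,
                       colSums(chip_counts) /
                         mean(colSums(chip_counts)), "/")
    chip_hot <- chip_regions[
      pmax(rowMeans(chip_norm[, cols_of(chip_samples, "chip_ant"),
                              drop = FALSE]),
           rowMeans(chip_norm[, cols_of(chip_samples, "chip_post"),
                              drop = FALSE])) >= cfg$min_chip_mean, ,
      drop = FALSE]
    has_chip <- overlaps_any(merged, chip_hot)
    merged$assay_evidence[has_chip] <-
      paste0(merged$assay_evidence[has_chip], ",CHIP")
    write_plain_tsv(merged, merged_file)
  } else log_stage("merge", "outputs present, skipped")
  merged <- read_tsv(merged_file, show_col_types = FALSE)

  # ---- stage: acr ----------------------------------------------------------
  log_stage("acr", "anterior vs posterior differential accessibility")
  atac_lib <- colSums(atac_counts)
  diff_ap <- nb_diff_test(atac_counts,
                          group_a = cols_of(atac_samples, "wt_ant"),
                          group_b = cols_of(atac_samples, "wt_post"),
                          lib_sizes = atac_lib)
  acr_sets <- select_pole_acrs(diff_ap, cfg)
  acrs <- list(anterior = acr_sets$a_specific,
               posterior = acr_sets$b_specific)
  for (pole in names(acrs)) {
    reg <- parse_region_keys(acrs[[pole]]$region)
    write_bed6(reg, file.path(res_dir, sprintf("acrs_%s.bed", pole)))
  }

  # ---- stage: split (enhancer vs promoter-like) ----------------------------
  log_stage("split", "splitting ACRs by H3K27ac evidence")
  chip_lib <- colSums(chip_counts)
  chip_norm_mean <- function(cond) {
    m <- sweep(chip_counts, 2, chip_lib / mean(chip_lib), "/")
    rowMeans(m[, cols_of(chip_samples, cond), drop = FALSE])
  }
  splits <- list()
  for (pole in names(acrs)) {
    wt_cond <- if (pole == "anterior") "wt_ant" else "wt_post"
    chip_cond <- if (pole == "anterior") "chip_ant" else "chip_post"
    atac_cols <- cols_of(atac_samples, wt_cond)
    chip_cols <- cols_of(chip_samples, chip_cond)
    cross_counts <- cbind(atac_counts[, atac_cols, drop = FALSE],
                          chip_counts[, chip_cols, drop = FALSE])
    cross_lib <- c(atac_lib[atac_cols], chip_lib[chip_cols])
    cross <- nb_diff_test(cross_counts, atac_cols, chip_cols,
                          lib_sizes = cross_lib)
    chip_evidence <- rownames(chip_counts)[chip_norm_mean(chip_cond) >=
                                             cfg$min_chip_mean]
    splits[[pole]] <- split_enhancer_promoter(acrs[[pole]], cross,
                                              chip_evidence)
    for (set in c("putative_enhancers", "promoter_like")) {
      reg <- parse_region_keys(splits[[pole]][[set]]$region)
      write_bed6(reg, file.path(res_dir, sprintf("%s_%s.bed", set, pole)))
    }
  }

  # ---- stage: states (second round) ----------------------------------------
  log_stage("states", "second-round RNAi accessibility states")
  states <- list()
  state_summaries <- list()
  for (pole in names(splits)) {
    wt_cond <- if (pole == "anterior") "wt_ant" else "wt_post"
    enh_regions <- splits[[pole]]$putative_enhancers$region
    for (rnai in c("notum_ant", "wnt1_post")) {
      key <- sprintf("%s_vs_%s", pole, rnai)
      sub <- atac_counts[enh_regions, , drop = FALSE]
      second <- nb_diff_test(sub,
                             group_a = cols_of(atac_samples, wt_cond),
                             group_b = cols_of(atac_samples, rnai),
                             lib_sizes = atac_lib)
      st <- second_round_states(second)
      states[[key]] <- st
      state_summaries[[key]] <- summarize_states(st$state)
      write_plain_tsv(st, file.path(res_dir,
                                    sprintf("states_%s.tsv", key)))
    }
  }
  jsonlite::write_json(
    lapply(state_summaries, function(s) {
      list(fractions = as.list(s$fractions),
           n_classified = s$n_classified,
           n_unclassified = s$n_unclassified)
    }),
    file.path(res_dir, "state_summary.json"), auto_unbox = TRUE, digits = NA
  )

  # ---- stage: cre ----------------------------------------------------------
  log_stage("cre", "annotating cis-regulatory elements")
  annos <- annotate_cres(merged, gm, cfg)
  write_plain_tsv(annos, file.path(res_dir, "cre_annotation.tsv"))
  for (cls in CRE_CLASSES) {
    sub <- annos[annos$cre_class == cls, , drop = FALSE]
    write_bed6(sub[, c("chrom", "start", "end")],
               file.path(res_dir, sprintf("cre_%s.bed", cls)))
  }

  # ---- stage: motifs -------------------------------------------------------
  log_stage("motifs", "scanning motifs and computing enrichment")
  bg <- genome_background(genome)
  pwms <- lapply(names(pfms), function(id) pwm_matrix(id, pfms[[id]], bg))
  names(pwms) <- names(pfms)
  annotated <- annos[annos$cre_class != "unannotated", , drop = FALSE]
  hits <- scan_regions(annotated, genome, pwms, cfg$motif_scan_p)
  write_plain_tsv(hits, file.path(res_dir, "motif_hits.tsv"))

  pole_cres <- lapply(names(acrs), function(pole) {
    acr_reg <- parse_region_keys(acrs[[pole]]$region)
    annotated[overlaps_any(annotated, acr_reg), , drop = FALSE]
  })
  names(pole_cres) <- names(acrs)
  enrichment <- list()
  for (pole in names(acrs)) {
    enh_cres <- pole_cres[[pole]][
      pole_cres[[pole]]$cre_class %in% c("FI", "Pro", "Dis"), , drop = FALSE]
    if (nrow(enh_cres) > 0) {
      enrichment[[pole]] <- motif_enrichment(
        enh_cres, genome, pwms,
        background_n = 10L * nrow(enh_cres),
        p_cut = cfg$motif_scan_p, adj_p = cfg$motif_adj_p,
        seed = derive_seed(params$seed, 7L))
      write_plain_tsv(enrichment[[pole]],
                      file.path(res_dir,
                                sprintf("motif_enrichment_%s.tsv", pole)))
    }
  }
  hits_by_pole <- lapply(pole_cres, function(cres) {
    hits[hits$region %in% cres$region, , drop = FALSE]
  })
  foxg <- foxg_ratio_categories(
    gene_motif_counts(pole_cres$anterior, hits_by_pole$anterior),
    gene_motif_counts(pole_cres$posterior, hits_by_pole$posterior),
    "FOXG_SYN")
  write_plain_tsv(foxg, file.path(res_dir, "foxg_categories.tsv"))

  # ---- stage: de -----------------------------------------------------------
  log_stage("de", "differential expression, wnt1 RNAi vs control")
  rna_groups <- rna_samples$condition[match(colnames(rna_counts),
                                            rna_samples$sample_id)]
  filtered <- cpm_filter(rna_counts, rna_groups, cfg)
  de <- moderated_de_test(filtered,
                          group_a = cols_of(rna_samples, "ctrl"),
                          group_b = cols_of(rna_samples, "wnt1"),
                          cfg = cfg)
  write_plain_tsv(de, file.path(res_dir, "de_results.tsv"))

  # ---- stage: integrate ----------------------------------------------------
  log_stage("integrate", "integrating DE genes with motif annotations")
  motif_ids <- names(pwms)
  tcf_enh <- genes_with_motif(annotated, hits, "TCF_SYN", "enhancer",
                              motif_ids)
  tcf_prom <- genes_with_motif(annotated, hits, "TCF_SYN", "promoter",
                               motif_ids)
  foxg_genes <- genes_with_motif(annotated, hits, "FOXG_SYN", "either",
                                 motif_ids)
  integration <- integrate_targets(de, tcf_enh, tcf_prom, foxg_genes)
  jsonlite::write_json(
    list(counts = as.list(integration$counts),
         downregulated = integration$downregulated,
         tcf_enhancer_down = integration$tcf_enhancer_down,
         tcf_promoter_down = integration$tcf_promoter_down,
         foxg_down = integration$foxg_down),
    file.path(res_dir, "integration_report.json"),
    auto_unbox = TRUE, digits = NA
  )

  manifest <- list(
    seed = params$seed,
    config = unclass(cfg),
    sim_params = unclass(params),
    outputs = {
      files <- sort(list.files(c(data_dir, res_dir), full.names = TRUE))
      stats::setNames(as.list(unname(tools::md5sum(files))),
                      file.path(basename(dirname(files)), basename(files)))
    },
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(manifest = manifest, diff_ap = diff_ap, acrs = acrs,
                 splits = splits, states = states,
                 state_summaries = state_summaries, annos = annos,
                 enrichment = enrichment, foxg = foxg, de = de,
                 integration = integration,
                 tcf_enhancer_genes = tcf_enh,
                 tcf_promoter_genes = tcf_prom,
                 foxg_genes = foxg_genes))
}
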