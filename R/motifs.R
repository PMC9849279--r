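DNA <- c("A", "C", "G", "T")

#' Build a position weight matrix object
#'
#' Converts a JASPAR-style count matrix into probability and log2-odds score
#' form against a background nucleotide model. A pseudocount proportional to
#' the background frequency is added to every cell before normalisation.
#'
#' @param motif_id Motif identifier.
#' @param counts `width x 4` non-negative count matrix, columns A, C, G, T.
#' @param background Length-4 background probabilities (A, C, G, T); defaults
#'   to uniform. Use [genome_background()] for genome-derived frequencies.
#' @param pseudocount Total pseudocount spread over the four letters by
#'   background weight (default 1).
#' @return Object of class `wr_pwm` with elements `motif_id`, `counts`,
#'   `background`, `pseudocount`, `prob` and `score` (log2-odds bits).
#' @export
pwm_matrix <- function(motif_id, counts, background = rep(0.25, 4),
                       pseudocount = 1) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == 4, nrow(counts) >= 4, all(counts >= 0),
            length(background) == 4, all(background > 0))
  colnames(counts) <- DNA
  background <- background / sum(background)
  adj <- counts + pseudocount * matrix(background, nrow(counts), 4,
                                       byrow = TRUE)
  prob <- adj / rowSums(adj)
  if (any(prob <= 0)) {
    stop("degenerate PWM: zero probability cell after pseudocount",
         call. = FALSE)
  }
  score <- log2(sweep(prob, 2, background, "/"))
  structure(list(motif_id = motif_id, counts = counts,
                 background = stats::setNames(background, DNA),
                 pseudocount = pseudocount, prob = prob, score = score,
                 cache = new.env(parent = emptyenv())),
            class = "wr_pwm")
}

#' @export
print.wr_pwm <- function(x, ...) {
  cat("<wr_pwm> ", x$motif_id, " width ", nrow(x$score), "\n", sep = "")
  invisible(x)
}

#' Mononucleotide background frequencies of a genome
#' @param genome Named character vector of sequences.
#' @return Length-4 probability vector (A, C, G, T).
#' @export
genome_background <- function(genome) {
  tab <- table(factor(strsplit(paste(genome, collapse = ""), "")[[1]],
                      levels = DNA))
  p <- as.numeric(tab) / sum(tab)
  stats::setNames(p, DNA)
}

#' Reverse complement of a PWM score matrix
#' @noRd
revcomp_score <- function(score) {
  score[rev(seq_len(nrow(score))), c(4, 3, 2, 1), drop = FALSE]
}

# Exact null distribution of the PWM score under the background model,
# computed by dynamic-programming convolution of per-position score
# distributions discretised at `delta` bits per bin.
#
# Returns list(min_bin, tail) with tail[k] = P(score >= (min_bin + k - 1) * delta).
pwm_score_null <- function(score, background, delta = 0.001) {
  bins <- round(score / delta)
  if (any(!is.finite(bins))) {
    stop("degenerate PWM: infinite score", call. = FALSE)
  }
  storage.mode(bins) <- "integer"
  cur <- 1
  cur_min <- 0L
  for (j in seq_len(nrow(bins))) {
    row <- bins[j, ]
    rmin <- min(row)
    new_len <- length(cur) + (max(row) - rmin)
    new <- numeric(new_len)
    for (l in 1:4) {
      off <- row[l] - rmin
      idx <- seq_along(cur) + off
      new[idx] <- new[idx] + cur * background[l]
    }
    cur <- new
    cur_min <- cur_min + rmin
  }
  tail <- rev(cumsum(rev(cur)))
  list(min_bin = cur_min, tail = tail, delta = delta)
}

# memoised per-strand null distribution (the DP convolution is the costly
# step of a scan, and identical for every sequence)
pwm_null_cached <- function(pwm, strand) {
  key <- paste0("null_", strand)
  if (is.null(pwm$cache[[key]])) {
    smat <- if (strand == "+") pwm$score else revcomp_score(pwm$score)
    pwm$cache[[key]] <- pwm_score_null(smat, pwm$background)
  }
  pwm$cache[[key]]
}

# P(score >= s) for a vector of scores, from a pwm_score_null object
null_tail_p <- function(null, scores) {
  k <- round(scores / null$delta) - null$min_bin + 1L
  k <- pmax(1L, k)
  p <- rep(0, length(scores))
  inside <- k <= length(null$tail)
  p[inside] <- null$tail[k[inside]]
  p
}

#' Score threshold for a match p-value
#'
#' The smallest log2-odds score `s` such that the exact background
#' probability of a single window scoring `>= s` is at most `p_cut`. The
#' null distribution is computed by dynamic-programming convolution of the
#' per-position score distribution, discretised at 1/1000 bit.
#'
#' @param pwm A [pwm_matrix()] object.
#' @param p_cut Match p-value in (0, 1].
#' @return Score threshold in bits.
#' @export
score_threshold <- function(pwm, p_cut) {
  stopifnot(inherits(pwm, "wr_pwm"), p_cut > 0, p_cut <= 1)
  null <- pwm_null_cached(pwm, "+")
  k <- which(null$tail <= p_cut)
  if (length(k) == 0) k <- length(null$tail) + 1L  # nothing passes
  (null$min_bin + min(k) - 1L) * null$delta
}

# integer codes 1..4 for A,C,G,T; NA otherwise (N never matches)
dna_codes <- function(seq) {
  match(strsplit(toupper(seq), "")[[1]], DNA)
}

# sliding-window log2-odds scores of a score matrix over coded sequence;
# windows containing non-ACGT letters score -Inf
window_scores <- function(codes, score) {
  w <- nrow(score)
  L <- length(codes)
  if (L < w) return(numeric(0))
  n <- L - w + 1L
  total <- numeric(n)
  bad <- logical(n)
  for (j in seq_len(w)) {
    cj <- codes[j:(j + n - 1L)]
    miss <- is.na(cj)
    bad <- bad | miss
    cj[miss] <- 1L
    total <- total + unname(score[j, cj])
  }
  total[bad] <- -Inf
  total
}

#' Scan a sequence with a PWM
#'
#' Both strands are scanned; windows whose log2-odds score reaches the
#' exact-null threshold for `p_cut` are emitted with their exact match
#' p-value. Coordinates are half-open on the forward strand; `N` bases never
#' match.
#'
#' @param seq DNA string (A/C/G/T/N).
#' @param pwm A [pwm_matrix()] object.
#' @param p_cut Match p-value cutoff (default 1e-4, the common FIMO default).
#' @return Tibble `motif_id`, `start`, `end`, `strand`, `score`, `p`.
#' @export
scan_pwm <- function(seq, pwm, p_cut = 1e-4) {
  stopifnot(inherits(pwm, "wr_pwm"))
  codes <- dna_codes(seq)
  w <- nrow(pwm$score)
  empty <- tibble(motif_id = character(), start = integer(), end = integer(),
                  strand = character(), score = numeric(), p = numeric())
  if (length(codes) < w) return(empty)
  out <- list()
  for (str in c("+", "-")) {
    smat <- if (str == "+") pwm$score else revcomp_score(pwm$score)
    null <- pwm_null_cached(pwm, str)
    thr_bin <- {
      k <- which(null$tail <= p_cut)
      if (length(k) == 0) Inf else (null$min_bin + min(k) - 1L) * null$delta
    }
    sc <- window_scores(codes, smat)
    hit <- which(sc >= thr_bin)
    if (length(hit) > 0) {
      out[[str]] <- tibble(
        motif_id = pwm$motif_id,
        start = hit - 1L,
        end = hit - 1L + w,
        strand = str,
        score = sc[hit],
        p = null_tail_p(null, sc[hit])
      )
    }
  }
  if (length(out) == 0) return(empty)
  arrange(bind_rows(out), .data$start, .data$strand)
}

#' Scan a set of regions against a motif library
#'
#' @param regions Interval tibble (`chrom`, `start`, `end`); an optional
#'   `region` column supplies keys, otherwise `chrom:start-end` is used.
#' @param genome Named character vector of chromosome sequences.
#' @param pwms List of [pwm_matrix()] objects.
#' @param p_cut Match p-value cutoff.
#' @return Tibble `region`, `motif_id`, `start`, `end`, `strand`, `score`,
#'   `p`, with `start`/`end` in genome coordinates.
#' @export
scan_regions <- function(regions, genome, pwms, p_cut = 1e-4) {
  check_intervals(regions)
  keys <- if ("region" %in% names(regions)) regions$region
          else region_keys(regions)
  out <- vector("list", nrow(regions) * length(pwms))
  k <- 0L
  for (i in seq_len(nrow(regions))) {
    chrom <- regions$chrom[i]
    if (!chrom %in% names(genome)) {
      stop("chromosome absent from genome: ", chrom, call. = FALSE)
    }
    seq <- substr(genome[[chrom]], regions$start[i] + 1L, regions$end[i])
    for (pwm in pwms) {
      hits <- scan_pwm(seq, pwm, p_cut)
      if (nrow(hits) > 0) {
        hits$start <- hits$start + regions$start[i]
        hits$end <- hits$end + regions$start[i]
        hits$region <- keys[i]
        k <- k + 1L
        out[[k]] <- hits
      }
    }
  }
  if (k == 0L) {
    return(tibble(region = character(), motif_id = character(),
                  start = integer(), end = integer(), strand = character(),
                  score = numeric(), p = numeric()))
  }
  bind_rows(out[seq_len(k)])[, c("region", "motif_id", "start", "end",
                                 "strand", "score", "p")]
}

#' Motif over-representation in target regions vs sampled background
#'
#' Background regions are length-matched intervals sampled uniformly from
#' the genome, excluding the target regions. For each motif the
#' region-level hit frequency (at least one match per region) in targets is
#' compared against the sampled background by a one-sided exact
#' (hypergeometric) test — the exact form of the binomial comparison, which
#' stays valid when the background frequency is itself estimated from few
#' regions; p-values are BH adjusted across motifs.
#'
#' @param target Interval tibble of target regions.
#' @param genome Named character vector of chromosome sequences.
#' @param pwms List of [pwm_matrix()] objects.
#' @param background_n Number of background regions (at least 10x the target
#'   count).
#' @param p_cut Match p-value for scanning (default 1e-4).
#' @param adj_p Adjusted p-value cutoff for flagging (default 0.05).
#' @param seed Integer seed for background sampling.
#' @return Tibble `motif_id`, `target_freq`, `bg_freq`, `p`, `adj_p`,
#'   `significant`.
#' @export
motif_enrichment <- function(target, genome, pwms, background_n = NULL,
                             p_cut = 1e-4, adj_p = 0.05, seed = 1L) {
  check_intervals(target)
  if (nrow(target) == 0) stop("empty target set", call. = FALSE)
  if (is.null(background_n)) background_n <- 10L * nrow(target)
  if (background_n < 10L * nrow(target)) {
    stop("background_n must be at least 10x the number of targets",
         call. = FALSE)
  }
  bg <- sample_background_regions(target, genome, background_n, seed)
  n_t <- nrow(target)
  n_b <- nrow(bg)
  rows <- lapply(pwms, function(pwm) {
    t_hits <- scan_regions(target, genome, list(pwm), p_cut)
    b_hits <- scan_regions(bg, genome, list(pwm), p_cut)
    t_keys <- if ("region" %in% names(target)) target$region
              else region_keys(target)
    k_t <- sum(t_keys %in% t_hits$region)
    k_b <- length(unique(b_hits$region))
    tibble(
      motif_id = pwm$motif_id,
      target_freq = k_t / n_t,
      bg_freq = k_b / n_b,
      # one-sided exact test: P(target hits >= k_t | margins)
      p = stats::phyper(k_t - 1L, k_t + k_b, n_t + n_b - k_t - k_b, n_t,
                        lower.tail = FALSE)
    )
  })
  out <- bind_rows(rows)
  out$adj_p <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$adj_p < adj_p
  arrange(out, .data$adj_p, .data$motif_id)
}

#' Sample length-matched background regions avoiding a target set
#' @noRd
sample_background_regions <- function(target, genome, n, seed) {
  chrom_len <- vapply(genome, nchar, integer(1))
  widths <- target$end - target$start
  out <- with_seed(seed, {
    picked <- list()
    got <- 0L
    guard <- 0L
    while (got < n && guard < 200L) {
      guard <- guard + 1L
      need <- n - got
      w <- sample(widths, need, replace = TRUE)
      chrom <- sample(names(genome), need, replace = TRUE,
                      prob = chrom_len / sum(chrom_len))
      maxstart <- chrom_len[chrom] - w
      ok <- maxstart >= 0
      w <- w[ok]; chrom <- chrom[ok]; maxstart <- maxstart[ok]
      start <- floor(stats::runif(length(w)) * (maxstart + 1))
      cand <- tibble(chrom = chrom, start = as.integer(start),
                     end = as.integer(start + w))
      keep <- !overlaps_any(cand, target)
      cand <- cand[keep, ]
      if (nrow(cand) > 0) {
        got <- got + nrow(cand)
        picked[[length(picked) + 1L]] <- cand
      }
    }
    if (got < n) {
      stop("could not sample enough background regions", call. = FALSE)
    }
    bind_rows(picked)[seq_len(n), ]
  })
  out$region <- sprintf("bg_%d", seq_len(nrow(out)))
  out
}

#' Which rows of `a` overlap any row of `b`?
#' @noRd
overlaps_any <- function(a, b) {
  if (nrow(a) == 0) return(logical(0))
  if (nrow(b) == 0) return(rep(FALSE, nrow(a)))
  GenomicRanges::countOverlaps(gr_from_tbl(a), gr_from_tbl(b),
                               ignore.strand = TRUE) > 0
}

#' Genes whose CREs of a compartment contain a motif
#'
#' @param annos CRE annotation tibble with `region`, `gene_id`, `cre_class`.
#' @param hits Motif hit tibble from [scan_regions()].
#' @param motif_id Motif to look up; must belong to `motif_ids`.
#' @param compartment `"enhancer"` (FI/Pro/Dis), `"promoter"` (CP/PP) or
#'   `"either"`.
#' @param motif_ids Universe of known motif identifiers (defaults to the
#'   motifs present in `hits`).
#' @return Character vector of gene identifiers.
#' @export
genes_with_motif <- function(annos, hits, motif_id,
                             compartment = c("either", "enhancer", "promoter"),
                             motif_ids = unique(hits$motif_id)) {
  compartment <- match.arg(compartment)
  if (!motif_id %in% motif_ids) {
    stop("unknown motif_id: ", motif_id, call. = FALSE)
  }
  classes <- switch(compartment,
                    enhancer = c("FI", "Pro", "Dis"),
                    promoter = c("CP", "PP"),
                    either = c("FI", "Pro", "Dis", "CP", "PP"))
  sel <- annos |> filter(.data$cre_class %in% classes)
  hit_regions <- unique(hits$region[hits$motif_id == motif_id])
  sort(unique(sel$gene_id[sel$region %in% hit_regions]))
}

#' Per-gene motif hit counts over a CRE set
#'
#' @param annos CRE annotation tibble with `region`, `gene_id`.
#' @param hits Motif hits from [scan_regions()].
#' @return Tibble `gene_id`, `motif_id`, `n`.
#' @export
gene_motif_counts <- function(annos, hits) {
  joined <- hits |>
    dplyr::inner_join(annos[, c("region", "gene_id")], by = "region")
  joined |>
    group_by(.data$gene_id, .data$motif_id) |>
    summarise(n = n(), .groups = "drop")
}

#' FoxG ratio categories per gene
#'
#' For each gene, the FoxG ratio in a pole is the number of FoxG motif
#' matches divided by the total number of motif matches over the gene's
#' regions in that pole (0 when the gene has no matches there). Categories:
#' `A_to_0` (FoxG only anterior), `ZERO_to_P` (FoxG only posterior),
#' `SIMILAR` (FoxG in both), `NONE` (FoxG in neither).
#'
#' @param counts_anterior,counts_posterior Tibbles from
#'   [gene_motif_counts()] computed on the pole-specific CRE sets.
#' @param foxg_id Identifier of the FoxG motif.
#' @return Tibble `gene_id`, `ratio_anterior`, `ratio_posterior`,
#'   `category`.
#' @export
foxg_ratio_categories <- function(counts_anterior, counts_posterior,
                                  foxg_id) {
  pole_ratio <- function(counts) {
    counts |>
      group_by(.data$gene_id) |>
      summarise(ratio = sum(.data$n[.data$motif_id == foxg_id]) /
                  max(sum(.data$n), 1L),
                .groups = "drop")
  }
  ra <- pole_ratio(counts_anterior)
  rp <- pole_ratio(counts_posterior)
  genes <- sort(unique(c(ra$gene_id, rp$gene_id)))
  out <- tibble(gene_id = genes) |>
    left_join(ra, by = "gene_id") |>
    dplyr::rename(ratio_anterior = "ratio") |>
    left_join(rp, by = "gene_id") |>
    dplyr::rename(ratio_posterior = "ratio")
  out$ratio_anterior[is.na(out$ratio_anterior)] <- 0
  out$ratio_posterior[is.na(out$ratio_posterior)] <- 0
  out$category <- with(out, ifelse(
    ratio_anterior > 0 & ratio_posterior == 0, "A_to_0",
    ifelse(ratio_anterior == 0 & ratio_posterior > 0, "ZERO_to_P",
           ifelse(ratio_anterior > 0 & ratio_posterior > 0, "SIMILAR",
                  "NONE"))))
  out
}
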