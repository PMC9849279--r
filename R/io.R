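#' @importFrom readr read_tsv write_tsv cols col_character col_integer
#'   col_double
NULL

# ---- BED / narrowPeak ------------------------------------------------------

#' Read a BED6 file
#'
#' @param path File path. Columns beyond the sixth are ignored.
#' @return Tibble `chrom`, `start`, `end`, `name`, `score`, `strand`.
#' @export
read_bed6 <- function(path) {
  tbl <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tbl) < 3) stop("BED needs at least 3 columns", call. = FALSE)
  out <- tibble(
    chrom = tbl[[1]],
    start = as.integer(tbl[[2]]),
    end = as.integer(tbl[[3]]),
    name = if (ncol(tbl) >= 4) tbl[[4]] else ".",
    score = if (ncol(tbl) >= 5) suppressWarnings(as.numeric(tbl[[5]])) else 0,
    strand = if (ncol(tbl) >= 6) tbl[[6]] else "."
  )
  check_intervals(out)
  out
}

#' Write a BED6 file (sorted, tab-separated, newline-terminated)
#'
#' @param tbl Tibble with `chrom`, `start`, `end`; missing `name`, `score`,
#'   `strand` are filled with `.`, `0`, `.`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(tbl, path) {
  check_intervals(tbl)
  out <- tibble(
    chrom = tbl$chrom,
    start = tbl$start,
    end = tbl$end,
    name = if ("name" %in% names(tbl)) tbl$name else ".",
    score = if ("score" %in% names(tbl)) tbl$score else 0,
    strand = if ("strand" %in% names(tbl)) tbl$strand else "."
  ) |> arrange(.data$chrom, .data$start, .data$end)
  write_plain_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a narrowPeak (BED6+4) file
#'
#' @param path File path.
#' @return Peak tibble with `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, `signal`, `pvalue`, `qvalue`, `summit` (offset from `start`).
#' @export
read_narrowpeak <- function(path) {
  tbl <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tbl) != 10) stop("narrowPeak requires 10 columns", call. = FALSE)
  out <- tibble(
    chrom = tbl[[1]], start = as.integer(tbl[[2]]), end = as.integer(tbl[[3]]),
    name = tbl[[4]], score = as.numeric(tbl[[5]]), strand = tbl[[6]],
    signal = as.numeric(tbl[[7]]), pvalue = as.numeric(tbl[[8]]),
    qvalue = as.numeric(tbl[[9]]), summit = as.integer(tbl[[10]])
  )
  check_intervals(out)
  out
}

#' Write a narrowPeak (BED6+4) file
#'
#' @param peaks Peak tibble with at least `chrom`, `start`, `end`, `summit`;
#'   `score` is scaled into the conventional integer column 5.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  check_intervals(peaks)
  stopifnot("summit" %in% names(peaks))
  score <- if ("score" %in% names(peaks)) peaks$score else 0
  out <- tibble(
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    name = if ("name" %in% names(peaks)) peaks$name
           else sprintf("peak_%d", seq_len(nrow(peaks))),
    score5 = pmin(1000L, as.integer(round(10 * score))),
    strand = ".",
    signal = if ("signal" %in% names(peaks)) peaks$signal else score,
    pvalue = if ("pvalue" %in% names(peaks)) peaks$pvalue else -1,
    qvalue = if ("qvalue" %in% names(peaks)) peaks$qvalue else score,
    summit = peaks$summit
  ) |> arrange(.data$chrom, .data$start, .data$end)
  write_plain_tsv(out, path, col_names = FALSE)
  invisible(path)
}

# deterministic, locale-independent writer used by all text outputs
write_plain_tsv <- function(tbl, path, col_names = TRUE) {
  df <- as.data.frame(tbl)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), "NA", formatC(x, format = "g", digits = 10))
  })
  lines <- do.call(paste, c(unname(df), sep = "\t"))
  if (col_names) lines <- c(paste(names(tbl), collapse = "\t"), lines)
  writeLines(lines, path)
  invisible(path)
}

# ---- GFF3 ------------------------------------------------------------------

#' Read gene models from GFF3
#'
#' Uses `gene` and `exon` features with `Parent` linkage; GFF3's 1-based
#' closed coordinates are converted to the package's 0-based half-open
#' convention on read.
#'
#' @param path GFF3 file path.
#' @return A [gene_models()] object.
#' @export
read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  genes_gr <- gr[gr$type == "gene"]
  exons_gr <- gr[gr$type == "exon"]
  genes <- tibble(
    gene_id = as.character(genes_gr$ID),
    chrom = as.character(GenomicRanges::seqnames(genes_gr)),
    start = GenomicRanges::start(genes_gr) - 1L,
    end = GenomicRanges::end(genes_gr),
    strand = as.character(GenomicRanges::strand(genes_gr))
  )
  parent <- vapply(exons_gr$Parent, function(p) as.character(p)[1], character(1))
  exons <- tibble(
    gene_id = parent,
    chrom = as.character(GenomicRanges::seqnames(exons_gr)),
    start = GenomicRanges::start(exons_gr) - 1L,
    end = GenomicRanges::end(exons_gr)
  )
  gene_models(genes, exons)
}

#' Write gene models to GFF3
#'
#' @param gm A [gene_models()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3_genes <- function(gm, path) {
  stopifnot(inherits(gm, "wr_genes"))
  g <- gm$genes
  e <- gm$exons |>
    left_join(g[, c("gene_id", "strand")], by = "gene_id")
  lines <- c(
    "##gff-version 3",
    sprintf("%s\twoundRegulome\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
            g$chrom, g$start + 1L, g$end, g$strand, g$gene_id),
    sprintf("%s\twoundRegulome\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
            e$chrom, e$start + 1L, e$end, e$strand, e$gene_id, e$exon_rank,
            e$gene_id)
  )
  writeLines(lines, path)
  invisible(path)
}

# ---- FASTA -----------------------------------------------------------------

#' Read a genome FASTA into a named character vector
#' @param path FASTA path.
#' @return Named character vector of uppercase sequences.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Write a named character vector of sequences as FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(seqs, path, width = 70L) {
  dss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(dss, path, width = width)
  invisible(path)
}

# ---- count tables ----------------------------------------------------------

#' Read a region/gene count table (TSV)
#'
#' First column holds the feature key (regions as `chrom:start-end`, or gene
#' identifiers); remaining columns are integer counts per sample.
#'
#' @param path TSV path.
#' @return Integer matrix with feature rownames and sample colnames.
#' @export
read_count_table <- function(path) {
  tbl <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                           check.names = FALSE)
  as.matrix(tbl)
}

#' Write a count matrix as TSV
#' @param counts Matrix with rownames (feature keys) and colnames (samples).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  tbl <- tibble(feature = rownames(counts))
  for (s in colnames(counts)) tbl[[s]] <- counts[, s]
  write_plain_tsv(tbl, path)
  invisible(path)
}

#' Parse `chrom:start-end` region keys into an interval tibble
#' @param keys Character vector of region keys.
#' @return Interval tibble with `region` (the key), `chrom`, `start`, `end`.
#' @export
parse_region_keys <- function(keys) {
  m <- regmatches(keys, regexec("^(.+):([0-9]+)-([0-9]+)$", keys))
  bad <- lengths(m) != 4
  if (any(bad)) stop("malformed region key: ", keys[bad][1], call. = FALSE)
  tibble(
    region = keys,
    chrom = vapply(m, `[`, character(1), 2),
    start = as.integer(vapply(m, `[`, character(1), 3)),
    end = as.integer(vapply(m, `[`, character(1), 4))
  )
}

#' Format interval rows as `chrom:start-end` keys
#' @param tbl Interval tibble.
#' @return Character vector of keys.
#' @export
region_keys <- function(tbl) {
  sprintf("%s:%d-%d", tbl$chrom, tbl$start, tbl$end)
}

# ---- JASPAR PFM ------------------------------------------------------------

#' Read position frequency matrices in JASPAR format
#'
#' Accepts both the bracketed dialect (`A [ 1 2 3 ]`) and plain four-row
#' count matrices under each `>motif_id` header.
#'
#' @param path File path.
#' @return Named list of `width x 4` count matrices (columns A, C, G, T).
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(heads) == 0) stop("no JASPAR records found", call. = FALSE)
  out <- list()
  bounds <- c(heads, length(lines) + 1L)
  for (i in seq_along(heads)) {
    id <- strsplit(sub("^>\\s*", "", lines[heads[i]]), "\\s+")[[1]][1]
    body <- lines[(heads[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(body) < 4) stop("motif ", id, ": expected 4 rows", call. = FALSE)
    rows <- lapply(body[1:4], function(l) {
      l <- gsub("^[ACGTacgt]?\\s*\\[?", "", l)
      l <- gsub("\\]\\s*$", "", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    w <- unique(lengths(rows))
    if (length(w) != 1) stop("motif ", id, ": ragged rows", call. = FALSE)
    mat <- t(do.call(rbind, rows))
    colnames(mat) <- c("A", "C", "G", "T")
    out[[id]] <- mat
  }
  out
}

#' Write position frequency matrices in JASPAR (bracketed) format
#' @param pfms Named list of `width x 4` count matrices.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_jaspar <- function(pfms, path) {
  lines <- unlist(lapply(names(pfms), function(id) {
    m <- pfms[[id]]
    c(paste0(">", id),
      vapply(c("A", "C", "G", "T"), function(b) {
        sprintf("%s  [ %s ]", b,
                paste(formatC(m[, b], format = "g", digits = 6),
                      collapse = " "))
      }, character(1)))
  }))
  writeLines(lines, path)
  invisible(path)
}
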