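#' Generate a synthetic annotated genome
#'
#' Lays out non-overlapping single-exon genes along each chromosome so that
#' the realized coding fraction matches `config$coding_fraction`, draws a
#' random nucleotide sequence at the configured GC fraction, and places
#' repeat loci (the only permitted karyotype breakpoints) and selection
#' marker loci on the designated disomic chromosomes.  Deterministic given
#' `config$seed`.
#'
#' @param config a [sim_config()] object.
#' @param n_genes optional total gene count; when supplied the coding
#'   fraction must be attainable with genes inside the configured length
#'   range, otherwise the call is rejected.
#' @param sequence logical; generate the nucleotide sequence (needed for
#'   effect annotation, variant refs and trinucleotide spectra).
#' @return an object of class `genome_annotation`: chromosome lengths,
#'   a `genes` data.frame (1-based inclusive `start`/`end`, `strand`,
#'   `tss`), the genome sequence as a [Biostrings::DNAStringSet], realized
#'   coding and GC fractions, repeat loci, marker loci and (empty by
#'   default) masked regions.
#' @examples
#' cfg <- sim_config(chrom_lengths = c(chrA = 50000), disome_chroms = "chrA",
#'                   seed = 7)
#' gen <- make_genome(cfg)
#' gen$coding_fraction
#' @export
make_genome <- function(config, n_genes = NULL, sequence = TRUE) {
  validate_sim_config(config)
  cf <- config$coding_fraction
  lr <- config$gene_length_range
  if (!is.null(n_genes)) {
    need <- cf * sum(config$chrom_lengths)
    if (n_genes * lr[2] < need || n_genes * lr[1] > sum(config$chrom_lengths))
      stop_aneuvol("coding_fraction ", cf, " is infeasible for ", n_genes,
                   " genes with CDS lengths in [", lr[1], ", ", lr[2], "]")
  }
  with_seed(config$seed + 1L, {
    genes <- lapply(names(config$chrom_lengths), function(chrom) {
      place_genes(chrom, config$chrom_lengths[[chrom]], cf, lr)
    })
    genes <- do.call(rbind, genes)
    if (nrow(genes)) {
      genes$gene_id <- sprintf("G%05d", seq_len(nrow(genes)))
      genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
      genes <- genes[, c("gene_id", "chrom", "start", "end", "strand", "tss")]
    }
    seqs <- NULL
    gc_real <- config$gc_fraction
    if (sequence) {
      p <- c((1 - config$gc_fraction) / 2, config$gc_fraction / 2,
             config$gc_fraction / 2, (1 - config$gc_fraction) / 2)
      seqs <- Biostrings::DNAStringSet(vapply(
        config$chrom_lengths,
        function(L) paste(sample(c("A", "C", "G", "T"), L, TRUE, p),
                          collapse = ""),
        character(1)))
      names(seqs) <- names(config$chrom_lengths)
      counts <- Biostrings::letterFrequency(seqs, c("GC", "AT"))
      gc_real <- sum(counts[, "G|C"]) / sum(counts)
    }
    # breakpoints land only at repeats; keep them interstitial so simulated
    # losses/amplifications span a detectable fraction of the chromosome
    repeats <- do.call(rbind, lapply(names(config$chrom_lengths), function(ch) {
      L <- config$chrom_lengths[[ch]]
      n <- max(2L, round(L / config$repeat_spacing))
      at <- seq(0.1, 0.9, length.out = n + 2)[-c(1, n + 2)] +
        runif(n, -0.3, 0.3) * 0.8 / (n + 1)
      data.frame(chrom = ch, pos = sort(round(at * L)))
    }))
    markers <- data.frame(
      chrom = config$disome_chroms,
      pos = pmax(1L, round(config$chrom_lengths[config$disome_chroms] * 0.95)),
      marker = rep_len(c("HIS3", "KANMX"), length(config$disome_chroms)),
      row.names = NULL)
    structure(list(
      chrom_lengths = config$chrom_lengths,
      genes = genes,
      sequences = seqs,
      coding_fraction = if (nrow(genes))
        sum(genes$end - genes$start + 1) / sum(config$chrom_lengths) else 0,
      gc_fraction = gc_real,
      repeat_loci = repeats,
      marker_loci = markers,
      masked = data.frame(chrom = character(), start = integer(),
                          end = integer()),
      disome_chroms = config$disome_chroms
    ), class = "genome_annotation")
  })
}

# Sequential gene placement: gene lengths uniform (snapped to codons),
# intergenic gaps drawn with mean len * (1 - cf) / cf so the realized
# coding fraction converges to cf.
place_genes <- function(chrom, L, cf, len_range) {
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character())
  if (cf <= 0) return(empty)
  out_start <- integer(); out_end <- integer()
  gap_k <- (1 - cf) / cf
  cursor <- 1L + round(runif(1, 0, mean(len_range) * gap_k))
  repeat {
    len <- round(runif(1, len_range[1], len_range[2]))
    len <- max(3L, 3L * round(len / 3))
    if (cursor + len - 1 > L) break
    out_start <- c(out_start, cursor)
    out_end <- c(out_end, cursor + len - 1L)
    cursor <- cursor + len + max(0L, round(len * gap_k * runif(1, 0.5, 1.5)))
  }
  if (!length(out_start)) return(empty)
  data.frame(chrom = chrom, start = out_start, end = out_end,
             strand = sample(c("+", "-"), length(out_start), TRUE))
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", length(x$chrom_lengths), "chromosomes,",
      sum(x$chrom_lengths), "bp,", nrow(x$genes), "genes\n")
  cat(sprintf("  coding fraction %.3f, GC fraction %.3f\n",
              x$coding_fraction, x$gc_fraction))
  invisible(x)
}

# Copy number at (chrom, pos) given a karyotype segment table
# (chrom, start, end, cn); positions outside any segment default to 1.
cn_at <- function(karyo, chrom, pos) {
  cn <- rep(1L, length(chrom))
  for (ch in unique(chrom)) {
    k <- karyo[karyo$chrom == ch, , drop = FALSE]
    if (!nrow(k)) next
    k <- k[order(k$start), ]
    i <- which(chrom == ch)
    j <- findInterval(pos[i], k$start)
    ok <- j >= 1
    jj <- pmax(j, 1L)
    cn[i] <- ifelse(ok & pos[i] <= k$end[jj], k$cn[jj], 1L)
  }
  cn
}

# region class of positions: "coding" if inside any gene CDS.  Genes are
# non-overlapping and sorted within chromosome, so findInterval suffices.
region_at <- function(genes, chrom, pos) {
  out <- rep("noncoding", length(chrom))
  if (!nrow(genes)) return(out)
  for (ch in unique(chrom)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (!nrow(g)) next
    g <- g[order(g$start), ]
    i <- which(chrom == ch)
    j <- findInterval(pos[i], g$start)
    jj <- pmax(j, 1L)
    out[i][j >= 1 & pos[i] <= g$end[jj]] <- "coding"
  }
  out
}
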