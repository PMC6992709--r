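# Shared small-world fixtures, built once per test run.

small_config <- function(seed = 1, ...) {
  sim_config(chrom_lengths = setNames(rep(50000L, 6), paste0("chr", 1:6)),
             disome_chroms = paste0("chr", 1:3),
             n_background = 10, n_trans_genes = 50,
             seed = seed, ...)
}

.fixture_cache <- new.env(parent = emptyenv())

# one fully simulated small world reused by several test files
fixture_world <- function() {
  if (is.null(.fixture_cache$world)) {
    cfg <- small_config(seed = 42)
    genome <- make_genome(cfg)
    truth <- simulate_lineages(genome, cfg)
    .fixture_cache$world <- list(
      cfg = cfg, genome = genome, truth = truth,
      coverage = simulate_coverage(truth, cfg),
      callsets = simulate_variant_observations(truth, cfg),
      expression = simulate_expression(truth, cfg),
      growth = simulate_growth(truth, cfg))
  }
  .fixture_cache$world
}

# a hand-built two-gene toy genome with explicit sequence, for effect
# annotation and promoter tests
toy_genome <- function(seq_plus = NULL) {
  # gene A (+ strand) at 1001..1009: codons CAA GGT GAT
  # gene B (- strand) at 2001..2009
  chrom_len <- 3000L
  base <- paste(rep("A", chrom_len), collapse = "")
  s <- base
  substr(s, 1001, 1009) <- "CAAGGTGAT"
  substr(s, 2001, 2009) <- "CATTCCGTA"
  if (!is.null(seq_plus)) s <- seq_plus
  genes <- data.frame(
    gene_id = c("GA", "GB"),
    chrom = "chrT",
    start = c(1001L, 2001L),
    end = c(1009L, 2009L),
    strand = c("+", "-"),
    tss = c(1001L, 2009L))
  structure(list(
    chrom_lengths = c(chrT = chrom_len),
    genes = genes,
    sequences = Biostrings::DNAStringSet(c(chrT = s)),
    coding_fraction = 18 / chrom_len,
    gc_fraction = 0.38,
    repeat_loci = data.frame(chrom = "chrT", pos = c(500L, 2500L)),
    marker_loci = data.frame(chrom = character(), pos = integer(),
                             marker = character()),
    masked = data.frame(chrom = character(), start = integer(),
                        end = integer()),
    disome_chroms = character()
  ), class = "genome_annotation")
}

# minimal variant observation row builder
vo <- function(chrom = "chr1", pos, ref = "A", alt = "T",
               type = "substitution", dp = 50L, ad = 50L,
               sample_id = "S", caller = "caller_a") {
  data.frame(sample_id = sample_id, chrom = chrom, pos = as.integer(pos),
             ref = ref, alt = alt, type = type, dp = as.integer(dp),
             ad = as.integer(ad), caller = caller)
}

# normalized-matrix stub from a log2 matrix
fake_norm <- function(log2mat, meta = NULL) {
  structure(list(log2 = log2mat,
                 size_factors = rep(1, ncol(log2mat)),
                 meta = meta %||% data.frame(
                   sample_id = colnames(log2mat),
                   strain = NA, role = NA, disome_chrom = NA)),
            class = "normalized_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
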