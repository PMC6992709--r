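#' Simulate windowed read coverage
#'
#' Tiles every chromosome with half-open windows of
#' `config$window_size` bp (the last window truncated at the chromosome
#' end) and draws read counts from a negative binomial with mean
#' `depth * copy_number * width / window_size` and dispersion
#' `nb_dispersion` (Poisson in the dispersion -> 0 limit).  Copy number is
#' taken from the sample's true karyotype at the window midpoint.
#'
#' @param truth an [simulate_lineages()] object.
#' @param config the matching [sim_config()].
#' @param samples sample ids to simulate (default: all).
#' @return named list of `coverage_profile` objects.
#' @export
simulate_coverage <- function(truth, config, samples = NULL) {
  validate_sim_config(config)
  assert_that(config$depth > 0, "depth must be positive")
  ids <- samples %||% truth$samples$sample_id
  grid <- window_grid(truth$genome$chrom_lengths, config$window_size)
  out <- lapply(ids, function(id) {
    k <- truth$karyotypes[truth$karyotypes$sample_id == id, ]
    mid <- floor((grid$start + grid$end) / 2) + 1L
    cn <- cn_at(k, grid$chrom, mid)
    mu <- config$depth * cn * (grid$end - grid$start) / config$window_size
    with_seed(config$seed + 3000L + match(id, truth$samples$sample_id), {
      counts <- draw_nb(mu, config$nb_dispersion)
      coverage_profile(id, data.frame(chrom = grid$chrom, start = grid$start,
                                      end = grid$end, count = counts))
    })
  })
  setNames(out, ids)
}

window_grid <- function(chrom_lengths, window_size) {
  do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    start <- seq(0L, L - 1L, by = window_size)
    data.frame(chrom = ch, start = start, end = pmin(start + window_size, L))
  }))
}

draw_nb <- function(mu, dispersion) {
  if (dispersion <= 1e-12) rpois(length(mu), mu)
  else rnbinom(length(mu), mu = mu, size = 1 / dispersion)
}

#' Simulate two variant-caller call sets per sample
#'
#' Every true de novo mutation appears in both call sets with total read
#' depth ~ Poisson(depth x copy number) and an alt-read fraction centred
#' on 0.5 when the site currently has copy number 2 (the variant sits on
#' one of two copies) and on 1.0 otherwise.  Each caller additionally
#' emits Poisson(`fp_rate`) private false positives, and each strain
#' carries `n_background` ancestral variants present in the ancestor and
#' all of its evolved lines (in both callers).
#'
#' @inheritParams simulate_coverage
#' @return named list (by sample) of lists with elements `a` and `b`,
#'   each a variant observation data.frame with columns `sample_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `type`, `dp`, `ad`, `caller` and a
#'   generator-only `origin` flag (`denovo`, `background`,
#'   `false_positive`).
#' @export
simulate_variant_observations <- function(truth, config, samples = NULL) {
  validate_sim_config(config)
  genome <- truth$genome
  ids <- samples %||% truth$samples$sample_id
  # strain-level background variants, avoiding all true de novo positions
  taken <- paste(truth$mutations$chrom, truth$mutations$pos)
  background <- with_seed(config$seed + 4L, {
    setNames(lapply(seq_len(nrow(truth$strains)), function(i) {
      draw_positions(genome, config$n_background, avoid = taken)
    }), truth$strains$strain)
  })
  out <- lapply(ids, function(id) {
    s <- truth$samples[truth$samples$sample_id == id, ]
    k <- truth$karyotypes[truth$karyotypes$sample_id == id, ]
    denovo <- truth$mutations[truth$mutations$sample_id == id, , drop = FALSE]
    bg <- background[[s$strain]]
    with_seed(config$seed + 5000L + match(id, truth$samples$sample_id), {
      shared <- rbind(
        if (nrow(denovo)) cbind(denovo[, c("chrom", "pos", "ref", "alt", "type")],
                                origin = "denovo"),
        if (nrow(bg)) cbind(bg, origin = "background"))
      shared_a <- observe_variants(shared, k, config, id, "caller_a")
      shared_b <- observe_variants(shared, k, config, id, "caller_b")
      avoid2 <- c(taken, paste(bg$chrom, bg$pos))
      fp_a <- draw_positions(genome, rpois(1, config$fp_rate), avoid = avoid2)
      fp_b <- draw_positions(genome, rpois(1, config$fp_rate),
                             avoid = c(avoid2, paste(fp_a$chrom, fp_a$pos)))
      fp_a$origin <- rep("false_positive", nrow(fp_a))
      fp_b$origin <- rep("false_positive", nrow(fp_b))
      list(a = rbind(shared_a, observe_variants(fp_a, k, config, id, "caller_a")),
           b = rbind(shared_b, observe_variants(fp_b, k, config, id, "caller_b")))
    })
  })
  setNames(out, ids)
}

# substitutions at positions not in `avoid`
draw_positions <- function(genome, n, avoid = character()) {
  empty <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), type = character())
  if (n == 0) return(empty)
  lens <- genome$chrom_lengths
  got <- empty
  while (nrow(got) < n) {
    chrom <- sample(names(lens), 1, prob = as.numeric(lens))
    pos <- sample.int(lens[[chrom]] - 12L, 1)
    if (paste(chrom, pos) %in% c(avoid, paste(got$chrom, got$pos))) next
    ref <- fetch_seq(genome, chrom, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    got <- rbind(got, data.frame(chrom = chrom, pos = pos, ref = ref,
                                 alt = alt, type = "substitution"))
  }
  got
}

observe_variants <- function(v, karyo, config, sample_id, caller) {
  if (is.null(v) || nrow(v) == 0)
    return(data.frame(sample_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      type = character(), dp = integer(), ad = integer(),
                      caller = character(), origin = character()))
  cn <- cn_at(karyo, v$chrom, v$pos)
  af_true <- ifelse(cn >= 2, 0.5, 1.0)
  dp <- pmax(1L, rpois(nrow(v), config$depth * cn))
  af <- pmin(1, pmax(0, rnorm(nrow(v), af_true, config$af_sd)))
  ad <- pmin(dp, pmax(0L, round(dp * af)))
  data.frame(sample_id = sample_id, chrom = v$chrom, pos = v$pos,
             ref = v$ref, alt = v$alt, type = v$type, dp = dp, ad = ad,
             caller = caller, origin = v$origin, row.names = NULL)
}

#' Simulate the gene x sample expression count matrix
#'
#' Baseline per-gene means are log-normal.  In a disomic ancestor, genes
#' on copy-number-2 segments are scaled by `dosage_factor` and the
#' strain's trans-affected genes by their drawn log2 deviations.  In an
#' evolved line, every log deviation from WT is multiplied by
#' `1 - attenuation` of that line, except where the line's own copy
#' number differs from the ancestor's (lost segments return to baseline,
#' newly amplified segments gain the dosage factor).  Counts are negative
#' binomial with dispersion `expr_dispersion`, and library sizes vary by
#' `libsize_range`.
#'
#' @inheritParams simulate_coverage
#' @return an `expression_matrix` object (see [expression_matrix()]).
#' @export
simulate_expression <- function(truth, config, samples = NULL) {
  validate_sim_config(config)
  assert_that(config$dosage_factor > 0, "dosage_factor must be positive")
  genome <- truth$genome
  genes <- genome$genes
  assert_that(nrow(genes) > 0, "genome has no genes to express")
  ids <- samples %||% truth$samples$sample_id
  base <- with_seed(config$seed + 6L,
                    exp(rnorm(nrow(genes), config$base_meanlog, config$base_sdlog)))
  counts <- matrix(0L, nrow(genes), length(ids),
                   dimnames = list(genes$gene_id, ids))
  for (id in ids) {
    s <- truth$samples[truth$samples$sample_id == id, ]
    dev <- log2_deviation(truth, genes, s)
    mu <- base * 2^dev
    with_seed(config$seed + 7000L + match(id, truth$samples$sample_id), {
      lib <- runif(1, config$libsize_range[1], config$libsize_range[2])
      counts[, id] <- draw_nb(lib * mu, config$expr_dispersion)
    })
  }
  meta <- truth$samples[match(ids, truth$samples$sample_id),
                        c("sample_id", "strain", "role", "disome_chrom")]
  expression_matrix(counts, meta)
}

# per-gene log2 deviation from the WT expectation for one sample
log2_deviation <- function(truth, genes, s) {
  dev <- numeric(nrow(genes))
  if (s$strain == "WT" && s$role == "ancestor") return(dev)
  anc_k <- truth$karyotypes[truth$karyotypes$sample_id ==
                              paste0(s$strain, "_anc"), ]
  anc_cn <- cn_at(anc_k, genes$chrom, genes$tss)
  ld <- log2(truth$config$dosage_factor)
  anc_dev <- ifelse(anc_cn >= 2, ld, 0)
  tr <- truth$trans[truth$trans$strain == s$strain, , drop = FALSE]
  if (!is.null(tr) && nrow(tr)) {
    i <- match(tr$gene_id, genes$gene_id)
    anc_dev[i] <- anc_dev[i] + tr$log2dev
  }
  if (s$role == "ancestor") return(anc_dev)
  a <- truth$expression$attenuation[truth$expression$sample_id == s$sample_id]
  own_k <- truth$karyotypes[truth$karyotypes$sample_id == s$sample_id, ]
  own_cn <- cn_at(own_k, genes$chrom, genes$tss)
  dev <- (1 - a) * anc_dev
  dev[own_cn < anc_cn] <- 0            # lost segment: back to baseline
  dev[own_cn > anc_cn] <- ld           # new amplification: dosage effect
  dev
}

#' Simulate plate-reader growth curves
#'
#' Logistic growth sampled on the configured time grid with the sample's
#' true doubling time, multiplicative log-normal measurement noise, and
#' `replicates` wells per sample.
#'
#' @inheritParams simulate_coverage
#' @param replicates wells per sample.
#' @param od0 inoculation OD600.
#' @param capacity carrying capacity (stationary OD600).
#' @return data.frame with columns `sample_id`, `replicate`, `time_min`,
#'   `od`.
#' @export
simulate_growth <- function(truth, config, samples = NULL, replicates = 3L,
                            od0 = 0.01, capacity = 1.0) {
  ids <- samples %||% truth$samples$sample_id
  tt <- seq(0, config$growth_duration, by = config$growth_interval)
  do.call(rbind, lapply(ids, function(id) {
    dbl <- truth$growth$doubling_min[truth$growth$sample_id == id]
    r <- log(2) / dbl
    od_true <- capacity * od0 * exp(r * tt) /
      (capacity + od0 * (exp(r * tt) - 1))
    with_seed(config$seed + 9000L + match(id, truth$samples$sample_id), {
      do.call(rbind, lapply(seq_len(replicates), function(rep) {
        noise <- if (config$growth_noise_sd > 0)
          exp(rnorm(length(tt), 0, config$growth_noise_sd)) else 1
        data.frame(sample_id = id, replicate = rep, time_min = tt,
                   od = od_true * noise)
      }))
    })
  }))
}
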