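#' Simulation configuration for the disome evolution generator
#'
#' Builds and validates the configuration object consumed by all
#' `simulate_*` generators.  Defaults describe the study design being
#' emulated: 16 yeast-like chromosomes totalling ~12.1 Mb, 74% coding,
#' 38% GC, 12 disomic strains plus a euploid wild type, three evolved
#' lines per strain propagated for 1200 generations, per-line mutation
#' counts around 7.9 substitutions and 3.75 small indels, a mutation
#' bias towards the duplicated chromosome, ~50x coverage in 100-bp
#' windows, and a 1.8-fold expression dosage effect on duplicated
#' chromosomes that attenuates during evolution.
#'
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param coding_fraction fraction of the genome inside coding sequence.
#' @param gc_fraction genomic GC fraction.
#' @param disome_chroms chromosome names duplicated in the disomic strains,
#'   one strain per entry.
#' @param lines_per_strain evolved lines founded per strain.
#' @param generations generations of propagation (all strains).
#' @param lambda_sub expected de novo substitutions per evolved line.
#' @param lambda_ind expected de novo small indels per evolved line.
#' @param dup_bias multiplier on the per-bp mutation probability on the
#'   duplicated chromosome.  The default 6 matches the observed
#'   enrichment of mutations on duplicated chromosomes (~28% of
#'   mutations on ~6% of the genome).
#' @param dosage_factor expected expression ratio of duplicated-chromosome
#'   genes over wild type.
#' @param attenuation length-2 range; each evolved line draws the fraction
#'   by which its log expression deviations from WT shrink, uniformly
#'   from this interval.
#' @param karyotype_event_probs named probabilities (`whole_loss`,
#'   `partial_loss`, `segmental_amplification`) of karyotype change per
#'   evolved line; must sum to <= 1, remainder retains the karyotype.
#' @param depth mean reads per 100-bp window at copy number 1.
#' @param nb_dispersion negative-binomial overdispersion of read counts
#'   (0 recovers Poisson).
#' @param window_size coverage window size in bp.
#' @param af_sd spread of the observed alt-read fraction of a fixed
#'   variant around its copy-number expectation (population sequencing
#'   of a fixed clone; see the methods vignette).
#' @param fp_rate expected caller-specific false positives per sample.
#' @param n_background ancestral background variants per strain (present
#'   in the ancestor and all its evolved lines).
#' @param expr_dispersion negative-binomial dispersion of expression counts.
#' @param n_trans_genes ancestral trans-acting expression changes per
#'   disomic strain (genes off the duplicated chromosome with altered
#'   expression relative to WT).
#' @param trans_sd standard deviation (log2) of those trans deviations.
#' @param base_meanlog,base_sdlog log-normal parameters of baseline gene
#'   expression means.
#' @param libsize_range relative library-size range across samples.
#' @param gene_length_range CDS length range (bp); lengths are snapped to
#'   multiples of 3.
#' @param repeat_spacing mean spacing (bp) of repeat loci, the only
#'   positions at which karyotype-change breakpoints are placed.
#' @param wt_doubling wild-type ancestor doubling time (minutes).
#' @param disome_doubling_range multiplier range for disome ancestor
#'   doubling times relative to WT.
#' @param wt_improvement fractional doubling-time decrease of evolved WT.
#' @param disome_improvement_range fractional decrease range for evolved
#'   disomic lines.
#' @param growth_noise_sd multiplicative (log-normal) OD measurement noise.
#' @param growth_interval OD sampling interval (minutes).
#' @param growth_duration length of the growth assay (minutes).
#' @param seed integer random seed controlling all generators.
#' @return a validated object of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$dosage_factor
#' @export
sim_config <- function(chrom_lengths = yeast_chrom_lengths(),
                       coding_fraction = 0.74,
                       gc_fraction = 0.38,
                       disome_chroms = paste0("chr", c("I", "II", "V", "VIII",
                         "IX", "X", "XI", "XII", "XIII", "XIV", "XV", "XVI")),
                       lines_per_strain = 3L,
                       generations = 1200,
                       lambda_sub = 7.9,
                       lambda_ind = 3.75,
                       dup_bias = 6,
                       dosage_factor = 1.8,
                       attenuation = c(0.1, 0.7),
                       karyotype_event_probs = c(whole_loss = 0.0625,
                         partial_loss = 0.25, segmental_amplification = 0.15),
                       depth = 50,
                       nb_dispersion = 0.05,
                       window_size = 100L,
                       af_sd = 0.02,
                       fp_rate = 2,
                       n_background = 30L,
                       expr_dispersion = 0.01,
                       n_trans_genes = 300L,
                       trans_sd = 0.8,
                       base_meanlog = log(100),
                       base_sdlog = 1,
                       libsize_range = c(0.7, 1.4),
                       gene_length_range = c(300L, 2400L),
                       repeat_spacing = 5e4,
                       wt_doubling = 90,
                       disome_doubling_range = c(1.2, 1.9),
                       wt_improvement = 0.08,
                       disome_improvement_range = c(0.16, 0.64),
                       growth_noise_sd = 0.01,
                       growth_interval = 15,
                       growth_duration = 1440,
                       seed = 1L) {
  cfg <- mget(names(formals()))
  cfg$chrom_lengths <- chrom_lengths
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Yeast-like chromosome lengths
#'
#' Default chromosome sizes (bp) for the synthetic genome: the sixteen
#' S. cerevisiae chromosome lengths rounded to the kb, ~12.07 Mb total.
#' @return named integer vector.
#' @export
yeast_chrom_lengths <- function() {
  kb <- c(I = 230, II = 813, III = 317, IV = 1532, V = 577, VI = 270,
          VII = 1091, VIII = 562, IX = 439, X = 745, XI = 666, XII = 1078,
          XIII = 924, XIV = 784, XV = 1091, XVI = 948)
  setNames(as.integer(kb * 1000), paste0("chr", names(kb)))
}

validate_sim_config <- function(cfg) {
  assert_that(is.numeric(cfg$chrom_lengths) && length(cfg$chrom_lengths) >= 1 &&
                all(cfg$chrom_lengths > 0),
              "chrom_lengths must be positive")
  assert_that(!is.null(names(cfg$chrom_lengths)) &&
                !anyDuplicated(names(cfg$chrom_lengths)),
              "chrom_lengths must be uniquely named")
  assert_that(is_fraction(cfg$coding_fraction), "coding_fraction must be in [0,1]")
  assert_that(is_fraction(cfg$gc_fraction), "gc_fraction must be in [0,1]")
  assert_that(all(cfg$disome_chroms %in% names(cfg$chrom_lengths)),
              "disome_chroms must name chromosomes present in chrom_lengths")
  assert_that(cfg$lines_per_strain >= 1, "lines_per_strain must be positive")
  assert_that(cfg$generations > 0, "generations must be positive")
  assert_that(cfg$lambda_sub >= 0 && cfg$lambda_ind >= 0,
              "mutation rates must be non-negative")
  assert_that(cfg$dup_bias >= 0, "dup_bias must be non-negative")
  assert_that(cfg$dosage_factor > 0, "dosage_factor must be positive")
  assert_that(is_fraction(cfg$attenuation) && length(cfg$attenuation) == 2 &&
                cfg$attenuation[1] <= cfg$attenuation[2],
              "attenuation must be an increasing range inside [0,1]")
  p <- cfg$karyotype_event_probs
  assert_that(is_fraction(p) && sum(p) <= 1 + 1e-12 &&
                setequal(names(p), c("whole_loss", "partial_loss",
                                     "segmental_amplification")),
              "karyotype_event_probs must be named probabilities summing to <= 1")
  assert_that(cfg$depth > 0, "depth must be positive")
  assert_that(cfg$nb_dispersion >= 0, "nb_dispersion must be non-negative")
  assert_that(cfg$window_size >= 1, "window_size must be positive")
  assert_that(cfg$fp_rate >= 0 && cfg$n_background >= 0,
              "fp_rate and n_background must be non-negative")
  invisible(cfg)
}
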