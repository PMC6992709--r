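#' Pipeline configuration
#'
#' Bundles the simulation configuration, stage toggles and module
#' parameters for [run_pipeline()].  Every report embeds the resolved
#' configuration and seed.
#'
#' @param sim a [sim_config()].
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "karyotype", "mutations", "rates", "expression",
#'   "growth")`.
#' @param out_dir optional output directory for TSV/JSON reports.
#' @param n,g genome size and generations used for rate estimates.
#' @param penalty segmentation penalty; `cn_threshold` copy-number call
#'   threshold; `min_reads`, `af_dup`, `af_other` catalogue filters;
#'   `fc_threshold` shift gene-set threshold; `fdr` differential
#'   expression threshold.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            stages = c("simulate", "karyotype", "mutations",
                                       "rates", "expression", "growth"),
                            out_dir = NULL,
                            n = 1.212e7, g = 1200,
                            penalty = 10, cn_threshold = 1.5,
                            min_reads = 5, af_dup = 0.40, af_other = 0.80,
                            fc_threshold = 1.5, fdr = 0.1) {
  known <- c("simulate", "karyotype", "mutations", "rates", "expression",
             "growth")
  assert_that(all(stages %in% known), "unknown stage name")
  structure(mget(names(formals())), class = "pipeline_config")
}

stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop_aneuvol("stage '", stage, "' failed: ", conditionMessage(e),
                 class = "aneuvol_stage_error"))
}

#' Run the full analysis pipeline on simulated data
#'
#' Executes the enabled stages in order: data simulation, karyotype
#' calling (each sample normalized to the wild-type ancestor coverage,
#' segmented and compared with its ancestor's call), de novo mutation
#' cataloguing (caller intersection, ancestor subtraction,
#' allele-fraction filters, effect and promoter annotation), rate and
#' localization statistics, the expression shift analysis, and growth
#' fitting.  Stage failures abort with the failing stage named; partial
#' results computed before the failure are retained in the error-free
#' report sections written so far.
#'
#' @param config a [pipeline_config()].
#' @param inputs optional precomputed inputs (a list with any of
#'   `genome`, `truth`, `coverage`, `callsets`, `expression`, `growth`)
#'   to skip parts of the simulate stage.
#' @return report list with one element per executed stage plus `meta`
#'   (resolved config, seed, package version).
#' @export
run_pipeline <- function(config = pipeline_config(), inputs = list()) {
  assert_that(inherits(config, "pipeline_config"),
              "config must be a pipeline_config")
  report <- list(meta = list(
    seed = config$sim$seed,
    package_version = as.character(utils::packageVersion("aneuvol")),
    n = config$n, g = config$g,
    config = config))
  st <- config$stages
  dat <- inputs
  if ("simulate" %in% st) {
    dat <- stage_try("simdata", {
      genome <- dat$genome %||% make_genome(config$sim)
      truth <- dat$truth %||% simulate_lineages(genome, config$sim)
      list(genome = genome, truth = truth,
           coverage = dat$coverage %||% simulate_coverage(truth, config$sim),
           callsets = dat$callsets %||%
             simulate_variant_observations(truth, config$sim),
           expression = dat$expression %||%
             simulate_expression(truth, config$sim),
           growth = dat$growth %||% simulate_growth(truth, config$sim))
    })
    report$simulate <- list(
      n_samples = nrow(dat$truth$samples),
      n_true_mutations = nrow(dat$truth$mutations))
  }
  samples <- dat$truth$samples
  karyos <- NULL
  if ("karyotype" %in% st) {
    report$karyotype <- stage_try("karyocall", {
      assert_that(!is.null(dat$coverage[["WT_anc"]]),
                  "missing WT coverage profile")
      wt_cov <- dat$coverage[["WT_anc"]]
      karyos <- lapply(samples$sample_id, function(id) {
        if (id == "WT_anc") return(NULL)
        tr <- normalize_coverage(dat$coverage[[id]], wt_cov,
                                 masked = dat$genome$masked)
        seg <- segment_ratio(tr, penalty = config$penalty,
                             cn_threshold = config$cn_threshold)
        anc <- samples$disome_chrom[samples$sample_id == id]
        call_karyotype(seg, ancestor = if (is.na(anc)) NA else anc)
      })
      names(karyos) <- samples$sample_id
      evolved_dis <- samples$sample_id[samples$role == "evolved" &
                                         !is.na(samples$disome_chrom)]
      changed <- vapply(evolved_dis, function(id)
        nrow(karyos[[id]]$changes) > 0, logical(1))
      list(calls = karyos,
           n_evolved_disomic = length(evolved_dis),
           n_retained = sum(!changed),
           changes = do.call(rbind, lapply(evolved_dis, function(id) {
             ch <- karyos[[id]]$changes
             if (nrow(ch)) cbind(sample_id = id, ch) else NULL
           })))
    })
  }
  catalogue <- NULL
  if ("mutations" %in% st) {
    report$mutations <- stage_try("mutcat", {
      evolved <- samples$sample_id[samples$role == "evolved"]
      catalogue <- do.call(rbind, lapply(evolved, function(id) {
        strain <- samples$strain[samples$sample_id == id]
        anc_id <- paste0(strain, "_anc")
        cons <- intersect_callers(dat$callsets[[id]]$a, dat$callsets[[id]]$b)
        anc <- intersect_callers(dat$callsets[[anc_id]]$a,
                                 dat$callsets[[anc_id]]$b)
        karyo <- if (!is.null(karyos)) karyos[[id]] else
          dat$truth$karyotypes[dat$truth$karyotypes$sample_id == id, ]
        m <- filter_denovo(cons, anc, karyo, min_reads = config$min_reads,
                           af_dup = config$af_dup, af_other = config$af_other)
        if (!nrow(m)) return(NULL)
        m <- annotate_effect(m, dat$genome)
        assign_promoter(m, dat$genome)
      }))
      list(catalogue = catalogue,
           n_mutations = if (is.null(catalogue)) 0L else nrow(catalogue))
    })
  }
  if ("rates" %in% st) {
    report$rates <- stage_try("mutstats", {
      evolved <- samples[samples$role == "evolved", ]
      per_sample <- vapply(evolved$sample_id, function(id)
        if (is.null(catalogue)) 0L else
          sum(catalogue$sample_id == id), integer(1))
      by_strain <- tapply(per_sample, evolved$strain, mean)
      rates <- apparent_rate(as.numeric(by_strain), config$n, config$g)
      rates$strain <- names(by_strain)
      dis <- samples$strain[!is.na(samples$disome_chrom)]
      loc <- if (!is.null(catalogue)) {
        ds <- unique(dis)
        succ <- vapply(ds, function(s) {
          ids <- evolved$sample_id[evolved$strain == s]
          sum(catalogue$on_dup[catalogue$sample_id %in% ids])
        }, numeric(1))
        tri <- vapply(ds, function(s) {
          ids <- evolved$sample_id[evolved$strain == s]
          sum(catalogue$sample_id %in% ids)
        }, numeric(1))
        keep <- tri >= 1
        if (any(keep)) {
          p0 <- vapply(ds[keep], function(s) p0_chromosome(
            samples$disome_chrom[samples$strain == s][1],
            dat$genome$chrom_lengths), numeric(1))
          localization_test(succ[keep], tri[keep], p0, labels = ds[keep])
        }
      }
      types <- if (!is.null(catalogue) && any(catalogue$type == "substitution"))
        per_type_rates(catalogue, n = config$n, g = config$g,
                       gc_fraction = dat$genome$gc_fraction)
      list(per_strain = rates, localization = loc, per_type = types)
    })
  }
  if ("expression" %in% st) {
    report$expression <- stage_try("exprshift", {
      filt <- filter_cpm(dat$expression)
      norm <- rle_normalize(filt)
      anc_dis <- samples[samples$role == "ancestor" &
                           !is.na(samples$disome_chrom), ]
      dosage <- vapply(seq_len(nrow(anc_dis)), function(i)
        chromosome_dosage(norm, dat$genome, anc_dis$disome_chrom[i],
                          anc_dis$sample_id[i], "WT_anc"), numeric(1))
      names(dosage) <- anc_dis$sample_id
      evo_dis <- samples[samples$role == "evolved" &
                           !is.na(samples$disome_chrom), ]
      shifts <- vapply(seq_len(nrow(evo_dis)), function(i) {
        sr <- expression_shift(norm, evo_dis$sample_id[i],
                               paste0(evo_dis$strain[i], "_anc"), "WT_anc",
                               fc_threshold = config$fc_threshold)
        if (sr$defined) sr$shift else NA_real_
      }, numeric(1))
      names(shifts) <- evo_dis$sample_id
      de <- common_de(norm, fdr = config$fdr)
      sa <- if (sum(!is.na(shifts)) >= 4 && sd(shifts, na.rm = TRUE) > 0)
        shift_association(norm, shifts, fdr = config$fdr)
      list(n_genes = nrow(norm$log2), dosage_median = dosage,
           shifts = shifts,
           n_shifted_towards_wt = sum(shifts > 0, na.rm = TRUE),
           common_de_significant = sum(de$significant, na.rm = TRUE),
           shift_assoc_significant = if (is.null(sa)) NA_integer_ else
             sum(sa$significant, na.rm = TRUE),
           common_de = de, shift_association = sa)
    })
  }
  if ("growth" %in% st) {
    report$growth <- stage_try("growthfit", {
      tab <- doubling_time_table(dat$growth)
      tab$strain <- samples$strain[match(tab$sample_id, samples$sample_id)]
      tab$role <- samples$role[match(tab$sample_id, samples$sample_id)]
      anc <- setNames(tab$doubling_min[tab$role == "ancestor"],
                      tab$strain[tab$role == "ancestor"])
      tab$pct_change <- ifelse(tab$role == "evolved",
                               relative_change(anc[tab$strain],
                                               tab$doubling_min), NA)
      tab
    })
  }
  if (!is.null(config$out_dir)) write_report(report, dat, config$out_dir)
  report
}

write_report <- function(report, dat, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  if (!is.null(dat$truth)) write_truth_json(dat$truth, p("truth.json"))
  if (!is.null(report$mutations$catalogue))
    write.table(report$mutations$catalogue, p("catalogue.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(report$rates$per_strain))
    write.table(report$rates$per_strain, p("rates.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(report$growth))
    write.table(report$growth, p("growth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(report$expression)) {
    write.table(data.frame(sample_id = names(report$expression$shifts),
                           shift = report$expression$shifts),
                p("shifts.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  summary <- report
  summary$karyotype$calls <- NULL
  summary$mutations$catalogue <- NULL
  summary$rates$localization <- NULL
  summary$expression$common_de <- NULL
  summary$expression$shift_association <- NULL
  summary$meta$config <- NULL
  jsonlite::write_json(summary, p("report.json"), auto_unbox = TRUE,
                       digits = NA, na = "null", force = TRUE, pretty = TRUE)
  invisible(out_dir)
}
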