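#' Simulate the evolution experiment and its ground truth
#'
#' Draws, for every strain (one euploid wild type plus one disomic strain
#' per entry of `config$disome_chroms`) and every evolved line, the true
#' karyotype (including whole losses, partial losses with breakpoints at
#' repeat loci, and segmental amplifications), de novo mutations (counts
#' Poisson with means `lambda_sub` / `lambda_ind`, positions uniform per
#' bp except multiplied by `dup_bias` on the duplicated chromosome),
#' per-line expression dosage and attenuation parameters, ancestral
#' trans-acting expression changes, and true growth rates.  Ancestor
#' samples carry zero de novo mutations.
#'
#' @param genome a [make_genome()] annotation.
#' @param config the [sim_config()] used to build `genome`.
#' @return an object of class `evo_truth` with components `samples`,
#'   `karyotypes` (per-sample copy-number segment tables), `mutations`,
#'   `events`, `expression` (per-line dosage/attenuation), `trans`
#'   (ancestral trans-acting deviations), `growth` (true doubling times,
#'   minutes) and the `genome` itself.
#' @export
simulate_lineages <- function(genome, config) {
  validate_sim_config(config)
  strains <- data.frame(
    strain = c("WT", paste0("D", seq_along(config$disome_chroms))),
    disome_chrom = c(NA_character_, config$disome_chroms))
  with_seed(config$seed + 2L, {
    samples <- do.call(rbind, lapply(seq_len(nrow(strains)), function(i) {
      st <- strains$strain[i]
      rbind(data.frame(sample_id = paste0(st, "_anc"), strain = st,
                       role = "ancestor", disome_chrom = strains$disome_chrom[i],
                       line = NA_integer_),
            data.frame(sample_id = paste0(st, "_ev", seq_len(config$lines_per_strain)),
                       strain = st, role = "evolved",
                       disome_chrom = strains$disome_chrom[i],
                       line = seq_len(config$lines_per_strain)))
    }))
    karyo <- list(); events <- list(); muts <- list()
    expr <- list(); growth <- list()
    anc_doubling <- setNames(
      c(config$wt_doubling,
        config$wt_doubling * runif(nrow(strains) - 1,
                                   config$disome_doubling_range[1],
                                   config$disome_doubling_range[2])),
      strains$strain)
    for (i in seq_len(nrow(samples))) {
      s <- samples[i, ]
      dup <- s$disome_chrom
      k <- base_karyotype(genome, dup)
      ev <- "retained"
      if (s$role == "evolved" && !is.na(dup)) {
        ev <- draw_event(config$karyotype_event_probs)
        if (ev == "segmental_amplification" &&
            length(genome$chrom_lengths) < 2)
          ev <- "retained"               # no other chromosome to amplify
        k <- apply_event(k, ev, dup, genome)
      }
      k$sample_id <- s$sample_id
      karyo[[i]] <- k
      if (s$role == "evolved" && !is.na(dup))
        events[[i]] <- data.frame(sample_id = s$sample_id, event = ev)
      if (s$role == "evolved") {
        m <- draw_mutations(genome, config, dup)
        if (nrow(m)) { m$sample_id <- s$sample_id; muts[[i]] <- m }
        expr[[i]] <- data.frame(
          sample_id = s$sample_id, strain = s$strain,
          dosage = config$dosage_factor,
          attenuation = runif(1, config$attenuation[1], config$attenuation[2]))
        impr <- if (s$strain == "WT") config$wt_improvement else
          runif(1, config$disome_improvement_range[1],
                config$disome_improvement_range[2])
        growth[[i]] <- data.frame(sample_id = s$sample_id,
                                  doubling_min = anc_doubling[[s$strain]] * (1 - impr))
      } else {
        growth[[i]] <- data.frame(sample_id = s$sample_id,
                                  doubling_min = anc_doubling[[s$strain]])
      }
    }
    trans <- do.call(rbind, lapply(which(!is.na(strains$disome_chrom)),
      function(i) {
        off <- genome$genes[genome$genes$chrom != strains$disome_chrom[i], ]
        n <- min(config$n_trans_genes, nrow(off))
        if (n == 0) return(NULL)
        data.frame(strain = strains$strain[i],
                   gene_id = sample(off$gene_id, n),
                   log2dev = rnorm(n, 0, config$trans_sd))
      }))
    mutations <- if (length(muts)) do.call(rbind, muts) else
      empty_mutation_truth()
    structure(list(
      samples = samples,
      strains = strains,
      karyotypes = do.call(rbind, karyo),
      events = if (length(events)) do.call(rbind, events) else
        data.frame(sample_id = character(), event = character()),
      mutations = mutations,
      expression = do.call(rbind, expr),
      trans = trans,
      growth = do.call(rbind, growth),
      genome = genome,
      config = config
    ), class = "evo_truth")
  })
}

empty_mutation_truth <- function() {
  data.frame(sample_id = character(), chrom = character(), pos = integer(),
             ref = character(), alt = character(), type = character(),
             region = character(), on_dup = logical())
}

base_karyotype <- function(genome, dup_chrom) {
  data.frame(chrom = names(genome$chrom_lengths), start = 1L,
             end = unname(genome$chrom_lengths),
             cn = ifelse(names(genome$chrom_lengths) %in% dup_chrom, 2L, 1L))
}

draw_event <- function(probs) {
  u <- runif(1)
  cum <- cumsum(probs)
  if (u < cum[["whole_loss"]]) "whole_loss"
  else if (u < cum[["partial_loss"]]) "partial_loss"
  else if (u < cum[["segmental_amplification"]]) "segmental_amplification"
  else "retained"
}

apply_event <- function(k, event, dup, genome) {
  if (event == "retained") return(k)
  if (event == "whole_loss") {
    k$cn[k$chrom == dup] <- 1L
    return(k)
  }
  if (event == "partial_loss") {
    L <- genome$chrom_lengths[[dup]]
    bp <- sample(genome$repeat_loci$pos[genome$repeat_loci$chrom == dup], 1)
    lose_left <- runif(1) < 0.5
    i <- which(k$chrom == dup)
    k <- k[-i, ]
    seg <- if (lose_left)
      data.frame(chrom = dup, start = c(1L, bp + 1L), end = c(bp, L),
                 cn = c(1L, 2L))
    else
      data.frame(chrom = dup, start = c(1L, bp + 1L), end = c(bp, L),
                 cn = c(2L, 1L))
    return(rbind(k, seg))
  }
  # segmental amplification of another chromosome, breakpoints at repeats
  others <- setdiff(names(genome$chrom_lengths), dup)
  target <- sample(others, 1)
  rp <- sort(genome$repeat_loci$pos[genome$repeat_loci$chrom == target])
  bps <- sort(sample(rp, 2))
  L <- genome$chrom_lengths[[target]]
  i <- which(k$chrom == target)
  k <- k[-i, ]
  seg <- data.frame(chrom = target,
                    start = c(1L, bps[1] + 1L, bps[2] + 1L),
                    end = c(bps[1], bps[2], L),
                    cn = c(1L, 2L, 1L))
  seg <- seg[seg$start <= seg$end, ]
  rbind(k, seg)
}

draw_mutations <- function(genome, config, dup_chrom) {
  n_sub <- rpois(1, config$lambda_sub)
  n_ind <- rpois(1, config$lambda_ind)
  n <- n_sub + n_ind
  if (n == 0) return(empty_mutation_truth()[, -1])
  w <- as.numeric(genome$chrom_lengths)
  if (!is.na(dup_chrom))
    w[names(genome$chrom_lengths) == dup_chrom] <-
      w[names(genome$chrom_lengths) == dup_chrom] * config$dup_bias
  repeat {
    chrom <- sample(names(genome$chrom_lengths), n, TRUE, prob = w)
    pos <- vapply(chrom, function(ch)
      sample.int(genome$chrom_lengths[[ch]] - 12L, 1), integer(1))
    if (!anyDuplicated(paste(chrom, pos))) break
  }
  type <- c(rep("substitution", n_sub),
            sample(c("insertion", "deletion"), n_ind, TRUE))
  ref <- character(n); alt <- character(n)
  for (i in seq_len(n)) {
    base <- fetch_seq(genome, chrom[i], pos[i], pos[i])
    if (type[i] == "substitution") {
      ref[i] <- base
      alt[i] <- sample(setdiff(c("A", "C", "G", "T"), base), 1)
    } else if (type[i] == "insertion") {
      len <- sample.int(10L, 1)
      ref[i] <- base
      alt[i] <- paste0(base, paste(sample(c("A", "C", "G", "T"), len, TRUE),
                                   collapse = ""))
    } else {
      len <- sample.int(10L, 1)
      ref[i] <- fetch_seq(genome, chrom[i], pos[i], pos[i] + len)
      alt[i] <- base
    }
  }
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, type = type,
             region = region_at(genome$genes, chrom, pos),
             on_dup = !is.na(dup_chrom) & chrom == dup_chrom,
             row.names = NULL)
}

fetch_seq <- function(genome, chrom, start, end) {
  if (is.null(genome$sequences)) {
    return(paste(rep("N", end - start + 1), collapse = ""))
  }
  as.character(Biostrings::subseq(genome$sequences[[chrom]], start, end))
}
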