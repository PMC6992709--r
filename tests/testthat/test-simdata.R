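test_that("sim_config validates its invariants", {
  expect_error(small_config(dup_bias = -1), "dup_bias")
  expect_error(small_config(depth = 0), "depth")
  expect_error(small_config(dosage_factor = 0), "dosage")
  expect_error(small_config(coding_fraction = 1.2), "coding_fraction")
  expect_error(small_config(karyotype_event_probs = c(
    whole_loss = 0.5, partial_loss = 0.4, segmental_amplification = 0.2)),
    "karyotype_event_probs")
  expect_error(small_config(attenuation = c(0.8, 0.2)), "attenuation")
})

test_that("make_genome realizes the coding fraction and is deterministic", {
  cfg <- sim_config(chrom_lengths = setNames(rep(5e4L, 16), paste0("c", 1:16)),
                    disome_chroms = "c1", seed = 3)
  g1 <- make_genome(cfg)
  expect_gte(g1$coding_fraction, 0.73)
  expect_lte(g1$coding_fraction, 0.75)
  # gene intervals non-overlapping and inside bounds
  for (ch in unique(g1$genes$chrom)) {
    gg <- g1$genes[g1$genes$chrom == ch, ]
    expect_true(all(gg$start[-1] > gg$end[-nrow(gg)]))
    expect_true(all(gg$end <= g1$chrom_lengths[[ch]]))
  }
  expect_true(all((g1$genes$end - g1$genes$start + 1) %% 3 == 0))
  g2 <- make_genome(cfg)
  expect_identical(g1$genes, g2$genes)
  expect_identical(as.character(g1$sequences), as.character(g2$sequences))
})

test_that("make_genome degenerate and infeasible cases", {
  cfg <- small_config(coding_fraction = 0)
  g <- make_genome(cfg, sequence = FALSE)
  expect_identical(nrow(g$genes), 0L)
  expect_identical(g$coding_fraction, 0)
  expect_error(make_genome(small_config(), n_genes = 2),
               "infeasible")
})

test_that("realized GC fraction tracks the configured value", {
  g <- make_genome(small_config(seed = 5))
  expect_lt(abs(g$gc_fraction - 0.38), 0.01)
})

test_that("zero mutation rates give zero mutations; ancestors always clean", {
  cfg <- small_config(lambda_sub = 0, lambda_ind = 0)
  tr <- simulate_lineages(make_genome(cfg, sequence = FALSE), cfg)
  expect_identical(nrow(tr$mutations), 0L)
  tr2 <- simulate_lineages(make_genome(small_config(), sequence = FALSE),
                           small_config())
  anc <- tr2$samples$sample_id[tr2$samples$role == "ancestor"]
  expect_false(any(tr2$mutations$sample_id %in% anc))
})

test_that("substitution totals follow the Poisson law (Monte-Carlo oracle)", {
  # 32 disome lines at lambda_sub = 7.9: mean total over 200 replicates
  # must fall within 3 standard errors of 252.8
  cfg <- sim_config(chrom_lengths = c(chrA = 20000L, chrB = 20000L),
                    disome_chroms = "chrA", lines_per_strain = 32L,
                    lambda_sub = 7.9, lambda_ind = 0, n_trans_genes = 5,
                    seed = 1)
  gen <- make_genome(cfg, sequence = FALSE)
  totals <- vapply(1:200, function(s) {
    cfg$seed <- s
    tr <- simulate_lineages(gen, cfg)
    dis <- tr$samples$sample_id[tr$samples$strain == "D1" &
                                  tr$samples$role == "evolved"]
    sum(tr$mutations$sample_id %in% dis &
          tr$mutations$type == "substitution")
  }, numeric(1))
  se <- sqrt(252.8 / 200)
  expect_lt(abs(mean(totals) - 252.8), 3 * se)
})

test_that("dup_bias concentrates mutations as the closed form predicts", {
  # bias 10 on a chromosome covering 5% of the genome:
  # expected on-dup fraction = 10*0.05 / (0.95 + 10*0.05) ~ 0.345
  cfg <- sim_config(chrom_lengths = c(dup = 5000L, rest = 95000L),
                    disome_chroms = "dup", lines_per_strain = 20L,
                    lambda_sub = 500, lambda_ind = 0, dup_bias = 10,
                    n_trans_genes = 5,
                    karyotype_event_probs = c(whole_loss = 0,
                      partial_loss = 0, segmental_amplification = 0),
                    seed = 2)
  tr <- simulate_lineages(make_genome(cfg, sequence = FALSE), cfg)
  dis <- tr$samples$sample_id[tr$samples$strain == "D1" &
                                tr$samples$role == "evolved"]
  m <- tr$mutations[tr$mutations$sample_id %in% dis, ]
  expect_gte(nrow(m), 9000)
  expect_lt(abs(mean(m$on_dup) - 10 * 0.05 / (0.95 + 10 * 0.05)), 0.02)
})

test_that("coverage windows tile chromosomes with a truncated last window", {
  cfg <- sim_config(chrom_lengths = c(chrA = 10050L), disome_chroms = "chrA",
                    seed = 1, n_trans_genes = 1)
  tr <- simulate_lineages(make_genome(cfg, sequence = FALSE), cfg)
  cov <- simulate_coverage(tr, cfg, samples = "WT_anc")[[1]]
  w <- cov$windows
  expect_identical(w$start[1], 0L)
  expect_identical(w$end[nrow(w)], 10050L)
  expect_identical(w$end[nrow(w)] - w$start[nrow(w)], 50L)
  expect_true(all(w$start[-1] == w$end[-nrow(w)]))
})

test_that("coverage mean scales with copy number (Poisson limit)", {
  cfg <- sim_config(chrom_lengths = c(dup = 100000L, ref = 100000L),
                    disome_chroms = "dup", nb_dispersion = 0, depth = 50,
                    n_trans_genes = 5,
                    karyotype_event_probs = c(whole_loss = 0,
                      partial_loss = 0, segmental_amplification = 0),
                    seed = 4)
  tr <- simulate_lineages(make_genome(cfg, sequence = FALSE), cfg)
  cov <- simulate_coverage(tr, cfg, samples = "D1_ev1")[[1]]
  w <- cov$windows
  ratio <- mean(w$count[w$chrom == "dup"]) / mean(w$count[w$chrom == "ref"])
  expect_gte(ratio, 1.95)
  expect_lte(ratio, 2.05)
})

test_that("generators are deterministic given the seed", {
  cfg <- small_config(seed = 9)
  gen <- make_genome(cfg)
  t1 <- simulate_lineages(gen, cfg); t2 <- simulate_lineages(gen, cfg)
  expect_identical(t1$mutations, t2$mutations)
  expect_identical(t1$karyotypes, t2$karyotypes)
  c1 <- simulate_coverage(t1, cfg, samples = "D1_ev1")
  c2 <- simulate_coverage(t2, cfg, samples = "D1_ev1")
  expect_identical(c1[["D1_ev1"]]$windows, c2[["D1_ev1"]]$windows)
  e1 <- simulate_expression(t1, cfg); e2 <- simulate_expression(t2, cfg)
  expect_identical(e1$counts, e2$counts)
  g1 <- simulate_growth(t1, cfg); g2 <- simulate_growth(t2, cfg)
  expect_identical(g1, g2)
})

test_that("variant observations cover truth, flag false positives, and share background", {
  w <- fixture_world()
  truth_keys <- paste(w$truth$mutations$chrom, w$truth$mutations$pos,
                      w$truth$mutations$sample_id)
  for (id in c("D1_ev1", "D2_ev2", "WT_ev1")) {
    cs <- w$callsets[[id]]
    for (caller in c("a", "b")) {
      v <- cs[[caller]]
      dn <- v[v$origin == "denovo", ]
      expect_true(all(paste(dn$chrom, dn$pos, id) %in% truth_keys))
      expect_true(all(v$origin %in%
                        c("denovo", "background", "false_positive")))
    }
    # every true mutation of this line appears in both callers
    tm <- w$truth$mutations[w$truth$mutations$sample_id == id, ]
    for (caller in c("a", "b")) {
      v <- cs[[caller]]
      expect_true(all(paste(tm$chrom, tm$pos) %in% paste(v$chrom, v$pos)))
    }
  }
  # background ancestral variants present in ancestor and all evolved lines
  anc_bg <- w$callsets[["D1_anc"]]$a
  anc_bg <- anc_bg[anc_bg$origin == "background", ]
  expect_gt(nrow(anc_bg), 0)
  for (id in c("D1_ev1", "D1_ev2", "D1_ev3")) {
    ev <- w$callsets[[id]]$a
    expect_true(all(paste(anc_bg$chrom, anc_bg$pos) %in%
                      paste(ev$chrom, ev$pos)))
  }
})

test_that("alt fractions of duplicated-chromosome variants centre on one half", {
  cfg <- sim_config(chrom_lengths = c(dup = 50000L, ref = 50000L),
                    disome_chroms = "dup", lines_per_strain = 10L,
                    lambda_sub = 120, lambda_ind = 0, dup_bias = 50,
                    depth = 50, fp_rate = 0, n_background = 0,
                    n_trans_genes = 5,
                    karyotype_event_probs = c(whole_loss = 0,
                      partial_loss = 0, segmental_amplification = 0),
                    seed = 6)
  gen <- make_genome(cfg, sequence = FALSE)
  tr <- simulate_lineages(gen, cfg)
  cs <- simulate_variant_observations(tr, cfg,
    samples = tr$samples$sample_id[tr$samples$strain == "D1" &
                                     tr$samples$role == "evolved"])
  af <- unlist(lapply(cs, function(s) {
    v <- s$a[s$a$chrom == "dup" & s$a$origin == "denovo", ]
    v$ad / v$dp
  }))
  expect_gte(length(af), 1000)
  expect_gte(mean(af), 0.45)
  expect_lte(mean(af), 0.55)
})

test_that("fp_rate 0 makes the caller intersection equal the truth plus background", {
  cfg <- small_config(fp_rate = 0, seed = 7)
  gen <- make_genome(cfg, sequence = FALSE)
  tr <- simulate_lineages(gen, cfg)
  cs <- simulate_variant_observations(tr, cfg, samples = "D1_ev1")
  cons <- intersect_callers(cs[["D1_ev1"]]$a, cs[["D1_ev1"]]$b)
  tm <- tr$mutations[tr$mutations$sample_id == "D1_ev1", ]
  expect_setequal(paste(cons$chrom, cons$pos)[cons$origin == "denovo"],
                  paste(tm$chrom, tm$pos))
  expect_true(all(cons$origin %in% c("denovo", "background")))
})

test_that("expression dosage vanishes at factor 1 and attenuation 1 restores WT", {
  cfg <- sim_config(chrom_lengths = c(dup = 1000000L, ref = 1000000L),
                    disome_chroms = "dup", lines_per_strain = 1L,
                    dosage_factor = 1, n_trans_genes = 0,
                    karyotype_event_probs = c(whole_loss = 0,
                      partial_loss = 0, segmental_amplification = 0),
                    seed = 8)
  gen <- make_genome(cfg, sequence = FALSE)
  tr <- simulate_lineages(gen, cfg)
  ex <- simulate_expression(tr, cfg, samples = c("WT_anc", "D1_anc"))
  norm <- rle_normalize(filter_cpm(ex))
  med <- chromosome_dosage(norm, gen, "dup", "D1_anc", "WT_anc")
  expect_gte(sum(gen$genes$chrom == "dup"), 500)
  expect_gte(med, 0.95); expect_lte(med, 1.05)

  cfg2 <- cfg; cfg2$dosage_factor <- 1.8; cfg2$attenuation <- c(1, 1)
  tr2 <- simulate_lineages(gen, cfg2)
  ex2 <- simulate_expression(tr2, cfg2, samples = c("WT_anc", "D1_ev1"))
  norm2 <- rle_normalize(filter_cpm(ex2))
  med2 <- chromosome_dosage(norm2, gen, "dup", "D1_ev1", "WT_anc")
  expect_gte(med2, 0.95); expect_lte(med2, 1.05)
})

test_that("growth curves match the closed form without noise", {
  cfg <- small_config(growth_noise_sd = 0, seed = 10)
  gen <- make_genome(cfg, sequence = FALSE)
  tr <- simulate_lineages(gen, cfg)
  # effectively exponential when capacity is far away
  gr <- simulate_growth(tr, cfg, samples = "WT_anc", replicates = 1,
                        od0 = 1e-4, capacity = 1e9)
  dbl <- tr$growth$doubling_min[tr$growth$sample_id == "WT_anc"]
  expect_equal(gr$od, 1e-4 * 2^(gr$time_min / dbl), tolerance = 1e-6)
})

test_that("full-pipeline apparent-rate recovery covers the generative rate", {
  # lambda_sub = 8, depth 50, 3 lines x 4 strains: the estimate's 95%
  # interval must cover the generative rate in >= 90 of 100 seeds
  cfg <- sim_config(chrom_lengths = setNames(rep(40000L, 4), paste0("chr", 1:4)),
                    disome_chroms = paste0("chr", 1:4),
                    lambda_sub = 8, lambda_ind = 0, depth = 50,
                    n_background = 5, n_trans_genes = 5, fp_rate = 2,
                    seed = 1)
  gen <- make_genome(cfg, sequence = FALSE)
  n_bp <- sum(cfg$chrom_lengths); g <- cfg$generations
  u_true <- 8 / (n_bp * g)
  hits <- vapply(1:100, function(s) {
    cfg$seed <- s
    tr <- simulate_lineages(gen, cfg)
    ev <- tr$samples$sample_id[tr$samples$role == "evolved" &
                                 tr$samples$strain != "WT"]
    cs <- simulate_variant_observations(tr, cfg, samples = c(ev,
      paste0(unique(tr$samples$strain[tr$samples$strain != "WT"]), "_anc")))
    m_tot <- sum(vapply(ev, function(id) {
      strain <- tr$samples$strain[tr$samples$sample_id == id]
      cons <- intersect_callers(cs[[id]]$a, cs[[id]]$b)
      anc <- cs[[paste0(strain, "_anc")]]$a
      k <- tr$karyotypes[tr$karyotypes$sample_id == id, ]
      nrow(filter_denovo(cons, anc, k))
    }, numeric(1)))
    est <- apparent_rate(m_tot, n_bp, length(ev) * g)
    abs(est$u - u_true) <= 1.96 * est$se
  }, logical(1))
  expect_gte(sum(hits), 90)
})
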