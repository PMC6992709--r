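em <- function(counts, roles = NULL, strains = NULL) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)) && ncol(counts))
    colnames(counts) <- paste0("S", seq_len(ncol(counts)))
  if (is.null(rownames(counts)) && nrow(counts))
    rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  expression_matrix(counts, data.frame(
    sample_id = colnames(counts),
    strain = strains %||% rep("D1", ncol(counts)),
    role = roles %||% rep("evolved", ncol(counts)),
    disome_chrom = "chr1"))
}

test_that("CPM filter keeps 'at least half' inclusively", {
  m <- rbind(a = c(1, 1, 0, 0), b = c(0, 0, 0, 1), c = c(2, 2, 2, 2))
  big <- matrix(rep(1e6 - colSums(m), each = 1), 1)  # pad to library 1e6
  x <- em(rbind(m, pad = 1e6 - colSums(m)))
  f <- filter_cpm(x)
  expect_true(all(c("a", "c") %in% rownames(f$counts)))
  expect_false("b" %in% rownames(f$counts))
  # all genes above threshold everywhere: identity
  y <- em(matrix(10, 5, 4))
  expect_identical(dim(filter_cpm(y)$counts), c(5L, 4L))
  expect_error(filter_cpm(em(matrix(0L, 0, 3))), "empty")
})

test_that("RLE size factors match the hand-computed median of ratios", {
  x <- em(cbind(c(10, 30, 100), c(20, 60, 200)))
  n <- rle_normalize(x)
  expect_equal(unname(n$size_factors), c(sqrt(0.5), sqrt(2)),
               tolerance = 1e-4)
  # normalized values equal across the two proportional samples
  expect_equal(n$log2[, 1], n$log2[, 2])
  # identical samples: equal factors
  xi <- em(cbind(c(5, 8), c(5, 8), c(5, 8)))
  expect_equal(unname(rle_normalize(xi)$size_factors), rep(1, 3))
})

test_that("RLE equivariance properties hold", {
  set.seed(4)
  counts <- matrix(rnbinom(600, mu = 100, size = 10) + 1, 100, 6)
  x <- em(counts)
  n <- rle_normalize(x)
  # doubling one sample doubles its factor relative to every other
  # sample (the per-gene geometric-mean reference itself drifts by
  # 2^(1/n), so the absolute factor scales by 2 * 2^(-1/n); see ledger)
  c2 <- counts; c2[, 3] <- c2[, 3] * 2L
  n2 <- rle_normalize(em(c2))
  expect_equal(unname(n2$size_factors[3] / n2$size_factors[1]),
               unname(2 * n$size_factors[3] / n$size_factors[1]),
               tolerance = 1e-12)
  # and its normalized profile only shifts by a common constant
  shift <- n2$log2[, 3] - n$log2[, 3]
  expect_lt(sd(shift), 0.01)
  # permuting samples permutes factors identically
  perm <- c(4, 1, 6, 2, 3, 5)
  np <- rle_normalize(em(counts[, perm]))
  expect_equal(unname(np$size_factors), unname(n$size_factors[perm]))
  # adding one constant gene moves a finite median by at most O(1/n):
  # negligible at realistic gene counts (exact only in the continuous
  # limit, see the methods vignette)
  set.seed(5)
  big <- matrix(rnbinom(2000 * 6, mu = 100, size = 10) + 1, 2000, 6)
  nb <- rle_normalize(em(big))
  nbc <- rle_normalize(em(rbind(big, const = 50)))
  expect_equal(unname(nbc$size_factors), unname(nb$size_factors),
               tolerance = 5e-3)
})

test_that("RLE factors agree with the DESeq2 median-of-ratios oracle", {
  set.seed(12)
  counts <- matrix(rnbinom(1200, mu = 80, size = 5) + 1, 200, 6,
                   dimnames = list(paste0("g", 1:200), paste0("s", 1:6)))
  mine <- rle_normalize(em(counts))$size_factors
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  ref <- ref / exp(mean(log(ref)))   # same geometric-mean-1 convention
  expect_equal(unname(mine), unname(ref), tolerance = 1e-10)
})

test_that("chromosome dosage is the median linear ratio", {
  g <- list(genes = data.frame(gene_id = paste0("g", 1:12),
                               chrom = rep(c("chr1", "chr2"), each = 6)))
  log2m <- cbind(WT = rep(0, 12),
                 S = c(log2(c(1.8, 2, 2.2, 2, 2, 2)), rep(0, 6)))
  rownames(log2m) <- paste0("g", 1:12)
  n <- fake_norm(log2m)
  expect_equal(chromosome_dosage(n, g, "chr1", "S", "WT", min_genes = 5), 2)
  expect_error(chromosome_dosage(n, g, "chr1", "S", "WT", min_genes = 10),
               "fewer than")
})

test_that("expression shift reproduces the worked example", {
  l2 <- cbind(WT = rep(0, 4),
              ANC = c(1.0, -1.2, 0.3, 0.9),
              EVO = c(0.5, -0.6, 0.15, 0.45))
  rownames(l2) <- paste0("g", 1:4)
  sr <- expression_shift(fake_norm(l2), "EVO", "ANC", "WT")
  expect_setequal(sr$genes, c("g1", "g2", "g4"))
  expect_equal(sr$d_anc, sqrt(1 + 1.44 + 0.81), tolerance = 1e-12)
  expect_equal(sr$d_evo, sqrt(1 + 1.44 + 0.81) / 2, tolerance = 1e-12)
  expect_equal(sr$shift, 0.5, tolerance = 1e-12)
})

test_that("shift properties: endpoints, linear scaling, base invariance", {
  set.seed(6)
  anc <- rnorm(50, 0, 1.2)
  l2 <- cbind(WT = rep(0, 50), ANC = anc, EVO = anc)
  rownames(l2) <- paste0("g", 1:50)
  expect_equal(expression_shift(fake_norm(l2), "EVO", "ANC", "WT")$shift, 0)
  l2[, "EVO"] <- 0
  expect_equal(expression_shift(fake_norm(l2), "EVO", "ANC", "WT")$shift, 1)
  for (cc in c(0.25, 0.6, 0.9)) {
    l2[, "EVO"] <- cc * anc
    expect_equal(expression_shift(fake_norm(l2), "EVO", "ANC", "WT")$shift,
                 1 - cc, tolerance = 1e-12)
  }
  # changing the log base rescales both distances identically
  l2[, "EVO"] <- 0.4 * anc
  s2 <- expression_shift(fake_norm(l2), "EVO", "ANC", "WT")
  sln <- expression_shift(fake_norm(l2 * log(2)), "EVO", "ANC", "WT")
  s10 <- expression_shift(fake_norm(l2 * log10(2)), "EVO", "ANC", "WT")
  expect_equal(s2$shift, sln$shift, tolerance = 1e-9)
  expect_equal(s2$shift, s10$shift, tolerance = 1e-9)
  # empty gene set: flagged undefined
  flat <- cbind(WT = rep(0, 5), ANC = rep(0.1, 5), EVO = rep(0, 5))
  rownames(flat) <- paste0("g", 1:5)
  sr <- expression_shift(fake_norm(flat), "EVO", "ANC", "WT")
  expect_false(sr$defined)
  expect_true(is.na(sr$shift))
})

test_that("common DE detects a uniform shift with high power", {
  # 32 evolved + 12 ancestors, true log2 shift 2 on one gene, sd 0.3
  n_anc <- 12; n_evo <- 32
  strains <- rep(paste0("D", 1:4), len = n_anc + n_evo)
  roles <- rep(c("ancestor", "evolved"), c(n_anc, n_evo))
  hits <- 0L
  for (seed in 1:100) {
    set.seed(seed)
    y <- matrix(rnorm(50 * (n_anc + n_evo), 5, 0.3), 50)
    y[1, roles == "evolved"] <- y[1, roles == "evolved"] + 2
    rownames(y) <- paste0("g", 1:50)
    colnames(y) <- paste0("s", seq_len(ncol(y)))
    norm <- fake_norm(y, meta = data.frame(sample_id = colnames(y),
                                           strain = strains, role = roles,
                                           disome_chrom = "chr1"))
    res <- common_de(norm)
    if (res$significant[res$gene == "g1"]) hits <- hits + 1L
  }
  expect_gte(hits, 95)
})

test_that("common DE drops constant genes from the BH family", {
  roles <- rep(c("ancestor", "evolved"), each = 4)
  y <- matrix(rnorm(40, 0, 1), 5, 8)
  y[3, ] <- 7                       # constant gene
  rownames(y) <- paste0("g", 1:5); colnames(y) <- paste0("s", 1:8)
  norm <- fake_norm(y, meta = data.frame(sample_id = colnames(y),
                                         strain = "D1", role = roles,
                                         disome_chrom = "chr1"))
  res <- common_de(norm, strain_covariate = FALSE)
  expect_true(is.na(res$p[res$gene == "g3"]))
  expect_true(is.na(res$q[res$gene == "g3"]))
  expect_false(anyNA(res$q[res$gene != "g3"]))
})

test_that("shift association is exact for a perfectly tracking gene and
           calibrated under the null", {
  set.seed(13)
  shifts <- setNames(runif(12, 0, 0.8), paste0("e", 1:12))
  y <- matrix(rnorm(1000 * 12), 1000, 12,
              dimnames = list(paste0("g", 1:1000), names(shifts)))
  y[1, ] <- shifts                   # expression equals the shift exactly
  norm <- fake_norm(y)
  res <- shift_association(norm, shifts)
  expect_equal(res$slope[res$gene == "g1"], 1, tolerance = 1e-9)
  expect_lt(res$p[res$gene == "g1"], 1e-12)
  expect_identical(res$direction[res$gene == "g1"], "positive")
  # null genes: p-values uniform (KS test on the other 999 genes)
  ks <- suppressWarnings(ks.test(res$p[res$gene != "g1"], "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_error(shift_association(norm, setNames(rep(0.3, 12),
                                                colnames(y))), "constant")
  expect_error(shift_association(norm, shifts[1:3]), ">= 4")
})

test_that("hypergeometric enrichment equals exhaustive enumeration", {
  universe <- paste0("g", 1:100)
  selected <- paste0("g", 1:10)
  sets <- list(hit = paste0("g", c(1:5, 51:55)),    # overlap 5
               none = paste0("g", 90:99),           # overlap 0
               half = paste0("g", 6:25))
  res <- set_enrichment(selected, universe, sets)
  # oracle: P(X >= 5) by explicit enumeration of the hypergeometric pmf
  pmf <- vapply(0:10, function(k)
    choose(10, k) * choose(90, 10 - k) / choose(100, 10), numeric(1))
  expect_equal(res$p[res$set == "hit"], sum(pmf[(5:10) + 1]),
               tolerance = 1e-12)
  expect_gte(res$p[res$set == "none"], 0.5)
  # selected = universe forces overlap: p = 1 everywhere
  res2 <- set_enrichment(universe, universe, sets)
  expect_true(all(res2$p == 1))
  expect_error(set_enrichment("g1", character(), sets), "universe")
  expect_error(set_enrichment("zz", universe, sets), "within universe")
})

test_that("recovered shifts track generative attenuations in rank", {
  # default-scale world with karyotype events off: losses and
  # amplifications move dosage deviations independently of attenuation,
  # so the attenuation-shift mapping is defined on stable karyotypes
  cfg <- sim_config(karyotype_event_probs = c(whole_loss = 0,
                      partial_loss = 0, segmental_amplification = 0),
                    seed = 1)
  gen <- make_genome(cfg, sequence = FALSE)
  rhos <- vapply(1:20, function(s) {
    cfg$seed <- s
    tr <- simulate_lineages(gen, cfg)
    ex <- simulate_expression(tr, cfg)
    norm <- rle_normalize(filter_cpm(ex))
    evo <- tr$samples[tr$samples$role == "evolved" &
                        !is.na(tr$samples$disome_chrom), ]
    shifts <- vapply(seq_len(nrow(evo)), function(i) {
      expression_shift(norm, evo$sample_id[i],
                       paste0(evo$strain[i], "_anc"), "WT_anc")$shift
    }, numeric(1))
    att <- tr$expression$attenuation[
      match(evo$sample_id, tr$expression$sample_id)]
    cor(shifts, att, method = "spearman")
  }, numeric(1))
  expect_gte(min(rhos), 0.9)
})
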