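#' Expression count matrix container
#'
#' @param counts integer matrix, genes x samples.
#' @param meta sample metadata data.frame with columns `sample_id`,
#'   `strain`, `role` (WT ancestor / ancestor / evolved), and
#'   `disome_chrom`; rows match the columns of `counts`.
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(counts, meta) {
  counts <- as.matrix(counts)
  assert_that(all(counts >= 0), "counts must be non-negative")
  assert_that(ncol(counts) == nrow(meta) &&
                all(colnames(counts) == meta$sample_id),
              "metadata rows must match count columns")
  structure(list(counts = counts, meta = meta), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples\n")
  invisible(x)
}

#' Filter genes by counts per million
#'
#' Keeps a gene iff its CPM is at least `min_cpm` in at least
#' `ceiling(min_fraction * n_samples)` samples ("at least half"
#' inclusive).
#'
#' @param x an [expression_matrix()].
#' @param min_cpm CPM threshold (default 1).
#' @param min_fraction required fraction of samples (default 0.5).
#' @return the filtered `expression_matrix`.
#' @export
filter_cpm <- function(x, min_cpm = 1, min_fraction = 0.5) {
  assert_that(inherits(x, "expression_matrix"), "x must be an expression_matrix")
  assert_that(nrow(x$counts) > 0 && ncol(x$counts) > 0, "empty matrix")
  lib <- colSums(x$counts)
  assert_that(all(lib > 0), "library sizes must be positive")
  cpm <- t(t(x$counts) / lib) * 1e6
  need <- ceiling(min_fraction * ncol(x$counts))
  keep <- rowSums(cpm >= min_cpm) >= need
  expression_matrix(x$counts[keep, , drop = FALSE], x$meta)
}

#' Relative log expression (RLE) normalization
#'
#' Median-of-ratios size factors: genes with a zero count in any sample
#' are excluded from factor estimation; each sample's factor is the
#' (geometric-interpolated) median over the remaining genes of
#' count / per-gene geometric mean.  Factors are rescaled to geometric
#' mean 1, so size factors are equivariant: multiplying one sample's
#' counts by a constant multiplies its factor by that constant and
#' leaves its normalized values unchanged.  Normalized expression is
#' `log2(count / factor + 1)`.
#'
#' @param x an [expression_matrix()] with at least two samples and at
#'   least one gene expressed in every sample.
#' @return object of class `normalized_matrix` with fields `log2`,
#'   `size_factors`, `meta`.
#' @export
rle_normalize <- function(x) {
  assert_that(inherits(x, "expression_matrix"), "x must be an expression_matrix")
  assert_that(ncol(x$counts) >= 2, "need >= 2 samples")
  nz <- rowSums(x$counts == 0) == 0
  assert_that(any(nz), "no gene with nonzero counts in all samples")
  lc <- log(x$counts[nz, , drop = FALSE])
  logref <- rowMeans(lc)
  sf <- exp(apply(lc - logref, 2, median))
  sf <- sf / exp(mean(log(sf)))
  log2 <- log2(t(t(x$counts) / sf) + 1)
  structure(list(log2 = log2, size_factors = sf, meta = x$meta),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat("normalized_matrix:", nrow(x$log2), "genes x", ncol(x$log2),
      "samples (RLE + log2)\n")
  invisible(x)
}

#' Median expression dosage of a chromosome
#'
#' Median, over the genes of one chromosome, of the linear-scale
#' expression ratio of a sample to the wild type.
#'
#' @param norm a [rle_normalize()] result.
#' @param genome [make_genome()] annotation (gene-to-chromosome map).
#' @param chrom chromosome of interest; must carry >= `min_genes` genes
#'   present in the matrix.
#' @param sample,wt_sample column ids.
#' @param min_genes minimum genes required (default 10).
#' @return scalar median fold change.
#' @export
chromosome_dosage <- function(norm, genome, chrom, sample, wt_sample,
                              min_genes = 10) {
  ids <- genome$genes$gene_id[genome$genes$chrom == chrom]
  ids <- intersect(ids, rownames(norm$log2))
  assert_that(length(ids) >= min_genes,
              "fewer than ", min_genes, " genes on ", chrom)
  ratio <- 2 ^ (norm$log2[ids, sample] - norm$log2[ids, wt_sample])
  median(ratio)
}

#' Expression shift towards wild type
#'
#' The gene set `G` comprises genes whose ancestor/WT expression ratio
#' is at least `fc_threshold` or at most `1/fc_threshold`.  On `G`, the
#' Euclidean distance in log space between evolved line and WT is
#' normalized by the ancestor-WT distance; the shift towards WT is one
#' minus that normalized distance.  A shift of 1 means full return to
#' euploid-like expression; 0 means no change from the ancestor.
#'
#' @param norm a [rle_normalize()] result (any log base works; the
#'   shift is base-invariant).
#' @param evolved,ancestor,wt column ids sharing the gene universe.
#' @param fc_threshold linear fold-change threshold defining `G`
#'   (default 1.5, applied two-sidedly).
#' @return object of class `shift_result`: `genes` (the set `G`),
#'   `d_anc`, `d_evo`, `normalized_distance`, `shift`, `defined`.
#' @export
expression_shift <- function(norm, evolved, ancestor, wt,
                             fc_threshold = 1.5) {
  assert_that(fc_threshold > 1, "fc_threshold must exceed 1")
  la <- norm$log2[, ancestor]; lw <- norm$log2[, wt]; le <- norm$log2[, evolved]
  dev_anc <- la - lw
  g <- abs(dev_anc) >= log2(fc_threshold)
  if (!any(g)) {
    return(structure(list(genes = character(), d_anc = NA_real_,
                          d_evo = NA_real_, normalized_distance = NA_real_,
                          shift = NA_real_, defined = FALSE),
                     class = "shift_result"))
  }
  d_anc <- sqrt(sum((la[g] - lw[g])^2))
  d_evo <- sqrt(sum((le[g] - lw[g])^2))
  structure(list(genes = rownames(norm$log2)[g], d_anc = d_anc, d_evo = d_evo,
                 normalized_distance = d_evo / d_anc,
                 shift = 1 - d_evo / d_anc, defined = TRUE),
            class = "shift_result")
}

#' @export
print.shift_result <- function(x, ...) {
  if (!x$defined) cat("shift_result: undefined (empty gene set)\n")
  else cat(sprintf("shift_result: %d genes, D_anc %.3f, D_evo %.3f, shift %.3f\n",
                   length(x$genes), x$d_anc, x$d_evo, x$shift))
  invisible(x)
}

# per-gene least squares with t tests on one coefficient.
# Y: genes x samples, X: design matrix. Returns estimate, p, q.
gene_lm <- function(Y, X, coef) {
  qr_x <- qr(X)
  assert_that(qr_x$rank == ncol(X), "design matrix is rank deficient")
  df <- ncol(Y) - ncol(X)
  assert_that(df >= 1, "zero residual degrees of freedom")
  beta <- t(qr.coef(qr_x, t(Y)))
  fit <- t(qr.fitted(qr_x, t(Y)))
  rss <- rowSums((Y - fit)^2)
  sigma2 <- rss / df
  xtxinv <- chol2inv(qr.R(qr_x))
  se <- sqrt(sigma2 * xtxinv[coef, coef])
  est <- beta[, coef]
  tstat <- est / se
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  # a perfect fit (rss ~ 0, nonzero effect) is machine-limited, p -> 0;
  # a constant gene carries no information and is undefined (NA)
  perfect <- se <= 1e-12 * pmax(abs(est), 1)
  p[perfect] <- 0
  rowvar <- rowSums((Y - rowMeans(Y))^2)
  p[rowvar <= 1e-18 * pmax(rowSums(Y^2), 1)] <- NA
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- p.adjust(p[ok], "BH")
  data.frame(gene = rownames(Y), estimate = est, p = p, q = q,
             row.names = NULL)
}

#' Common differential expression between ancestors and evolved lines
#'
#' Per gene, a least-squares fit of normalized log2 expression on an
#' evolved-vs-ancestor indicator; by default a strain covariate block
#' makes the contrast within-strain.  Two-sided t tests on the
#' indicator, Benjamini-Hochberg across genes (genes with undefined
#' tests are dropped from the family), significance at `q <= fdr`.
#'
#' @param norm a [rle_normalize()] result; WT samples are excluded, and
#'   both roles need >= 2 samples.
#' @param strain_covariate include the strain block (default TRUE); the
#'   pooled no-covariate model is available with FALSE.
#' @param fdr FDR threshold (default 0.1).
#' @return data.frame `gene`, `log2fc`, `p`, `q`, `significant`.
#' @export
common_de <- function(norm, strain_covariate = TRUE, fdr = 0.1) {
  meta <- norm$meta
  use <- meta$strain != "WT" & meta$role %in% c("ancestor", "evolved")
  meta <- meta[use, ]
  Y <- norm$log2[, meta$sample_id, drop = FALSE]
  assert_that(sum(meta$role == "evolved") >= 2 &&
                sum(meta$role == "ancestor") >= 2,
              "need >= 2 samples per role")
  evolved <- as.integer(meta$role == "evolved")
  X <- if (strain_covariate && length(unique(meta$strain)) > 1)
    cbind(model.matrix(~ factor(meta$strain)), evolved)
  else cbind(1, evolved)
  res <- gene_lm(Y, X, ncol(X))
  names(res)[names(res) == "estimate"] <- "log2fc"
  res$significant <- !is.na(res$q) & res$q <= fdr
  res
}

#' Genes associated with the expression shift towards WT
#'
#' Per gene, least-squares regression of evolved-line log2 expression on
#' the numeric shift covariate; two-sided t test on the slope with BH
#' adjustment and the direction of association reported.
#'
#' @param norm a [rle_normalize()] result.
#' @param shifts named numeric vector of shift values per evolved
#'   sample (>= 4 defined values with nonzero variance).
#' @param fdr FDR threshold (default 0.1).
#' @return data.frame `gene`, `slope`, `p`, `q`, `significant`,
#'   `direction`.
#' @export
shift_association <- function(norm, shifts, fdr = 0.1) {
  shifts <- shifts[!is.na(shifts)]
  assert_that(length(shifts) >= 4, "need >= 4 evolved lines with defined shift")
  assert_that(sd(shifts) > 0, "constant shift vector")
  Y <- norm$log2[, names(shifts), drop = FALSE]
  res <- gene_lm(Y, cbind(1, shift = shifts), 2)
  names(res)[names(res) == "estimate"] <- "slope"
  res$significant <- !is.na(res$q) & res$q <= fdr
  res$direction <- ifelse(res$slope >= 0, "positive", "negative")
  res
}

#' Gene set over-representation (hypergeometric) test
#'
#' One-sided hypergeometric p-value for the overlap of the selected
#' genes with each annotation set (both intersected with the universe),
#' BH-adjusted across sets.
#'
#' @param selected character vector, a subset of `universe`.
#' @param universe character vector of all tested genes (non-empty).
#' @param annotation_sets named list of character vectors.
#' @return data.frame `set`, `overlap`, `set_size`, `selected_size`,
#'   `universe_size`, `p`, `q`.
#' @export
set_enrichment <- function(selected, universe, annotation_sets) {
  assert_that(length(universe) > 0, "empty universe")
  assert_that(all(selected %in% universe), "selected must be within universe")
  n_sel <- length(selected)
  N <- length(universe)
  rows <- lapply(names(annotation_sets), function(nm) {
    K <- intersect(annotation_sets[[nm]], universe)
    k <- length(intersect(K, selected))
    p <- if (length(K) == 0) 1 else
      phyper(k - 1, length(K), N - length(K), n_sel, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = length(K),
               selected_size = n_sel, universe_size = N, p = p)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, "BH")
  out[order(out$p), , drop = FALSE]
}
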