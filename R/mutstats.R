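#' Apparent mutation rate with standard error
#'
#' The apparent rate of fixed mutations per nucleotide per generation is
#' `u = m / (n * g)` where `m` is the number of detected de novo
#' mutations (a count, or a per-line mean), `n` the number of bases in
#' the reference genome and `g` the number of generations.  The standard
#' error is `sqrt(u / (n * g))`, the Poisson-sampling error of the
#' count.  Note the algebraic identity `se / u = 1 / sqrt(m)` for
#' `m > 0`.
#'
#' @param m mutation count (or per-line mean count), vectorized.
#' @param n genome size in bp (default 1.212e7; see the methods
#'   vignette for the calibration of this default).
#' @param g generations (default 1200).
#' @return data.frame with columns `m`, `n`, `g`, `u`, `se`.
#' @export
apparent_rate <- function(m, n = 1.212e7, g = 1200) {
  assert_that(all(m >= 0), "mutation counts must be non-negative")
  assert_that(all(n > 0) && all(g > 0), "n and g must be positive")
  u <- m / (n * g)
  data.frame(m = m, n = n, g = g, u = u, se = sqrt(u / (n * g)))
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

SPECTRUM6_CLASSES <- c("C:G>T:A", "C:G>A:T", "C:G>G:C",
                       "T:A>C:G", "T:A>A:T", "T:A>G:C")

# strand-collapsed (pyrimidine reference) class of a substitution
substitution_class <- function(ref, alt) {
  flip <- ref %in% c("G", "A")
  ref2 <- ifelse(flip, COMPLEMENT[ref], ref)
  alt2 <- ifelse(flip, COMPLEMENT[alt], alt)
  out <- rep(NA_character_, length(ref))
  out[ref2 == "C" & alt2 == "T"] <- "C:G>T:A"
  out[ref2 == "C" & alt2 == "A"] <- "C:G>A:T"
  out[ref2 == "C" & alt2 == "G"] <- "C:G>G:C"
  out[ref2 == "T" & alt2 == "C"] <- "T:A>C:G"
  out[ref2 == "T" & alt2 == "A"] <- "T:A>A:T"
  out[ref2 == "T" & alt2 == "G"] <- "T:A>G:C"
  out
}

#' Composition-normalized per-type mutation rates
#'
#' Counts substitutions in the six strand-collapsed base-change classes
#' and converts each to a rate `m_class / (n * f * g)`, where `f` is the
#' genomic GC fraction for classes originating from C:G pairs and the
#' AT fraction for classes originating from T:A pairs.
#'
#' @param mutations mutation data.frame with `ref`, `alt`, `type`
#'   columns; only substitutions are used.
#' @param n genome size (bp); `g` generations.
#' @param gc_fraction genomic GC fraction.
#' @param at_fraction genomic AT fraction; must sum with `gc_fraction`
#'   to 1 (tolerance 1e-9).
#' @param g generations.
#' @return list with `counts`, `rates` (per class) and `spectrum` (rates
#'   normalized to sum 1; all-zero input gives a zero vector).
#' @export
per_type_rates <- function(mutations, n, g, gc_fraction,
                           at_fraction = 1 - gc_fraction) {
  assert_that(abs(gc_fraction + at_fraction - 1) <= 1e-9,
              "GC and AT fractions must sum to 1")
  sub <- mutations[mutations$type == "substitution", , drop = FALSE]
  cls <- substitution_class(sub$ref, sub$alt)
  counts <- vapply(SPECTRUM6_CLASSES, function(k) sum(cls == k, na.rm = TRUE),
                   numeric(1))
  f <- ifelse(startsWith(SPECTRUM6_CLASSES, "C:G"), gc_fraction, at_fraction)
  rates <- counts / (n * f * g)
  spectrum <- if (sum(rates) > 0) rates / sum(rates) else rates
  list(counts = counts, rates = rates, spectrum = spectrum)
}

#' Exact two-sided binomial test
#'
#' The default `"double"` method doubles the smaller exact tail
#' probability and caps at 1; `"minlike"` sums the probabilities of all
#' outcomes no more likely than the observed one (the `binom.test`
#' convention).
#'
#' @param x successes; `n` trials; `p0` null success probability.
#' @param method `"double"` (default) or `"minlike"`.
#' @return two-sided p-value.
#' @export
binom_test_twosided <- function(x, n, p0, method = c("double", "minlike")) {
  method <- match.arg(method)
  assert_that(p0 > 0 && p0 < 1, "p0 must lie strictly inside (0,1)")
  assert_that(n >= 1 && x >= 0 && x <= n, "need 0 <= x <= n, n >= 1")
  if (method == "double") {
    lower <- pbinom(x, n, p0)
    upper <- pbinom(x - 1, n, p0, lower.tail = FALSE)
    min(1, 2 * min(lower, upper))
  } else {
    d <- dbinom(0:n, n, p0)
    min(1, sum(d[d <= d[x + 1] * (1 + 1e-7)]))
  }
}

#' Mutation localization binomial tests
#'
#' Tests, per strain, whether mutations are over- or under-represented
#' in a target region: on the duplicated chromosome (`p0` = duplicated
#' chromosome length over the summed single-copy chromosome lengths) or
#' in coding sequence (`p0` = the genomic coding fraction).  Two-sided
#' exact binomial p-values are adjusted across strains by
#' Benjamini-Hochberg.
#'
#' @param successes,trials integer vectors (per strain).
#' @param p0 null probability, scalar or per strain.
#' @param labels optional strain labels.
#' @param method passed to [binom_test_twosided()].
#' @return data.frame `label`, `successes`, `trials`, `p0`, `p`, `q`.
#' @export
localization_test <- function(successes, trials, p0, labels = NULL,
                              method = "double") {
  assert_that(all(trials >= 1), "need at least one trial per strain")
  p0 <- rep_len(p0, length(successes))
  p <- mapply(binom_test_twosided, successes, trials, p0,
              MoreArgs = list(method = method))
  data.frame(label = labels %||% as.character(seq_along(successes)),
             successes = successes, trials = trials, p0 = p0,
             p = p, q = p.adjust(p, "BH"))
}

#' Null probability for the duplicated-chromosome localization test
#'
#' @param dup_chrom duplicated chromosome name.
#' @param chrom_lengths named chromosome lengths (bp).
#' @param count_dup_twice if TRUE the duplicated chromosome contributes
#'   twice its length to the denominator (and twice to the numerator),
#'   reflecting its doubled mutational target; default FALSE uses plain
#'   single-copy lengths.
#' @return scalar p0.
#' @export
p0_chromosome <- function(dup_chrom, chrom_lengths, count_dup_twice = FALSE) {
  L <- chrom_lengths[[dup_chrom]]
  tot <- sum(chrom_lengths)
  if (count_dup_twice) 2 * L / (tot + L) else L / tot
}

SPECTRUM96_SUBS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Channel labels of the 96-trinucleotide-context spectrum
#'
#' COSMIC channel order: substitution-major (C>A, C>G, C>T, T>A, T>C,
#' T>G), then 5' flank, then 3' flank, each A, C, G, T.
#' @return character vector of 96 labels like `"A[C>A]A"`.
#' @export
spectrum96_channels <- function() {
  bases <- c("A", "C", "G", "T")
  unlist(lapply(SPECTRUM96_SUBS, function(s)
    unlist(lapply(bases, function(f5)
      paste0(f5, "[", s, "]", bases)))))
}

#' Trinucleotide-context mutational spectrum
#'
#' Counts substitutions in the 96 pyrimidine-centred trinucleotide
#' channels (purine-reference mutations are reverse-complemented),
#' divides each channel by the genomic frequency of its context
#' (strand-collapsed), and normalizes the result to sum 1.
#'
#' @param mutations mutation data.frame (substitutions are used; must be
#'   non-empty).
#' @param genome [make_genome()] annotation with sequence.
#' @return named numeric vector of 96 channel weights summing to 1.
#' @export
spectrum96 <- function(mutations, genome) {
  sub <- mutations[mutations$type == "substitution", , drop = FALSE]
  assert_that(nrow(sub) > 0, "no substitutions to build a spectrum from")
  assert_that(!is.null(genome$sequences), "genome sequence required")
  channels <- spectrum96_channels()
  counts <- setNames(numeric(96), channels)
  for (i in seq_len(nrow(sub))) {
    L <- genome$chrom_lengths[[sub$chrom[i]]]
    if (sub$pos[i] < 2 || sub$pos[i] > L - 1) next
    ctx <- fetch_seq(genome, sub$chrom[i], sub$pos[i] - 1, sub$pos[i] + 1)
    ref <- sub$ref[i]; alt <- sub$alt[i]
    if (ref %in% c("A", "G")) {
      ctx <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(ctx)))
      ref <- COMPLEMENT[[ref]]; alt <- COMPLEMENT[[alt]]
    }
    ch <- paste0(substr(ctx, 1, 1), "[", ref, ">", alt, "]", substr(ctx, 3, 3))
    counts[ch] <- counts[ch] + 1
  }
  ctx_freq <- genome_context_frequencies(genome)
  ctx_of <- paste0(substr(channels, 1, 1), substr(channels, 3, 3),
                   substr(channels, 7, 7))
  w <- counts / ctx_freq[ctx_of]
  w[!is.finite(w)] <- 0
  w / sum(w)
}

# strand-collapsed genomic trinucleotide frequencies, keyed by the
# pyrimidine-centred context
genome_context_frequencies <- function(genome) {
  tf <- colSums(Biostrings::trinucleotideFrequency(genome$sequences))
  out <- setNames(numeric(32), unique(paste0(
    rep(c("A", "C", "G", "T"), each = 8),
    rep(c("C", "T"), each = 4, times = 4),
    c("A", "C", "G", "T"))))
  for (tri in names(tf)) {
    mid <- substr(tri, 2, 2)
    key <- if (mid %in% c("C", "T")) tri else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(tri)))
    out[key] <- out[key] + tf[[tri]]
  }
  out
}

#' Cosine similarity of a spectrum to reference signatures
#'
#' @param spectrum numeric 96-vector (channel order as
#'   [spectrum96_channels()]).
#' @param signatures numeric matrix, 96 rows (channels) by k signatures.
#' @return data.frame `signature`, `cosine`, sorted by decreasing
#'   similarity.
#' @export
signature_similarity <- function(spectrum, signatures) {
  signatures <- as.matrix(signatures)
  assert_that(length(spectrum) == nrow(signatures),
              "channel dimensions of spectrum and signatures differ")
  ns <- sqrt(sum(spectrum^2))
  nm <- sqrt(colSums(signatures^2))
  assert_that(ns > 0 && all(nm > 0), "zero-norm vector in similarity")
  sim <- as.numeric(crossprod(signatures, spectrum)) / (ns * nm)
  out <- data.frame(signature = colnames(signatures) %||%
                      paste0("S", seq_len(ncol(signatures))),
                    cosine = sim)
  out[order(-out$cosine), , drop = FALSE]
}

#' Correlation of mutation load with duplicated-chromosome length
#'
#' Pearson correlation between per-strain mean mutation counts and the
#' lengths of the duplicated chromosomes, with the two-sided p-value
#' from the t transform on n - 2 degrees of freedom.
#'
#' @param counts per-strain mean mutation counts (>= 3 strains).
#' @param lengths duplicated-chromosome lengths, same order.
#' @return list with `r`, `p`, `n`.
#' @export
count_length_correlation <- function(counts, lengths) {
  assert_that(length(counts) == length(lengths) && length(counts) >= 3,
              "need >= 3 paired strains")
  assert_that(sd(counts) > 0 && sd(lengths) > 0,
              "zero variance: correlation undefined")
  ct <- cor.test(counts, lengths, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(counts))
}

#' Read a mutational signature matrix from TSV
#'
#' Expects 96 rows (channel labels in COSMIC order in the first column)
#' and one column per signature.
#'
#' @param path TSV file path.
#' @return numeric matrix with channel rownames.
#' @export
read_signature_matrix <- function(path) {
  d <- read.delim(path, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  assert_that(nrow(m) == 96, "signature matrix must have 96 channel rows")
  m[spectrum96_channels(), , drop = FALSE]
}
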