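---
title: "Models and methods behind aneuvol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind aneuvol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The experiment being modelled

A haploid yeast strain carrying one extra copy of a single chromosome (a
*disome*) grows more slowly than its euploid parent, mostly because every
gene on the duplicated chromosome is expressed at roughly double dosage.
When such strains are propagated by daily serial dilution for on the
order of 1200 generations — with both copies of the duplicated chromosome
held in place by selection markers — they adapt. The adaptive routes this
package is built to quantify are:

* **karyotype changes**: complete or partial loss of the extra copy, or
  segmental amplifications of other chromosomes, with breakpoints at
  repetitive elements;
* **de novo mutations**, fixed at an *apparent rate* that confounds the
  spontaneous rate with selection, and biased in location (towards
  noncoding sequence, and towards the duplicated chromosome);
* **expression attenuation**: the largest ancestral deviations from the
  wild-type transcriptome shrink during evolution, quantified here as a
  *shift towards WT*;
* **growth restoration**, measured as the relative decrease in doubling
  time.

`aneuvol` implements the complete computational chain for such a study
and a generative simulator of it, so that every stage can be tested
against known ground truth.

# Karyotype inference from read depth

Coverage is counted in 100-bp windows (0-based, half-open; the last
window of each chromosome is truncated). For a sample $s$ and wild-type
reference $w$ the per-window ratio is

$$r(x) = \frac{c_s(x)/T_s}{c_w(x)/T_w},$$

with $T$ the total mapped reads. This makes the track invariant to
library size, but note a structural consequence: in a disome, $T_s$
includes the extra chromosome, so single-copy windows sit slightly below
1 and duplicated windows slightly below 2. With a duplicated chromosome
that is $f$ of the genome, copy-number-2 windows sit at $2/(1+f)$. For
real yeast disomes $f \le 0.09$ and the CN-2 level is $\ge 1.83$, safely
above the call threshold of 1.5; in miniature simulated genomes with
large $f$ the compression is visible (the README demo shows it), which
is a property of total-read normalisation, not an artefact of the
implementation.

**Segmentation** is recursive binary segmentation on the log2 ratio: the
candidate split maximises the reduction in within-segment sum of
squares and is accepted when the reduction exceeds
`penalty` $\times \hat\sigma^2$, where
$\hat\sigma^2 = \mathrm{mad}(\Delta x)^2/2$ is a chromosome-wide noise
estimate from successive differences (robust to the very level shifts
being sought). The default penalty of 10 is a BIC-flavoured constant:
with ~50× coverage it accepts shifts of half a copy over a few dozen
windows while rejecting noise. The estimator was chosen over more
elaborate changepoint machinery because it is deterministic, exactly
testable against a brute-force single-split oracle, and its accepted
breakpoints are *nested* in the penalty (lowering the penalty only adds
breakpoints — asserted in the tests with `merge = FALSE`; the merging of
adjacent equal-CN segments that the calling step wants can remove
breakpoints again, which is why the raw set is exposed). An epsilon
guard (`1e-9`) prevents splits on pure floating-point residue in
noiseless tracks.

**Calling.** A segment is copy number 2 iff its mean ratio is ≥ 1.5, the
midpoint between one and two copies. A chromosome is *disomic* when ≥
95% of its length is CN 2, *euploid* when ≤ 5% is (the symmetric
tolerance stops one spurious window from turning a whole loss into a
partial loss), and *partial* otherwise. Changes versus the ancestor
follow from the two status labels: disomic→euploid is a whole loss,
disomic→partial a partial loss, euploid→partial/disomic a segmental
amplification. The 95% rule is a package choice — the source analysis
classified karyotypes qualitatively — and is recorded in the call object
(`disomic_fraction`).

Windows flagged as masked in the annotation (rDNA-like arrays) and
windows with zero wild-type coverage are excluded from all segmentation
statistics.

# The mutation catalogue

Two callers' call sets are intersected on the key (chromosome, position,
ref, alt) after parsimonious normalisation (shared trailing then leading
bases trimmed, position advanced), which reconciles indel dialects. Read
counts of the consensus are taken from the first caller — the source
procedure does not say how counts were reconciled, and the tests never
depend on which caller is chosen.

A consensus variant enters the de novo catalogue iff

1. total reads ≥ 5;
2. alt-read fraction ≥ 0.40 if the site lies on a copy-number-2 region,
   ≥ 0.80 otherwise — evaluated against the **evolved line's own**
   karyotype, not the ancestor's, because the allele fraction reflects
   the current copy number (a line that lost the extra copy is held to
   the 0.80 bar);
3. the key is absent from the ancestor call set (shared variants predate
   the experiment).

Raising any threshold can only shrink the catalogue (monotonicity is a
tested property). Coding substitutions are translated with the standard
codon table (`no.init.codon = TRUE`, so an alternative initiator such as
TTG is Leu, not Met); stop gain is *nonsense*, an amino-acid change
*missense*, otherwise *silent*; the rare stop-loss is reported as
missense since the three-class scheme has no better slot. Coding indels
keep region `coding` with a `coding_indel` flag and no effect class.
Noncoding variants are assigned to the gene with the nearest
transcription start site within 750 bp (the average yeast promoter
length), *provided the variant is upstream of that TSS on the gene's
strand* — the directionality is a deliberate tightening of
"closest gene within 750 bp", toggleable via `require_upstream = FALSE`;
exact distance ties go to the smaller TSS coordinate.

# Rates, spectra and localisation

The **apparent mutation rate** is $u = m/(n g)$ per nucleotide per
generation, with standard error $\sqrt{u/(n g)}$ (the Poisson sampling
error; the identity $se/u = 1/\sqrt{m}$ is asserted for random inputs).
Two numbers deserve comment:

* $n$ defaults to $1.212\times 10^7$ bp. The source never states the
  reference length it divided by; this value is the one under which the
  packaged per-strain counts reproduce the printed
  $1.1/4.1/16.5\times10^{-10}$ rates simultaneously, and it is within
  a percent of the W303 assembly size. It is a configurable, logged
  assumption.
* $g = 1200$ for every strain. Disomes go through fewer generations in
  the same time, so their rates are slightly underestimated — the
  original analysis accepts the same bias.

Per-type rates divide the six strand-collapsed substitution classes by
$n f g$, with $f$ the genomic GC fraction for C:G-origin classes and
the AT fraction otherwise (default GC 0.38, overridable from the
annotation). The 96-channel spectrum is pyrimidine-centred, divided by
the strand-collapsed genomic trinucleotide frequencies and renormalised
to sum 1; similarity to reference signature matrices (COSMIC layout,
channel-major TSV) is plain cosine.

**Localisation tests** are exact two-sided binomial tests. Two-sided is
implemented as *twice the smaller exact tail, capped at 1* — the
minimum-likelihood convention of `binom.test` is available behind
`method = "minlike"` — because the source says only "two-sided" and the
doubled-tail version is the one an enumeration oracle pins down
trivially. The duplicated-chromosome null probability defaults to
$L_{dup}/\sum L$ over single-copy lengths; counting the duplicated
chromosome twice (it is, after all, twice the target) is available via
`count_dup_twice = TRUE` and changes results, so the flag state is part
of the output. p-values are BH-adjusted across strains.

# Expression: normalisation and the shift statistic

Genes are kept when CPM ≥ 1 in at least half the samples (inclusive,
`ceiling(0.5 n)`). RLE normalisation excludes genes with any zero count
from factor estimation, takes each sample's median log-ratio to the
per-gene geometric means, and **rescales the factors to geometric mean
1**. The rescale is a deliberate deviation from raw median-of-ratios:
size factors are only identified up to a global constant, and with the
geometric-mean-1 convention the estimator is cleanly equivariant —
multiplying one sample by $\lambda$ multiplies its factor by $\lambda$
*relative to every other sample* (the absolute factor moves by
$\lambda^{1-1/n}$ because the reference itself drifts; the identity that
does hold exactly is tested). Adding a single gene moves a finite median
by $O(1/\text{genes})$, so the "constant gene changes nothing" intuition
is exact only in the continuous limit; the test uses 2000 genes and a
5e-3 tolerance. Normalised expression is $\log_2(c/\hat s_j + 1)$; the
pseudocount of 1 (applied after size-factor division) is the
conventional guard for zero counts and slightly compresses
low-expression fold changes.

The **shift towards WT** of an evolved line $e$ with ancestor $a$ is
computed on the gene set $G$ where the ancestor/WT ratio is ≥ 1.5 or ≤
1/1.5 (two-sided on the linear ratio, equivalent to
$|\log_2 FC| \ge \log_2 1.5$):

$$D = \sqrt{\sum_{g \in G} (\log x_g - \log x^{WT}_g)^2}, \qquad
\text{shift} = 1 - D_e / D_a.$$

The statistic is invariant to the logarithm base (both distances scale
together) and linear in deviation scaling: if every ancestral deviation
is shrunk by a factor $c$, the shift is exactly $1-c$. Both are asserted
numerically. An empty $G$ yields a flagged undefined result rather than
an error. The distance is computed on whatever normalised matrix the
pipeline produced (post-filter, post-RLE); the source does not say which
stage fed its metric.

**Gene-wise models.** Common differential expression regresses
normalised log2 expression on an evolved indicator with a strain
covariate block, so the contrast is within-strain (a pooled mode is
available with `strain_covariate = FALSE`; the source wording "a single
statistical model" permits either, and both are exposed because its "274
genes" cannot be reproduced without the original data). Shift
association regresses evolved-line expression on the numeric shift.
Both use ordinary least squares with two-sided t tests — not the
empirical-Bayes moderation of the original tool chain, which is a tool
choice rather than a described computation — and BH at FDR 0.1. Genes
with undefined tests (constant across samples) are dropped from the BH
family rather than set to p = 1; genes that fit perfectly (zero residual
with nonzero effect) get the machine-limited p of 0. Enrichment of a
selected set against a universe is the one-sided hypergeometric upper
tail, BH-adjusted across sets.

# Growth curves

The spline is fitted to $\log_2(\mathrm{OD}_{600})$ — not raw OD — so its
maximal derivative *is* the maximal specific growth rate in doublings
per minute and the estimate is invariant to vertical scaling; the
doubling time is the reciprocal. Smoothing is chosen by generalised
cross-validation unless `smoothing` (a `spar` value) is given. The first
30 minutes are discarded by default as instrument equilibration
(toggleable). Curves with max/min OD < 2 are rejected as "insufficient
dynamic range" rather than returning a meaningless number. The relative
change between ancestor and evolved is $100(t_a - t_e)/t_a$, positive
when the evolved line is faster.

# The synthetic world

The generator's defaults *are* the study design: 16 yeast-like
chromosomes (~12.07 Mb), 74% coding, 38% GC; 12 disomic strains plus a
euploid WT, 3 evolved lines each, 1200 generations; per-line
substitution and indel counts Poisson with means 7.9 and 3.75; coverage
of 50 reads per 100-bp window per copy; a 1.8-fold expression dosage
factor. Values the study does not pin down were chosen once:

* `dup_bias = 6` — the per-bp mutation probability multiplier on the
  duplicated chromosome. Calibrated from the observed localisation
  (~28% of mutations on chromosomes comprising ~6% of the genome solves
  to a bias of ≈ 6).
* `karyotype_event_probs = (0.0625, 0.25, 0.15)` for whole loss /
  partial loss / segmental amplification — roughly the observed 10/32
  lines with events. Events are drawn per line, mutually exclusively;
  breakpoints fall only on *repeat loci*, placed near-evenly in the
  interior 10–90% of each chromosome so that simulated events always
  span a detectable chromosome fraction (subtelomeric micro-events
  would be invisible to a 95% length rule by construction and would
  test nothing).
* `attenuation ~ U(0.1, 0.7)` per line; every evolved log-deviation from
  WT is scaled by $1-a$, except where the line's own copy number changed
  (lost segments return to baseline, new amplifications gain the dosage
  factor). This makes the generative world exactly linear in the sense
  the shift statistic measures, so shift ≈ attenuation up to counting
  noise.
* `nb_dispersion = 0.05` for coverage and `expr_dispersion = 0.01` for
  expression counts (negative binomial; the Poisson limit at 0). The
  expression value is the low biological noise expected when whole
  well-mixed populations are sequenced in a single batch, and it is the
  regime in which the shift statistic recovers attenuation *ranks* at
  Spearman ≥ 0.9 — a property the package treats as part of the stated
  world; at dispersions several-fold higher, strain-dependent noise
  inflation of $D_e/D_a$ degrades cross-strain rank agreement.
* `af_sd = 0.02` — the spread of a fixed variant's observed alt-read
  fraction around its copy-number expectation (0.5 on CN-2, 1.0 on
  CN-1). A fixed clone's population allele frequency is essentially
  exact; the residual spread stands in for mapping noise and is chosen
  so that callable variants at depth ≥ 30 pass the 0.40/0.80 filters
  with overwhelming probability, making any catalogue error
  attributable to the intersection/subtraction logic under test.
* Growth: WT ancestor doubling 90 min; disome ancestors 1.2–1.9× WT;
  evolved improvements 8% (WT) and 16–64% (disomes); logistic curves at
  15-min sampling with 1% multiplicative noise.

What the generator does **not** emulate: read-level data (no FASTQ, no
mapping artefacts), sequence-resolved indels, selection dynamics within
populations, mutator phenotypes, co-occurring karyotype events in one
line, and trans effects of karyotype change on other chromosomes'
expression. A green recovery test therefore establishes that the
pipeline inverts this generative model — not that it is robust to
alignment artefacts or demographic complications the model omits.

# Degenerate inputs and tie-breaks

* Segmentation refuses chromosomes with fewer than 2 windows and
  penalties ≤ 0; constant tracks return one segment.
* `filter_denovo` on an empty consensus returns an empty, fully typed
  catalogue.
* Genes whose CDS length is not a multiple of 3 mark their mutations
  `unannotatable` instead of guessing a frame.
* Promoter ties (exact equidistance) go to the smaller TSS coordinate,
  then gene id.
* `binom_test_twosided` requires $p_0$ strictly inside (0,1);
  doubled-tail p-values are capped at 1.
* An all-zero coverage sample, mismatched window grids, or a wild type
  with > 1% zero-coverage windows are rejected with explicit messages.
* The CLI distinguishes configuration errors (exit 2), missing inputs
  (exit 3) and computation failures (exit 4).

# Known limitations

* The karyotype caller targets the CN 1-vs-2 regime of the disome
  design; higher amplifications are all called "2".
* Rate estimates inherit the fixed-$g$ assumption; per-strain generation
  counts, if known, can be passed per call.
* OLS gene-wise tests are less powerful than moderated alternatives at
  very small replicate numbers; the acceptance property tested is FDR
  control under the global null and power at the study's sample sizes,
  not optimality.
* The printed per-strain binomial p-values and the exact 22/32, 274-gene
  and 359-gene results of the original study require its deposited
  sequencing data and are out of scope; the property and recovery suites
  stand in for them.
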