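#' Packaged per-strain mutation count fixture
#'
#' Per-strain mutation totals of the evolution experiment: duplicated
#' chromosome length (kb), number of evolved lines analysed, total
#' mutations, mutations on the duplicated chromosome, substitutions and
#' indels split by coding/noncoding, and the missense/nonsense/silent
#' breakdown of coding substitutions.  The coding/noncoding split is the
#' unique reconstruction consistent with all row and column totals (253
#' disomic substitutions, 120 disomic indels, per-strain totals); see
#' [validate_table1()].
#'
#' @return data.frame, one row per strain (WT plus 12 disomes).
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_mutations.tsv", package = "aneuvol")
  d <- read.delim(path)
  validate_table1(d)
  d
}

#' Check the internal consistency of the mutation count fixture
#'
#' Asserts all marginal totals: per strain, substitutions + indels equal
#' the total mutation count and the effect classes sum to the coding
#' substitutions; across disomes, substitutions sum to 253, indels to
#' 120, and evolved lines to 32.
#'
#' @param d a [table1_fixture()]-shaped data.frame.
#' @return invisibly, `d` (errors if a constraint is violated).
#' @export
validate_table1 <- function(d) {
  subs <- d$sub_coding + d$sub_noncoding
  inds <- d$indel_coding + d$indel_noncoding
  assert_that(all(subs + inds == d$total_mutations),
              "per-strain substitutions + indels != total mutations")
  assert_that(all(d$missense + d$nonsense + d$silent == d$sub_coding),
              "effect classes do not sum to coding substitutions")
  dis <- d$strain != "WT"
  assert_that(sum(subs[dis]) == 253, "disomic substitutions must total 253")
  assert_that(sum(inds[dis]) == 120, "disomic indels must total 120")
  assert_that(sum(d$lines[dis]) == 32, "evolved disomic lines must total 32")
  invisible(d)
}

#' Summary report over the mutation count fixture
#'
#' Recomputes, from the per-strain counts, the per-line means (overall
#' disomic, per strain, and wild type) and the apparent mutation rates
#' via [apparent_rate()], reporting both full precision values and the
#' conventional roundings (rates to one decimal on the 1e-10 scale,
#' means to one or two decimals).
#'
#' @param fixture a [table1_fixture()]-shaped data.frame.
#' @param n genome size in bp (default 1.212e7).
#' @param g generations (default 1200).
#' @return list with `per_strain` (data.frame of per-line means and
#'   rates), `overall` (disomic means, rate mean/min/max, WT values) and
#'   the `n`, `g` assumptions.
#' @export
summarize_table1 <- function(fixture = table1_fixture(), n = 1.212e7,
                             g = 1200) {
  validate_table1(fixture)
  d <- fixture
  subs <- d$sub_coding + d$sub_noncoding
  inds <- d$indel_coding + d$indel_noncoding
  per_strain <- data.frame(
    strain = d$strain,
    lines = d$lines,
    sub_per_line = subs / d$lines,
    indel_per_line = inds / d$lines,
    mut_per_line = d$total_mutations / d$lines)
  rate <- apparent_rate(per_strain$mut_per_line, n, g)
  per_strain$rate <- rate$u
  per_strain$rate_se <- rate$se
  per_strain$rate_1e10 <- round(rate$u * 1e10, 1)
  dis <- d$strain != "WT"
  overall <- list(
    disome_sub_per_line = sum(subs[dis]) / sum(d$lines[dis]),
    disome_indel_per_line = sum(inds[dis]) / sum(d$lines[dis]),
    wt_mut_per_line = d$total_mutations[!dis] / d$lines[!dis],
    wt_rate = per_strain$rate[!dis],
    disome_rate_mean = mean(per_strain$rate[dis]),
    disome_rate_min = min(per_strain$rate[dis]),
    disome_rate_min_strain = per_strain$strain[dis][which.min(per_strain$rate[dis])],
    disome_rate_max = max(per_strain$rate[dis]),
    disome_rate_max_strain = per_strain$strain[dis][which.max(per_strain$rate[dis])])
  list(per_strain = per_strain, overall = overall, n = n, g = g)
}
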