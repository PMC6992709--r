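#' Normalize variant representation for matching
#'
#' Puts each record into a canonical parsimonious form before keys are
#' compared: shared trailing bases of ref/alt are trimmed, then shared
#' leading bases (advancing the position), always keeping at least one
#' base on each allele.  This reconciles the indel dialects of different
#' callers before intersection.
#'
#' @param v variant observation data.frame (`chrom`, `pos`, `ref`,
#'   `alt`, ...).
#' @return the same data.frame with normalized `pos`, `ref`, `alt`.
#' @export
normalize_variants <- function(v) {
  if (!nrow(v)) return(v)
  for (i in seq_len(nrow(v))) {
    r <- strsplit(v$ref[i], "")[[1]]
    a <- strsplit(v$alt[i], "")[[1]]
    while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]; a <- a[-length(a)]
    }
    pos <- v$pos[i]
    while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
      r <- r[-1]; a <- a[-1]; pos <- pos + 1L
    }
    v$ref[i] <- paste(r, collapse = ""); v$alt[i] <- paste(a, collapse = "")
    v$pos[i] <- pos
  }
  v
}

variant_key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")

#' Intersect two caller call sets
#'
#' Variants are keyed by (chromosome, position, ref, alt) after
#' [normalize_variants()]; the consensus consists of the keys present in
#' both call sets and carries the read counts of the first caller.
#'
#' @param calls_a,calls_b variant observation data.frames from the same
#'   sample.  Duplicate keys within one set are rejected.
#' @return the consensus subset of `calls_a`.
#' @export
intersect_callers <- function(calls_a, calls_b) {
  a <- normalize_variants(calls_a)
  b <- normalize_variants(calls_b)
  ka <- variant_key(a); kb <- variant_key(b)
  assert_that(!anyDuplicated(ka) && !anyDuplicated(kb),
              "duplicate variant keys within one call set")
  out <- a[ka %in% kb, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter consensus variants to the de novo mutation catalogue
#'
#' Keeps a variant iff (i) its total read count is at least `min_reads`,
#' (ii) its alt-read fraction is at least `af_dup` when the site lies on
#' a copy-number-2 region of the line's own karyotype and at least
#' `af_other` otherwise, and (iii) its key is absent from the ancestor
#' call set (variants shared with the ancestor predate the evolution
#' experiment).
#'
#' @param consensus consensus variants from [intersect_callers()].
#' @param ancestor_variants ancestor call set (any caller; keys only).
#' @param karyotype the line's [call_karyotype()] result (or a truth-style
#'   segment data.frame `chrom`/`start`/`end`/`cn` with 1-based closed
#'   coordinates).
#' @param min_reads minimum total reads (default 5).
#' @param af_dup,af_other alt-fraction thresholds on duplicated
#'   (copy-number 2) and single-copy regions (defaults 0.40 / 0.80).
#' @return mutation data.frame: the retained variants with `on_dup`
#'   (copy number 2 at the site) and placeholder annotation columns.
#' @export
filter_denovo <- function(consensus, ancestor_variants, karyotype,
                          min_reads = 5, af_dup = 0.40, af_other = 0.80) {
  assert_that(is_fraction(af_dup) && is_fraction(af_other),
              "allele-fraction thresholds must lie in [0,1]")
  assert_that(min_reads >= 0, "min_reads must be non-negative")
  v <- normalize_variants(consensus)
  anc_keys <- variant_key(normalize_variants(ancestor_variants))
  seg <- karyotype_segments_1based(karyotype)
  cn <- cn_at(seg, v$chrom, v$pos)
  af <- ifelse(v$dp > 0, v$ad / v$dp, 0)
  thr <- ifelse(cn >= 2, af_dup, af_other)
  keep <- v$dp >= min_reads & af >= thr & !(variant_key(v) %in% anc_keys)
  out <- v[keep, , drop = FALSE]
  nr <- nrow(out)
  out$on_dup <- cn[keep] >= 2
  out$region <- rep(NA_character_, nr)
  out$effect <- rep(NA_character_, nr)
  out$coding_indel <- rep(FALSE, nr)
  out$gene_id <- rep(NA_character_, nr)
  out$promoter_gene <- rep(NA_character_, nr)
  rownames(out) <- NULL
  out
}

karyotype_segments_1based <- function(karyotype) {
  if (inherits(karyotype, "karyotype_call")) {
    s <- karyotype$segments
    data.frame(chrom = s$chrom, start = s$start + 1L, end = s$end, cn = s$cn)
  } else {
    assert_that(all(c("chrom", "start", "end", "cn") %in% names(karyotype)),
                "karyotype must be a karyotype_call or a segment table")
    karyotype
  }
}

#' Annotate coding effects of catalogued mutations
#'
#' Substitutions inside a CDS are translated with the standard codon
#' table: stop gain is `nonsense`, an amino-acid change `missense`, a
#' synonymous change `silent`.  Positions outside any CDS are
#' `noncoding`.  Indels inside a CDS keep region `coding` with the side
#' flag `coding_indel` set (they are excluded from the three
#' substitution effect classes).  Genes whose CDS length is not a
#' multiple of 3 cannot be annotated; their mutations are flagged
#' `unannotatable`.
#'
#' @param mutations mutation data.frame from [filter_denovo()] (or any
#'   frame with `chrom`, `pos`, `ref`, `alt`, `type`).
#' @param genome a [make_genome()] annotation with sequence.
#' @return the input with `region`, `effect`, `coding_indel`, `gene_id`
#'   and `unannotatable` filled in.
#' @export
annotate_effect <- function(mutations, genome) {
  assert_that(!is.null(genome$sequences),
              "genome sequence required for effect annotation")
  m <- mutations
  m$region <- region_at(genome$genes, m$chrom, m$pos)
  m$effect <- ifelse(m$region == "noncoding", "noncoding", NA_character_)
  m$coding_indel <- m$region == "coding" & m$type != "substitution"
  m$gene_id <- NA_character_
  m$unannotatable <- FALSE
  coding <- which(m$region == "coding")
  for (i in coding) {
    g <- genome$genes[genome$genes$chrom == m$chrom[i] &
                        genome$genes$start <= m$pos[i] &
                        genome$genes$end >= m$pos[i], ][1, ]
    m$gene_id[i] <- g$gene_id
    if (m$type[i] != "substitution") next
    cds_len <- g$end - g$start + 1
    if (cds_len %% 3 != 0) { m$unannotatable[i] <- TRUE; next }
    m$effect[i] <- substitution_effect(genome, g, m$pos[i], m$alt[i])
  }
  m
}

substitution_effect <- function(genome, gene, pos, alt) {
  cds_pos <- if (gene$strand == "+") pos - gene$start + 1 else gene$end - pos + 1
  codon_i <- ceiling(cds_pos / 3)
  offset <- cds_pos - (codon_i - 1) * 3       # 1..3 within codon
  if (gene$strand == "+") {
    c_start <- gene$start + (codon_i - 1) * 3
    codon <- fetch_seq(genome, gene$chrom, c_start, c_start + 2)
    mut <- codon
    substr(mut, offset, offset) <- alt
  } else {
    c_end <- gene$end - (codon_i - 1) * 3
    fwd <- fetch_seq(genome, gene$chrom, c_end - 2, c_end)
    mut_fwd <- fwd
    substr(mut_fwd, 4 - offset, 4 - offset) <- alt
    codon <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
    mut <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(mut_fwd)))
  }
  aa_ref <- as.character(Biostrings::translate(Biostrings::DNAString(codon),
                                               no.init.codon = TRUE))
  aa_alt <- as.character(Biostrings::translate(Biostrings::DNAString(mut),
                                               no.init.codon = TRUE))
  if (aa_ref == aa_alt) "silent"
  else if (aa_alt == "*") "nonsense"
  else "missense"                             # includes rare stop-loss
}

#' Assign noncoding mutations to gene promoters
#'
#' A noncoding mutation is attributed to the gene with the nearest
#' transcription start site, provided the distance is at most
#' `max_dist` bp and (by default) the variant lies upstream of that TSS
#' on the gene's strand.  Ties in distance go to the gene with the
#' smaller TSS chromosome coordinate.
#'
#' @param mutations annotated mutation data.frame.
#' @param genome a [make_genome()] annotation.
#' @param max_dist maximum TSS distance in bp (default 750, the average
#'   yeast promoter length).
#' @param require_upstream demand that the variant is on the upstream
#'   side of the TSS (default TRUE; set FALSE for plain nearest-TSS
#'   assignment).
#' @return the input with `promoter_gene` and `promoter_dist` filled in
#'   for assignable noncoding mutations.
#' @export
assign_promoter <- function(mutations, genome, max_dist = 750,
                            require_upstream = TRUE) {
  m <- mutations
  m$promoter_gene <- NA_character_
  m$promoter_dist <- NA_real_
  genes <- genome$genes
  if (!nrow(genes)) return(m)
  for (i in which(m$region == "noncoding")) {
    g <- genes[genes$chrom == m$chrom[i], , drop = FALSE]
    if (!nrow(g)) next
    if (require_upstream) {
      ok <- ifelse(g$strand == "+", m$pos[i] < g$tss, m$pos[i] > g$tss)
      g <- g[ok, , drop = FALSE]
      if (!nrow(g)) next
    }
    d <- abs(g$tss - m$pos[i])
    cand <- which(d <= max_dist)
    if (!length(cand)) next
    cand <- cand[order(d[cand], g$tss[cand], g$gene_id[cand])]
    m$promoter_gene[i] <- g$gene_id[cand[1]]
    m$promoter_dist[i] <- d[cand[1]]
  }
  m
}
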