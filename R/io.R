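#' Read and write bedGraph coverage tracks
#'
#' Four-column bedGraph (chrom, start, end, count; 0-based half-open),
#' with an optional `track` header line which is ignored on read.
#'
#' @param profile a [coverage_profile()].
#' @param path file path.
#' @return `read_bedgraph` returns a `coverage_profile`.
#' @export
write_bedgraph <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=%s", profile$sample_id), con)
  write.table(profile$windows[, c("chrom", "start", "end", "count")], con,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @param sample_id sample identifier to attach on read.
#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path, sample_id = basename(path)) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "track") & nzchar(lines)]
  d <- read.delim(text = lines, header = FALSE,
                  col.names = c("chrom", "start", "end", "count"))
  coverage_profile(sample_id, d)
}

#' Write copy-number segments as BED
#'
#' BED5 with the called copy number in the score column.
#'
#' @param segments segment table from [segment_ratio()].
#' @param path file path.
#' @export
write_segments_bed <- function(segments, path) {
  bed <- data.frame(chrom = segments$chrom, start = segments$start,
                    end = segments$end,
                    name = sprintf("CN%d", segments$cn),
                    score = segments$cn)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read and write minimal VCF call sets
#'
#' The dialect used throughout the package: VCFv4.2 header, columns
#' CHROM POS ID REF ALT QUAL FILTER INFO, 1-based positions, read
#' support in the INFO fields `DP` (total reads) and `AD` (alt reads).
#' Catalogue annotations, when present, are carried as INFO tags
#' `TYPE`, `REGION`, `EFFECT`, `PROMOTER_GENE` and `ON_DUP`.
#'
#' @param v variant observation or mutation data.frame.
#' @param path file path.
#' @param sample_id sample id recorded in the header / attached on read.
#' @return `read_minimal_vcf` returns a variant data.frame with columns
#'   `sample_id`, `chrom`, `pos`, `ref`, `alt`, `type`, `dp`, `ad` plus
#'   any annotation tags found.
#' @export
write_minimal_vcf <- function(v, path, sample_id = v$sample_id[1] %||% "NA") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##sample=%s", sample_id),
               "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
               "##INFO=<ID=AD,Number=1,Type=Integer,Description=\"Alt read depth\">",
               "##INFO=<ID=TYPE,Number=1,Type=String,Description=\"Variant type\">",
               "##INFO=<ID=REGION,Number=1,Type=String,Description=\"coding|noncoding\">",
               "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Coding effect\">",
               "##INFO=<ID=PROMOTER_GENE,Number=1,Type=String,Description=\"Promoter assignment\">",
               "##INFO=<ID=ON_DUP,Number=0,Type=Flag,Description=\"On duplicated chromosome\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO"), collapse = "\t")), con)
  if (nrow(v)) {
    info <- sprintf("DP=%d;AD=%d;TYPE=%s", v$dp %||% 0L, v$ad %||% 0L, v$type)
    if (!is.null(v$region))
      info <- paste0(info, ifelse(is.na(v$region), "",
                                  paste0(";REGION=", v$region)))
    if (!is.null(v$effect))
      info <- paste0(info, ifelse(is.na(v$effect), "",
                                  paste0(";EFFECT=", v$effect)))
    if (!is.null(v$promoter_gene))
      info <- paste0(info, ifelse(is.na(v$promoter_gene), "",
                                  paste0(";PROMOTER_GENE=", v$promoter_gene)))
    if (!is.null(v$on_dup))
      info <- paste0(info, ifelse(v$on_dup %in% TRUE, ";ON_DUP", ""))
    rec <- data.frame(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", info)
    write.table(rec, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_minimal_vcf
#' @export
read_minimal_vcf <- function(path, sample_id = NULL) {
  lines <- readLines(path)
  if (is.null(sample_id)) {
    s <- grep("^##sample=", lines, value = TRUE)
    sample_id <- if (length(s)) sub("^##sample=", "", s[1]) else basename(path)
  }
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(body)) {
    return(data.frame(sample_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      type = character(), dp = integer(), ad = integer()))
  }
  d <- read.delim(text = body, header = FALSE,
                  col.names = c("chrom", "pos", "id", "ref", "alt", "qual",
                                "filter", "info"))
  tag <- function(info, key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
    out <- rep(NA_character_, length(info))
    hit <- regexpr(paste0("(^|;)", key, "=[^;]*"), info) > 0
    out[hit] <- sub(paste0("^;?", key, "="), "", m)
    out
  }
  out <- data.frame(sample_id = sample_id, chrom = d$chrom, pos = d$pos,
                    ref = d$ref, alt = d$alt,
                    type = tag(d$info, "TYPE"),
                    dp = as.integer(tag(d$info, "DP")),
                    ad = as.integer(tag(d$info, "AD")))
  reg <- tag(d$info, "REGION")
  if (any(!is.na(reg))) {
    out$region <- reg
    out$effect <- tag(d$info, "EFFECT")
    out$promoter_gene <- tag(d$info, "PROMOTER_GENE")
    out$on_dup <- grepl("(^|;)ON_DUP(;|$)", d$info)
  }
  out
}

#' Write the genome annotation as GFF3 plus a chromosome-sizes TSV
#'
#' @param genome a [make_genome()] annotation.
#' @param gff_path GFF3 output path.
#' @param sizes_path optional chromosome-sizes TSV path (chrom, length).
#' @export
write_genome_gff3 <- function(genome, gff_path, sizes_path = NULL) {
  con <- file(gff_path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (ch in names(genome$chrom_lengths))
    writeLines(sprintf("##sequence-region %s 1 %d", ch,
                       genome$chrom_lengths[[ch]]), con)
  g <- genome$genes
  if (nrow(g)) {
    rec <- data.frame(g$chrom, "aneuvol", "CDS", g$start, g$end, ".",
                      g$strand, "0", sprintf("ID=%s", g$gene_id))
    write.table(rec, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  if (!is.null(sizes_path))
    write.table(data.frame(chrom = names(genome$chrom_lengths),
                           length = unname(genome$chrom_lengths)),
                sizes_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(gff_path)
}

#' Read and write expression count matrices as TSV
#'
#' Genes in rows (first column `gene_id`), one column per sample.
#'
#' @param x an [expression_matrix()]; `path` file path.
#' @param meta optional metadata data.frame for reading (defaults to
#'   bare sample ids).
#' @return `read_expression_tsv` returns an `expression_matrix`.
#' @export
write_expression_tsv <- function(x, path) {
  d <- data.frame(gene_id = rownames(x$counts), x$counts,
                  check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path, meta = NULL) {
  d <- read.delim(path, check.names = FALSE)
  counts <- as.matrix(d[, -1, drop = FALSE])
  rownames(counts) <- d[[1]]
  if (is.null(meta))
    meta <- data.frame(sample_id = colnames(counts), strain = NA_character_,
                       role = NA_character_, disome_chrom = NA_character_)
  expression_matrix(counts, meta)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes,
#' tab-separated.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(strsplit(lines, "\t"), function(f) f[-(1:2)])
  names(out) <- vapply(strsplit(lines, "\t"), `[`, character(1), 1)
  out
}

#' Write the simulation ground truth as JSON
#'
#' @param truth an [simulate_lineages()] object.
#' @param path output path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(list(
    samples = truth$samples, karyotypes = truth$karyotypes,
    events = truth$events, mutations = truth$mutations,
    expression = truth$expression, growth = truth$growth),
    path, dataframe = "rows", na = "null", digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read plate-reader growth curves from long-format TSV
#'
#' Expects columns `sample_id` (or `well`), `replicate` (optional),
#' `time_min`, `od`.
#'
#' @param path TSV file path.
#' @return data.frame suitable for [doubling_time_table()].
#' @export
read_growth_tsv <- function(path) {
  d <- read.delim(path)
  if (is.null(d$sample_id) && !is.null(d$well)) d$sample_id <- d$well
  if (is.null(d$replicate)) d$replicate <- 1L
  assert_that(all(c("sample_id", "time_min", "od") %in% names(d)),
              "growth TSV needs sample_id/well, time_min, od columns")
  d[, c("sample_id", "replicate", "time_min", "od")]
}
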