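# File interchange: FASTA via Biostrings, BED (0-based half-open), the TSV
# schemas shared by the analysis stages, a GEO series-matrix reader, and
# bundle materialisation.

#' Read / write FASTA
#'
#' Thin wrappers over Biostrings keeping the package's plain-character
#' sequence convention.
#'
#' @param path file path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path, width = 80L)
  invisible(path)
}

#' Read / write BED intervals
#'
#' Three-plus-column BED (chrom, start, end, optional name), tab-separated,
#' 0-based half-open -- the same convention as [genomic_interval()].
#'
#' @param path file path.
#' @return `read_bed`: data.frame `chrom`, `start`, `end` (and `name` when
#'   present).
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  names(df) <- c("chrom", "start", "end", "name")[seq_len(ncol(df))]
  df
}

#' @rdname read_bed
#' @param df data.frame with columns `chrom`, `start`, `end` and optionally
#'   `name`.
#' @export
write_bed <- function(df, path) {
  cols <- intersect(c("chrom", "start", "end", "name"), names(df))
  utils::write.table(df[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write the package's TSV tables
#'
#' All stage tables (Ct tables, trace tables, group files, probe annotation,
#' ground truth) are headered, tab-separated text.
#'
#' @param path file path.
#' @return `read_tsv`: data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_tsv
#' @param df data.frame.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe-by-sample matrix TSV
#'
#' First column holds the probe/feature ids, remaining columns one sample
#' each (the Beta-matrix and expression-matrix layout).
#'
#' @param path file path.
#' @return numeric matrix with probe rownames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' @rdname read_matrix_tsv
#' @param mat matrix with rownames.
#' @param id_col name of the first (id) column (default `"probe"`).
#' @export
write_matrix_tsv <- function(mat, path, id_col = "probe") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   row.names = NULL)
  names(df)[1] <- id_col
  write_tsv(df, path)
}

#' Read a GEO series-matrix flavoured TSV
#'
#' Series-matrix files wrap a probe-by-sample value table in `!`-prefixed
#' metadata lines (and delimit it with `!series_matrix_table_begin`/`_end`).
#' This reader skips the metadata and returns the numeric matrix; sample ids
#' are taken from the table's header row. Values are tab-separated and may
#' be quoted.
#'
#' @param path file path.
#' @return numeric matrix, probe ids as rownames, sample ids as colnames.
#' @export
read_series_matrix <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "!") & nzchar(lines)
  if (!any(keep)) stop("no data lines found in series matrix ", path)
  con <- textConnection(lines[keep])
  on.exit(close(con))
  df <- utils::read.table(con, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "\"")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Materialise a cohort bundle on disk
#'
#' Writes every table of a [simulate_cohort()] bundle in the package's
#' external formats: `locus.fa`, `cgi.bed`, `cpg_sites.bed`, `beta.tsv`,
#' `probe_annotation.tsv`, `expression.tsv`, `groups.tsv`,
#' `ct_expression.tsv`, `ct_qmsp.tsv`, `traces/<sample>.tsv` and
#' `ground_truth.tsv`.
#'
#' @param bundle a `"cohort_bundle"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write_fasta(c(locus = bundle$locus$seq), p("locus.fa"))
  cgi <- bundle$locus$cgi
  write_bed(data.frame(chrom = cgi$chrom, start = cgi$start, end = cgi$end,
                       name = "CpGsim"), p("cgi.bed"))
  sites <- sort(c(bundle$locus$cpg_sites_cgi, bundle$locus$cpg_sites_flank))
  write_bed(data.frame(chrom = cgi$chrom, start = sites, end = sites + 2L),
            p("cpg_sites.bed"))
  write_matrix_tsv(bundle$beta, p("beta.tsv"))
  write_tsv(bundle$annotation, p("probe_annotation.tsv"))
  write_matrix_tsv(bundle$expr, p("expression.tsv"), id_col = "feature")
  write_tsv(bundle$groups, p("groups.tsv"))
  write_tsv(bundle$ct_expression, p("ct_expression.tsv"))
  write_tsv(bundle$ct_qmsp, p("ct_qmsp.tsv"))
  dir.create(p("traces"), showWarnings = FALSE)
  for (s in names(bundle$traces))
    write_tsv(bundle$traces[[s]], p("traces", paste0(s, ".tsv")))
  gt <- bundle$ground_truth
  write_tsv(gt, p("ground_truth.tsv"))
  invisible(dir)
}
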