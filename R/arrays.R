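# Methylation-array Beta processing, miRNA-array normalisation, locus
# profiling and methylation-expression integration.
#
# A Beta matrix is a plain numeric matrix, probes in rows (rownames = probe
# ids), samples in columns; probe annotation travels alongside as a
# data.frame with columns probe, chrom, start, end, cgi (0-based half-open,
# cgi = "" outside islands), as in the limma tradition of matrix + side
# tables. Beta is defined as the plain ratio M/(M+U); no vendor background
# offset is applied.

#' Beta value from methylated/unmethylated signal intensities
#'
#' `M / (M + U)`, the average ratio of methylated-probe signal to total
#' signal. Probes where both channels are zero are undefined and become
#' missing values, never 0.
#'
#' @param m_signal,u_signal non-negative intensities; vectorised.
#' @return Beta value(s) in \[0, 1\], `NA` where both signals are zero.
#' @examples
#' beta_from_signals(300, 100)  # 0.75
#' @export
beta_from_signals <- function(m_signal, u_signal) {
  if (any(m_signal < 0 | u_signal < 0, na.rm = TRUE))
    stop("signals must be non-negative")
  tot <- m_signal + u_signal
  ifelse(tot > 0, m_signal / tot, NA_real_)
}

#' Quantile normalisation of an expression matrix
#'
#' Forces every column (sample) onto the same empirical distribution: each
#' value is replaced by the mean, across columns, of the values sharing its
#' within-column rank. Afterwards all column sorted value multisets are
#' identical and the grand mean is preserved. Rows containing missing values
#' are dropped with a message; a single-column matrix is returned unchanged
#' with a warning. Tied values receive the average of the tied reference
#' quantiles.
#'
#' @param mat numeric matrix, features in rows, samples in columns.
#' @return normalised matrix of the retained rows.
#' @examples
#' quantile_normalize(cbind(a = c(1, 2, 3), b = c(4, 5, 6)))
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) {
    warning("single-column matrix: quantile normalisation is the identity")
    return(mat)
  }
  keep <- stats::complete.cases(mat)
  if (any(!keep)) {
    message("dropping ", sum(!keep), " row(s) with missing values")
    mat <- mat[keep, , drop = FALSE]
  }
  ref <- rowMeans(apply(mat, 2L, sort))
  out <- apply(mat, 2L, function(x) {
    r <- rank(x, ties.method = "average")
    (ref[floor(r)] + ref[ceiling(r)]) / 2
  })
  dimnames(out) <- dimnames(mat)
  out
}

#' Mean Beta difference between two sample groups at one probe
#'
#' `mean(Beta, group_a) - mean(Beta, group_b)`; missing Betas are excluded
#' from the means.
#'
#' @param betas Beta matrix (probes x samples).
#' @param group_a,group_b character vectors of column (sample) names; both
#'   must have at least one non-missing Beta at the probe.
#' @param probe probe id (row name).
#' @return the DeltaBeta, in \[-1, 1\].
#' @examples
#' b <- rbind(cg1 = c(s1 = 0.8, s2 = 0.6, s3 = 0.3, s4 = 0.3))
#' delta_beta(b, c("s1", "s2"), c("s3", "s4"), "cg1")  # 0.4
#' @export
delta_beta <- function(betas, group_a, group_b, probe) {
  if (!probe %in% rownames(betas))
    stop("probe '", probe, "' not found in Beta matrix")
  miss <- setdiff(c(group_a, group_b), colnames(betas))
  if (length(miss))
    stop("sample(s) not in Beta matrix: ", paste(miss, collapse = ", "))
  a <- betas[probe, group_a]; b <- betas[probe, group_b]
  if (all(is.na(a)) || all(is.na(b)))
    stop("all Betas missing for one group at probe ", probe)
  mean(a, na.rm = TRUE) - mean(b, na.rm = TRUE)
}

#' Three-class methylation call from a Beta value
#'
#' Beta below 0.3 is unmethylated, 0.3 up to (but excluding) 0.7 partially
#' methylated, 0.7 and above methylated; the shared 0.7 boundary is assigned
#' to the methylated class, mirroring the strict `< 0.3` lower bound.
#'
#' @param beta numeric vector in \[0, 1\].
#' @return character vector in `c("unmethylated", "partial", "methylated")`.
#' @export
classify_beta <- function(beta) {
  if (any(!is.finite(beta)) || any(beta < 0 | beta > 1))
    stop("Beta must lie in [0, 1]")
  ifelse(beta < 0.3, "unmethylated",
         ifelse(beta < 0.7, "partial", "methylated"))
}

#' Dichotomise samples by one probe's Beta
#'
#' Splits samples into methylated (`Beta >= cut`) and unmethylated groups at
#' a chosen probe, the device used to contrast expression between patient
#' methylation classes. Samples with a missing Beta are excluded with a
#' message.
#'
#' @param betas Beta matrix.
#' @param probe probe id.
#' @param cut Beta cut-point in (0, 1); default 0.3, the unmethylated-class
#'   boundary.
#' @return list with character vectors `methylated`, `unmethylated`,
#'   `excluded`.
#' @export
dichotomize_by_probe <- function(betas, probe, cut = 0.3) {
  if (!probe %in% rownames(betas))
    stop("probe '", probe, "' not found in Beta matrix")
  stopifnot(cut > 0, cut < 1)
  b <- betas[probe, ]
  excl <- colnames(betas)[is.na(b)]
  if (length(excl))
    message("excluding sample(s) with missing Beta: ",
            paste(excl, collapse = ", "))
  ok <- !is.na(b)
  res <- list(methylated = colnames(betas)[ok & b >= cut],
              unmethylated = colnames(betas)[ok & b < cut],
              excluded = excl)
  if (!length(res$methylated) || !length(res$unmethylated))
    warning("dichotomisation produced an empty group; ",
            "downstream group tests will be skipped")
  res
}

#' Methylation-expression association at a probe/feature pair
#'
#' Two complementary views of epigenetic silencing: (i) Pearson correlation
#' between a probe's Beta and a feature's expression across the paired
#' samples, and (ii) a Mann-Whitney contrast of expression between the
#' methylated and unmethylated sample classes obtained by
#' [dichotomize_by_probe()]. Pairing is by sample name; pairwise-complete
#' observations are used and nothing is imputed.
#'
#' @param betas Beta matrix.
#' @param expression expression matrix (features x samples, log2 scale).
#' @param probe probe id in `betas`.
#' @param feature feature id in `expression`.
#' @param cut dichotomisation Beta cut-point (default 0.3).
#' @return list with `correlation` (a `"methyl_test"`, no-call on constant
#'   input), `group_test` (a `"methyl_test"` or `NULL` if a class is empty
#'   or too small), `dichotomy`, and `n` paired samples.
#' @export
methylation_expression_association <- function(betas, expression, probe,
                                               feature, cut = 0.3) {
  if (!probe %in% rownames(betas))
    stop("probe '", probe, "' not found in Beta matrix")
  if (!feature %in% rownames(expression))
    stop("feature '", feature, "' not found in expression matrix")
  common <- intersect(colnames(betas), colnames(expression))
  if (length(common) < 3)
    stop("need >= 3 paired samples, got ", length(common))
  b <- betas[probe, common]
  e <- expression[feature, common]
  corr <- pearson_r(b, e)
  dich <- suppressWarnings(
    dichotomize_by_probe(betas[, common, drop = FALSE], probe, cut))
  gt <- NULL
  if (length(dich$methylated) >= 2 && length(dich$unmethylated) >= 2)
    gt <- mann_whitney_u(e[dich$unmethylated], e[dich$methylated])
  list(correlation = corr, group_test = gt, dichotomy = dich,
       n = sum(is.finite(b) & is.finite(e)))
}

#' Correlation with and without a designated outlier sample
#'
#' Reports the Pearson correlation over all samples and over the samples
#' excluding one labelled outlier, side by side; neither is substituted for
#' the other.
#'
#' @param x,y paired numeric vectors.
#' @param labels sample labels parallel to `x`.
#' @param outlier_label the label to hold out (must occur in `labels`).
#' @return list with `r_all`, `r_without` (each a `"methyl_test"`;
#'   `r_without` is a no-call `NA` when fewer than 3 samples remain) and
#'   `n_removed`.
#' @export
correlation_with_outlier <- function(x, y, labels, outlier_label) {
  stopifnot(length(x) == length(y), length(labels) == length(x))
  if (!outlier_label %in% labels)
    stop("outlier label '", outlier_label, "' not among sample labels")
  if (length(x) < 4) stop("need at least 4 samples")
  keep <- labels != outlier_label
  r_all <- pearson_r(x, y)
  r_without <- if (sum(keep) >= 3) pearson_r(x[keep], y[keep]) else
    .test_result(NA_real_, NA_real_, "pearson", sum(keep),
                 note = "no-call: fewer than 3 samples after removal")
  list(r_all = r_all, r_without = r_without, n_removed = sum(!keep))
}

#' Per-probe group methylation means across a genomic locus
#'
#' Orders the probes falling inside an interval by genomic position and
#' reports each group's mean Beta per probe together with CpG-island
#' membership -- the table behind locus-wide methylation profiles. Both the
#' number of CGI probes and the total probe count are attached as
#' attributes, since locus summaries are quoted both ways.
#'
#' @param betas Beta matrix.
#' @param annotation data.frame `probe`, `chrom`, `start`, `end`, `cgi`
#'   (0-based half-open; empty `cgi` means outside any island).
#' @param interval a `genomic_interval` to profile.
#' @param groups data.frame `sample`, `group` covering the Beta columns.
#' @return data.frame `probe`, `chrom`, `start`, `cgi`, then one
#'   `mean_beta_<group>` column per group, ordered by `start`; attributes
#'   `n_cgi_probes` and `n_probes`. Empty when no probe falls in the
#'   interval (with a warning).
#' @export
locus_profile <- function(betas, annotation, interval, groups) {
  stopifnot(inherits(interval, "genomic_interval"))
  need <- c("probe", "chrom", "start", "end", "cgi")
  if (!all(need %in% names(annotation)))
    stop("annotation missing column(s): ",
         paste(setdiff(need, names(annotation)), collapse = ", "))
  ann <- annotation[annotation$chrom == interval$chrom &
                      annotation$start >= interval$start &
                      annotation$start < interval$end, , drop = FALSE]
  ann <- ann[ann$probe %in% rownames(betas), , drop = FALSE]
  if (!nrow(ann)) {
    warning("no probes in interval ", format_interval(interval))
    out <- data.frame(probe = character(0), chrom = character(0),
                      start = numeric(0), cgi = character(0))
    attr(out, "n_probes") <- 0L; attr(out, "n_cgi_probes") <- 0L
    return(out)
  }
  ann <- ann[order(ann$start), , drop = FALSE]
  out <- data.frame(probe = ann$probe, chrom = ann$chrom, start = ann$start,
                    cgi = ann$cgi, row.names = NULL)
  for (g in unique(groups$group)) {
    cols <- intersect(groups$sample[groups$group == g], colnames(betas))
    out[[paste0("mean_beta_", g)]] <-
      rowMeans(betas[ann$probe, cols, drop = FALSE], na.rm = TRUE)
  }
  attr(out, "n_probes") <- nrow(out)
  attr(out, "n_cgi_probes") <- sum(!is.na(ann$cgi) & ann$cgi != "")
  out
}
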