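# Comparative-CT relative quantification (2^-ddCt) for miRNA / pri-miRNA /
# mRNA TaqMan-style assays, plus demethylation-induction scoring.

#' Validate a Ct table
#'
#' The replicate-level Ct table is the common input of the qPCR and qMSP
#' stages: one row per (sample, assay, replicate) with columns `sample`,
#' `group`, `assay`, `replicate`, `ct` and optionally `condition`.
#' Undetected reactions are `NA` in `ct` (never imputed to a cycle number).
#'
#' @param ct data.frame to check.
#' @param require_condition require a `condition` column (paired designs).
#' @return the table, invisibly, with `ct` coerced to numeric.
#' @export
validate_ct_table <- function(ct, require_condition = FALSE) {
  need <- c("sample", "group", "assay", "replicate", "ct")
  if (require_condition) need <- c(need, "condition")
  miss <- setdiff(need, names(ct))
  if (length(miss))
    stop("Ct table missing column(s): ", paste(miss, collapse = ", "))
  if (is.character(ct$ct))
    ct$ct[tolower(ct$ct) %in% c("undetected", "undetermined", "na")] <- NA
  ct$ct <- suppressWarnings(as.numeric(ct$ct))
  bad <- which(!is.na(ct$ct) & (ct$ct <= 0 | ct$ct >= 45))
  if (length(bad))
    stop("Ct values must be in (0, 45) when numeric; offending row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  invisible(ct)
}

#' Delta-Ct of a target against a reference assay
#'
#' Technical replicates are averaged on the Ct scale before subtraction
#' (standard comparative-CT practice). Undetected replicates are excluded; if
#' either assay has no numeric replicate the result is a no-call (`NA`),
#' propagated rather than zeroed.
#'
#' @param target_cts,reference_cts replicate Ct vectors (`NA` = undetected).
#' @return `mean(target) - mean(reference)`, or `NA_real_` for a no-call.
#' @examples
#' delta_ct(c(25, 25), c(20, 20))  # 5
#' @export
delta_ct <- function(target_cts, reference_cts) {
  t_ok <- target_cts[is.finite(target_cts)]
  r_ok <- reference_cts[is.finite(reference_cts)]
  if (!length(t_ok) || !length(r_ok)) return(NA_real_)
  mean(t_ok) - mean(r_ok)
}

#' Relative quantity from two delta-Ct values
#'
#' The comparative-CT quantity `2^-(dCt_sample - dCt_calibrator)`.
#'
#' @param delta_ct_sample,delta_ct_calibrator delta-Ct values (cycles).
#' @return dimensionless relative quantity (> 0), `NA` if either input is.
#' @examples
#' relative_quantity(5, 3)  # 0.25
#' @export
relative_quantity <- function(delta_ct_sample, delta_ct_calibrator) {
  2^(-(delta_ct_sample - delta_ct_calibrator))
}

#' Per-sample relative expression against a calibrator group
#'
#' Computes each sample's delta-Ct (target minus reference assay, replicate
#' means), sets the calibrator delta-Ct to the arithmetic mean delta-Ct over
#' the calibrator group's samples, and reports `rq = 2^-ddCt`. With this
#' definition the calibrator group's mean ddCt is exactly 0, i.e. its
#' geometric-mean rq is exactly 1 ("relative to mean expression of bone").
#'
#' @param ct a Ct table ([validate_ct_table()]).
#' @param target,reference assay ids (must differ).
#' @param calibrator_group group label whose mean delta-Ct calibrates rq.
#' @param condition optional value to filter the `condition` column on.
#' @return data.frame `sample`, `group`, `assay`, `reference`, `delta_ct`,
#'   `ddct`, `rq`; samples lacking a numeric target or reference Ct carry
#'   `NA` (no-call) and are messaged, not dropped silently.
#' @export
group_relative_expression <- function(ct, target, reference,
                                      calibrator_group,
                                      condition = NULL) {
  ct <- validate_ct_table(ct)
  if (target == reference) stop("target and reference assays must differ")
  if (!is.null(condition)) {
    if (!"condition" %in% names(ct)) stop("Ct table has no condition column")
    ct <- ct[ct$condition == condition, , drop = FALSE]
  }
  samples <- unique(ct$sample)
  grp <- ct$group[match(samples, ct$sample)]
  if (!any(grp == calibrator_group))
    stop("calibrator group '", calibrator_group, "' has no samples")
  dct <- vapply(samples, function(s) {
    delta_ct(ct$ct[ct$sample == s & ct$assay == target],
             ct$ct[ct$sample == s & ct$assay == reference])
  }, numeric(1))
  if (anyNA(dct))
    message("no-call (missing target or reference Ct) for sample(s): ",
            paste(samples[is.na(dct)], collapse = ", "))
  cal <- mean(dct[grp == calibrator_group], na.rm = TRUE)
  ddct <- dct - cal
  data.frame(sample = samples, group = grp, assay = target,
             reference = reference, delta_ct = unname(dct),
             ddct = unname(ddct), rq = 2^(-unname(ddct)),
             row.names = NULL)
}

#' Demethylation-induction call for one sample
#'
#' Fold change of relative expression after a demethylating treatment
#' (5-Aza-2'-deoxycytidine); a transcript counts as induced at a fold of at
#' least 1.3 (a 30 percent increase).
#'
#' @param rq_untreated,rq_treated relative quantities (> 0).
#' @param threshold induction fold threshold (default 1.3).
#' @return list with `fold` and logical `induced`.
#' @examples
#' induction(1, 1.3)$induced   # TRUE
#' induction(1, 1.29)$induced  # FALSE
#' @export
induction <- function(rq_untreated, rq_treated, threshold = 1.3) {
  stopifnot(rq_untreated > 0, rq_treated > 0)
  fold <- rq_treated / rq_untreated
  list(fold = fold, induced = fold >= threshold)
}

#' Induction scoring across a paired untreated/treated cohort
#'
#' For each cell line with both conditions, the induction fold of a target
#' assay is `2^-(dCt_treated - dCt_untreated)` (the calibrator cancels), and
#' the line is induced at fold >= `threshold`. Pairing is preserved so the
#' per-line delta-Ct pairs can feed a paired t-test. Lines missing a
#' condition, or with a no-call delta-Ct in either condition, are excluded
#' with a message.
#'
#' @param ct Ct table with a `condition` column.
#' @param target,reference assay ids.
#' @param untreated,treated the two condition labels.
#' @param threshold induction fold threshold (default 1.3).
#' @return list with `folds` (data.frame `sample`, `group`,
#'   `delta_ct_untreated`, `delta_ct_treated`, `fold`, `induced`),
#'   `n_induced`, `n`, and `paired_test` (a `"methyl_test"` from
#'   [paired_t()] on the per-line delta-Ct pairs, or `NULL` when n < 2).
#' @export
induction_cohort <- function(ct, target, reference,
                             untreated = "untreated", treated = "treated",
                             threshold = 1.3) {
  ct <- validate_ct_table(ct, require_condition = TRUE)
  samples <- unique(ct$sample)
  dct_for <- function(s, cond)
    delta_ct(ct$ct[ct$sample == s & ct$assay == target &
                     ct$condition == cond],
             ct$ct[ct$sample == s & ct$assay == reference &
                     ct$condition == cond])
  d_u <- vapply(samples, dct_for, numeric(1), cond = untreated)
  d_t <- vapply(samples, dct_for, numeric(1), cond = treated)
  ok <- is.finite(d_u) & is.finite(d_t)
  if (any(!ok))
    message("excluding unpaired or no-call line(s): ",
            paste(samples[!ok], collapse = ", "))
  samples <- samples[ok]; d_u <- d_u[ok]; d_t <- d_t[ok]
  fold <- 2^(-(d_t - d_u))
  folds <- data.frame(sample = samples,
                      group = ct$group[match(samples, ct$sample)],
                      delta_ct_untreated = unname(d_u),
                      delta_ct_treated = unname(d_t),
                      fold = unname(fold),
                      induced = unname(fold >= threshold),
                      row.names = NULL)
  ptest <- if (length(samples) >= 2 && stats::sd(d_t - d_u) > 0)
    paired_t(d_u, d_t) else NULL
  list(folds = folds, n_induced = sum(folds$induced), n = nrow(folds),
       paired_test = ptest)
}
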