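# Quantitative methylation-specific PCR: gene:ALU ratios, percent of
# methylated reference (PMR), cohort-derived scoring thresholds and
# increased-methylation calls.

#' Gene:ALU ratio from replicate Ct values
#'
#' Reference-normalised abundance of methylated template: the median over
#' paired replicates of `2^-(Ct_gene - Ct_ALU)`. With unequal replicate
#' counts the replicates cannot be paired, so the ratio of per-assay medians
#' `2^-(median(gene) - median(ALU))` is used instead. A fully undetected gene
#' assay gives ratio 0 flagged below detection; a fully undetected ALU
#' reference invalidates the sample (input-DNA control failure).
#'
#' @param gene_cts,alu_cts replicate Ct vectors (`NA` = undetected).
#' @return the ratio, with attribute `below_detection` (logical).
#' @examples
#' gene_alu_ratio(c(25, 25, 25), c(20, 20, 20))  # 2^-5
#' @export
gene_alu_ratio <- function(gene_cts, alu_cts) {
  alu <- alu_cts[is.finite(alu_cts)]
  if (!length(alu))
    stop("ALU reference fully undetected: sample invalid (control failure)")
  gene <- gene_cts[is.finite(gene_cts)]
  if (!length(gene))
    return(structure(0, below_detection = TRUE))
  ratio <- if (length(gene) == length(alu))
    stats::median(2^(-(gene - alu)))
  else
    2^(-(stats::median(gene) - stats::median(alu)))
  structure(ratio, below_detection = FALSE)
}

#' Percent of methylated reference
#'
#' A sample's gene:ALU ratio divided by the median gene:ALU ratio of the
#' fully methylated positive control, times 100. The positive control itself
#' scores PMR 100 by construction.
#'
#' @param sample_ratio gene:ALU ratio of the sample.
#' @param positive_control_ratio gene:ALU ratio of the fully methylated
#'   control; must be > 0 (otherwise the plate is unusable).
#' @return PMR in percent (>= 0).
#' @examples
#' pmr(0.05, 0.5)  # 10
#' @export
pmr <- function(sample_ratio, positive_control_ratio) {
  if (!is.finite(positive_control_ratio) || positive_control_ratio <= 0)
    stop("positive-control gene:ALU ratio must be > 0 (bad plate)")
  if (any(sample_ratio < 0)) stop("sample ratio must be >= 0")
  100 * sample_ratio / positive_control_ratio
}

#' Cohort-derived methylation-scoring threshold
#'
#' To keep assay specificity high, the threshold for scoring tumour samples
#' as methylated is the highest PMR observed across the normal-bone series.
#'
#' @param bone_pmrs PMR values of the normal-bone samples (non-empty).
#' @return the maximum bone PMR.
#' @export
scoring_threshold <- function(bone_pmrs) {
  bone_pmrs <- bone_pmrs[is.finite(bone_pmrs)]
  if (!length(bone_pmrs))
    stop("no bone PMR values supplied: cannot derive scoring threshold")
  max(bone_pmrs)
}

#' Methylation call against a scoring threshold
#'
#' Samples with PMR equal to or above the threshold are considered
#' methylated. (A strict `>` variant circulates for the same rule; see
#' [qmsp_cohort()], which reports both when they differ.)
#'
#' @param pmr PMR value(s).
#' @param threshold from [scoring_threshold()].
#' @return logical vector.
#' @export
call_methylated <- function(pmr, threshold) {
  pmr >= threshold
}

#' Increased-methylation call against the bone average
#'
#' A sample shows increased methylation when its PMR strictly exceeds twice
#' the mean PMR of the normal bones.
#'
#' @param pmr PMR value(s).
#' @param bone_mean_pmr mean PMR across the bone group (>= 0).
#' @param multiplier fold over the bone mean (default 2).
#' @return logical vector.
#' @export
call_increased <- function(pmr, bone_mean_pmr, multiplier = 2) {
  stopifnot(bone_mean_pmr >= 0)
  pmr > multiplier * bone_mean_pmr
}

#' qMSP analysis of a multi-group cohort
#'
#' Computes per-sample gene:ALU ratios and PMR against the plate's fully
#' methylated positive control, derives the scoring threshold from the bone
#' group, makes methylated / increased-methylation calls, summarises per
#' group, and contrasts every other group against bone with the
#' Mann-Whitney U test. Groups with fewer than 2 samples are excluded from
#' testing but still summarised.
#'
#' @param ct Ct table whose assays include the methylation-specific target
#'   and the ALU reference; the positive control is one of its samples.
#' @param gene_assay,alu_assay assay ids (defaults `"target"`, `"ALU-C4"`).
#' @param control_sample sample id of the fully methylated positive control.
#' @param bone_group label of the normal-bone group (default `"bone"`).
#' @param increased_multiplier fold over the bone mean for the
#'   increased-methylation call (default 2).
#' @return list with `pmr_table` (`sample`, `group`, `gene_alu_ratio`,
#'   `below_detection`, `pmr`, `methylated`, `methylated_strict`,
#'   `increased`), `threshold`, `bone_mean_pmr`, `group_summary` (per-group
#'   n, mean/median PMR, counts called), and `tests` (bone-vs-group
#'   `"methyl_test"`s).
#' @export
qmsp_cohort <- function(ct, gene_assay = "target", alu_assay = "ALU-C4",
                        control_sample, bone_group = "bone",
                        increased_multiplier = 2) {
  ct <- validate_ct_table(ct)
  if (!control_sample %in% ct$sample)
    stop("positive control sample '", control_sample, "' not in Ct table")
  ratio_of <- function(s)
    gene_alu_ratio(ct$ct[ct$sample == s & ct$assay == gene_assay],
                   ct$ct[ct$sample == s & ct$assay == alu_assay])
  control_ratio <- as.numeric(ratio_of(control_sample))
  samples <- setdiff(unique(ct$sample), control_sample)
  ratios <- lapply(samples, ratio_of)
  ratio_num <- vapply(ratios, as.numeric, numeric(1))
  below <- vapply(ratios, function(r) isTRUE(attr(r, "below_detection")),
                  logical(1))
  pmr_vals <- pmr(ratio_num, control_ratio)
  grp <- ct$group[match(samples, ct$sample)]
  if (!any(grp == bone_group))
    stop("bone group '", bone_group, "' has no samples")
  thr <- scoring_threshold(pmr_vals[grp == bone_group])
  bone_mean <- mean(pmr_vals[grp == bone_group])
  meth <- call_methylated(pmr_vals, thr)
  meth_strict <- pmr_vals > thr
  if (any(meth != meth_strict))
    message("inclusive (>=) and strict (>) threshold calls differ for: ",
            paste(samples[meth != meth_strict], collapse = ", "))
  tab <- data.frame(sample = samples, group = grp,
                    gene_alu_ratio = ratio_num, below_detection = below,
                    pmr = pmr_vals, methylated = meth,
                    methylated_strict = meth_strict,
                    increased = call_increased(pmr_vals, bone_mean,
                                               increased_multiplier),
                    row.names = NULL)
  groups <- unique(grp)
  group_summary <- do.call(rbind, lapply(groups, function(g) {
    v <- tab[tab$group == g, ]
    data.frame(group = g, n = nrow(v), mean_pmr = mean(v$pmr),
               median_pmr = stats::median(v$pmr),
               n_methylated = sum(v$methylated),
               n_increased = sum(v$increased), row.names = NULL)
  }))
  test_groups <- setdiff(groups, bone_group)
  tests <- list()
  for (g in test_groups) {
    va <- tab$pmr[tab$group == bone_group]
    vb <- tab$pmr[tab$group == g]
    if (length(va) >= 2 && length(vb) >= 2)
      tests[[g]] <- mann_whitney_u(va, vb)
    else
      message("group '", g, "' (or bone) has n < 2: excluded from testing")
  }
  list(pmr_table = tab, threshold = thr, bone_mean_pmr = bone_mean,
       group_summary = group_summary, tests = tests)
}
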