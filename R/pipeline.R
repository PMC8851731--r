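# End-to-end pipeline: qPCR -> qMSP -> trace calling -> array integration,
# reporting plain TSV tables plus a machine-readable run log. Every threshold
# the stages apply lives in the pipeline configuration.

#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis in one validated object;
#' the stages receive thresholds only from here.
#'
#' @param induction_fold induction fold threshold (default 1.3, a 30 percent
#'   increase).
#' @param beta_unmethylated,beta_methylated Beta class boundaries (defaults
#'   0.3 and 0.7).
#' @param bs_unmethylated,bs_methylated bisulfite-trace ratio class
#'   boundaries (defaults 0.2 and 0.8).
#' @param increased_multiplier fold over the bone-average PMR for the
#'   increased-methylation call (default 2).
#' @param dichotomize_cut Beta cut for sample dichotomisation (default 0.3).
#' @param seed seed recorded in the run log (default 1).
#' @return object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(induction_fold = 1.3,
                            beta_unmethylated = 0.3, beta_methylated = 0.7,
                            bs_unmethylated = 0.2, bs_methylated = 0.8,
                            increased_multiplier = 2,
                            dichotomize_cut = 0.3,
                            seed = 1) {
  stopifnot(induction_fold > 0,
            beta_unmethylated > 0, beta_unmethylated < beta_methylated,
            beta_methylated < 1,
            bs_unmethylated > 0, bs_unmethylated < bs_methylated,
            bs_methylated < 1,
            increased_multiplier > 0,
            dichotomize_cut > 0, dichotomize_cut < 1)
  structure(as.list(environment()), class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(name, " stage: ", conditionMessage(e), call. = FALSE))
}

#' Run the integrated methylation/expression pipeline
#'
#' Executes, in order: comparative-CT expression quantification with
#' induction scoring (qpcr), PMR scoring with threshold calls and group
#' contrasts (qmsp), bisulfite-trace calling (seqmeth), and Beta/expression
#' integration (arrays). Writes one TSV per stage, a cross-stage summary
#' table and a JSON run log (package version, seed, every threshold
#' applied) to the report directory. Any stage failure aborts with an error
#' naming the stage; TSVs already written are preserved. Given identical
#' inputs and configuration the report is byte-identical across runs.
#'
#' @param bundle a `"cohort_bundle"` (from [simulate_cohort()]), or a
#'   directory written by [write_cohort()].
#' @param out_dir report directory (created; default `tempfile()`).
#' @param config a [pipeline_config()].
#' @return `out_dir`, invisibly; the report contains `qpcr_expression.tsv`,
#'   `qpcr_induction.tsv`, `qmsp_pmr.tsv`, `qmsp_groups.tsv`,
#'   `trace_calls.tsv`, `integration.tsv`, `summary.tsv`, `run_log.json`.
#' @export
run_pipeline <- function(bundle, out_dir = tempfile("methylmir_report_"),
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(bundle)) bundle <- read_cohort(bundle)
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  logline <- function(...) message("[", format(Sys.time(), "%H:%M:%S"),
                                   "] ", ...)

  # qpcr stage
  logline("qpcr: relative expression and induction")
  qpcr <- .stage("qpcr", {
    if (is.null(bundle$ct_expression)) stop("no expression Ct table")
    rel <- group_relative_expression(
      bundle$ct_expression, target = "miR-486-5p", reference = "RNU44",
      calibrator_group = "bone", condition = "untreated")
    ind <- induction_cohort(
      bundle$ct_expression, target = "miR-486-5p", reference = "RNU44",
      threshold = config$induction_fold)
    write_tsv(rel, p("qpcr_expression.tsv"))
    write_tsv(ind$folds, p("qpcr_induction.tsv"))
    list(rel = rel, ind = ind)
  })

  # qmsp stage
  logline("qmsp: PMR scoring and group contrasts")
  qm <- .stage("qmsp", {
    if (is.null(bundle$ct_qmsp)) stop("no qMSP Ct table")
    res <- qmsp_cohort(bundle$ct_qmsp, control_sample = "CpGenome",
                       bone_group = "bone",
                       increased_multiplier = config$increased_multiplier)
    write_tsv(res$pmr_table, p("qmsp_pmr.tsv"))
    write_tsv(res$group_summary, p("qmsp_groups.tsv"))
    res
  })

  # seqmeth stage: trace calling
  logline("seqmeth: bisulfite trace calling")
  traces <- .stage("seqmeth", {
    if (is.null(bundle$traces)) stop("no trace tables")
    calls <- do.call(rbind, lapply(names(bundle$traces), function(s) {
      tc <- call_traces(bundle$traces[[s]])
      cbind(sample = s, tc)
    }))
    write_tsv(calls, p("trace_calls.tsv"))
    calls
  })

  # arrays stage: integration
  logline("arrays: methylation-expression integration")
  integ <- .stage("arrays", {
    probe <- bundle$annotation$probe[
      bundle$annotation$standin == "cg00176210"][1]
    if (is.na(probe)) stop("no designated promoter probe in annotation")
    assoc <- methylation_expression_association(
      bundle$beta, bundle$expr, probe, "miR-486-5p",
      cut = config$dichotomize_cut)
    db <- delta_beta(bundle$beta,
                     bundle$groups$sample[bundle$groups$group ==
                                            "tumour_methylated"],
                     bundle$groups$sample[bundle$groups$group == "bone"],
                     probe)
    out <- data.frame(
      probe = probe, feature = "miR-486-5p",
      pearson_r = assoc$correlation$statistic,
      pearson_p = assoc$correlation$p,
      group_p = if (is.null(assoc$group_test)) NA_real_ else
        assoc$group_test$p,
      delta_beta = db,
      n_methylated = length(assoc$dichotomy$methylated),
      n_unmethylated = length(assoc$dichotomy$unmethylated))
    write_tsv(out, p("integration.tsv"))
    out
  })

  # summary + run log
  logline("summary")
  .stage("summary", {
    qsum <- qm$group_summary
    summary <- data.frame(
      quantity = c("n_samples", "induced_fraction",
                   "delta_beta_promoter", "pearson_r",
                   "pmr_threshold", "bone_mean_pmr",
                   paste0("n_methylated_", qsum$group),
                   paste0("n_increased_", qsum$group)),
      value = c(nrow(bundle$groups),
                qpcr$ind$n_induced / max(1, qpcr$ind$n),
                integ$delta_beta, integ$pearson_r,
                qm$threshold, qm$bone_mean_pmr,
                qsum$n_methylated, qsum$n_increased))
    write_tsv(summary, p("summary.tsv"))
    log <- list(
      package = "methylmiR",
      version = as.character(utils::packageVersion("methylmiR")),
      seed = config$seed,
      thresholds = config[setdiff(names(config), "seed")],
      stages = c("qpcr", "qmsp", "seqmeth", "arrays"))
    writeLines(jsonlite::toJSON(log, auto_unbox = TRUE, pretty = TRUE,
                                digits = NA),
               p("run_log.json"))
  })
  invisible(out_dir)
}

#' Read a cohort bundle back from a directory
#'
#' Inverse of [write_cohort()] for the tables the pipeline consumes. The
#' per-sample methylation patterns are not re-read (they are not needed by
#' any pipeline stage); the locus sequence and CGI interval are.
#'
#' @param dir directory written by [write_cohort()].
#' @return a `"cohort_bundle"` (without `patterns` and `config`).
#' @export
read_cohort <- function(dir) {
  p <- function(...) file.path(dir, ...)
  for (f in c("locus.fa", "cgi.bed", "beta.tsv", "groups.tsv",
              "ct_expression.tsv", "ct_qmsp.tsv"))
    if (!file.exists(p(f))) stop("missing bundle file: ", f)
  seqs <- read_fasta(p("locus.fa"))
  cgi_df <- read_bed(p("cgi.bed"))
  cgi <- genomic_interval(cgi_df$chrom[1], cgi_df$start[1], cgi_df$end[1])
  seqlen <- nchar(seqs[[1]])
  trace_files <- list.files(p("traces"), pattern = "\\.tsv$",
                            full.names = TRUE)
  traces <- lapply(trace_files, read_tsv)
  names(traces) <- sub("\\.tsv$", "", basename(trace_files))
  structure(list(
    locus = list(seq = unname(seqs[[1]]),
                 interval = genomic_interval(cgi_df$chrom[1], 0, seqlen),
                 cgi = cgi),
    groups = read_tsv(p("groups.tsv")),
    beta = read_matrix_tsv(p("beta.tsv")),
    annotation = if (file.exists(p("probe_annotation.tsv")))
      read_tsv(p("probe_annotation.tsv")) else NULL,
    expr = if (file.exists(p("expression.tsv")))
      read_matrix_tsv(p("expression.tsv")) else NULL,
    ct_expression = read_tsv(p("ct_expression.tsv")),
    ct_qmsp = read_tsv(p("ct_qmsp.tsv")),
    traces = if (length(traces)) traces else NULL,
    ground_truth = if (file.exists(p("ground_truth.tsv")))
      read_tsv(p("ground_truth.tsv")) else NULL),
    class = "cohort_bundle")
}
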