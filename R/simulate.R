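# Seeded synthetic-cohort generator. Produces a locus with a CpG island, per-
# sample methylation patterns, Beta and miRNA-expression matrices, qPCR and
# qMSP Ct tables and bisulfite-trace tables that carry the statistical
# structure the analysis stages assume (inverse log-linear methylation-
# expression coupling, replicate Ct noise, binomial trace sampling), together
# with the ground truth needed to score parameter recovery.

# Independent substreams: one master seed, one deterministic 31-bit seed per
# named generator, so adding a generator never perturbs existing streams.
.substream_seed <- function(seed, name) {
  h <- as.double(seed %% 2147483647L)
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 2147483647
  as.integer(h)
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe the study conditions the package targets: a small
#' normal-bone series, a majority-methylated tumour cell-line panel, an
#' unmethylated tumour minority, and a xenograft cohort of mixed methylation;
#' promoter methylation inversely coupled to expression on the log2 scale;
#' technical noise at qPCR-replicate magnitude.
#'
#' @param seed master seed; every downstream draw derives from it.
#' @param n_bone,n_tumour_methylated,n_tumour_unmethylated,n_xenograft group
#'   sizes (defaults 6 / 14 / 7 / 41).
#' @param beta_params named list of `c(mean, sd)` per group for the promoter
#'   methylation fraction (defaults: bone 0.15/0.08, tumour_methylated
#'   0.75/0.10, tumour_unmethylated 0.20/0.08, xenograft 0.45/0.25).
#' @param coupling_a,coupling_b intercept and slope of the inverse coupling
#'   `log2 expression = a - b * Beta` (defaults 8 and 4).
#' @param sigma_e sd of the biological noise on latent log2 expression
#'   (default 0.5).
#' @param assay_offset_sd sd of the independent per-assay offsets shared
#'   latent expression receives for the mature / primary / host transcripts
#'   (default 0.3; induces their high mutual correlation).
#' @param ct_sd technical replicate noise on Ct values, cycles (default 0.2).
#' @param n_replicates technical replicates per reaction (default 3).
#' @param trace_depth molecules sampled per CpG in trace simulation
#'   (default 500).
#' @param trace_n_sites CpGs covered by the sequencing amplicon (default 34).
#' @param cgi_length,cgi_cpg_count island geometry (defaults 1109 bp, 79
#'   CpGs).
#' @param flank_length,flank_cpg_count flank geometry per side (defaults
#'   1000 bp, 10 CpGs).
#' @param flank_methylation methylation probability of CpGs outside the
#'   island, hypermethylated in all groups (default 0.85).
#' @param n_probes array probes placed on locus CpGs (default 96).
#' @param probe_noise_sd measurement noise on probe Beta (default 0.03).
#' @param aza_multiplier multiplicative effect of demethylating treatment on
#'   the methylated fraction (default 0.5).
#' @param qmsp_floor detection floor added to the methylated fraction before
#'   log2 in qMSP Ct generation (default 1e-4).
#' @param qmsp_offset,alu_ct,ref_ct,expr_ct_offset Ct-scale plumbing
#'   constants (gene-vs-ALU offset, ALU baseline, reference-gene baseline,
#'   target offset).
#' @return object of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1,
                       n_bone = 6, n_tumour_methylated = 14,
                       n_tumour_unmethylated = 7, n_xenograft = 41,
                       beta_params = list(
                         bone = c(mean = 0.15, sd = 0.08),
                         tumour_methylated = c(mean = 0.75, sd = 0.10),
                         tumour_unmethylated = c(mean = 0.20, sd = 0.08),
                         xenograft = c(mean = 0.45, sd = 0.25)),
                       coupling_a = 8, coupling_b = 4, sigma_e = 0.5,
                       assay_offset_sd = 0.3,
                       ct_sd = 0.2, n_replicates = 3,
                       trace_depth = 500, trace_n_sites = 34,
                       cgi_length = 1109, cgi_cpg_count = 79,
                       flank_length = 1000, flank_cpg_count = 10,
                       flank_methylation = 0.85,
                       n_probes = 96, probe_noise_sd = 0.03,
                       aza_multiplier = 0.5,
                       qmsp_floor = 1e-4, qmsp_offset = 3,
                       alu_ct = 18, ref_ct = 20, expr_ct_offset = 12) {
  cfg <- as.list(environment())
  for (g in names(cfg$beta_params)) {
    p <- cfg$beta_params[[g]]
    if (p[["sd"]] <= 0) stop("beta sd for group '", g, "' must be > 0")
    if (p[["mean"]] <= 0 || p[["mean"]] >= 1)
      stop("beta mean for group '", g, "' must be in (0, 1)")
  }
  stopifnot(cfg$sigma_e > 0, cfg$ct_sd > 0, cfg$trace_depth >= 50,
            cfg$cgi_length >= 200, cfg$aza_multiplier > 0,
            cfg$aza_multiplier <= 1)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed ", x$seed, "; groups bone=", x$n_bone,
      " tumour_methylated=", x$n_tumour_methylated,
      " tumour_unmethylated=", x$n_tumour_unmethylated,
      " xenograft=", x$n_xenograft, "; coupling b=", x$coupling_b, "\n",
      sep = "")
  invisible(x)
}

.sim_samples <- function(config) {
  grp <- c(rep("bone", config$n_bone),
           rep("tumour_methylated", config$n_tumour_methylated),
           rep("tumour_unmethylated", config$n_tumour_unmethylated),
           rep("xenograft", config$n_xenograft))
  id <- unlist(lapply(split(grp, grp)[unique(grp)], function(g)
    sprintf("%s_%02d", g, seq_along(g))), use.names = FALSE)
  data.frame(sample = id, group = grp, row.names = NULL)
}

#' Simulate a locus with a CpG island
#'
#' Builds a random sequence whose central island has an exact CpG count and
#' a CpG density and GC content well above its flanks. CpG sites are planted
#' at chosen positions and the filler bases are resampled so that no
#' accidental `CG` arises, making the island's CpG count exactly
#' `cgi_cpg_count`.
#'
#' @param config a [sim_config()].
#' @return list with `seq`, `interval` (whole locus), `cgi` (island
#'   interval), `cpg_sites_cgi`, `cpg_sites_flank` (0-based positions).
#' @export
simulate_locus <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.substream_seed(config$seed, "locus"))
  fl <- config$flank_length; cl <- config$cgi_length
  L <- 2L * fl + cl
  # plant CpGs on even offsets inside each region: spacing >= 2 guaranteed
  plant <- function(start, len, k) {
    slots <- seq.int(0L, len - 2L, by = 2L)
    as.integer(start + sort(sample(slots, k)))
  }
  cgi_sites <- plant(fl, cl, config$cgi_cpg_count)
  flank_sites <- c(plant(0L, fl, config$flank_cpg_count),
                   plant(fl + cl, fl, config$flank_cpg_count))
  chars <- character(L)
  in_cgi <- seq_len(L) - 1L >= fl & seq_len(L) - 1L < fl + cl
  chars[in_cgi] <- sample(c("A", "C", "G", "T"), sum(in_cgi), TRUE,
                          prob = c(0.15, 0.35, 0.35, 0.15))
  chars[!in_cgi] <- sample(c("A", "C", "G", "T"), sum(!in_cgi), TRUE,
                           prob = c(0.30, 0.20, 0.20, 0.30))
  sites <- c(cgi_sites, flank_sites)
  chars[sites + 1L] <- "C"; chars[sites + 2L] <- "G"
  seq <- paste(chars, collapse = "")
  # demote accidental CGs (their G -> A cannot create a new CG)
  extra <- setdiff(find_cpg_sites(seq), sites)
  if (length(extra)) {
    chars[extra + 2L] <- "A"
    seq <- paste(chars, collapse = "")
  }
  list(seq = seq,
       interval = genomic_interval("chrSim", 0, L),
       cgi = genomic_interval("chrSim", fl, fl + cl),
       cpg_sites_cgi = cgi_sites,
       cpg_sites_flank = sort(flank_sites))
}

#' Simulate per-sample methylation patterns and an array Beta matrix
#'
#' Each sample draws a promoter (island) methylation fraction from its
#' group's distribution (normal, clipped to \[0.01, 0.99\]); island CpG
#' states are Bernoulli in that fraction, flank CpGs Bernoulli in the
#' uniformly high flank methylation. Array probes sit on a subset of locus
#' CpGs; probe Beta is the local methylation probability plus clipped
#' measurement noise. Two designated island probes stand in for the promoter
#' probes interrogated on real arrays (recorded in the annotation's
#' `standin` column as cg00176210 and cg08194989).
#'
#' @param config a [sim_config()].
#' @param locus result of [simulate_locus()].
#' @return list with `groups` (sample/group data.frame), `fractions` (named
#'   per-sample island methylation fraction -- ground truth), `patterns`
#'   (named list of [methylation_pattern()]), `beta` (probe x sample
#'   matrix), `annotation` (probe, chrom, start, end, cgi, standin).
#' @export
simulate_methylation <- function(config, locus) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.substream_seed(config$seed, "methylation"))
  groups <- .sim_samples(config)
  n <- nrow(groups)
  pars <- config$beta_params
  fractions <- vapply(groups$group, function(g)
    min(0.99, max(0.01, stats::rnorm(1, pars[[g]][["mean"]],
                                     pars[[g]][["sd"]]))), numeric(1))
  names(fractions) <- groups$sample

  all_sites <- sort(c(locus$cpg_sites_cgi, locus$cpg_sites_flank))
  is_cgi_site <- all_sites %in% locus$cpg_sites_cgi
  patterns <- lapply(groups$sample, function(s) {
    p <- ifelse(is_cgi_site, fractions[[s]], config$flank_methylation)
    methylation_pattern(all_sites,
                        stats::rbinom(length(all_sites), 1L, p) == 1L,
                        interval = locus$interval)
  })
  names(patterns) <- groups$sample

  n_cgi_probes <- min(length(locus$cpg_sites_cgi),
                      max(2L, round(config$n_probes / 3)))
  probe_sites <- sort(c(
    sample(locus$cpg_sites_cgi, n_cgi_probes),
    sample(locus$cpg_sites_flank,
           min(length(locus$cpg_sites_flank),
               config$n_probes - n_cgi_probes))))
  probe_ids <- sprintf("cgSIM%05d", seq_along(probe_sites))
  probe_in_cgi <- probe_sites %in% locus$cpg_sites_cgi
  designated <- probe_ids[probe_in_cgi][1:2]
  standin <- rep("", length(probe_ids))
  standin[match(designated, probe_ids)] <- c("cg00176210", "cg08194989")
  annotation <- data.frame(
    probe = probe_ids, chrom = locus$interval$chrom,
    start = probe_sites, end = probe_sites + 2L,
    cgi = ifelse(probe_in_cgi, "CpGsim", ""),
    standin = standin, row.names = NULL)

  beta <- matrix(NA_real_, length(probe_ids), n,
                 dimnames = list(probe_ids, groups$sample))
  for (s in groups$sample) {
    p <- ifelse(probe_in_cgi, fractions[[s]], config$flank_methylation)
    beta[, s] <- pmin(1, pmax(0, p + stats::rnorm(
      length(p), 0, config$probe_noise_sd)))
  }
  list(groups = groups, fractions = fractions, patterns = patterns,
       beta = beta, annotation = annotation)
}

#' Simulate qRT-PCR Ct tables (and array expression) from methylation
#'
#' Latent log2 expression follows the inverse coupling
#' `a - b * fraction + Normal(0, sigma_e)`; the mature miRNA, its primary
#' transcript and the host-gene transcript share the latent value plus
#' independent per-assay offsets. Ct values are reference Ct plus a constant
#' minus the latent expression, with replicate noise; the treated condition
#' re-draws with the fraction multiplied by the demethylation effect. A
#' small miRNA-array-style log2 expression matrix containing the mature
#' feature is emitted for the integration stage.
#'
#' @param config a [sim_config()].
#' @param fractions named per-sample methylation fractions.
#' @param groups sample/group data.frame.
#' @return list with `ct` (replicate Ct table: sample, group, assay,
#'   replicate, ct, condition; assays `miR-486-5p`/`RNU44` and
#'   `pri-mir-486`, `ANK1v1-4`/`GAPDH`), `expr` (feature x sample log2
#'   matrix, untreated), `latent` (data.frame of the ground-truth latents
#'   and expected folds).
#' @export
simulate_expression <- function(config, fractions, groups) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.substream_seed(config$seed, "expression"))
  samples <- groups$sample
  n <- length(samples)
  a <- config$coupling_a; b <- config$coupling_b
  lat_u <- a - b * fractions[samples] + stats::rnorm(n, 0, config$sigma_e)
  lat_t <- a - b * fractions[samples] * config$aza_multiplier +
    stats::rnorm(n, 0, config$sigma_e)
  assays <- list("miR-486-5p" = "RNU44",
                 "pri-mir-486" = "GAPDH",
                 "ANK1v1-4" = "GAPDH")
  ref_base <- c(RNU44 = config$ref_ct, GAPDH = config$ref_ct - 1)
  rows <- list()
  off <- function() stats::rnorm(1, 0, config$assay_offset_sd)
  for (cond in c("untreated", "treated")) {
    lat <- if (cond == "untreated") lat_u else lat_t
    for (i in seq_len(n)) {
      for (tgt in names(assays)) {
        refg <- assays[[tgt]]
        lat_assay <- lat[i] + off()
        ct_t <- ref_base[[refg]] + config$expr_ct_offset - lat_assay +
          stats::rnorm(config$n_replicates, 0, config$ct_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          sample = samples[i], group = groups$group[i], assay = tgt,
          replicate = seq_len(config$n_replicates), ct = ct_t,
          condition = cond)
      }
      for (refg in unique(unlist(assays))) {
        ct_r <- ref_base[[refg]] +
          stats::rnorm(config$n_replicates, 0, config$ct_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          sample = samples[i], group = groups$group[i], assay = refg,
          replicate = seq_len(config$n_replicates), ct = ct_r,
          condition = cond)
      }
    }
  }
  ct <- do.call(rbind, rows)
  # miRNA-array-style matrix: the mature feature plus unrelated features
  n_extra <- 49L
  expr <- rbind(
    matrix(stats::rnorm(n_extra * n, 7, 1.5), n_extra, n,
           dimnames = list(sprintf("feature_%03d", seq_len(n_extra)),
                           samples)),
    "miR-486-5p" = lat_u)
  latent <- data.frame(
    sample = samples, group = groups$group,
    fraction = unname(fractions[samples]),
    latent_untreated = unname(lat_u), latent_treated = unname(lat_t),
    expected_log2_fold = unname(b * fractions[samples] *
                                  (1 - config$aza_multiplier)),
    row.names = NULL)
  list(ct = ct, expr = expr, latent = latent)
}

#' Simulate bisulfite-sequencing trace tables
#'
#' For each sample and each amplicon CpG, the number of methylated molecules
#' is Binomial(depth, site methylation probability); cytosine and thymine
#' peak heights are the molecule counts times channel gains jittered by
#' +/-10 percent.
#'
#' @param config a [sim_config()].
#' @param fractions named per-sample island methylation fractions.
#' @param locus result of [simulate_locus()].
#' @return named list of data.frames `site`, `c_height`, `t_height` (one per
#'   sample; sites are the first `trace_n_sites` island CpGs).
#' @export
simulate_traces <- function(config, fractions, locus) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.substream_seed(config$seed, "traces"))
  sites <- utils::head(locus$cpg_sites_cgi, config$trace_n_sites)
  d <- config$trace_depth
  out <- lapply(names(fractions), function(s) {
    m <- stats::rbinom(length(sites), d, fractions[[s]])
    gain_c <- 1000 * stats::runif(length(sites), 0.9, 1.1)
    gain_t <- 1000 * stats::runif(length(sites), 0.9, 1.1)
    data.frame(site = sites, c_height = m * gain_c,
               t_height = (d - m) * gain_t)
  })
  names(out) <- names(fractions)
  out
}

#' Simulate a qMSP Ct table with ALU reference and positive control
#'
#' Gene Ct is ALU Ct plus a constant minus `log2(fraction + floor)`, so the
#' gene:ALU ratio tracks the methylated DNA fraction; the fully methylated
#' positive control (sample `CpGenome`, group `control`) is generated at
#' fraction 1. Replicate noise applies to both assays.
#'
#' @param config a [sim_config()].
#' @param fractions named per-sample methylation fractions.
#' @param groups sample/group data.frame.
#' @return Ct table with assays `target` and `ALU-C4` (no condition column).
#' @export
simulate_qmsp <- function(config, fractions, groups) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.substream_seed(config$seed, "qmsp"))
  samples <- c(groups$sample, "CpGenome")
  grp <- c(groups$group, "control")
  fr <- c(fractions[groups$sample], CpGenome = 1.0)
  rows <- list()
  for (i in seq_along(samples)) {
    alu <- config$alu_ct + stats::rnorm(config$n_replicates, 0, config$ct_sd)
    gene <- config$alu_ct + config$qmsp_offset -
      log2(fr[[i]] + config$qmsp_floor) +
      stats::rnorm(config$n_replicates, 0, config$ct_sd)
    rows[[length(rows) + 1L]] <- data.frame(
      sample = samples[i], group = grp[i], assay = "target",
      replicate = seq_len(config$n_replicates), ct = gene)
    rows[[length(rows) + 1L]] <- data.frame(
      sample = samples[i], group = grp[i], assay = "ALU-C4",
      replicate = seq_len(config$n_replicates), ct = alu)
  }
  do.call(rbind, rows)
}

#' Simulate a complete cohort bundle
#'
#' Composes the locus, methylation, expression, trace and qMSP generators
#' under one master seed. The bundle carries every latent parameter needed
#' to score recovery.
#'
#' @param config a [sim_config()] (default configuration if omitted).
#' @return object of class `"cohort_bundle"`: `locus`, `groups`,
#'   `fractions`, `patterns`, `beta`, `annotation`, `expr`, `ct_expression`,
#'   `ct_qmsp`, `traces`, `ground_truth`, `config`.
#' @seealso [write_cohort()] to materialise the bundle as FASTA/BED/TSV.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  locus <- simulate_locus(config)
  meth <- simulate_methylation(config, locus)
  expr <- simulate_expression(config, meth$fractions, meth$groups)
  traces <- simulate_traces(config, meth$fractions, locus)
  qm <- simulate_qmsp(config, meth$fractions, meth$groups)
  structure(list(locus = locus, groups = meth$groups,
                 fractions = meth$fractions, patterns = meth$patterns,
                 beta = meth$beta, annotation = meth$annotation,
                 expr = expr$expr, ct_expression = expr$ct,
                 ct_qmsp = qm, traces = traces,
                 ground_truth = expr$latent, config = config),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("<cohort_bundle> ", nrow(x$groups), " samples (",
      paste(sprintf("%s=%d", names(table(x$groups$group)),
                    as.integer(table(x$groups$group))), collapse = ", "),
      "); locus ", format_interval(x$locus$interval),
      "; seed ", x$config$seed, "\n", sep = "")
  invisible(x)
}
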