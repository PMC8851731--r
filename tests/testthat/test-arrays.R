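test_that("beta_from_signals is M/(M+U) with missing on zero signal", {
  expect_equal(beta_from_signals(300, 100), 0.75)
  expect_equal(beta_from_signals(0, 500), 0)
  expect_equal(beta_from_signals(500, 0), 1)
  expect_true(is.na(beta_from_signals(0, 0)))
  expect_error(beta_from_signals(-1, 5), "non-negative")
  set.seed(12)
  m <- runif(100, 0, 5000); u <- runif(100, 0, 5000)
  b <- beta_from_signals(m, u)
  expect_true(all(b >= 0 & b <= 1))
})

test_that("quantile normalisation equalises column distributions", {
  # two-column closed form
  out <- quantile_normalize(cbind(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(unname(out[, "a"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out[, "b"]), c(2.5, 3.5, 4.5))
  # identical columns are a fixed point
  m <- cbind(x = c(5, 1, 3), y = c(5, 1, 3))
  expect_equal(quantile_normalize(m), m)
  expect_warning(quantile_normalize(cbind(z = 1:3)), "single-column")

  set.seed(8)
  for (i in 1:100) {
    mat <- matrix(rnorm(20), 5, 4)
    qn <- quantile_normalize(mat)
    # independent rank-average oracle via order()
    ref <- rowMeans(apply(mat, 2, sort))
    oracle <- mat
    for (j in 1:4) oracle[order(mat[, j]), j] <- ref
    expect_equal(qn, oracle)
    # column sorted multisets identical, grand mean preserved
    for (j in 2:4) expect_equal(sort(qn[, j]), sort(qn[, 1]))
    expect_equal(mean(qn), mean(mat))
  }
  # cross-check against limma on one matrix
  mat <- matrix(rnorm(40), 10, 4)
  expect_equal(unname(quantile_normalize(mat)),
               unname(limma::normalizeQuantiles(mat)))
})

test_that("quantile normalisation drops incomplete rows with a message", {
  mat <- matrix(rnorm(20), 5, 4)
  mat[2, 3] <- NA
  expect_message(out <- quantile_normalize(mat), "1 row")
  expect_equal(nrow(out), 4)
})

test_that("delta_beta is the difference of group means", {
  b <- rbind(cg1 = c(s1 = 0.8, s2 = 0.6, s3 = 0.3, s4 = 0.3))
  expect_equal(delta_beta(b, c("s1", "s2"), c("s3", "s4"), "cg1"), 0.4)
  expect_equal(delta_beta(b, c("s1", "s2"), c("s1", "s2"), "cg1"), 0)
  # group means 0.66 vs 0.30 give the hypermethylation magnitude 0.36
  b2 <- rbind(p = c(a1 = 0.70, a2 = 0.62, b1 = 0.28, b2 = 0.32))
  expect_equal(delta_beta(b2, c("a1", "a2"), c("b1", "b2"), "p"), 0.36)
  expect_error(delta_beta(b, c("s1"), c("s2"), "cgX"), "not found")
  expect_true(abs(delta_beta(b, "s1", "s4", "cg1")) <= 1)
})

test_that("classify_beta is a total monotone step function on [0,1]", {
  expect_identical(classify_beta(0.2), "unmethylated")
  expect_identical(classify_beta(0.5), "partial")
  expect_identical(classify_beta(0.7), "methylated")  # boundary to methylated
  expect_identical(classify_beta(c(0, 0.299, 0.3, 0.699, 1)),
                   c("unmethylated", "unmethylated", "partial", "partial",
                     "methylated"))
  grid <- seq(0, 1, by = 0.001)
  lev <- match(classify_beta(grid), c("unmethylated", "partial", "methylated"))
  expect_false(anyNA(lev))
  expect_true(all(diff(lev) >= 0))
  expect_error(classify_beta(-0.1), "0, 1")
})

test_that("dichotomisation partitions samples at the Beta cut", {
  b <- rbind(cg = c(s1 = 0.1, s2 = 0.2, s3 = 0.8, s4 = 0.9))
  d <- dichotomize_by_probe(b, "cg", 0.3)
  expect_setequal(d$methylated, c("s3", "s4"))
  expect_setequal(d$unmethylated, c("s1", "s2"))
  # all below the cut: one empty group, warning
  b_low <- rbind(cg = c(s1 = 0.1, s2 = 0.2))
  expect_warning(d2 <- dichotomize_by_probe(b_low, "cg", 0.5), "empty group")
  expect_length(d2$methylated, 0)
  # missing Beta excluded with a message
  b_na <- rbind(cg = c(s1 = 0.1, s2 = NA, s3 = 0.9))
  expect_message(d3 <- dichotomize_by_probe(b_na, "cg"), "s2")
  expect_identical(d3$excluded, "s2")

  # threshold-scan oracle on a seeded cohort
  set.seed(14)
  bb <- rbind(p = setNames(runif(30), sprintf("s%02d", 1:30)))
  d4 <- dichotomize_by_probe(bb, "p", 0.3)
  expect_setequal(d4$methylated, colnames(bb)[bb["p", ] >= 0.3])
})

test_that("methylation-expression association recovers programmed coupling", {
  # exact anti-linearity: r = -1
  samples <- sprintf("s%02d", 1:10)
  beta <- rbind(p = setNames(seq(0.05, 0.95, length.out = 10), samples))
  expr <- rbind(f = setNames(-beta["p", ], samples))
  res <- methylation_expression_association(beta, expr, "p", "f")
  expect_equal(res$correlation$statistic, -1)

  # independent vectors: |r| < 0.25 at n = 100
  set.seed(40)
  s100 <- sprintf("s%03d", 1:100)
  b0 <- rbind(p = setNames(runif(100), s100))
  e0 <- rbind(f = setNames(rnorm(100), s100))
  res0 <- methylation_expression_association(b0, e0, "p", "f")
  expect_lt(abs(res0$correlation$statistic), 0.25)

  # coupled synthetic cohort: strong negative r, significant group contrast
  cfg <- sim_config(seed = 31, n_bone = 5, n_tumour_methylated = 6,
                    n_tumour_unmethylated = 5, n_xenograft = 4)
  bundle <- simulate_cohort(cfg)
  probe <- bundle$annotation$probe[bundle$annotation$standin == "cg00176210"]
  res1 <- methylation_expression_association(bundle$beta, bundle$expr,
                                             probe, "miR-486-5p")
  expect_lt(res1$correlation$statistic, -0.5)
  expect_lt(res1$group_test$p, 0.05)

  # constant Beta: correlation is a no-call, not an error
  b_const <- rbind(p = setNames(rep(0.5, 10), samples))
  res_c <- suppressWarnings(
    methylation_expression_association(b_const, expr, "p", "f"))
  expect_true(is.na(res_c$correlation$statistic))
})

test_that("the coupling sign is recovered across seeded replicates", {
  # with slope b >= 2 and n = 20, r is negative in >= 95/100 replicates
  negatives <- 0L
  for (seed in 1:100) {
    cfg <- sim_config(seed = seed, n_bone = 5, n_tumour_methylated = 5,
                      n_tumour_unmethylated = 5, n_xenograft = 5,
                      coupling_b = 2)
    locus <- simulate_locus(cfg)
    meth <- simulate_methylation(cfg, locus)
    expr <- simulate_expression(cfg, meth$fractions, meth$groups)
    probe <- meth$annotation$probe[meth$annotation$standin == "cg00176210"]
    r <- pearson_r(meth$beta[probe, ], expr$expr["miR-486-5p", ])$statistic
    if (r < 0) negatives <- negatives + 1L
  }
  expect_gte(negatives, 95L)
})

test_that("correlation with and without an outlier are both reported", {
  # collinear data plus one extreme off-line point
  x <- c(1:11, 2)
  y <- c(2 * (1:11) + 3, 40)
  labels <- c(sprintf("cl%02d", 1:11), "MG-63")
  res <- correlation_with_outlier(x, y, labels, "MG-63")
  expect_equal(res$r_without$statistic, 1)
  expect_lt(res$r_all$statistic, res$r_without$statistic)
  expect_equal(res$n_removed, 1)

  # outlier on the line: both correlations agree
  x2 <- 1:12; y2 <- 3 * (1:12) - 1
  res2 <- correlation_with_outlier(x2, y2, labels, "MG-63")
  expect_equal(res2$r_all$statistic, res2$r_without$statistic)

  # seeded cohort: 11 near-collinear lines + one high-expression outlier
  set.seed(3)
  xs <- rnorm(11); ys <- 1.5 * xs + rnorm(11, 0, 0.15)
  res3 <- correlation_with_outlier(c(xs, 0), c(ys, 8), labels, "MG-63")
  expect_gte(res3$r_without$statistic, 0.9)
  expect_error(correlation_with_outlier(x, y, labels, "absent"),
               "not among")
})

test_that("locus_profile orders probes and summarises per group", {
  ann <- data.frame(probe = c("p3", "p1", "p2"), chrom = "chr1",
                    start = c(300, 100, 200), end = c(302, 102, 202),
                    cgi = c("", "CpG10", "CpG10"))
  betas <- rbind(p1 = c(a = 0.1, b = 0.3), p2 = c(a = 0.2, b = 0.4),
                 p3 = c(a = 0.9, b = 0.8))
  groups <- data.frame(sample = c("a", "b"), group = c("g1", "g2"))
  prof <- locus_profile(betas, ann, genomic_interval("chr1", 0, 400), groups)
  expect_identical(prof$probe, c("p1", "p2", "p3"))
  expect_equal(prof$mean_beta_g1, c(0.1, 0.2, 0.9))
  expect_equal(prof$mean_beta_g2, c(0.3, 0.4, 0.8))
  expect_identical(attr(prof, "n_cgi_probes"), 2L)

  # probes outside the interval are excluded
  prof2 <- locus_profile(betas, ann, genomic_interval("chr1", 150, 400),
                         groups)
  expect_identical(prof2$probe, c("p2", "p3"))
  expect_warning(
    locus_profile(betas, ann, genomic_interval("chr1", 500, 600), groups),
    "no probes")

  # synthetic locus: row count equals an annotation-filter oracle
  bundle <- simulate_cohort(small_config(seed = 61))
  prof3 <- locus_profile(bundle$beta, bundle$annotation,
                         bundle$locus$interval, bundle$groups)
  expect_identical(attr(prof3, "n_probes"),
                   sum(bundle$annotation$start >= 0 &
                         bundle$annotation$start <
                           bundle$locus$interval$end))
  expect_identical(attr(prof3, "n_cgi_probes"),
                   sum(bundle$annotation$cgi != ""))
  # island probes are hypermethylated in tumours, flanks in everyone
  cgi_rows <- prof3$cgi != ""
  expect_gt(mean(prof3$mean_beta_tumour_methylated[cgi_rows]),
            mean(prof3$mean_beta_bone[cgi_rows]) + 0.4)
})
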