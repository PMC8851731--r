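# Small-sample statistics used across the package. Pearson correlation and the
# paired t-test are delegated to base R; the Mann-Whitney U test is authored
# here because its exact/approximate switchover, tie handling and continuity
# correction must be pinned for reproducibility (see mann_whitney_u).

.test_result <- function(statistic, p, method, n, note = NULL, ...) {
  structure(c(list(statistic = statistic, p = p, method = method, n = n,
                   note = note), list(...)),
            class = "methyl_test")
}

#' @export
print.methyl_test <- function(x, ...) {
  cat("<methyl_test> ", x$method, ": statistic = ",
      format(x$statistic, digits = 4), ", p = ", format(x$p, digits = 4),
      ", n = ", paste(x$n, collapse = "/"),
      if (!is.null(x$note)) paste0("  [", x$note, "]"), "\n", sep = "")
  invisible(x)
}

#' Pearson correlation with two-sided p-value
#'
#' Correlation between two paired vectors; the p-value comes from the
#' t-transform with `n - 2` degrees of freedom (base [stats::cor.test()]).
#' Pairs with a missing value in either vector are dropped. A constant vector
#' makes the correlation undefined and yields a no-call (`NA` statistic and
#' p) rather than an error, so cohort loops keep running.
#'
#' @param x,y numeric vectors of equal length; at least 3 complete pairs.
#' @return a `"methyl_test"` with fields `statistic` (r), `p`, `method`
#'   (`"pearson"`), `n`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3)
    stop("pearson_r needs at least 3 complete pairs, got ", n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(.test_result(NA_real_, NA_real_, "pearson", n,
                        note = "undefined: constant input"))
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  .test_result(unname(ct$estimate), ct$p.value, "pearson", n)
}

# Exact two-sided Mann-Whitney p by full enumeration of the C(n, na) rank
# assignments. Only valid without ties; the U null is then symmetric so the
# tail-doubling and |U - mu| definitions coincide. The enumerated null for
# each (na, nb) is cached for the session.
.mwu_null_cache <- new.env(parent = emptyenv())

.mwu_exact_p <- function(u_obs, na, nb) {
  key <- paste(na, nb)
  u_all <- .mwu_null_cache[[key]]
  if (is.null(u_all)) {
    n <- na + nb
    splits <- utils::combn(n, na)
    u_all <- colSums(matrix(seq_len(n)[splits], nrow = na)) -
      na * (na + 1) / 2
    .mwu_null_cache[[key]] <- u_all
  }
  mu <- na * nb / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

#' Mann-Whitney U test (exact small-sample, tie-corrected otherwise)
#'
#' Rank-sum comparison of two independent groups. When the combined sample
#' size is at most 12 and there are no ties, the two-sided p-value is exact,
#' computed by full enumeration of all rank assignments. Otherwise a normal
#' approximation with midranks, tie-corrected variance and a 0.5 continuity
#' correction is used. The `method` field records which path was taken.
#'
#' @param a,b numeric vectors (each n >= 1); `NA`s dropped.
#' @return a `"methyl_test"` with `statistic` = U for group `a` (number of
#'   (a, b) pairs with a > b, counting ties as 1/2), `p`, `method`
#'   (`"mann-whitney-exact"` or `"mann-whitney-normal"`), `n = c(na, nb)`.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
#' @export
mann_whitney_u <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  na <- length(a); nb <- length(b)
  if (na < 1 || nb < 1) stop("each group needs at least one observation")
  pooled <- c(a, b)
  r <- rank(pooled)                       # midranks
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0
  if (!has_ties && na + nb <= 12) {
    p <- .mwu_exact_p(u, na, nb)
    return(.test_result(u, p, "mann-whitney-exact", c(na, nb)))
  }
  n <- na + nb
  mu <- na * nb / 2
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0)                        # all observations identical
    return(.test_result(u, 1, "mann-whitney-normal", c(na, nb),
                        note = "degenerate: zero variance"))
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  .test_result(u, p, "mann-whitney-normal", c(na, nb))
}

#' Paired t-test for before/after designs
#'
#' Two-sided paired t-test on the differences `after - before`, delegated to
#' base [stats::t.test()]. Zero-variance differences make the statistic
#' undefined and yield a no-call instead of an error.
#'
#' @param before,after numeric vectors of equal length, n >= 2; pairs with a
#'   missing value dropped.
#' @return a `"methyl_test"` with `statistic` (t), `p`, `method`
#'   (`"paired-t"`), `n` (number of complete pairs).
#' @export
paired_t <- function(before, after) {
  stopifnot(length(before) == length(after))
  ok <- is.finite(before) & is.finite(after)
  before <- before[ok]; after <- after[ok]
  n <- length(before)
  if (n < 2) stop("paired_t needs at least 2 complete pairs")
  d <- after - before
  if (stats::sd(d) == 0)
    return(.test_result(NA_real_, NA_real_, "paired-t", n,
                        note = "degenerate: zero-variance differences"))
  tt <- stats::t.test(after, before, paired = TRUE,
                      alternative = "two.sided")
  .test_result(unname(tt$statistic), tt$p.value, "paired-t", n)
}
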