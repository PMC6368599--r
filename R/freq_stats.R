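#' Frequentist test utilities
#'
#' Small wrappers used across the pipeline stages, all returning a uniform
#' `"test_result"` structure: `statistic`, `p_value`, `effect` (test-specific
#' scale), and a 95% confidence interval.
#'
#' @name freq_stats
NULL

.test_result <- function(statistic, p_value, effect, ci_lower = NA_real_,
                         ci_upper = NA_real_, effect_type = NA_character_) {
  structure(list(statistic = statistic, p_value = p_value, effect = effect,
                 ci_lower = ci_lower, ci_upper = ci_upper,
                 effect_type = effect_type),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("statistic %.4g, p = %.4g, %s = %.4g [%.4g, %.4g]\n",
              x$statistic, x$p_value,
              ifelse(is.na(x$effect_type), "effect", x$effect_type),
              x$effect, x$ci_lower, x$ci_upper))
  invisible(x)
}

#' Welch's two-sample t test from summary statistics
#'
#' Operates on (n, mean, sd) summaries so raw patient-level rows never need
#' to leave the preprocessing stage. Two-sided p from the t distribution
#' with Welch-Satterthwaite degrees of freedom.
#'
#' @param a,b numeric vectors `c(n, mean, sd)` (names optional).
#' @return a `test_result`; `effect` is `mean(a) - mean(b)` with a 95%
#'   t-based confidence interval.
#' @export
welch_t <- function(a, b) {
  a <- unname(a); b <- unname(b)
  n1 <- a[1]; m1 <- a[2]; s1 <- a[3]
  n2 <- b[1]; m2 <- b[2]; s2 <- b[3]
  if (n1 < 2 || n2 < 2) stop("welch_t needs n >= 2 in both samples")
  if (s1 < 0 || s2 < 0) stop("standard deviations must be non-negative")
  v1 <- s1^2 / n1; v2 <- s2^2 / n2
  se <- sqrt(v1 + v2)
  eff <- m1 - m2
  if (se == 0) {
    p <- if (eff == 0) 1 else 0
    return(.test_result(if (eff == 0) 0 else sign(eff) * Inf, p, eff,
                        eff, eff, "mean difference"))
  }
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  tstat <- eff / se
  p <- 2 * stats::pt(-abs(tstat), df)
  crit <- stats::qt(0.975, df)
  .test_result(tstat, p, eff, eff - crit * se, eff + crit * se,
               "mean difference")
}

#' Two-sided Mann-Whitney U test
#'
#' Exact p value for small samples without ties, normal approximation with
#' tie correction otherwise (via [stats::wilcox.test()]). The effect is the
#' unpaired difference of sample medians.
#'
#' @param a,b numeric samples.
#' @param exact_max use the exact distribution when both sample sizes are
#'   at most this and there are no ties.
#' @return a `test_result`; `statistic` is the U statistic for sample `a`.
#' @export
mann_whitney_u <- function(a, b, exact_max = 20) {
  stopifnot(length(a) > 0, length(b) > 0)
  exact <- length(a) <= exact_max && length(b) <= exact_max &&
    !anyDuplicated(c(a, b))
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = !exact))
  .test_result(unname(wt$statistic), wt$p.value,
               stats::median(a) - stats::median(b),
               effect_type = "median difference")
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p by the probability-mass method: the sum of hypergeometric
#' probabilities of all tables as or less probable than the observed one
#' (the [stats::fisher.test()] convention). The effect is the sample odds
#' ratio with the conditional-likelihood confidence interval.
#'
#' @param tab 2x2 matrix of non-negative integers.
#' @return a `test_result`; with a zero margin the test is undefined and
#'   `p = 1` with an `NA` effect is returned.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0), all(tab == round(tab)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(.test_result(NA_real_, 1, NA_real_, effect_type = "odds ratio"))
  ft <- stats::fisher.test(tab)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  .test_result(unname(tab[1, 1]), ft$p.value, or,
               ft$conf.int[1], ft$conf.int[2], "odds ratio")
}

#' Variance-ratio F test
#'
#' Compares the variances of two approximately normal samples; the effect
#' is `var(a)/var(b)` with an F-distribution confidence interval. Normality
#' is the caller's responsibility.
#'
#' @param a,b numeric samples with at least 2 values each.
#' @return a `test_result`.
#' @export
variance_ratio_f <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::var(b) == 0) stop("variance of `b` is zero")
  vt <- stats::var.test(a, b)
  .test_result(unname(vt$statistic), vt$p.value, unname(vt$estimate),
               vt$conf.int[1], vt$conf.int[2], "variance ratio")
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment, preserving input
#' order.
#'
#' @param p numeric vector of p values in `[0, 1]` (`NA` allowed and
#'   propagated).
#' @return adjusted values, same length and order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param x,y equal-length numeric vectors, n >= 4.
#' @return a `test_result`; `effect` is r.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in input to pearson_r")
  ct <- stats::cor.test(x, y, method = "pearson")
  .test_result(unname(ct$statistic), ct$p.value, unname(ct$estimate),
               ct$conf.int[1], ct$conf.int[2], "correlation")
}
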