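#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed sample skewness (D'Agostino 1970) and kurtosis
#' (Anscombe & Glynn 1983) z scores into the omnibus statistic
#' K2 = Z1^2 + Z2^2, referred to a chi-square distribution with 2 df.
#'
#' @param x numeric vector, n >= 8.
#' @return A list with `statistic` (K2), `p_value`, and the component
#'   z scores `z_skew`, `z_kurt`.
#' @export
dagostino_pearson <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8L) stop("D'Agostino-Pearson test requires n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  b1 <- m3 / m2^1.5      # sample skewness g1
  b2 <- m4 / m2^2        # sample kurtosis g2 (not excess)
  # skewness: D'Agostino (1970)
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis: Anscombe & Glynn (1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))
  k2 <- z1^2 + z2^2
  list(statistic = k2,
       p_value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2)
}

new_comparison <- function(means, sems, ns, diff, test, stat, df, p, norm_p) {
  structure(list(means = means, sems = sems, n = ns, mean_diff = diff,
                 test = test, statistic = unname(stat), df = df,
                 p_value = unname(p), normality_p = norm_p),
            class = "pwave_comparison")
}

#' @export
print.pwave_comparison <- function(x, ...) {
  df_txt <- if (is.null(x$df) || is.na(x$df)) "" else sprintf(", df = %.1f", x$df)
  cat(sprintf("<%s> means %s, diff %.4g, stat %.4g%s, p = %.4g\n",
              x$test, paste(sprintf("%.4g", x$means), collapse = " vs "),
              x$mean_diff, x$statistic, df_txt, x$p_value))
  invisible(x)
}

sem <- function(x) stats::sd(x) / sqrt(length(x))

# Normality gate used by both comparisons: the K2 test needs n >= 8;
# smaller samples are treated as parametric (the t test is the default path).
gate_normal <- function(x, alpha = 0.05) {
  if (length(x) < 8L) return(list(normal = TRUE, p = NA_real_))
  p <- dagostino_pearson(x)$p_value
  list(normal = p > alpha, p = p)
}

#' Paired pre/post comparison
#'
#' A paired t test on the differences `pre - post` when their distribution
#' is not rejected by the D'Agostino-Pearson test at `alpha` (samples with
#' n < 8 default to the t test); otherwise the Wilcoxon signed-rank test.
#' The result records which path ran.
#'
#' @param pre,post equal-length numeric vectors (n >= 3).
#' @param alpha normality rejection level for the gate.
#' @return A `pwave_comparison` with fields `means`, `sems`, `mean_diff`
#'   (mean of `pre - post`), `test` (`"paired-t"` or `"signed-rank"`),
#'   `statistic`, `df`, `p_value`, `normality_p`.
#' @export
paired_compare <- function(pre, post, alpha = 0.05) {
  if (length(pre) != length(post)) stop("length mismatch between pre and post")
  if (length(pre) < 3L) stop("need at least 3 pairs")
  d <- pre - post
  if (stats::sd(d) == 0)
    stop("degenerate paired data: zero-variance differences")
  g <- gate_normal(d, alpha)
  if (g$normal) {
    tt <- stats::t.test(pre, post, paired = TRUE)
    new_comparison(c(pre = mean(pre), post = mean(post)),
                   c(pre = sem(pre), post = sem(post)),
                   length(pre), mean(d), "paired-t",
                   tt$statistic, unname(tt$parameter), tt$p.value, g$p)
  } else {
    wt <- stats::wilcox.test(pre, post, paired = TRUE, exact = FALSE,
                             correct = TRUE)
    new_comparison(c(pre = mean(pre), post = mean(post)),
                   c(pre = sem(pre), post = sem(post)),
                   length(pre), mean(d), "signed-rank",
                   wt$statistic, NA_real_, wt$p.value, g$p)
  }
}

#' Unpaired (two-group) comparison
#'
#' Welch's t test on the two samples when neither is rejected by the
#' normality gate; the Wilcoxon rank-sum test otherwise. Typically applied
#' to per-patient pre-to-post change scores of the two study arms.
#'
#' @param a,b numeric vectors (each n >= 3).
#' @param alpha normality rejection level.
#' @param var_equal use the pooled-variance Student t instead of Welch.
#' @return A `pwave_comparison`; `mean_diff` is `mean(a) - mean(b)`.
#' @export
unpaired_compare <- function(a, b, alpha = 0.05, var_equal = FALSE) {
  if (length(a) < 3L || length(b) < 3L)
    stop("need at least 3 observations per group")
  ga <- gate_normal(a, alpha); gb <- gate_normal(b, alpha)
  norm_p <- c(a = ga$p, b = gb$p)
  if (ga$normal && gb$normal) {
    tt <- stats::t.test(a, b, var.equal = var_equal)
    new_comparison(c(a = mean(a), b = mean(b)), c(a = sem(a), b = sem(b)),
                   c(length(a), length(b)), mean(a) - mean(b),
                   if (var_equal) "student-t" else "welch-t",
                   tt$statistic, unname(tt$parameter), tt$p.value, norm_p)
  } else {
    wt <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    new_comparison(c(a = mean(a), b = mean(b)), c(a = sem(a), b = sem(b)),
                   c(length(a), length(b)), mean(a) - mean(b), "rank-sum",
                   wt$statistic, NA_real_, wt$p.value, norm_p)
  }
}

#' Intraobserver variability between two measurement runs
#'
#' For paired measurement vectors of the same recordings analysed twice,
#' reports the mean absolute inter-run difference, its SEM, and the
#' percentage variability (mean absolute difference divided by the mean
#' absolute parameter value across both runs, x100).
#'
#' @param run1,run2 equal-length numeric vectors.
#' @return A list of class `variability_result`: `mean_abs_diff`, `sem`,
#'   `percent`, `n`.
#' @export
intraobserver_variability <- function(run1, run2) {
  if (length(run1) != length(run2)) stop("length mismatch between runs")
  d <- abs(run1 - run2)
  denom <- mean(abs(c(run1, run2)))
  structure(list(mean_abs_diff = mean(d), sem = sem(d),
                 percent = if (denom > 0) mean(d) / denom * 100 else 0,
                 n = length(d)),
            class = "variability_result")
}
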