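#' Pooled two-proportion z test
#'
#' The binomial proportions test used for the cohort comparisons: the
#' two-sample z statistic with pooled variance,
#' z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2)) with p the pooled proportion,
#' and a two-sided p-value from the normal distribution. With zero pooled
#' variance (no successes or no failures anywhere) the proportions are equal
#' and p = 1.
#'
#' @param x1,n1 successes and trials in cohort 1.
#' @param x2,n2 successes and trials in cohort 2.
#' @return a list of class `prop_test_result`: `x1`, `n1`, `x2`, `n2`, `p1`,
#'   `p2`, `z`, `p_value`.
#' @export
two_proportion_test <- function(x1, n1, x2, n2) {
  if (n1 <= 0 || n2 <= 0) stopf("trial counts must be positive")
  if (x1 < 0 || x2 < 0 || x1 > n1 || x2 > n2) {
    stopf("successes must lie in [0, n]")
  }
  p1 <- x1 / n1
  p2 <- x2 / n2
  pool <- (x1 + x2) / (n1 + n2)
  v <- pool * (1 - pool) * (1 / n1 + 1 / n2)
  if (v <= 0) {
    z <- 0
    p <- 1
  } else {
    z <- (p1 - p2) / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(x1 = x1, n1 = n1, x2 = x2, n2 = n2, p1 = p1, p2 = p2,
                 z = z, p_value = p),
            class = "prop_test_result")
}

#' @export
print.prop_test_result <- function(x, ...) {
  cat(sprintf("two-proportion z test: %d/%d (%.1f%%) vs %d/%d (%.1f%%), z = %.3f, p = %.3g\n",
              x$x1, x$n1, 100 * x$p1, x$x2, x$n2, 100 * x$p2,
              x$z, x$p_value))
  invisible(x)
}

#' Two-sample t test from summary statistics
#'
#' Student's t test between two cohorts given only n, mean and standard
#' deviation per cohort (the form needed to compare published demographic
#' summaries). Pooled-variance Student form by default; Welch as an option.
#'
#' @param n1,mean1,sd1 summary of cohort 1 (n at least 2, sd non-negative).
#' @param n2,mean2,sd2 summary of cohort 2.
#' @param var_equal pooled-variance Student form (default) or Welch.
#' @return a list `t`, `df`, `p_value` (two-sided).
#' @export
t_test_means <- function(n1, mean1, sd1, n2, mean2, sd2, var_equal = TRUE) {
  if (n1 < 2 || n2 < 2) stopf("each cohort needs n >= 2")
  if (sd1 < 0 || sd2 < 0) stopf("standard deviations must be non-negative")
  if (var_equal) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    a <- sd1^2 / n1
    b <- sd2^2 / n2
    se <- sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
  }
  if (se == 0) {
    t <- 0
    p <- 1
  } else {
    t <- (mean1 - mean2) / se
    p <- 2 * stats::pt(-abs(t), df)
  }
  list(t = t, df = df, p_value = p)
}

#' One-tailed Fisher exact p-value for a 2x2 table
#'
#' Exact hypergeometric tail probability of the observed or a more extreme
#' split given fixed margins — identical to
#' `fisher.test(alternative = "greater")` on the table
#' `rbind(c(x1, n1 - x1), c(x2, n2 - x2))`, but vectorised.
#'
#' @param x1,n1,x2,n2 successes and trials per arm (vectorised).
#' @return P(X >= x1) under the null of equal proportions.
#' @export
fisher_one_tailed_p <- function(x1, n1, x2, n2) {
  m <- x1 + x2
  stats::phyper(x1 - 1, m, n1 + n2 - m, n1, lower.tail = FALSE)
}

#' Monte-Carlo power of the one-tailed Fisher exact test
#'
#' Simulates two-arm binomial outcomes at the baseline event rate and at the
#' reduced rate `baseline_rate * (1 - relative_reduction)`, applies the
#' one-tailed Fisher exact test (control arm larger) at level `alpha` to each
#' replicate, and reports the rejection fraction. Reproducible under a fixed
#' seed; the global RNG state is untouched.
#'
#' @param baseline_rate event rate in the control arm, in (0,1).
#' @param relative_reduction relative rate reduction in the second arm
#'   (0 for the null).
#' @param n_per_arm encounters per arm.
#' @param alpha test level.
#' @param tails `"one"` (default) or `"two"`.
#' @param replicates Monte-Carlo replicates (at least 1000 for reporting).
#' @param seed RNG seed (mandatory).
#' @return a list of class `power_estimate` with the design parameters and
#'   `power`, the rejection fraction.
#' @export
fisher_power_simulation <- function(baseline_rate, relative_reduction,
                                    n_per_arm, alpha = 0.04,
                                    tails = c("one", "two"),
                                    replicates = 1000, seed) {
  tails <- match.arg(tails)
  stopifnot(baseline_rate > 0, baseline_rate < 1,
            relative_reduction >= 0, relative_reduction < 1,
            n_per_arm >= 1, replicates >= 1)
  p2 <- baseline_rate * (1 - relative_reduction)
  pvals <- withr::with_seed(seed, {
    x1 <- stats::rbinom(replicates, n_per_arm, baseline_rate)
    x2 <- stats::rbinom(replicates, n_per_arm, p2)
    if (tails == "one") {
      fisher_one_tailed_p(x1, n_per_arm, x2, n_per_arm)
    } else {
      vapply(seq_len(replicates), function(i) {
        stats::fisher.test(matrix(c(x1[i], n_per_arm - x1[i],
                                    x2[i], n_per_arm - x2[i]),
                                  nrow = 2, byrow = TRUE))$p.value
      }, numeric(1))
    }
  })
  structure(list(baseline_rate = baseline_rate,
                 relative_reduction = relative_reduction,
                 n_per_arm = n_per_arm, alpha = alpha, tails = tails,
                 replicates = replicates, seed = seed,
                 power = mean(pvals <= alpha)),
            class = "power_estimate")
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf("Fisher %s-tailed power: %.3f (baseline %.3f, reduction %.0f%%, n = %d/arm, alpha = %.3f, %d reps)\n",
              x$tails, x$power, x$baseline_rate, 100 * x$relative_reduction,
              x$n_per_arm, x$alpha, x$replicates))
  invisible(x)
}
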