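#' Summarize one group of measurements
#'
#' Mean and sample standard deviation (n - 1 denominator), the summary
#' form used for every group comparison in cohort tables. Can also be
#' constructed directly from published summary statistics.
#'
#' @param values Numeric vector (at least one value), or `NULL` when
#'   `n`, `mean`, `sd` are given directly.
#' @param n,mean,sd Summary statistics, used when `values` is `NULL`.
#' @return Object of class `"group_summary"` with `n`, `mean`, `sd`.
#' @export
group_summary <- function(values = NULL, n = NULL, mean = NULL, sd = NULL) {
  if (!is.null(values)) {
    if (length(values) == 0) stop("cannot summarize an empty group")
    n <- length(values)
    mean <- base::mean(values)
    sd <- if (n >= 2) stats::sd(values) else NA_real_
  } else {
    stopifnot(!is.null(n), !is.null(mean), !is.null(sd))
  }
  structure(list(n = as.integer(n), mean = mean, sd = sd),
            class = "group_summary")
}

as_group_summary <- function(x) {
  if (inherits(x, "group_summary")) x else group_summary(x)
}

#' Two-tailed unpaired Student's t test
#'
#' Pooled-variance Student's t test (the classical equal-variance form) on
#' two independent groups, each given either as raw values or as a
#' [group_summary()] — the pooled form needs only n, mean and sd, so
#' published summaries can stand in for unavailable raw data. Degrees of
#' freedom are `n1 + n2 - 2`; the p-value is two-tailed. Set
#' `var_equal = FALSE` for the Welch form instead.
#'
#' Degenerate inputs: two groups with zero pooled variance and equal
#' means give `t = 0, p = 1`; zero pooled variance with unequal means
#' gives `p = 0` with a warning.
#'
#' @param group_a,group_b Numeric vectors (n >= 2) or `group_summary`
#'   objects.
#' @param var_equal Pooled-variance Student form when `TRUE` (default);
#'   Welch-Satterthwaite otherwise.
#' @return List of class `"t_test_result"`: `t_statistic`, `df`,
#'   `p_two_tailed`, plus both group summaries.
#' @export
students_t_test <- function(group_a, group_b, var_equal = TRUE) {
  a <- as_group_summary(group_a)
  b <- as_group_summary(group_b)
  if (a$n < 2 || b$n < 2) stop("each group needs at least two observations")
  if (var_equal) {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  } else {
    va <- a$sd^2 / a$n
    vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  if (se == 0) {
    if (a$mean == b$mean) {
      t_stat <- 0; p <- 1
    } else {
      warning("zero pooled variance with unequal means; p -> 0")
      t_stat <- sign(a$mean - b$mean) * Inf; p <- 0
    }
  } else {
    t_stat <- (a$mean - b$mean) / se
    p <- 2 * stats::pt(-abs(t_stat), df)
  }
  structure(list(t_statistic = t_stat, df = df, p_two_tailed = p,
                 group_a = a, group_b = b),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf(
    "Student's t test (two-tailed): t = %.3f, df = %.4g, p = %.4g\n",
    x$t_statistic, x$df, x$p_two_tailed))
  cat(sprintf("  group A: n = %d, mean = %.3f, sd = %.3f\n",
              x$group_a$n, x$group_a$mean, x$group_a$sd))
  cat(sprintf("  group B: n = %d, mean = %.3f, sd = %.3f\n",
              x$group_b$n, x$group_b$mean, x$group_b$sd))
  invisible(x)
}
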