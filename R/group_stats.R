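#' Group summary statistics
#'
#' @param label group label.
#' @param n number of subjects (>= 2).
#' @param mean,sd group mean and standard deviation (sd >= 0).
#' @return A `group_summary` list.
#' @export
group_summary <- function(label, n, mean, sd) {
  if (n < 2) stopf("'n' must be >= 2")
  if (sd < 0) stopf("'sd' must be >= 0")
  structure(list(label = label, n = as.integer(n), mean = mean, sd = sd),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary> %s: n=%d, %.3f +/- %.3f\n",
              x$label, x$n, x$mean, x$sd))
  invisible(x)
}

new_test_result <- function(t, df, p, mean_difference, test) {
  structure(list(t = t, df = df, p_two_sided = p,
                 mean_difference = mean_difference, test = test),
            class = "vep_test_result")
}

#' @export
print.vep_test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: t(%g) = %.4f, p = %.4g, diff = %.4f\n",
              x$test, x$df, x$t, x$p_two_sided, x$mean_difference))
  invisible(x)
}

#' Shapiro-Wilk normality screen
#'
#' Normality check applied to per-group values before t-testing. The
#' result is reported, never used to switch tests silently.
#'
#' @param values numeric vector, 3 <= n <= 5000, non-constant.
#' @return A list with `W` and `p`.
#' @export
normality_test <- function(values) {
  n <- length(values)
  if (n < 3 || n > 5000) stopf("Shapiro-Wilk requires 3 <= n <= 5000 (got %d)", n)
  if (stats::sd(values) == 0) stopf("Shapiro-Wilk undefined for a constant sample")
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Pooled two-sample Student t-test on raw values
#'
#' Classical equal-variance two-sided Student t-test: the pooled variance
#' uses `n1 + n2 - 2` degrees of freedom. Difference is `mean(a) -
#' mean(b)`.
#'
#' @param group_a,group_b numeric vectors, each with >= 2 values.
#' @return A `vep_test_result`.
#' @export
ttest_raw <- function(group_a, group_b) {
  n1 <- length(group_a); n2 <- length(group_b)
  if (n1 < 2 || n2 < 2) stopf("each group needs >= 2 values")
  ttest_summary(group_summary("a", n1, mean(group_a), stats::sd(group_a)),
                group_summary("b", n2, mean(group_b), stats::sd(group_b)))
}

#' Pooled two-sample Student t-test from summary statistics
#'
#' Worked-example mode: recomputes the pooled t-test from printed group
#' means, SDs and sizes. Algebraically identical to [ttest_raw()] on the
#' underlying values.
#'
#' @param a,b [group_summary()] objects.
#' @return A `vep_test_result`.
#' @export
#' @examples
#' # published single-trial VEP comparison: p rounds to 0.007
#' ttest_summary(group_summary("EM", 20, 0.824, 0.661),
#'               group_summary("HV", 20, 0.250, 0.605))
ttest_summary <- function(a, b) {
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  if (a$sd == 0 && b$sd == 0) stopf("zero pooled variance")
  df <- a$n + b$n - 2L
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
  se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  t <- (a$mean - b$mean) / se
  new_test_result(t, df, 2 * stats::pt(-abs(t), df), a$mean - b$mean,
                  "pooled two-sample Student t")
}

#' Compare the two groups of a cohort results table
#'
#' Summarizes each group and runs the pooled Student t-test on the chosen
#' metric, with a Shapiro-Wilk screen per group and an alpha-level
#' decision flag.
#'
#' @param table data.frame with columns `group` and the metric columns
#'   `st_vep_uV` / `n1p1_uV` (as produced by [cohort_table()]).
#' @param metric `"st_vep"` or `"n1p1"`.
#' @param alpha significance level (default 0.05).
#' @return A list: `summaries` (two [group_summary()]s), `normality`
#'   (per-group Shapiro-Wilk), `test` (a `vep_test_result`),
#'   `significant` (logical), `metric`, `alpha`.
#' @export
compare_groups <- function(table, metric = c("st_vep", "n1p1"),
                           alpha = 0.05) {
  metric <- match.arg(metric)
  col <- paste0(metric, "_uV")
  if (!col %in% names(table)) stopf("table lacks column '%s'", col)
  labs <- unique(as.character(table$group))
  if (length(labs) != 2L)
    stopf("expected exactly two groups, found %d", length(labs))
  vals <- lapply(labs, function(g) table[[col]][table$group == g])
  ns <- vapply(vals, length, 1L)
  if (any(ns < 2)) stopf("each group needs >= 2 subjects")
  summaries <- Map(function(lab, v)
    group_summary(lab, length(v), mean(v), stats::sd(v)), labs, vals)
  normality <- lapply(vals, function(v)
    tryCatch(normality_test(v), error = function(e) list(W = NA, p = NA)))
  names(normality) <- labs
  test <- ttest_raw(vals[[1]], vals[[2]])
  list(summaries = summaries, normality = normality, test = test,
       significant = test$p_two_sided < alpha, metric = metric,
       alpha = alpha)
}
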