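#' Group summary (mean, SEM, n)
#'
#' Summary statistics of one group's 930 nm normalized ratios, either
#' computed from raw per-subject values or transcribed from a published
#' table. The group standard deviation is recovered as `sem * sqrt(n)`.
#'
#' @param label Group label.
#' @param n Subject count, >= 2.
#' @param mean Group mean.
#' @param sem Standard error of the mean, >= 0.
#' @return A `group_summary` object.
#' @export
group_summary <- function(label, n, mean, sem) {
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  if (sem < 0) stop("sem must be >= 0", call. = FALSE)
  structure(
    list(label = label, n = as.integer(n), mean = mean, sem = sem,
         sd = sem * sqrt(n)),
    class = "group_summary"
  )
}

#' @rdname group_summary
#' @param values Numeric vector of per-subject values (length >= 2).
#' @export
summarize_group <- function(values, label = "group") {
  if (length(values) < 2) stop("need >= 2 values", call. = FALSE)
  n <- length(values)
  group_summary(label, n, mean(values), stats::sd(values) / sqrt(n))
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary> %s: n=%d, mean=%.4g, sem=%.4g\n",
              x$label, x$n, x$mean, x$sem))
  invisible(x)
}

pooled_sd <- function(a, b) {
  sqrt(((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2))
}

#' Shapiro-Wilk normality test
#'
#' The normality gate applied to each group before the unpaired t-test.
#' Thin wrapper around [stats::shapiro.test()] with the contract made
#' explicit: 3 to 50 non-constant values.
#'
#' @param values Numeric vector, 3 <= n <= 50, not all equal.
#' @return List with `W` and `p`.
#' @export
shapiro_wilk <- function(values) {
  n <- length(values)
  if (n < 3 || n > 50) stop("need 3 <= n <= 50 values", call. = FALSE)
  if (stats::sd(values) == 0) {
    stop("constant input: Shapiro-Wilk is undefined", call. = FALSE)
  }
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Unpaired t-test from group summaries
#'
#' Pooled-variance (Student) two-sample t-test computed from (mean, SEM, n)
#' summaries: per-group SDs are `sem * sqrt(n)`, the pooled variance is
#' `((n1-1) sd1^2 + (n2-1) sd2^2) / (n1+n2-2)`,
#' `t = (m1 - m2) / (sp * sqrt(1/n1 + 1/n2))` with `df = n1 + n2 - 2`, and
#' the two-sided p-value comes from the t distribution. For equal group
#' sizes this reduces to `t = (m1 - m2) / sqrt(sem1^2 + sem2^2)`. Computing
#' summaries from raw values and calling this function reproduces
#' `t.test(..., var.equal = TRUE)` exactly. A Welch variant
#' (`var_equal = FALSE`, Welch-Satterthwaite df) is available; with equal
#' variances and group sizes its t equals the pooled t.
#'
#' @param a,b [group_summary()] objects.
#' @param var_equal Pooled-variance Student test (default) or Welch.
#' @return A `group_comparison`: list with the two summaries,
#'   `t_statistic`, `df`, `p_two_sided`, `cohens_d` and `method`.
#' @examples
#' a <- group_summary("steatosis", 5, 0.762, 0.146)
#' b <- group_summary("healthy", 5, 0.219, 0.081)
#' t_test_summary(a, b)$p_two_sided
#' @export
t_test_summary <- function(a, b, var_equal = TRUE) {
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  delta <- a$mean - b$mean
  if (var_equal) {
    sp <- pooled_sd(a, b)
    df <- a$n + b$n - 2
    if (sp == 0) {
      if (delta != 0) {
        stop("degenerate input: zero pooled SD with unequal means",
             call. = FALSE)
      }
      t <- 0
      d <- 0
    } else {
      t <- delta / (sp * sqrt(1 / a$n + 1 / b$n))
      d <- delta / sp
    }
    method <- "pooled"
  } else {
    va <- a$sem^2
    vb <- b$sem^2
    if (va + vb == 0) {
      if (delta != 0) {
        stop("degenerate input: zero variance with unequal means",
             call. = FALSE)
      }
      t <- 0
      df <- a$n + b$n - 2
    } else {
      t <- delta / sqrt(va + vb)
      df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
    }
    sp <- pooled_sd(a, b)
    d <- if (sp > 0) delta / sp else 0
    method <- "welch"
  }
  p <- if (t == 0) 1 else 2 * stats::pt(-abs(t), df)
  structure(
    list(
      summaries = list(a = a, b = b), t_statistic = t, df = df,
      p_two_sided = p, cohens_d = d, normality_p = NULL, method = method
    ),
    class = "group_comparison"
  )
}

#' Cohen's d from group summaries
#'
#' Standardized mean difference `d = (m1 - m2) / sp` with `sp` the pooled
#' standard deviation; the sign follows `m1 - m2`.
#'
#' @param a,b [group_summary()] objects.
#' @return Scalar effect size.
#' @export
cohens_d_summary <- function(a, b) {
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  sp <- pooled_sd(a, b)
  if (sp == 0) {
    if (a$mean == b$mean) return(0)
    stop("degenerate input: zero pooled SD", call. = FALSE)
  }
  (a$mean - b$mean) / sp
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> %s vs %s (%s): t=%.3f, df=%.3g, p=%.4g, d=%.3f\n",
    x$summaries$a$label, x$summaries$b$label, x$method,
    x$t_statistic, x$df, x$p_two_sided, x$cohens_d
  ))
  if (!is.null(x$normality_p)) {
    cat(sprintf("  Shapiro-Wilk p: %s=%.3g, %s=%.3g\n",
                x$summaries$a$label, x$normality_p[1],
                x$summaries$b$label, x$normality_p[2]))
  }
  invisible(x)
}

#' Two-group comparison with normality gate
#'
#' The full inferential procedure for a 930 nm comparison: Shapiro-Wilk on
#' each group, then the unpaired t-test. If either group fails the gate at
#' `gate_alpha` a warning is emitted and the t-test is still reported,
#' together with a rank-based Mann-Whitney fallback in the `fallback`
#' field. Constant groups (possible when an ROI's ratio peaks exactly at
#' the target wavelength for every subject) get `NA` normality p-values.
#'
#' @param values_a,values_b Per-subject values, length >= 3 each for the
#'   gate (>= 2 for the test itself).
#' @param gate_alpha Normality gate level (default 0.05).
#' @param labels Character pair of group labels.
#' @param var_equal Pooled (default) or Welch t-test.
#' @return A `group_comparison` with `normality_p` (possibly `NA`) and, when
#'   the gate fails, a `fallback` list with the Mann-Whitney statistic and
#'   p-value.
#' @export
compare_groups <- function(values_a, values_b, gate_alpha = 0.05,
                           labels = c("a", "b"), var_equal = TRUE) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop("need >= 2 values per group", call. = FALSE)
  }
  gate_p <- vapply(list(values_a, values_b), function(v) {
    if (length(v) < 3 || stats::sd(v) == 0) return(NA_real_)
    shapiro_wilk(v)$p
  }, numeric(1))
  a <- summarize_group(values_a, labels[1])
  b <- summarize_group(values_b, labels[2])
  cmp <- t_test_summary(a, b, var_equal = var_equal)
  cmp$normality_p <- gate_p
  gate_failed <- any(!is.na(gate_p) & gate_p < gate_alpha)
  if (gate_failed) {
    warning("normality gate failed (Shapiro-Wilk p < ", gate_alpha,
            "); reporting the t-test with a Mann-Whitney fallback",
            call. = FALSE)
    mw <- suppressWarnings(stats::wilcox.test(values_a, values_b))
    cmp$fallback <- list(method = "mann-whitney",
                         statistic = unname(mw$statistic),
                         p_two_sided = mw$p.value)
  }
  cmp
}
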