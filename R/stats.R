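#' Per-unit medians
#'
#' The study-level aggregation: one summary value per acquisition unit
#' (microscope field or experiment); downstream tests operate on these
#' medians, not on pooled raw values. Even-length units use the mean of
#' the two central order statistics. Units with no usable values are
#' excluded with a message.
#'
#' @param data data.frame in long format.
#' @param value,unit,group column names for the measured value, the unit
#'   id, and (optionally) the group label.
#' @return data.frame with one row per unit: `unit`, `median` and, when
#'   `group` is given, the unit's group.
#' @export
per_unit_median <- function(data, value = "value", unit = "unit",
                            group = NULL) {
  stopifnot(all(c(value, unit) %in% names(data)))
  v <- data[[value]]; u <- data[[unit]]
  keep <- !is.na(v)
  dropped <- setdiff(unique(u), unique(u[keep]))
  if (length(dropped) > 0L)
    message(sprintf("excluding unit(s) with no values: %s",
                    paste(dropped, collapse = ", ")))
  v <- v[keep]; u <- u[keep]
  med <- tapply(v, u, stats::median)
  out <- data.frame(unit = names(med), median = as.numeric(med))
  if (!is.null(group)) {
    g <- data[[group]][keep]
    out$group <- as.vector(tapply(g, u, function(x) as.character(x[1L])))
  }
  rownames(out) <- NULL
  out
}

#' Mean and standard error of the mean
#'
#' @param x numeric values.
#' @return List with `mean`, `sem` (= sample SD / sqrt(n)) and `n`. With a
#'   single value the SEM is undefined: `NA` with a warning of class
#'   `myoquant_undefined_warning`.
#' @export
mean_sem <- function(x) {
  x <- as.numeric(x)
  if (length(x) == 0L || anyNA(x)) stop("`x` must be non-empty without NA")
  n <- length(x)
  sem <- if (n < 2L) {
    warn_undefined("SEM undefined for a single value")
    NA_real_
  } else stats::sd(x) / sqrt(n)
  list(mean = mean(x), sem = sem, n = n)
}

#' Two-sided normal-tail p value
#'
#' `p = 2 * (1 - Phi(|z|))` with the standard normal CDF, the mapping that
#' links a rank-sum z statistic to its printed two-sided p value.
#'
#' @param z z statistic(s), finite.
#' @return Two-sided p value(s) in (0, 1].
#' @export
normal_two_sided_p <- function(z) {
  if (any(!is.finite(z))) stop("`z` must be finite")
  pmin(2 * stats::pnorm(-abs(z)), 1)
}

#' Significance stars
#'
#' Star coding with strict thresholds: `*` p < 0.05, `**` p < 0.01,
#' `***` p < 0.001, `****` p < 0.00001; boundary values (e.g. p = 0.05)
#' get no star.
#'
#' @param p p value(s).
#' @return Character vector of `"ns"`, `"*"`, `"**"`, `"***"` or `"****"`.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) return(NA_character_)
    if (pp < 1e-5) "****" else if (pp < 1e-3) "***" else
      if (pp < 1e-2) "**" else if (pp < 0.05) "*" else "ns"
  }, character(1))
}

new_test_result <- function(method, statistic, p, n, degenerate = FALSE) {
  structure(list(method = method, statistic = statistic, p.value = p,
                 n = n, stars = significance_stars(p),
                 degenerate = degenerate),
            class = "myoquant_test")
}

#' @export
print.myoquant_test <- function(x, ...) {
  cat(sprintf("<%s> %s = %.4g, p = %.4g %s (n = %s)%s\n", x$method,
              names(x$statistic)[1L], x$statistic[[1L]], x$p.value,
              if (x$stars == "ns") "" else x$stars,
              paste(x$n, collapse = "/"),
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' Wilcoxon rank-sum test with normal approximation
#'
#' Rank-sum test on two independent groups using midranks for ties, the
#' tie-corrected variance, and no continuity correction; the two-sided p
#' value is `2 * (1 - Phi(|z|))`. This is the z-statistic form whose
#' (z, p) pairs are printed alongside per-field median comparisons.
#'
#' @param x,y numeric values of the two groups (each of length >= 2).
#' @return A test result (class `myoquant_test`) with the z statistic, the
#'   rank sum `W` of `x`, the two-sided p value, group sizes and stars.
#'   When all values are identical across both groups the result is
#'   degenerate with z = 0 and p = 1.
#' @export
wilcoxon_ranksum <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 values")
  if (anyNA(x) || anyNA(y)) stop("values must not contain NA")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))                       # midranks
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  v <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (v <= 0) {
    res <- new_test_result("wilcoxon_ranksum", c(z = 0, W = W), 1,
                           c(n1, n2), degenerate = TRUE)
    return(res)
  }
  z <- (W - mu) / sqrt(v)
  new_test_result("wilcoxon_ranksum", c(z = z, W = W),
                  normal_two_sided_p(z), c(n1, n2))
}

#' Two-sample Student t test
#'
#' Classical equal-variance two-sample t test by default (Welch via
#' `var_equal = FALSE`), two-sided. Groups that are both constant and
#' equal give the degenerate result t = 0, p = 1.
#'
#' @param x,y numeric values of the two groups (each of length >= 2).
#' @param var_equal pool the variance (default TRUE).
#' @return A test result (class `myoquant_test`).
#' @export
students_t <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 values")
  res <- tryCatch(stats::t.test(x, y, var.equal = var_equal),
                  error = function(e) NULL)
  if (is.null(res)) {
    if (isTRUE(all.equal(mean(x), mean(y))))
      return(new_test_result("students_t", c(t = 0), 1,
                             c(length(x), length(y)), degenerate = TRUE))
    stop("t test failed on degenerate input with unequal means")
  }
  new_test_result(if (var_equal) "students_t" else "welch_t",
                  c(t = unname(res$statistic)), res$p.value,
                  c(length(x), length(y)))
}
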