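#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed skewness z (D'Agostino 1970) and kurtosis z
#' (Anscombe & Glynn 1983) into the K^2 statistic, chi-squared with 2
#' degrees of freedom under normality. Moments are population (biased)
#' sample moments. Requires n >= 8 for the kurtosis transformation to be
#' defined.
#'
#' @param x Numeric vector, n >= 8.
#' @return List with `statistic` (K^2), `p.value`, `z_skew`, `z_kurt`, `n`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) stop("D'Agostino-Pearson test requires n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("zero variance")
  b1 <- mean((x - m)^3) / m2^1.5      # sample skewness g1
  b2 <- mean((x - m)^4) / m2^2        # sample kurtosis b2
  # skewness transform
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  if (y == 0) y <- 1  # degenerate symmetric case
  z_skew <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis transform
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqrtbeta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrtbeta1 * (2 / sqrtbeta1 + sqrt(1 + 4 / sqrtbeta1^2))
  t1 <- 1 - 2 / (9 * a)
  denom <- 1 + xk * sqrt(2 / (a - 4))
  t2 <- sign(denom) * abs((1 - 2 / a) / abs(denom))^(1 / 3)
  z_kurt <- (t1 - t2) / sqrt(2 / (9 * a))
  k2 <- z_skew^2 + z_kurt^2
  list(statistic = k2, p.value = stats::pchisq(k2, 2, lower.tail = FALSE),
       z_skew = z_skew, z_kurt = z_kurt, n = n)
}

# internal: Dunn's post-hoc z tests vs a control group, tie-corrected,
# Bonferroni-adjusted over the control comparisons
dunn_vs_control <- function(values, group, control) {
  g <- as.character(group)
  N <- length(values)
  rk <- rank(values)
  ties <- table(rk)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_corr
  mr <- tapply(rk, g, mean)
  ns <- tapply(rk, g, length)
  others <- setdiff(names(mr), control)
  z <- vapply(others, function(o)
    (mr[[o]] - mr[[control]]) / sqrt(s2 * (1 / ns[[o]] + 1 / ns[[control]])),
    1)
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group = others, n = as.integer(ns[others]), z = z,
             p_unadjusted = p,
             p_adjusted = pmin(1, p * length(others)),
             row.names = NULL)
}

#' Normality-gated multiple comparison of groups against a control
#'
#' Reproduces the comparison scheme used for per-cell imaging metrics: each
#' group is tested for normality with the D'Agostino-Pearson omnibus test;
#' only if every group passes (p > `normality_alpha`) does the parametric
#' path run (one-way ANOVA followed by Dunnett's test against the control),
#' otherwise the nonparametric path runs (Kruskal-Wallis followed by
#' Dunn's test against the control, Bonferroni-adjusted). Groups smaller
#' than 8 cannot be normality-tested and force the nonparametric path with
#' a flag.
#'
#' @param values Numeric vector of measurements.
#' @param group Group labels (same length).
#' @param control Name of the control group.
#' @param alpha Significance level for the per-group comparisons (default
#'   0.001, the convention of the emulated analyses).
#' @param normality_alpha Gate level for the normality test (default 0.05).
#' @param family `"auto"` (gated), or force `"nonparametric"` /
#'   `"parametric"`.
#' @return Object of class `group_comparison`: list with `family`,
#'   `normality` (per-group p), `omnibus` (statistic, p, method),
#'   `comparisons` (per group vs control: adjusted p, significance at
#'   `alpha`), `alpha`, `flags`.
#' @export
compare_groups <- function(values, group, control, alpha = 0.001,
                           normality_alpha = 0.05,
                           family = c("auto", "nonparametric", "parametric")) {
  family <- match.arg(family)
  stopifnot(length(values) == length(group), alpha > 0, alpha < 1)
  g <- as.character(group)
  groups <- unique(g)
  if (length(groups) < 2) stop("need at least two groups")
  if (!control %in% groups) stop("control group '", control, "' not found")
  ns <- table(g)
  flags <- character(0)
  norm_p <- rep(NA_real_, length(groups))
  names(norm_p) <- groups
  if (family == "auto") {
    if (any(ns < 8)) {
      family <- "nonparametric"
      flags <- c(flags, "groups with n < 8: normality untestable, nonparametric path forced")
    } else {
      norm_p <- vapply(groups, function(gr)
        dagostino_pearson(values[g == gr])$p.value, 1)
      family <- if (all(norm_p > normality_alpha)) "parametric" else
        "nonparametric"
    }
  }
  if (family == "nonparametric") {
    om <- stats::kruskal.test(values, factor(g))
    comp <- dunn_vs_control(values, g, control)
    omnibus <- list(method = "Kruskal-Wallis",
                    statistic = unname(om$statistic), p.value = om$p.value)
  } else {
    fg <- stats::relevel(factor(g), ref = control)
    dat <- data.frame(y = values, g = fg)
    fit <- stats::aov(y ~ g, data = dat)
    om <- summary(fit)[[1]]
    gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
    sm <- summary(gl)
    others <- sub(" - .*$", "", names(sm$test$coefficients))
    comp <- data.frame(group = others,
                       n = as.integer(ns[others]),
                       z = unname(sm$test$tstat),
                       p_unadjusted = NA_real_,
                       p_adjusted = unname(as.numeric(sm$test$pvalues)),
                       row.names = NULL)
    omnibus <- list(method = "one-way ANOVA",
                    statistic = om[["F value"]][1],
                    p.value = om[["Pr(>F)"]][1])
  }
  comp$significant <- comp$p_adjusted < alpha
  structure(list(family = family, normality = norm_p, omnibus = omnibus,
                 comparisons = comp, control = control, alpha = alpha,
                 flags = flags),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> ", x$omnibus$method, " (", x$family,
      " path), omnibus p = ", format.pval(x$omnibus$p.value),
      ", alpha = ", x$alpha, "\n", sep = "")
  print(x$comparisons)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Two-group two-tailed t test
#'
#' Welch's unequal-variance t test by default, with a pooled-variance
#' toggle. Two zero-variance samples yield an undefined, flagged result.
#'
#' @param a,b Numeric vectors, each n >= 2.
#' @param var_equal Use the pooled-variance (Student) form.
#' @return List with `statistic`, `p.value`, `df`, `flagged`.
#' @export
two_group_test <- function(a, b, var_equal = FALSE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::var(a) == 0 && stats::var(b) == 0)
    return(list(statistic = NA_real_, p.value = NA_real_, df = NA_real_,
                flagged = TRUE))
  tt <- stats::t.test(a, b, var.equal = var_equal,
                      alternative = "two.sided")
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       df = unname(tt$parameter), flagged = FALSE)
}
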