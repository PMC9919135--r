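#' Balanced two-factor table
#'
#' Assembles responses indexed by two crossed factors into the balanced table
#' required by the two-factor decomposition: every (A, B) cell must hold the
#' same number t of observations, with at least two levels per factor.
#'
#' @param a,b factor (or coercible) level labels per observation. In the flow
#'   study A is the pump suction flow and B the gas concentration.
#' @param response numeric response per observation (sensor voltage).
#' @return Data frame of class `"factorial_table"` with columns `a`, `b`,
#'   `response` and attributes `r`, `s`, `t` (level and replicate counts).
#' @export
factorial_table <- function(a, b, response) {
  stopifnot(length(a) == length(b), length(b) == length(response))
  if (any(!is.finite(response))) stop("factorial_table: non-finite responses")
  a <- factor(a)
  b <- factor(b)
  r <- nlevels(a)
  s <- nlevels(b)
  if (r < 2 || s < 2) stop("factorial_table: each factor needs >= 2 levels")
  counts <- table(a, b)
  if (length(unique(as.vector(counts))) != 1) {
    stop("unbalanced design: all cells must have the same number of observations")
  }
  t <- as.vector(counts)[1]
  structure(
    data.frame(a = a, b = b, response = response),
    r = r, s = s, t = t,
    class = c("factorial_table", "data.frame")
  )
}

#' Two-factor ANOVA with interaction
#'
#' Decomposes the total sum of squares of a balanced two-factor table into
#' main effects, interaction and error:
#' `SST = SSA + SSB + SSAB + SSE`, with
#' `SSA = s*t * sum_i (Xbar_i - Xbar)^2`,
#' `SSB = r*t * sum_j (Xbar_j - Xbar)^2`,
#' `SSAB = t * sum_ij (Xbar_ij - Xbar_i - Xbar_j + Xbar)^2`, and
#' `SSE = sum_ijk (X_ijk - Xbar_ij)^2`. F statistics are ratios of mean
#' squares against the error mean square, with p-values from the F
#' distribution.
#'
#' @param table a [factorial_table()].
#' @return List of class `"flow_anova"` with sums of squares, degrees of
#'   freedom, mean squares, F statistics and p-values, plus the grand,
#'   marginal and cell means used.
#' @export
two_way_anova <- function(table) {
  stopifnot(inherits(table, "factorial_table"))
  r <- attr(table, "r"); s <- attr(table, "s"); t <- attr(table, "t")
  if (t < 2) stop("interaction inestimable: need >= 2 observations per cell")
  x <- table$response
  grand <- mean(x)
  mean_a <- tapply(x, table$a, mean)
  mean_b <- tapply(x, table$b, mean)
  mean_ab <- tapply(x, list(table$a, table$b), mean)   # r x s matrix

  ss_a <- s * t * sum((mean_a - grand)^2)
  ss_b <- r * t * sum((mean_b - grand)^2)
  inter <- sweep(sweep(mean_ab, 1, mean_a), 2, mean_b) + grand
  ss_ab <- t * sum(inter^2)
  cell_of <- mean_ab[cbind(as.integer(table$a), as.integer(table$b))]
  ss_e <- sum((x - cell_of)^2)
  ss_t <- sum((x - grand)^2)

  df_a <- r - 1
  df_b <- s - 1
  df_ab <- (r - 1) * (s - 1)
  df_e <- r * s * (t - 1)
  ms_e <- ss_e / df_e
  f_a <- (ss_a / df_a) / ms_e
  f_b <- (ss_b / df_b) / ms_e
  f_ab <- (ss_ab / df_ab) / ms_e

  structure(list(
    ss_total = ss_t, ss_a = ss_a, ss_b = ss_b, ss_ab = ss_ab, ss_e = ss_e,
    df_a = df_a, df_b = df_b, df_ab = df_ab, df_e = df_e,
    ms_a = ss_a / df_a, ms_b = ss_b / df_b, ms_ab = ss_ab / df_ab, ms_e = ms_e,
    f_a = f_a, f_b = f_b, f_ab = f_ab,
    p_a = stats::pf(f_a, df_a, df_e, lower.tail = FALSE),
    p_b = stats::pf(f_b, df_b, df_e, lower.tail = FALSE),
    p_ab = stats::pf(f_ab, df_ab, df_e, lower.tail = FALSE),
    grand_mean = grand, mean_a = mean_a, mean_b = mean_b, mean_ab = mean_ab,
    r = r, s = s, t = t
  ), class = "flow_anova")
}

#' @export
print.flow_anova <- function(x, ...) {
  fmt_p <- function(p) ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))
  tab <- data.frame(
    `Sum Sq` = c(x$ss_a, x$ss_b, x$ss_ab, x$ss_e),
    Df = c(x$df_a, x$df_b, x$df_ab, x$df_e),
    `Mean Sq` = c(x$ms_a, x$ms_b, x$ms_ab, x$ms_e),
    F = c(x$f_a, x$f_b, x$f_ab, NA),
    `p` = c(fmt_p(x$p_a), fmt_p(x$p_b), fmt_p(x$p_ab), ""),
    row.names = c("A (flow)", "B (concentration)", "A:B", "Error"),
    check.names = FALSE
  )
  cat("Two-factor ANOVA with interaction\n")
  print(tab)
  invisible(x)
}

#' LSD comparison with homogeneous subsets
#'
#' Post-hoc least-significant-difference comparison of one factor's level
#' means after [two_way_anova()]. The LSD at level `alpha` is
#' `t(1 - alpha/2, df_e) * sqrt(2 * MSE / n)`, with n observations per level.
#' Levels are sorted by mean and grouped into maximal contiguous subsets
#' whose extreme means differ by less than the LSD; each subset is reported
#' with the p-value of its extreme-pair comparison (1 for singletons).
#'
#' @param table a [factorial_table()].
#' @param factor which factor to compare, `"A"` or `"B"`.
#' @param alpha significance level in (0, 1).
#' @return List of class `"lsd_result"`: sorted `means`, `n_per_level`,
#'   `lsd`, `subsets` (list of level-name vectors), `subset_p`.
#' @export
lsd_subsets <- function(table, factor = c("A", "B"), alpha = 0.05) {
  factor <- match.arg(factor)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop("lsd_subsets: 'alpha' must be in (0, 1)")
  }
  aov_res <- two_way_anova(table)
  f <- if (factor == "A") table$a else table$b
  means <- sort(tapply(table$response, f, mean))
  n_lvl <- length(table$response) / nlevels(f)
  lsd <- stats::qt(1 - alpha / 2, aov_res$df_e) * sqrt(2 * aov_res$ms_e / n_lvl)

  pair_p <- function(d) {
    tt <- abs(d) / sqrt(2 * aov_res$ms_e / n_lvl)
    2 * stats::pt(tt, aov_res$df_e, lower.tail = FALSE)
  }
  # sort-and-merge sweep: from each level not yet covered, extend while the
  # extreme pair stays within the LSD; keep only maximal subsets
  k <- length(means)
  subsets <- list()
  subset_p <- numeric(0)
  last_end <- 0
  for (i in seq_len(k)) {
    j <- i
    while (j < k && (means[j + 1] - means[i]) <= lsd) j <- j + 1
    if (j > last_end) {
      subsets[[length(subsets) + 1]] <- names(means)[i:j]
      subset_p <- c(subset_p, if (j == i) 1 else pair_p(means[j] - means[i]))
      last_end <- j
    }
  }
  structure(list(
    factor = factor, means = means, n_per_level = n_lvl, lsd = lsd,
    alpha = alpha, subsets = subsets, subset_p = subset_p,
    df_e = aov_res$df_e, ms_e = aov_res$ms_e
  ), class = "lsd_result")
}

#' @export
print.lsd_result <- function(x, ...) {
  k <- length(x$means)
  m <- matrix("", k, length(x$subsets),
              dimnames = list(names(x$means),
                              paste("subset", seq_along(x$subsets))))
  for (j in seq_along(x$subsets)) {
    m[x$subsets[[j]], j] <- sprintf("%.7f", x$means[x$subsets[[j]]])
  }
  cat(sprintf("LSD comparison (factor %s, alpha = %g, LSD = %.4g, n = %g/level)\n",
              x$factor, x$alpha, x$lsd, x$n_per_level))
  print(as.data.frame(m))
  cat("subset p-values:", sprintf("%.3f", x$subset_p), "\n")
  invisible(x)
}

#' Homogeneity-of-variance check (Levene, median-centered)
#'
#' Thin wrapper reporting the Brown-Forsythe form of Levene's test (one-way
#' F on absolute deviations from group medians), used to check the equal
#' variance assumption before the ANOVA. Degenerate all-constant groups
#' return statistic 0 with p-value 1.
#'
#' @param response numeric observations.
#' @param group grouping factor (>= 2 groups).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
variance_homogeneity_test <- function(response, group) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("variance_homogeneity_test: need >= 2 groups")
  dev <- abs(response - stats::ave(response, group, FUN = stats::median))
  if (all(dev < .Machine$double.eps^0.5 * max(1, abs(response)))) {
    return(list(statistic = 0, df = c(nlevels(group) - 1,
                                      length(response) - nlevels(group)),
                p_value = 1))
  }
  # near-zero within-group deviations make the internal F unstable; the
  # statistic itself is still well defined, so silence that warning
  lt <- suppressWarnings(
    car::leveneTest(response, group, center = stats::median)
  )
  list(statistic = lt[1, "F value"], df = c(lt[1, "Df"], lt[2, "Df"]),
       p_value = lt[1, "Pr(>F)"])
}

#' Normality check of residuals (Shapiro-Wilk)
#'
#' Thin wrapper around [stats::shapiro.test()] applied to ANOVA residuals.
#'
#' @param residuals numeric vector, length 3 to 5000.
#' @return List with `statistic`, `p_value`.
#' @export
normality_test <- function(residuals) {
  if (length(residuals) < 3) stop("normality_test: need >= 3 residuals")
  st <- stats::shapiro.test(residuals)
  list(statistic = unname(st$statistic), p_value = st$p.value)
}
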