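#' Fit the multivariate-regression calibration
#'
#' Ordinary least squares of concentration on the NO-sensor feature `x1` and
#' the scaled flow feature `x2`. Two forms are supported: `"linear"`
#' (`y ~ x1 + x2`) and `"quadratic"` (`y ~ x1 + x2 + x1:x2 + x2^2`), the
#' reduced quadratic used for flow correction; a full quadratic adding `x1^2`
#' is available via `full_quadratic = TRUE` for comparison. Reported fit
#' statistics: per-coefficient SE / t / p, overall F p-value, adjusted R2,
#' RMSE (`sqrt(SSE/n)`), and Gaussian profile AIC `n*log(SSE/n) + 2*(k+1)`.
#'
#' @param samples data frame with columns `x1`, `x2` and `concentration`
#'   (or `y`); typically a [build_calibration_samples()] result.
#' @param form `"linear"` or `"quadratic"`.
#' @param full_quadratic if `TRUE` with `form = "quadratic"`, also include
#'   the `x1^2` term.
#' @return Object of class `"mr_model"`: `terms` (monomial labels),
#'   `coefficients`, `coef_table`, `sigma`-free fit stats (`r2`, `adj_r2`,
#'   `rmse`, `aic`, `f_p_value`), `n`, `form`, and `scaling` metadata
#'   (the `x2` divisor inherited from the samples, if any).
#' @export
fit_mr <- function(samples, form = c("quadratic", "linear"),
                   full_quadratic = FALSE) {
  form <- match.arg(form)
  df <- data.frame(
    y = samples$concentration %||% samples$y,
    x1 = samples$x1,
    x2 = samples$x2
  )
  terms <- switch(form,
    linear = c("x1", "x2"),
    quadratic = if (full_quadratic) {
      c("x1", "x2", "x1:x2", "x2^2", "x1^2")
    } else {
      c("x1", "x2", "x1:x2", "x2^2")
    }
  )
  rhs <- c("x1", "x2",
           if (form == "quadratic") c("I(x1 * x2)", "I(x2^2)"),
           if (form == "quadratic" && full_quadratic) "I(x1^2)")
  k <- length(rhs)
  if (nrow(df) < k + 1) stop("fit_mr: too few samples for the requested form")
  fml <- stats::as.formula(paste("y ~", paste(rhs, collapse = " + ")))
  fit <- stats::lm(fml, data = df)
  if (fit$rank < k + 1) stop("singular fit: design matrix is rank deficient")
  # exact interpolation is a legitimate input here; summary.lm warns on it
  sm <- suppressWarnings(summary(fit))
  n <- nrow(df)
  sse <- sum(stats::residuals(fit)^2)
  fstat <- sm$fstatistic
  structure(list(
    form = form,
    terms = terms,
    coefficients = stats::setNames(stats::coef(fit), c("(Intercept)", terms)),
    coef_table = sm$coefficients,
    r2 = sm$r.squared,
    adj_r2 = sm$adj.r.squared,
    rmse = sqrt(sse / n),
    aic = n * log(sse / n) + 2 * (k + 1),
    f_p_value = if (is.null(fstat)) NA_real_ else
      unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
    n = n,
    scaling = list(x2_divisor = attr(samples, "x2_divisor") %||% 1),
    fit = fit
  ), class = "mr_model")
}

#' The published reduced-quadratic flow-correction polynomial
#'
#' Returns the reference calibration
#' `y = 0.41225 + 1.3929*x1 - 0.35554*x2 - 0.063957*x1*x2 + 0.075741*x2^2`
#' as an `"mr_model"` whose coefficients are fixed constants, usable with
#' [predict_mr()] and as a generator in recovery checks.
#'
#' @return Object of class `"mr_model"` (no fit statistics).
#' @export
reference_mr_model <- function() {
  structure(list(
    form = "quadratic",
    terms = c("x1", "x2", "x1:x2", "x2^2"),
    coefficients = c(
      "(Intercept)" = 0.41225,
      x1 = 1.3929,
      x2 = -0.35554,
      "x1:x2" = -0.063957,
      "x2^2" = 0.075741
    ),
    r2 = NA_real_, adj_r2 = NA_real_, rmse = NA_real_, aic = NA_real_,
    f_p_value = NA_real_, n = NA_integer_,
    scaling = list(x2_divisor = 1000),
    fit = NULL
  ), class = "mr_model")
}

#' Evaluate an MR calibration at new inputs
#'
#' Direct polynomial evaluation of the model's terms; `x1` and `x2` must be
#' on the model's input scale (`x2` already divided by
#' `model$scaling$x2_divisor`).
#'
#' @param model an `"mr_model"`.
#' @param x1,x2 numeric vectors (recycled to a common length).
#' @return Predicted concentration(s).
#' @export
predict_mr <- function(model, x1, x2) {
  if (any(!is.finite(x1)) || any(!is.finite(x2))) {
    stop("predict_mr: inputs must be finite")
  }
  b <- model$coefficients
  basis <- list(
    "x1" = x1, "x2" = x2,
    "x1:x2" = x1 * x2, "x2^2" = x2^2, "x1^2" = x1^2
  )
  out <- rep(b[["(Intercept)"]], length.out = max(length(x1), length(x2)))
  for (tm in model$terms) out <- out + b[[tm]] * basis[[tm]]
  out
}

#' @export
predict.mr_model <- function(object, newdata, ...) {
  predict_mr(object, newdata$x1, newdata$x2)
}

#' Select among candidate MR calibrations
#'
#' Lexicographic rule over models fitted on the same samples: candidates in
#' which every coefficient p-value and the overall F p-value fall below
#' `alpha` are preferred; within the preferred tier the lowest AIC wins,
#' with ties broken by lowest RMSE.
#'
#' @param candidates list of `"mr_model"` objects.
#' @param alpha significance level for the t and F screens.
#' @return The selected `"mr_model"`, with attribute `"comparison"` holding
#'   the full comparison table.
#' @export
model_select <- function(candidates, alpha = 0.05) {
  if (length(candidates) == 0) stop("model_select: no candidates")
  cmp <- do.call(rbind, lapply(candidates, function(m) {
    data.frame(
      form = m$form,
      k = length(m$terms),
      all_sig = all(m$coef_table[, "Pr(>|t|)"] < alpha) &&
        is.finite(m$f_p_value) && m$f_p_value < alpha,
      adj_r2 = m$adj_r2, rmse = m$rmse, aic = m$aic,
      f_p_value = m$f_p_value
    )
  }))
  ord <- order(!cmp$all_sig, cmp$aic, cmp$rmse)
  best <- candidates[[ord[1]]]
  attr(best, "comparison") <- cmp
  best
}

#' @export
print.mr_model <- function(x, ...) {
  cat(sprintf("MR calibration (%s form, x2 divisor %g)\n",
              x$form, x$scaling$x2_divisor))
  co <- x$coefficients
  eq <- paste0(sprintf("%.6g", co[1]),
               paste0(sprintf(" %+.6g*", co[-1]), names(co)[-1],
                      collapse = ""))
  cat("  y =", eq, "\n")
  if (is.finite(x$rmse %||% NA_real_)) {
    cat(sprintf("  n = %d, adj R2 = %.5f, RMSE = %.5g, AIC = %.5g\n",
                x$n, x$adj_r2, x$rmse, x$aic))
  }
  invisible(x)
}
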