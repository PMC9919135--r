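#' Discrimination threshold from training runs
#'
#' The routing threshold tau is the mean of the smoothed NO-channel voltage
#' over the training run(s) acquired at the discrimination condition —
#' by default 50 ppb at 1000 SCCM, the boundary between the regime where the
#' polynomial calibration is more accurate (below) and where the network
#' calibration is (above).
#'
#' @param runs list of `"run_series"` objects (the training set).
#' @param concentration,flow the discrimination condition.
#' @param window moving-average window used for the NO channel.
#' @return tau in volts.
#' @export
compute_threshold <- function(runs, concentration = 50, flow = 1000,
                              window = 51) {
  hit <- Filter(function(r) {
    r$condition$concentration == concentration && r$condition$flow == flow
  }, runs)
  if (length(hit) == 0) {
    stop(sprintf("missing condition: no run at %g ppb / %g SCCM",
                 concentration, flow))
  }
  mean(unlist(lapply(hit, function(r) moving_average(r$no_voltage, window))))
}

#' Threshold-switched hybrid calibrator
#'
#' Combines the polynomial (MR) and network (GA-BP) calibrators with a
#' voltage threshold on the NO-channel feature: samples with `x1 >= tau`
#' are corrected by the GA-BP model, samples with `x1 < tau` by the MR
#' model. Ties route to GA-BP (a measure-zero event for continuous data).
#'
#' @param mr an `"mr_model"`.
#' @param gabp a `"gabp_model"`.
#' @param tau routing threshold in volts (see [compute_threshold()]).
#' @param provenance optional list recording how tau was obtained.
#' @return Object of class `"hybrid_model"`.
#' @export
hybrid_model <- function(mr, gabp, tau, provenance = list(
                           concentration = 50, flow = 1000,
                           statistic = "mean")) {
  stopifnot(inherits(mr, "mr_model"), inherits(gabp, "gabp_model"),
            is.finite(tau))
  structure(list(mr = mr, gabp = gabp, tau = tau, provenance = provenance),
            class = "hybrid_model")
}

#' Predict with the hybrid calibrator
#'
#' Every prediction is exactly the routed sub-model's prediction.
#'
#' @param model a [hybrid_model()].
#' @param x1,x2 numeric input vectors.
#' @return Predicted concentration(s) in ppb, with attribute `"route"`
#'   (`"mr"` or `"gabp"` per sample).
#' @export
predict_hybrid <- function(model, x1, x2) {
  use_gabp <- x1 >= model$tau
  out <- numeric(length(x1))
  if (any(use_gabp)) {
    out[use_gabp] <- predict_gabp(model$gabp, x1[use_gabp], x2[use_gabp])
  }
  if (any(!use_gabp)) {
    out[!use_gabp] <- predict_mr(model$mr, x1[!use_gabp], x2[!use_gabp])
  }
  attr(out, "route") <- ifelse(use_gabp, "gabp", "mr")
  out
}

#' @export
predict.hybrid_model <- function(object, newdata, ...) {
  predict_hybrid(object, newdata$x1, newdata$x2)
}

#' Calibration accuracy metrics
#'
#' Computes the standard verification metrics plus the instrument precision
#' in percent of full scale: `R2 = 1 - SSE/SStot`, MSE, RMSE, and
#' `precision_fs = max |prediction - truth| / full_scale * 100` (or the
#' mean-absolute-error variant with `precision_stat = "mean"`). Full scale
#' defaults to 200 ppb, the top of the design range.
#'
#' @param predictions,truths equal-length numeric vectors (ppb).
#' @param full_scale full-scale span in ppb.
#' @param precision_stat `"max"` (default) or `"mean"` absolute error in the
#'   %FS numerator.
#' @return List of class `"enose_metrics"`: `r2`, `mse`, `rmse`,
#'   `precision_fs`, `full_scale`, `n`, and `by_concentration` (mean
#'   prediction per true level).
#' @export
evaluate_predictions <- function(predictions, truths, full_scale = 200,
                                 precision_stat = c("max", "mean")) {
  precision_stat <- match.arg(precision_stat)
  if (length(predictions) != length(truths) || length(truths) < 1) {
    stop("evaluate_predictions: lengths must match and be >= 1")
  }
  if (full_scale <= 0) stop("evaluate_predictions: 'full_scale' must be positive")
  err <- predictions - truths
  sse <- sum(err^2)
  sstot <- sum((truths - mean(truths))^2)
  if (sstot == 0) stop("evaluate_predictions: zero variance in truths, R2 undefined")
  abs_stat <- if (precision_stat == "max") max(abs(err)) else mean(abs(err))
  by_conc <- tapply(predictions, truths, mean)
  structure(list(
    r2 = 1 - sse / sstot,
    mse = sse / length(err),
    rmse = sqrt(sse / length(err)),
    precision_fs = abs_stat / full_scale * 100,
    precision_stat = precision_stat,
    full_scale = full_scale,
    n = length(err),
    by_concentration = data.frame(
      concentration = as.numeric(names(by_conc)),
      mean_prediction = as.numeric(by_conc)
    )
  ), class = "enose_metrics")
}

#' @export
print.enose_metrics <- function(x, ...) {
  cat(sprintf(
    "n = %d: R2 = %.5f, MSE = %.5g, RMSE = %.5g, precision = %.2f %%FS (%s, FS = %g ppb)\n",
    x$n, x$r2, x$mse, x$rmse, x$precision_fs, x$precision_stat, x$full_scale
  ))
  invisible(x)
}

#' Flow-blind one-point baseline calibration
#'
#' The pre-correction reference: a single linear sensitivity `y ~ x1` fitted
#' only on training samples taken at the peak-gain flow and then applied at
#' every flow, i.e. a calibration that ignores the flow channel entirely.
#'
#' @param samples calibration samples (training split).
#' @param flow_set the flow (SCCM) whose samples define the sensitivity.
#' @return Object of class `"baseline_model"` with `intercept` and `slope`.
#' @export
fit_flow_blind_baseline <- function(samples, flow_set = 1000) {
  sel <- samples$flow_set == flow_set
  if (!any(sel)) stop(sprintf("missing condition: no samples at %g SCCM", flow_set))
  y <- (samples$concentration %||% samples$y)[sel]
  fit <- stats::lm(y ~ x1, data = data.frame(y = y, x1 = samples$x1[sel]))
  structure(list(intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 flow_set = flow_set),
            class = "baseline_model")
}

#' @export
predict.baseline_model <- function(object, newdata, ...) {
  object$intercept + object$slope * newdata$x1
}

#' Compare the three calibrators on a common test set
#'
#' Evaluates the MR, GA-BP and hybrid calibrators on the same test samples,
#' reports metrics per model and the RMSE broken down by true concentration,
#' and flags whether the hybrid RMSE is at or below each single model's.
#'
#' @param mr,gabp,hybrid fitted models.
#' @param samples test calibration samples.
#' @param full_scale full-scale span in ppb.
#' @param precision_stat passed to [evaluate_predictions()].
#' @return List of class `"model_comparison"`: `metrics` (named list),
#'   `rmse_by_concentration` (data frame), `hybrid_not_worse` (logical
#'   flags vs MR and GA-BP), `predictions`.
#' @export
compare_models <- function(mr, gabp, hybrid, samples, full_scale = 200,
                           precision_stat = "max") {
  y <- samples$concentration %||% samples$y
  if (length(y) == 0) stop("compare_models: empty test set")
  preds <- list(
    mr = predict_mr(mr, samples$x1, samples$x2),
    gabp = predict_gabp(gabp, samples$x1, samples$x2),
    hybrid = as.vector(predict_hybrid(hybrid, samples$x1, samples$x2))
  )
  metrics <- lapply(preds, evaluate_predictions, truths = y,
                    full_scale = full_scale, precision_stat = precision_stat)
  rmse_by <- do.call(rbind, lapply(sort(unique(y)), function(cc) {
    sel <- y == cc
    data.frame(
      concentration = cc,
      mr = sqrt(mean((preds$mr[sel] - y[sel])^2)),
      gabp = sqrt(mean((preds$gabp[sel] - y[sel])^2)),
      hybrid = sqrt(mean((preds$hybrid[sel] - y[sel])^2))
    )
  }))
  structure(list(
    metrics = metrics,
    rmse_by_concentration = rmse_by,
    hybrid_not_worse = c(
      vs_mr = metrics$hybrid$rmse <= metrics$mr$rmse,
      vs_gabp = metrics$hybrid$rmse <= metrics$gabp$rmse
    ),
    predictions = preds
  ), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  tab <- do.call(rbind, lapply(x$metrics, function(m) {
    data.frame(R2 = m$r2, MSE = m$mse, RMSE = m$rmse,
               `precision %FS` = m$precision_fs, check.names = FALSE)
  }))
  cat("Verification-set comparison\n")
  print(round(tab, 5))
  cat("\nRMSE by concentration (ppb)\n")
  print(round(x$rmse_by_concentration, 4))
  invisible(x)
}
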