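#' Centered moving-average smoother
#'
#' Smooths the NO-channel voltage trace with a centered moving mean. Near the
#' ends the window shrinks symmetrically so the output has the same length as
#' the input and no samples are discarded.
#'
#' @param series numeric vector.
#' @param window odd window length in samples, between 1 and `length(series)`.
#'   The default 51 spans about 5 s at the 10 Hz acquisition rate.
#' @return numeric vector, same length as `series`.
#' @export
moving_average <- function(series, window = 51) {
  n <- length(series)
  window <- as.integer(window)
  if (length(window) != 1 || is.na(window) || window < 1 || window %% 2 == 0) {
    stop("moving_average: 'window' must be an odd positive integer")
  }
  if (window > n) stop("moving_average: 'window' exceeds series length")
  if (window == 1) return(series)
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, series))
  idx <- seq_len(n)
  h <- pmin(half, idx - 1L, n - idx)
  (cs[idx + h + 1L] - cs[idx - h]) / (2 * h + 1)
}

#' Loess smoother for the flow channel
#'
#' Locally weighted linear regression (tricube weights, no robustness
#' iterations) of the series on its sample index, evaluated at every index.
#' Used to remove pump pulsation noise from the flow-sensor trace.
#'
#' @param series numeric vector.
#' @param span fraction of the data in each local window, in (0, 1]; the
#'   window must cover at least two points.
#' @return numeric vector, same length as `series`.
#' @export
loess_smooth <- function(series, span = 0.3) {
  n <- length(series)
  if (!is.numeric(span) || length(span) != 1 || span <= 0 || span > 1) {
    stop("loess_smooth: 'span' must be in (0, 1]")
  }
  if (span * n < 2) stop("loess_smooth: 'span' window covers fewer than 2 points")
  if (n < 3) return(series)
  stats::lowess(seq_len(n), series, f = span, iter = 0)$y
}

#' Five summary features of a smoothed trace
#'
#' Reduces a channel to the five statistics used for calibration: maximum,
#' mean, median, first quartile and third quartile. Quartiles use linear
#' interpolation between closest order statistics (R's default type-7
#' convention).
#'
#' @param series non-empty numeric vector.
#' @return Named numeric vector with elements `maximum`, `mean`, `median`,
#'   `q1`, `q3`.
#' @export
extract_features <- function(series) {
  if (length(series) == 0) stop("extract_features: empty series")
  if (any(!is.finite(series))) stop("extract_features: non-finite values")
  q <- stats::quantile(series, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(
    maximum = max(series),
    mean = mean(series),
    median = q[2],
    q1 = q[1],
    q3 = q[3]
  )
}

#' Feature kinds in their canonical order
#' @export
feature_kinds <- function() c("maximum", "mean", "median", "q1", "q3")

#' Build calibration samples from runs
#'
#' Per run: the NO channel is smoothed by a moving average and the flow
#' channel by loess, both channels are reduced to their five summary
#' features, and features are paired by kind (maximum with maximum, and so
#' on), giving exactly five calibration samples per run. The flow feature is
#' divided by `x2_divisor` (default 1000, i.e. SCCM to SLPM) so that both
#' model inputs are of order one.
#'
#' @param runs list of `"run_series"` objects.
#' @param window moving-average window for the NO channel.
#' @param span loess span for the flow channel.
#' @param x2_divisor divisor applied to the flow feature before modelling.
#' @return Data frame of class `"calibration_samples"` with columns
#'   `concentration` (= y, ppb), `flow_set`, `replicate`, `split`,
#'   `feature_kind`, `x1` (volts), `x2` (scaled flow). Attribute
#'   `x2_divisor` records the scaling.
#' @export
build_calibration_samples <- function(runs, window = 51, span = 0.3,
                                      x2_divisor = 1000) {
  if (inherits(runs, "run_series")) runs <- list(runs)
  rows <- lapply(runs, function(r) {
    if (is.null(r$no_voltage) || is.null(r$flow_reading)) {
      stop("malformed run: both 'no_voltage' and 'flow_reading' channels required")
    }
    f1 <- extract_features(moving_average(r$no_voltage, window))
    f2 <- extract_features(loess_smooth(r$flow_reading, span))
    data.frame(
      concentration = r$condition$concentration,
      flow_set = r$condition$flow,
      replicate = r$condition$replicate,
      split = r$condition$split,
      feature_kind = feature_kinds(),
      x1 = unname(f1[feature_kinds()]),
      x2 = unname(f2[feature_kinds()]) / x2_divisor,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "x2_divisor") <- x2_divisor
  attr(out, "window") <- window
  attr(out, "span") <- span
  class(out) <- c("calibration_samples", "data.frame")
  out
}
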