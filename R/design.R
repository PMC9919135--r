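#' Factorial experimental design for the bench experiment
#'
#' Builds the full concentration-by-flow factorial with replicate runs, the
#' layout of the bench campaign: six NO concentrations spanning the FeNO range
#' crossed with six pump suction flows, each measured twice, giving 72 runs.
#' By default the first replicate is labelled `"train"` and all later
#' replicates `"test"`, mirroring the bench convention of one acquisition for
#' model fitting and one for evaluation.
#'
#' @param concentrations numeric vector of true NO concentrations in ppb.
#' @param flows numeric vector of pump suction flow set points in SCCM.
#' @param replicates number of replicate runs per cell (>= 1).
#' @return A data frame of class `"enose_design"` with one row per run and
#'   columns `concentration` (ppb), `flow` (SCCM), `replicate`, `split`.
#' @examples
#' d <- generate_design()
#' nrow(d)            # 72
#' table(d$split)     # 36 train, 36 test
#' @export
generate_design <- function(concentrations = c(5, 25, 35, 50, 100, 200),
                            flows = c(200, 400, 600, 800, 1000, 1200),
                            replicates = 2) {
  if (length(concentrations) == 0 || length(flows) == 0) {
    stop("invalid design: 'concentrations' and 'flows' must be non-empty")
  }
  if (any(!is.finite(concentrations)) || any(concentrations <= 0)) {
    stop("invalid design: concentrations must be finite and positive")
  }
  if (any(!is.finite(flows)) || any(flows <= 0)) {
    stop("invalid design: flows must be finite and positive")
  }
  replicates <- as.integer(replicates)
  if (length(replicates) != 1 || is.na(replicates) || replicates < 1) {
    stop("invalid design: 'replicates' must be a positive integer")
  }
  d <- expand.grid(
    concentration = concentrations,
    flow = flows,
    replicate = seq_len(replicates),
    KEEP.OUT.ATTRS = FALSE
  )
  d$split <- ifelse(d$replicate == 1L, "train", "test")
  class(d) <- c("enose_design", "data.frame")
  d
}

#' Simulation parameters for synthetic two-channel runs
#'
#' Bundles the physical constants of the response-surface generator. The NO
#' channel follows a first-order rise to a plateau whose height is
#' `baseline_voltage + sensitivity * (concentration / 200) * flow_gain(flow)`,
#' with i.i.d. Gaussian noise on every sample; the flow channel reads the set
#' flow plus noise. The flow gain is a unimodal bump peaking at
#' `gain_peak_flow` (default 1000 SCCM), so responses fall off toward both
#' ends of the 200-1200 SCCM design range, fastest below the peak.
#'
#' Defaults are chosen to emulate a realistic electrochemical NO sensor:
#' a ~20 s response time constant, a gain spread of about 15% of the peak
#' across the design flows (large enough that a flow-blind calibration incurs
#' double-digit %FS errors), and per-sample noise giving the smoothed trace a
#' coefficient of variation of roughly 1-2% at mid-range concentrations.
#'
#' @param baseline_voltage sensor output at zero concentration, volts.
#' @param sensitivity plateau increment in volts for 200 ppb at unit gain.
#' @param rise_time_constant first-order response time constant, seconds.
#' @param gain_peak_flow flow of maximum gain, SCCM.
#' @param gain_width_low,gain_width_high log-scale widths of the gain bump
#'   below and above the peak (dimensionless).
#' @param noise_sd_voltage per-sample Gaussian noise SD on the NO channel, volts.
#' @param flow_noise_sd per-sample Gaussian noise SD on the flow channel, SCCM.
#' @param seed master integer seed for the dataset simulator.
#' @return A list of class `"sim_params"`.
#' @export
sim_params <- function(baseline_voltage = 0.05,
                       sensitivity = 3.0,
                       rise_time_constant = 20,
                       gain_peak_flow = 1000,
                       gain_width_low = 2.82,
                       gain_width_high = 0.48,
                       noise_sd_voltage = 0.05,
                       flow_noise_sd = 5,
                       seed = 1L) {
  p <- list(
    baseline_voltage = baseline_voltage,
    sensitivity = sensitivity,
    rise_time_constant = rise_time_constant,
    gain_peak_flow = gain_peak_flow,
    gain_width_low = gain_width_low,
    gain_width_high = gain_width_high,
    noise_sd_voltage = noise_sd_voltage,
    flow_noise_sd = flow_noise_sd,
    seed = as.integer(seed)
  )
  stopifnot(
    p$noise_sd_voltage >= 0, p$flow_noise_sd >= 0,
    p$rise_time_constant > 0, p$gain_peak_flow > 0,
    p$gain_width_low > 0, p$gain_width_high > 0
  )
  class(p) <- "sim_params"
  p
}

#' Flow-dependent sensitivity gain
#'
#' Dimensionless gain g(flow) multiplying the sensor sensitivity: a unimodal
#' log-scale Gaussian bump with different widths on either side of the peak,
#' equal to 1 at `gain_peak_flow` and decreasing away from it. The asymmetry
#' (broad below the peak, narrow above) reproduces the bench pattern in which
#' the mean response ranks 200 < {400, 600, 1200} < {800, 1000} SCCM.
#'
#' @param flow pump suction flow in SCCM (vectorized, must be positive).
#' @param params a [sim_params()] object.
#' @return numeric gain values in (0, 1].
#' @export
flow_gain <- function(flow, params = sim_params()) {
  if (any(!is.finite(flow)) || any(flow <= 0)) {
    stop("flow_gain: 'flow' must be finite and positive")
  }
  z <- log(flow / params$gain_peak_flow)
  w <- ifelse(z < 0, params$gain_width_low, params$gain_width_high)
  exp(-z^2 / (2 * w^2))
}

# Deterministic 32-bit sub-seed for one run, from the master seed and the
# condition triple; a small polynomial string hash keeps it stable across
# platforms and R versions.
condition_seed <- function(seed, concentration, flow, replicate) {
  key <- sprintf("%.6g|%.6g|%d", concentration, flow, as.integer(replicate))
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147481583
  as.integer((h + seed) %% 2147481583)
}

#' Simulate one two-channel run
#'
#' Generates one experimental run: a NO-sensor voltage trace rising with a
#' first-order time constant to its concentration- and flow-dependent plateau,
#' and a flow-sensor trace fluctuating around the set flow. Both channels get
#' i.i.d. Gaussian noise. The run is seeded deterministically from the master
#' seed and the condition triple, so a dataset is a pure function of its
#' design and parameters.
#'
#' @param condition a one-row data frame (or list) with `concentration`,
#'   `flow`, `replicate`, and optionally `split`.
#' @param params a [sim_params()] object.
#' @param sample_rate sampling frequency in Hz.
#' @param duration run length in seconds.
#' @return A list of class `"run_series"` with elements `condition`,
#'   `sample_rate`, `duration`, `time_s`, `no_voltage`, `flow_reading`.
#' @export
simulate_run <- function(condition, params = sim_params(),
                         sample_rate = 10, duration = 300) {
  cc <- as.list(condition)
  stopifnot(is.finite(cc$concentration), cc$concentration >= 0,
            is.finite(cc$flow), cc$flow > 0)
  n <- round(sample_rate * duration)
  t_s <- seq_len(n) / sample_rate
  plateau_gain <- 1 - exp(-t_s / params$rise_time_constant)
  signal <- params$baseline_voltage +
    params$sensitivity * (cc$concentration / 200) *
      flow_gain(cc$flow, params) * plateau_gain
  run_seed <- condition_seed(params$seed, cc$concentration, cc$flow,
                             cc$replicate %||% 1L)
  noise <- withr::with_seed(run_seed, {
    list(
      no = stats::rnorm(n, 0, params$noise_sd_voltage),
      fl = stats::rnorm(n, 0, params$flow_noise_sd)
    )
  })
  structure(
    list(
      condition = list(
        concentration = cc$concentration,
        flow = cc$flow,
        replicate = as.integer(cc$replicate %||% 1L),
        split = cc$split %||% "train"
      ),
      sample_rate = sample_rate,
      duration = duration,
      time_s = t_s,
      no_voltage = signal + noise$no,
      flow_reading = cc$flow + noise$fl
    ),
    class = "run_series"
  )
}

#' Simulate a full dataset of runs
#'
#' One [simulate_run()] per design row, with per-run sub-seeds derived from
#' the master seed so the whole dataset is reproducible and runs are
#' independent of design-row order.
#'
#' @param design an [generate_design()] data frame.
#' @param params a [sim_params()] object.
#' @param sample_rate,duration passed to [simulate_run()].
#' @return A list of `"run_series"` objects, one per design row.
#' @export
simulate_dataset <- function(design, params = sim_params(),
                             sample_rate = 10, duration = 300) {
  key <- paste(design$concentration, design$flow, design$replicate, sep = "|")
  if (anyDuplicated(key)) {
    stop("invalid design: duplicate (concentration, flow, replicate) triples")
  }
  lapply(seq_len(nrow(design)), function(i) {
    simulate_run(design[i, , drop = FALSE], params, sample_rate, duration)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.run_series <- function(x, ...) {
  cat(sprintf(
    "<run_series> %g ppb @ %g SCCM (rep %d, %s): %d samples @ %g Hz\n",
    x$condition$concentration, x$condition$flow, x$condition$replicate,
    x$condition$split, length(x$no_voltage), x$sample_rate
  ))
  invisible(x)
}
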