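#' Write / read one run as CSV
#'
#' One file per run: `#`-prefixed metadata header lines
#' (`concentration_ppb`, `flow_sccm`, `replicate`, `split`,
#' `sample_rate_hz`) followed by columns `time_s,no_voltage_v,flow_sccm`.
#' `read_run(write_run(run))` round-trips the run, including its condition.
#'
#' @param run a `"run_series"`.
#' @param path CSV file path.
#' @return `write_run()`: the path, invisibly. `read_run()`: a
#'   `"run_series"`.
#' @export
write_run <- function(run, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# concentration_ppb: %.10g", run$condition$concentration),
    sprintf("# flow_sccm: %.10g", run$condition$flow),
    sprintf("# replicate: %d", run$condition$replicate),
    sprintf("# split: %s", run$condition$split),
    sprintf("# sample_rate_hz: %.10g", run$sample_rate)
  ), con)
  utils::write.csv(
    data.frame(time_s = run$time_s, no_voltage_v = run$no_voltage,
               flow_sccm = run$flow_reading),
    con, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_run
#' @param path CSV file path written by [write_run()].
#' @export
read_run <- function(path) {
  lines <- readLines(path, n = 20)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- regmatches(ln, regexec("^#\\s*([a-z_]+):\\s*(.+)$", ln))[[1]]
    if (length(kv) == 3) meta[[kv[2]]] <- kv[3]
  }
  need <- c("concentration_ppb", "flow_sccm", "replicate", "split",
            "sample_rate_hz")
  missing <- setdiff(need, names(meta))
  if (length(missing)) {
    stop("format error: missing metadata keys: ", paste(missing, collapse = ", "))
  }
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time_s", "no_voltage_v", "flow_sccm") %in% names(df))) {
    stop("format error: expected columns time_s, no_voltage_v, flow_sccm")
  }
  if (!all(vapply(df, is.numeric, logical(1)))) {
    stop("parse error: non-numeric cells in run file")
  }
  rate <- as.numeric(meta$sample_rate_hz)
  structure(list(
    condition = list(
      concentration = as.numeric(meta$concentration_ppb),
      flow = as.numeric(meta$flow_sccm),
      replicate = as.integer(meta$replicate),
      split = meta$split
    ),
    sample_rate = rate,
    duration = nrow(df) / rate,
    time_s = df$time_s,
    no_voltage = df$no_voltage_v,
    flow_reading = df$flow_sccm
  ), class = "run_series")
}

#' Experiment configuration
#'
#' Assembles every knob of the end-to-end experiment into one serializable
#' list; [read_config()] loads it from YAML or JSON (by file extension) and
#' fills defaults for omitted entries.
#'
#' @param concentrations,flows,replicates design lists (see
#'   [generate_design()]).
#' @param sim a [sim_params()] object or plain list of its fields.
#' @param sample_rate,duration run geometry.
#' @param window,span,x2_divisor preprocessing settings.
#' @param anova_feature_kind feature kind used as the ANOVA response.
#' @param alpha significance level for tests and model selection.
#' @param mr_form MR form to fit alongside the linear one.
#' @param ga a [ga_config()] object or plain list of its fields.
#' @param learning_rate,max_epochs,tolerance backpropagation settings.
#' @param threshold_concentration,threshold_flow discrimination condition.
#' @param full_scale full-scale ppb for %FS metrics.
#' @return List of class `"experiment_config"`.
#' @export
experiment_config <- function(concentrations = c(5, 25, 35, 50, 100, 200),
                              flows = c(200, 400, 600, 800, 1000, 1200),
                              replicates = 2,
                              sim = sim_params(),
                              sample_rate = 10, duration = 300,
                              window = 51, span = 0.3, x2_divisor = 1000,
                              anova_feature_kind = "mean",
                              alpha = 0.05,
                              mr_form = "quadratic",
                              ga = ga_config(),
                              learning_rate = 0.05, max_epochs = 10000,
                              tolerance = 1e-9,
                              threshold_concentration = 50,
                              threshold_flow = 1000,
                              full_scale = 200) {
  structure(list(
    concentrations = concentrations, flows = flows, replicates = replicates,
    sim = sim, sample_rate = sample_rate, duration = duration,
    window = window, span = span, x2_divisor = x2_divisor,
    anova_feature_kind = anova_feature_kind, alpha = alpha,
    mr_form = mr_form, ga = ga,
    learning_rate = learning_rate, max_epochs = max_epochs,
    tolerance = tolerance,
    threshold_concentration = threshold_concentration,
    threshold_flow = threshold_flow,
    full_scale = full_scale
  ), class = "experiment_config")
}

#' @rdname experiment_config
#' @param path YAML (`.yml`/`.yaml`) or JSON (`.json`) configuration file;
#'   keys mirror the [experiment_config()] arguments, with `sim` and `ga`
#'   as nested maps.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yml = ,
    yaml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config extension: ", ext)
  )
  known <- names(formals(experiment_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  if (!is.null(raw$sim)) raw$sim <- do.call(sim_params, raw$sim)
  if (!is.null(raw$ga)) raw$ga <- do.call(ga_config, raw$ga)
  do.call(experiment_config, raw)
}

#' Run the whole flow-correction experiment
#'
#' Orchestrates every stage: simulate the factorial dataset, build
#' calibration samples, run the two-factor ANOVA with assumption checks and
#' the LSD flow comparison, fit the linear and quadratic MR calibrations and
#' select between them, train the GA-BP calibrator, compute the routing
#' threshold, assemble the hybrid, and evaluate all models (plus the
#' flow-blind baseline) on the test split.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional directory; when given, runs, features, models and
#'   the metrics report are written there.
#' @return List of class `"pipeline_result"` with elements `design`, `runs`,
#'   `samples` (train and test), `anova`, `assumptions`, `lsd`, `mr`,
#'   `mr_candidates`, `gabp`, `tau`, `hybrid`, `baseline`, `comparison`,
#'   `baseline_metrics`, `config`.
#' @export
run_pipeline <- function(config = experiment_config(), out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  design <- stage("design", generate_design(
    config$concentrations, config$flows, config$replicates
  ))
  runs <- stage("simulate", simulate_dataset(
    design, config$sim, config$sample_rate, config$duration
  ))
  samples <- stage("preprocess", build_calibration_samples(
    runs, window = config$window, span = config$span,
    x2_divisor = config$x2_divisor
  ))
  train <- samples[samples$split == "train", ]
  test <- samples[samples$split == "test", ]
  attr(train, "x2_divisor") <- attr(samples, "x2_divisor")
  attr(test, "x2_divisor") <- attr(samples, "x2_divisor")

  # ANOVA on one feature kind per run, so replicates are the within-cell
  # repeats: flow is factor A, concentration factor B
  anova_rows <- samples[samples$feature_kind == config$anova_feature_kind, ]
  tab <- stage("anova", factorial_table(
    anova_rows$flow_set, anova_rows$concentration, anova_rows$x1
  ))
  aov_res <- stage("anova", two_way_anova(tab))
  cell <- interaction(anova_rows$flow_set, anova_rows$concentration)
  assumptions <- stage("anova", list(
    homogeneity = variance_homogeneity_test(anova_rows$x1, cell),
    normality = normality_test(
      anova_rows$x1 - stats::ave(anova_rows$x1, cell)
    )
  ))
  lsd <- stage("anova", lsd_subsets(tab, "A", config$alpha))

  mr_candidates <- stage("fit-mr", list(
    linear = fit_mr(train, "linear"),
    quadratic = fit_mr(train, config$mr_form)
  ))
  mr <- stage("fit-mr", model_select(mr_candidates, config$alpha))

  gabp <- stage("fit-gabp", train_gabp(
    train, config$ga, learning_rate = config$learning_rate,
    max_epochs = config$max_epochs, tolerance = config$tolerance
  ))

  train_runs <- Filter(function(r) r$condition$split == "train", runs)
  tau <- stage("threshold", compute_threshold(
    train_runs, config$threshold_concentration, config$threshold_flow,
    window = config$window
  ))
  hybrid <- hybrid_model(mr, gabp, tau, provenance = list(
    concentration = config$threshold_concentration,
    flow = config$threshold_flow, statistic = "mean"
  ))

  comparison <- stage("evaluate", compare_models(
    mr, gabp, hybrid, test, full_scale = config$full_scale
  ))
  baseline <- stage("evaluate", fit_flow_blind_baseline(
    train, flow_set = config$threshold_flow
  ))
  baseline_metrics <- stage("evaluate", evaluate_predictions(
    predict(baseline, test), test$concentration,
    full_scale = config$full_scale
  ))

  result <- structure(list(
    design = design, runs = runs, samples = samples,
    train = train, test = test,
    anova = aov_res, assumptions = assumptions, lsd = lsd,
    mr = mr, mr_candidates = mr_candidates,
    gabp = gabp, tau = tau, hybrid = hybrid,
    baseline = baseline, comparison = comparison,
    baseline_metrics = baseline_metrics,
    config = config
  ), class = "pipeline_result")

  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

# Serialize the report bundle: runs, features, models (JSON) and metrics.
write_pipeline_result <- function(result, out_dir) {
  dir.create(file.path(out_dir, "runs"), recursive = TRUE,
             showWarnings = FALSE)
  for (r in result$runs) {
    fn <- sprintf("run_c%g_f%g_r%d.csv", r$condition$concentration,
                  r$condition$flow, r$condition$replicate)
    write_run(r, file.path(out_dir, "runs", fn))
  }
  utils::write.csv(result$samples, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(
      terms = result$mr$terms,
      coefficients = as.list(result$mr$coefficients),
      scaling = result$mr$scaling,
      adj_r2 = result$mr$adj_r2, rmse = result$mr$rmse, aic = result$mr$aic
    ),
    file.path(out_dir, "model_mr.json"), auto_unbox = TRUE, digits = NA
  )
  jsonlite::write_json(
    list(
      architecture = c(result$gabp$net$n_in, result$gabp$net$n_hidden,
                       result$gabp$net$n_out),
      chromosome = bp_encode(result$gabp$net),
      scaling = result$gabp$scaling,
      ga_best_fitness = result$gabp$ga_best_fitness,
      tau = result$tau
    ),
    file.path(out_dir, "model_gabp.json"), auto_unbox = TRUE, digits = NA
  )
  metrics <- do.call(rbind, lapply(
    c(result$comparison$metrics, list(baseline = result$baseline_metrics)),
    function(m) data.frame(r2 = m$r2, mse = m$mse, rmse = m$rmse,
                           precision_fs = m$precision_fs)
  ))
  metrics <- cbind(model = rownames(metrics), metrics)
  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(result$comparison$rmse_by_concentration,
                   file.path(out_dir, "rmse_by_concentration.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "Flow-correction pipeline: %d runs, %d train / %d test samples\n",
    length(x$runs), nrow(x$train), nrow(x$test)
  ))
  cat(sprintf("Routing threshold tau = %.4f V (%g ppb @ %g SCCM)\n\n",
              x$tau, x$hybrid$provenance$concentration,
              x$hybrid$provenance$flow))
  print(x$comparison)
  cat(sprintf("\nFlow-blind baseline: precision = %.2f %%FS; hybrid = %.2f %%FS\n",
              x$baseline_metrics$precision_fs,
              x$comparison$metrics$hybrid$precision_fs))
  invisible(x)
}
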