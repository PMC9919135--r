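test_that("compute_threshold averages the smoothed runs at the condition", {
  p0 <- sim_params(noise_sd_voltage = 0, flow_noise_sd = 0)
  # zero-concentration runs have a flat channel at the baseline
  flat1 <- simulate_run(list(concentration = 0, flow = 1000, replicate = 1), p0,
                        duration = 30)
  expect_equal(compute_threshold(list(flat1), 0, 1000, window = 21),
               p0$baseline_voltage)
  # two replicates: tau is the mean of both run means
  r1 <- simulate_run(list(concentration = 50, flow = 1000, replicate = 1),
                     sim_params(seed = 1), duration = 30)
  r2 <- simulate_run(list(concentration = 50, flow = 1000, replicate = 2),
                     sim_params(seed = 1), duration = 30)
  tau12 <- compute_threshold(list(r1, r2), 50, 1000, window = 21)
  m1 <- mean(moving_average(r1$no_voltage, 21))
  m2 <- mean(moving_average(r2$no_voltage, 21))
  expect_equal(tau12, (m1 + m2) / 2)
  expect_error(compute_threshold(list(r1), 35, 1000), "missing condition")
})

test_that("the threshold separates neighbouring concentrations at 1000 SCCM", {
  p <- sim_params(seed = 2)
  mk <- function(cc) simulate_run(list(concentration = cc, flow = 1000,
                                       replicate = 1), p, duration = 60)
  tau <- compute_threshold(list(mk(50)), 50, 1000)
  expect_gt(tau, mean(moving_average(mk(35)$no_voltage, 51)))
  expect_lt(tau, mean(moving_average(mk(100)$no_voltage, 51)))
})

test_that("hybrid predictions are bit-identical to the routed sub-model", {
  mr <- reference_mr_model()
  gabp <- stub_gabp()
  hm <- hybrid_model(mr, gabp, tau = 0.5)
  x1 <- c(0.1, 0.49, 0.5, 0.51, 0.9)
  x2 <- c(0.3, 0.4, 0.5, 0.6, 0.7)
  pred <- predict_hybrid(hm, x1, x2)
  route <- attr(pred, "route")
  expect_identical(route, c("mr", "mr", "gabp", "gabp", "gabp"))
  low <- route == "mr"
  expect_identical(as.vector(pred)[low], predict_mr(mr, x1[low], x2[low]))
  expect_identical(as.vector(pred)[!low],
                   predict_gabp(gabp, x1[!low], x2[!low]))
})

test_that("evaluate_predictions computes the stated metrics", {
  truth <- c(5, 25, 35, 50, 100, 200)
  perfect <- evaluate_predictions(truth, truth)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$precision_fs, 0)

  # a single 13.72 ppb error at FS 200 gives 6.86 %FS
  one_off <- truth + c(13.72, 0, 0, 0, 0, 0)
  expect_equal(evaluate_predictions(one_off, truth)$precision_fs, 6.86)

  # errors {3, 4}: RMSE = sqrt(12.5)
  m <- evaluate_predictions(c(13, 24), c(10, 20))
  expect_equal(m$rmse, sqrt(12.5))
  expect_equal(m$mse, 12.5)

  # permutation invariance and inverse scaling with full scale
  withr::with_seed(3, {
    pr <- truth + rnorm(6)
    perm <- sample(6)
  })
  expect_equal(evaluate_predictions(pr[perm], truth[perm])$precision_fs,
               evaluate_predictions(pr, truth)$precision_fs)
  expect_equal(evaluate_predictions(pr, truth, full_scale = 400)$precision_fs,
               evaluate_predictions(pr, truth, full_scale = 200)$precision_fs / 2)

  expect_error(evaluate_predictions(1:3, 1:4), "lengths")
  expect_error(evaluate_predictions(1:3, rep(2, 3)), "zero variance")
})

test_that("extreme thresholds collapse the hybrid onto one sub-model", {
  runs <- quick_runs(seed = 4)
  s <- build_calibration_samples(runs, window = 21)
  train <- s[s$split == "train", ]
  test <- s[s$split == "test", ]
  mr <- fit_mr(train, "quadratic")
  gabp <- train_gabp(train, quick_ga(), max_epochs = 500)

  all_mr <- hybrid_model(mr, gabp, tau = max(test$x1) + 1)
  cmp_mr <- compare_models(mr, gabp, all_mr, test)
  expect_identical(cmp_mr$metrics$hybrid$rmse, cmp_mr$metrics$mr$rmse)

  all_gabp <- hybrid_model(mr, gabp, tau = min(test$x1) - 1)
  cmp_g <- compare_models(mr, gabp, all_gabp, test)
  expect_identical(cmp_g$metrics$hybrid$rmse, cmp_g$metrics$gabp$rmse)

  expect_error(compare_models(mr, gabp, all_mr, test[0, ]), "empty")
})

test_that("the flow-blind baseline ignores the flow channel", {
  runs <- quick_runs(seed = 6)
  s <- build_calibration_samples(runs, window = 21)
  train <- s[s$split == "train", ]
  bl <- fit_flow_blind_baseline(train, flow_set = 1000)
  nd <- data.frame(x1 = c(0.5, 1.5), x2 = c(0.2, 1.2))
  expect_equal(predict(bl, nd),
               bl$intercept + bl$slope * nd$x1)
  expect_error(fit_flow_blind_baseline(train, flow_set = 333),
               "missing condition")
})
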