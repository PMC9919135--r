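random_net <- function() {
  bp_decode(runif(9, -1, 1))
}

test_that("the forward pass matches hand-computed values", {
  # all-zero parameters: hidden activations 0.5, output 0
  net0 <- bp_network()
  expect_equal(as.vector(bp_forward(net0, c(0.3, -1))), 0)
  # zero output layer regardless of hidden values
  net1 <- bp_network(w_ih = matrix(rnorm(4), 2, 2), theta_h = c(1, -1))
  expect_equal(as.vector(bp_forward(net1, c(5, 5))), 0)
  # one explicit case: single effective path
  net2 <- bp_network(w_ih = matrix(c(2, 0, 0, 0), 2, 2),
                     theta_h = c(0, 0),
                     w_ho = matrix(c(1, 0), 2, 1), theta_o = 0.25)
  expect_equal(as.vector(bp_forward(net2, c(1, 0))),
               1 / (1 + exp(-2)) - 0.25)
  expect_identical(bp_forward(net2, c(1, 0)), bp_forward(net2, c(1, 0)))
  expect_error(bp_forward(net2, c(NA, 1)), "finite")
})

test_that("per-sample and mean errors follow their definitions", {
  net <- bp_network()   # predicts 0 everywhere
  expect_equal(bp_mean_error(net, matrix(0, 1, 2), 0), 0)
  # single output with error 2: E_k = 1/2 * 2^2 = 2
  expect_equal(as.vector(bp_sample_errors(net, matrix(0, 1, 2), 2)), 2)
  # E is the mean of per-sample E_k
  ek <- bp_sample_errors(net, matrix(0, 2, 2), c(sqrt(2), sqrt(6)))
  expect_equal(unname(ek), c(1, 3))
  expect_equal(bp_mean_error(net, matrix(0, 2, 2), c(sqrt(2), sqrt(6))), 2)
  expect_error(bp_sample_errors(net, matrix(0, 0, 2), numeric(0)), "empty")
})

test_that("analytic gradients agree with central differences", {
  withr::with_seed(55, {
    for (i in 1:10) {
      net <- random_net()
      m <- sample(1:8, 1)
      x <- matrix(rnorm(2 * m), m, 2)
      y <- matrix(rnorm(m), m, 1)
      g <- enoseflow:::flatten_gradient(enoseflow:::bp_gradient(net, x, y))
      fd <- fd_gradient(net, x, y)
      expect_equal(g, fd, tolerance = 1e-5)
    }
  })
})

test_that("plain gradient descent decreases E and respects zero gradients", {
  withr::with_seed(60, {
    net <- random_net()
    x <- matrix(runif(40), 20, 2)
    y <- matrix(x[, 1], 20, 1)
    tr <- backprop_train(net, x, y, learning_rate = 0.005, max_epochs = 300,
                         tolerance = 0, method = "gd")
    traj <- attr(tr, "trajectory")
    expect_true(all(diff(traj) <= 1e-12))
    expect_lt(tail(traj, 1), traj[1])
  })
  # a net already at E = 0 on representable data stays unchanged
  net <- bp_network(w_ih = matrix(c(1, 0, 0, 1), 2, 2), theta_h = c(0, 0),
                    w_ho = matrix(c(2, -1), 2, 1), theta_o = 0.5)
  x <- matrix(runif(10), 5, 2)
  y <- bp_forward(net, x)
  tr <- backprop_train(net, x, y, max_epochs = 50, method = "gd")
  expect_equal(bp_encode(tr), bp_encode(net))
  expect_error(backprop_train(net, x, y, learning_rate = -1), "positive")
})

test_that("rprop reaches much lower error than it starts with", {
  withr::with_seed(61, {
    net <- random_net()
    x <- matrix(runif(60), 30, 2)
    y <- matrix(0.5 * x[, 1] + 0.3 * x[, 2], 30, 1)
    tr <- backprop_train(net, x, y, max_epochs = 2000, method = "rprop")
    traj <- attr(tr, "trajectory")
    expect_lt(tail(traj, 1), traj[1] * 1e-3)
  })
})

test_that("chromosome encoding round-trips and validates length", {
  expect_length(bp_encode(bp_network()), 9)
  withr::with_seed(70, {
    for (i in 1:5) {
      net <- random_net()
      expect_equal(bp_encode(bp_decode(bp_encode(net))), bp_encode(net))
    }
  })
  z <- bp_decode(rep(0, 9))
  expect_true(all(bp_encode(z) == 0))
  expect_error(bp_decode(rep(0, 8)), "length")
})

test_that("the GA is seeded, elitist, and beats random initialization", {
  withr::with_seed(80, {
    x <- matrix(runif(40), 20, 2)
    target <- random_net()
    y <- bp_forward(target, x)
  })
  xv <- x[11:20, ]; yv <- y[11:20, , drop = FALSE]
  xf <- x[1:10, ]; yf <- y[1:10, , drop = FALSE]

  cfg <- ga_config(population_size = 4, generations = 8, inner_epochs = 20,
                   seed = 5)
  g1 <- ga_optimize(xf, yf, xv, yv, cfg)
  g2 <- ga_optimize(xf, yf, xv, yv, cfg)
  expect_identical(bp_encode(g1), bp_encode(g2))
  # elitism: per-generation best fitness never increases
  expect_true(all(diff(attr(g1, "best_fitness")) <= 0))
  expect_error(ga_config(population_size = 1), "population_size")

  # raw-fitness GA beats the median of random initializations in most seeds
  wins <- 0
  for (seed in 1:20) {
    cfg0 <- ga_config(population_size = 5, generations = 10,
                      fitness = "initial", seed = seed)
    ga_net <- ga_optimize(xf, yf, xv, yv, cfg0)
    ga_e <- bp_mean_error(ga_net, xv, yv)
    withr::with_seed(1000 + seed, {
      rand_e <- vapply(1:5, function(i) {
        bp_mean_error(bp_decode(runif(9, -1, 1)), xv, yv)
      }, numeric(1))
    })
    if (ga_e <= median(rand_e)) wins <- wins + 1
  }
  expect_gte(wins, 14)
})

test_that("train_gabp halves the samples, is reproducible, and fits a planted net", {
  withr::with_seed(90, {
    planted <- bp_network(w_ih = matrix(c(2, -1, 0.5, 1), 2, 2),
                          theta_h = c(0.2, -0.3),
                          w_ho = matrix(c(1.5, -0.8), 2, 1), theta_o = -0.1)
    x <- matrix(runif(360), 180, 2)
    y <- as.vector(bp_forward(planted, x))
  })
  samples <- data.frame(x1 = x[, 1], x2 = x[, 2], y = y)
  cfg <- ga_config(population_size = 4, generations = 10, inner_epochs = 50,
                   seed = 3)
  m1 <- train_gabp(samples, cfg, max_epochs = 3000)
  expect_length(m1$idx_fit, 90)
  expect_length(m1$idx_val, 90)
  expect_length(intersect(m1$idx_fit, m1$idx_val), 0)
  m2 <- train_gabp(samples, cfg, max_epochs = 3000)
  expect_identical(bp_encode(m1$net), bp_encode(m2$net))
  # realizable target: validation error becomes tiny
  expect_lt(m1$val_error, 1e-4)
  expect_error(train_gabp(samples[1:3, ], cfg), "at least 4")
})

test_that("gabp predictions invert the stored min-max scaling exactly", {
  g <- stub_gabp(x_range = rbind(c(0.1, 0.2), c(1.1, 1.2)),
                 y_range = c(5, 200))
  x1 <- c(0.1, 0.6); x2 <- c(0.2, 0.7)
  sx <- cbind((x1 - 0.1) / 1, (x2 - 0.2) / 1)
  manual <- as.vector(bp_forward(g$net, sx)) * 195 + 5
  expect_equal(predict_gabp(g, x1, x2), manual)
})
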