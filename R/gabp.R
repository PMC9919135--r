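#' Construct a small feedforward backpropagation network
#'
#' The flow-correction network is a 2-2-1 multilayer perceptron: two inputs
#' (NO-sensor feature and scaled flow feature), one hidden layer of two
#' logistic-sigmoid neurons, and a single identity-output neuron. Each neuron
#' computes `f(sum_i w_i * x_i - theta)` with threshold `theta` subtracted.
#'
#' @param n_in,n_hidden,n_out layer sizes.
#' @param w_ih input-to-hidden weight matrix (`n_in` x `n_hidden`).
#' @param theta_h hidden thresholds (length `n_hidden`).
#' @param w_ho hidden-to-output weight matrix (`n_hidden` x `n_out`).
#' @param theta_o output thresholds (length `n_out`).
#' @return Object of class `"bp_network"`.
#' @export
bp_network <- function(n_in = 2, n_hidden = 2, n_out = 1,
                       w_ih = matrix(0, n_in, n_hidden),
                       theta_h = numeric(n_hidden),
                       w_ho = matrix(0, n_hidden, n_out),
                       theta_o = numeric(n_out)) {
  w_ih <- matrix(w_ih, n_in, n_hidden)
  w_ho <- matrix(w_ho, n_hidden, n_out)
  stopifnot(length(theta_h) == n_hidden, length(theta_o) == n_out,
            all(is.finite(w_ih)), all(is.finite(w_ho)),
            all(is.finite(theta_h)), all(is.finite(theta_o)))
  structure(list(n_in = n_in, n_hidden = n_hidden, n_out = n_out,
                 w_ih = w_ih, theta_h = theta_h,
                 w_ho = w_ho, theta_o = theta_o),
            class = "bp_network")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Forward pass of the network
#'
#' @param net a [bp_network()].
#' @param x input matrix (rows = samples, `n_in` columns) or a single input
#'   vector.
#' @return Matrix of outputs (rows = samples, `n_out` columns).
#' @export
bp_forward <- function(net, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (any(!is.finite(x))) stop("bp_forward: inputs must be finite")
  stopifnot(ncol(x) == net$n_in)
  h <- sigmoid(sweep(x %*% net$w_ih, 2, net$theta_h))
  sweep(h %*% net$w_ho, 2, net$theta_o)
}

#' Per-sample and mean network error
#'
#' The per-sample error is `E_k = 1/2 * sum_j (yhat_jk - y_jk)^2`; the
#' training objective is its mean `E = mean_k(E_k)` over the set.
#'
#' @param net a [bp_network()].
#' @param x input matrix, `y` target matrix (rows = samples).
#' @return `bp_sample_errors()`: vector of `E_k`; `bp_mean_error()`: scalar `E`.
#' @export
bp_sample_errors <- function(net, x, y) {
  if (is.null(dim(y))) y <- matrix(y, ncol = net$n_out)
  if (nrow(y) == 0) stop("bp_sample_errors: empty sample set")
  pred <- bp_forward(net, x)
  0.5 * rowSums((pred - y)^2)
}

#' @rdname bp_sample_errors
#' @export
bp_mean_error <- function(net, x, y) mean(bp_sample_errors(net, x, y))

# Analytic gradient of the mean error E with respect to all parameters.
# Thresholds are subtracted in the activation, so their gradients carry the
# opposite sign of a bias term.
bp_gradient <- function(net, x, y) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (is.null(dim(y))) y <- matrix(y, ncol = net$n_out)
  m <- nrow(x)
  h <- sigmoid(sweep(x %*% net$w_ih, 2, net$theta_h))
  out <- sweep(h %*% net$w_ho, 2, net$theta_o)
  d_out <- (out - y) / m                       # dE/d(out), identity output
  d_h <- (d_out %*% t(net$w_ho)) * h * (1 - h) # back through sigmoid
  list(
    w_ih = t(x) %*% d_h,
    theta_h = -colSums(d_h),
    w_ho = t(h) %*% d_out,
    theta_o = -colSums(d_out)
  )
}

flatten_gradient <- function(g) {
  c(as.vector(g$w_ih), as.vector(g$w_ho), g$theta_h, g$theta_o)
}

#' Train a network by full-batch backpropagation
#'
#' Full-batch descent on the mean error `E`, stopping after `max_epochs` or
#' when the epoch-to-epoch change in `E` falls below `tolerance`. Two update
#' rules are available: `"rprop"` (resilient backpropagation — per-parameter
#' step sizes adapted from gradient sign agreement, with backtracking on
#' sign flips; the default, as it converges far faster and more reliably on
#' this small full-batch problem) and `"gd"` (plain steepest descent with a
#' fixed learning rate).
#'
#' @param net starting [bp_network()].
#' @param x,y training inputs/targets (rows = samples).
#' @param learning_rate positive step size (`"gd"`), or the initial step
#'   size (`"rprop"`).
#' @param max_epochs maximum number of full-batch epochs.
#' @param tolerance convergence threshold on the epoch-to-epoch change in
#'   `E`; for `"rprop"` it must hold over 10 consecutive epochs, since a
#'   single rejected step can leave `E` momentarily unchanged.
#' @param method update rule, `"rprop"` or `"gd"`.
#' @param x_val,y_val optional held-out samples; when given, the returned
#'   network is the one with the lowest held-out error along the training
#'   trajectory (early stopping against over-fitting).
#' @return The trained `"bp_network"` with attribute `"trajectory"` (the `E`
#'   value after each epoch, starting with the initial `E`); with a held-out
#'   set, also attribute `"val_error"` (held-out error of the returned
#'   network).
#' @export
backprop_train <- function(net, x, y, learning_rate = 0.05,
                           max_epochs = 5000, tolerance = 1e-9,
                           method = c("rprop", "gd"),
                           x_val = NULL, y_val = NULL) {
  method <- match.arg(method)
  if (!is.numeric(learning_rate) || learning_rate <= 0) {
    stop("backprop_train: 'learning_rate' must be positive")
  }
  if (is.null(dim(x))) x <- matrix(x, ncol = net$n_in)
  if (is.null(dim(y))) y <- matrix(y, ncol = net$n_out)
  m <- nrow(x)
  n_in <- net$n_in; n_hidden <- net$n_hidden; n_out <- net$n_out
  i1 <- n_in * n_hidden; i2 <- i1 + n_hidden * n_out; i3 <- i2 + n_hidden
  len <- i3 + n_out
  theta <- bp_encode(net)
  w_ih <- net$w_ih; w_ho <- net$w_ho
  theta_h <- net$theta_h; theta_o <- net$theta_o

  track_val <- !is.null(x_val)
  if (track_val) {
    if (is.null(dim(x_val))) x_val <- matrix(x_val, ncol = n_in)
    y_val <- matrix(y_val, ncol = n_out)
    mv <- nrow(x_val)
    best_val <- Inf
    best_theta <- theta
  }
  if (method == "rprop") {
    step <- rep(min(learning_rate, 0.1), len)
    g_prev <- rep(0, len)
  }
  traj <- numeric(max_epochs + 2)
  flat_count <- 0
  patience <- if (method == "rprop") 10 else 1
  e_prev <- NA_real_
  n_states <- 0
  for (epoch in 0:max_epochs) {
    h <- 1 / (1 + exp(-(x %*% w_ih - rep(theta_h, each = m))))
    err <- h %*% w_ho - rep(theta_o, each = m) - y
    e_cur <- 0.5 * sum(err^2) / m
    n_states <- epoch + 1
    traj[n_states] <- e_cur
    if (track_val) {
      hv <- 1 / (1 + exp(-(x_val %*% w_ih - rep(theta_h, each = mv))))
      ev <- 0.5 * sum((hv %*% w_ho - rep(theta_o, each = mv) - y_val)^2) / mv
      if (ev < best_val) {
        best_val <- ev
        best_theta <- theta
      }
    }
    if (epoch > 0) {
      flat_count <- if (abs(e_prev - e_cur) < tolerance) flat_count + 1 else 0
      if (flat_count >= patience) break
    }
    e_prev <- e_cur
    if (epoch == max_epochs) break
    d_out <- err / m
    d_h <- (d_out %*% t(w_ho)) * h * (1 - h)
    g <- c(as.vector(crossprod(x, d_h)), as.vector(crossprod(h, d_out)),
           -colSums(d_h), -colSums(d_out))
    if (method == "gd") {
      theta <- theta - learning_rate * g
    } else {
      agree <- sign(g * g_prev)
      step <- pmin(pmax(step * ifelse(agree > 0, 1.2,
                                      ifelse(agree < 0, 0.5, 1)),
                        1e-10), 1)
      theta <- theta + ifelse(agree < 0, 0, -sign(g) * step)
      g_prev <- ifelse(agree < 0, 0, g)
    }
    w_ih[] <- theta[seq_len(i1)]
    w_ho[] <- theta[(i1 + 1):i2]
    theta_h <- theta[(i2 + 1):i3]
    theta_o <- theta[(i3 + 1):len]
  }
  out_theta <- if (track_val) best_theta else theta
  net <- bp_decode(out_theta, n_in, n_hidden, n_out)
  if (track_val) attr(net, "val_error") <- best_val
  attr(net, "trajectory") <- traj[seq_len(n_states)]
  net
}

#' Chromosome encoding of network parameters
#'
#' Flattens all weights then all thresholds into one real gene vector, the
#' representation evolved by the genetic algorithm. Gene order: `w_ih`
#' (column-major), `w_ho` (column-major), `theta_h`, `theta_o` — 9 genes for
#' the default 2-2-1 architecture.
#'
#' @param net a [bp_network()].
#' @param chromosome numeric gene vector.
#' @param n_in,n_hidden,n_out architecture for decoding.
#' @return `bp_encode()`: numeric vector; `bp_decode()`: `"bp_network"`.
#' @export
bp_encode <- function(net) {
  c(as.vector(net$w_ih), as.vector(net$w_ho), net$theta_h, net$theta_o)
}

#' @rdname bp_encode
#' @export
bp_decode <- function(chromosome, n_in = 2, n_hidden = 2, n_out = 1) {
  len <- n_in * n_hidden + n_hidden * n_out + n_hidden + n_out
  if (length(chromosome) != len) {
    stop(sprintf("bp_decode: chromosome length %d, expected %d",
                 length(chromosome), len))
  }
  i <- 0
  take <- function(k) {
    v <- chromosome[(i + 1):(i + k)]
    i <<- i + k
    v
  }
  bp_network(
    n_in, n_hidden, n_out,
    w_ih = matrix(take(n_in * n_hidden), n_in, n_hidden),
    w_ho = matrix(take(n_hidden * n_out), n_hidden, n_out),
    theta_h = take(n_hidden),
    theta_o = take(n_out)
  )
}

#' Genetic-algorithm settings
#'
#' @param population_size number of chromosomes (>= 2); default 5.
#' @param generations number of GA iterations; default 50.
#' @param p_crossover per-pair arithmetic (blend) crossover probability.
#' @param p_mutation per-gene Gaussian mutation probability.
#' @param mutation_scale SD of the mutation perturbation.
#' @param elitism number of best individuals copied unchanged each generation.
#' @param init_range genes initialized uniformly in `[-init_range, init_range]`.
#' @param fitness `"refined"` (validation error after a short inner
#'   backpropagation refinement; default) or `"initial"` (validation error of
#'   the raw chromosome).
#' @param inner_epochs inner refinement epochs when `fitness = "refined"`.
#' @param seed integer seed.
#' @return List of class `"ga_config"`.
#' @export
ga_config <- function(population_size = 5, generations = 50,
                      p_crossover = 0.8, p_mutation = 0.1,
                      mutation_scale = 0.1, elitism = 1,
                      init_range = 1, fitness = c("refined", "initial"),
                      inner_epochs = 200, seed = 1L) {
  stopifnot(population_size >= 2, generations >= 1,
            p_crossover >= 0, p_crossover <= 1,
            p_mutation >= 0, p_mutation <= 1,
            mutation_scale >= 0, elitism >= 0,
            elitism <= population_size, inner_epochs >= 0)
  structure(list(
    population_size = as.integer(population_size),
    generations = as.integer(generations),
    p_crossover = p_crossover, p_mutation = p_mutation,
    mutation_scale = mutation_scale, elitism = as.integer(elitism),
    init_range = init_range, fitness = match.arg(fitness),
    inner_epochs = as.integer(inner_epochs), seed = as.integer(seed)
  ), class = "ga_config")
}

#' Genetic-algorithm search for initial network parameters
#'
#' Evolves chromosomes encoding the network's weights and thresholds with
#' tournament selection (size 2), arithmetic blend crossover, per-gene
#' Gaussian mutation and elitism. Fitness is the mean error on the
#' validation split — by default after a short inner backpropagation
#' refinement, so the winner is the initialization that *trains* best; the
#' chromosome returned is the unrefined initial parameter set.
#'
#' @param x_fit,y_fit fitting-split inputs/targets (used by the inner
#'   refinement).
#' @param x_val,y_val validation-split inputs/targets (fitness).
#' @param config a [ga_config()].
#' @param n_in,n_hidden,n_out architecture.
#' @return The best initial `"bp_network"`, with attributes
#'   `"best_fitness"` (per-generation best, length `generations + 1`
#'   including the initial population) and `"fitness"` (the winner's).
#' @export
ga_optimize <- function(x_fit, y_fit, x_val, y_val, config = ga_config(),
                        n_in = 2, n_hidden = 2, n_out = 1) {
  if (is.null(dim(x_fit))) x_fit <- matrix(x_fit, ncol = n_in)
  if (is.null(dim(x_val))) x_val <- matrix(x_val, ncol = n_in)
  y_fit <- matrix(y_fit, ncol = n_out)
  y_val <- matrix(y_val, ncol = n_out)
  if (nrow(x_val) == 0) stop("ga_optimize: validation split is empty")
  len <- n_in * n_hidden + n_hidden * n_out + n_hidden + n_out
  np <- config$population_size

  fitness_of <- function(chrom) {
    net <- bp_decode(chrom, n_in, n_hidden, n_out)
    if (config$fitness == "refined" && config$inner_epochs > 0) {
      net <- backprop_train(net, x_fit, y_fit, max_epochs = config$inner_epochs,
                            tolerance = 0)
    }
    bp_mean_error(net, x_val, y_val)
  }

  withr::with_seed(config$seed, {
    pop <- lapply(seq_len(np), function(i) {
      stats::runif(len, -config$init_range, config$init_range)
    })
    fit <- vapply(pop, fitness_of, numeric(1))
    best_per_gen <- numeric(config$generations + 1)
    best_per_gen[1] <- min(fit)

    for (gen in seq_len(config$generations)) {
      ord <- order(fit)
      elite <- pop[ord[seq_len(config$elitism)]]
      tournament <- function() {
        ij <- sample.int(np, 2, replace = TRUE)
        pop[[ij[which.min(fit[ij])]]]
      }
      children <- list()
      while (length(children) < np - config$elitism) {
        p1 <- tournament()
        p2 <- tournament()
        if (stats::runif(1) < config$p_crossover) {
          u <- stats::runif(1)
          c1 <- u * p1 + (1 - u) * p2
          c2 <- (1 - u) * p1 + u * p2
        } else {
          c1 <- p1
          c2 <- p2
        }
        children <- c(children, list(c1, c2))
      }
      children <- children[seq_len(np - config$elitism)]
      children <- lapply(children, function(ch) {
        hit <- stats::runif(len) < config$p_mutation
        ch[hit] <- ch[hit] + stats::rnorm(sum(hit), 0, config$mutation_scale)
        ch
      })
      pop <- c(elite, children)
      fit <- vapply(pop, fitness_of, numeric(1))
      best_per_gen[gen + 1] <- min(fit)
    }
    best <- pop[[which.min(fit)]]
    net <- bp_decode(best, n_in, n_hidden, n_out)
    attr(net, "best_fitness") <- best_per_gen
    attr(net, "fitness") <- min(fit)
    net
  })
}

#' Train the GA-initialized backpropagation calibrator
#'
#' End-to-end GA-BP fitting on calibration samples: the samples are randomly
#' halved (seeded) into a fitting and a verification group; `x1`, `x2` and
#' `y` are min-max scaled to `[0, 1]` using fitting-group ranges (stored in
#' the model); the genetic algorithm picks the initial weights and
#' thresholds; full-batch backpropagation then trains to convergence on the
#' fitting group.
#'
#' @param samples data frame with `x1`, `x2` and `concentration` (or `y`).
#' @param config a [ga_config()]; its `seed` also seeds the halving.
#' @param learning_rate,max_epochs,tolerance backpropagation settings.
#' @param n_hidden hidden-layer size.
#' @param method backpropagation update rule (see [backprop_train()]).
#' @return Object of class `"gabp_model"`: the trained `"bp_network"` plus
#'   min-max `scaling`, the split indices, GA fitness trajectory and final
#'   errors on both groups (scaled units).
#' @export
train_gabp <- function(samples, config = ga_config(),
                       learning_rate = 0.05, max_epochs = 10000,
                       tolerance = 1e-9, n_hidden = 2,
                       method = c("rprop", "gd")) {
  method <- match.arg(method)
  y <- samples$concentration %||% samples$y
  x <- cbind(x1 = samples$x1, x2 = samples$x2)
  m <- length(y)
  if (m < 4) stop("train_gabp: need at least 4 samples")

  withr::with_seed(config$seed, {
    idx_fit <- sort(sample.int(m, m %/% 2))
  })
  idx_val <- setdiff(seq_len(m), idx_fit)

  rng <- list(
    x_min = apply(x[idx_fit, , drop = FALSE], 2, min),
    x_max = apply(x[idx_fit, , drop = FALSE], 2, max),
    y_min = min(y[idx_fit]), y_max = max(y[idx_fit])
  )
  span <- function(lo, hi) ifelse(hi > lo, hi - lo, 1)
  sx <- sweep(sweep(x, 2, rng$x_min), 2, span(rng$x_min, rng$x_max), "/")
  sy <- (y - rng$y_min) / span(rng$y_min, rng$y_max)

  init <- ga_optimize(sx[idx_fit, , drop = FALSE], sy[idx_fit],
                      sx[idx_val, , drop = FALSE], sy[idx_val],
                      config, n_in = 2, n_hidden = n_hidden, n_out = 1)
  # the verification group guards against over-fitting: keep the parameters
  # at the verification-error minimum of the training trajectory
  net <- backprop_train(init, sx[idx_fit, , drop = FALSE], sy[idx_fit],
                        learning_rate = learning_rate,
                        max_epochs = max_epochs, tolerance = tolerance,
                        method = method,
                        x_val = sx[idx_val, , drop = FALSE],
                        y_val = sy[idx_val])
  structure(list(
    net = net,
    scaling = rng,
    idx_fit = idx_fit, idx_val = idx_val,
    ga_best_fitness = attr(init, "best_fitness"),
    bp_trajectory = attr(net, "trajectory"),
    fit_error = bp_mean_error(net, sx[idx_fit, , drop = FALSE],
                              sy[idx_fit]),
    val_error = bp_mean_error(net, sx[idx_val, , drop = FALSE],
                              sy[idx_val]),
    config = config
  ), class = "gabp_model")
}

#' Predict concentration with a trained GA-BP calibrator
#'
#' Applies the stored min-max scaling to the inputs, runs the forward pass,
#' and inverts the output scaling back to ppb.
#'
#' @param model a `"gabp_model"`.
#' @param x1,x2 numeric input vectors on the calibration-sample scale.
#' @return Predicted concentration(s) in ppb.
#' @export
predict_gabp <- function(model, x1, x2) {
  rng <- model$scaling
  span <- function(lo, hi) ifelse(hi > lo, hi - lo, 1)
  sx <- cbind(
    (x1 - rng$x_min[1]) / span(rng$x_min[1], rng$x_max[1]),
    (x2 - rng$x_min[2]) / span(rng$x_min[2], rng$x_max[2])
  )
  out <- bp_forward(model$net, sx)
  as.vector(out) * span(rng$y_min, rng$y_max) + rng$y_min
}

#' @export
predict.gabp_model <- function(object, newdata, ...) {
  predict_gabp(object, newdata$x1, newdata$x2)
}

#' @export
print.gabp_model <- function(x, ...) {
  cat(sprintf(
    "GA-BP calibrator (2-%d-1): fit E = %.3g, verification E = %.3g (scaled)\n",
    x$net$n_hidden, x$fit_error, x$val_error
  ))
  cat(sprintf("  GA: pop %d, %d generations, best fitness %.3g -> %.3g\n",
              x$config$population_size, x$config$generations,
              x$ga_best_fitness[1], utils::tail(x$ga_best_fitness, 1)))
  invisible(x)
}
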