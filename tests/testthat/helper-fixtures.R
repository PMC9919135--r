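# Shared fixtures: small designs and fast simulation settings so unit tests
# stay quick; full-size runs are exercised in the acceptance tests.

quick_design <- function(concentrations = c(25, 100),
                         flows = c(200, 600, 1000),
                         replicates = 2) {
  generate_design(concentrations, flows, replicates)
}

# 30 s runs at 10 Hz: 300 samples per channel
quick_runs <- function(design = quick_design(), seed = 1,
                       noise_sd = 0.05, duration = 30) {
  simulate_dataset(design, sim_params(seed = seed, noise_sd_voltage = noise_sd),
                   duration = duration)
}

quick_ga <- function(seed = 1) {
  ga_config(population_size = 3, generations = 5, inner_epochs = 30,
            seed = seed)
}

# a hand-built GA-BP model wrapper (identity-like scaling) for routing tests
stub_gabp <- function(net = bp_network(w_ih = diag(2), theta_h = c(0, 0),
                                       w_ho = matrix(c(1, 1), 2, 1),
                                       theta_o = 0),
                      x_range = rbind(c(0, 0), c(1, 1)),
                      y_range = c(0, 1)) {
  structure(list(
    net = net,
    scaling = list(x_min = x_range[1, ], x_max = x_range[2, ],
                   y_min = y_range[1], y_max = y_range[2]),
    idx_fit = 1L, idx_val = 2L,
    ga_best_fitness = NA_real_, bp_trajectory = NA_real_,
    fit_error = NA_real_, val_error = NA_real_,
    config = ga_config()
  ), class = "gabp_model")
}

# balanced factorial table with i.i.d. N(0, 1) noise and optional effects
random_table <- function(r = 3, s = 3, t = 2, effect_a = 0, effect_b = 0) {
  grid <- expand.grid(a = seq_len(r), b = seq_len(s), k = seq_len(t))
  resp <- stats::rnorm(nrow(grid)) +
    effect_a * grid$a + effect_b * grid$b
  factorial_table(grid$a, grid$b, resp)
}

# Independent oracle: two-factor decomposition via explicit loops over
# cell/marginal means, no vectorized shortcuts.
naive_two_way <- function(tab) {
  a <- as.integer(tab$a); b <- as.integer(tab$b); x <- tab$response
  r <- max(a); s <- max(b); t <- length(x) / (r * s)
  grand <- mean(x)
  ss_a <- 0
  for (i in 1:r) ss_a <- ss_a + s * t * (mean(x[a == i]) - grand)^2
  ss_b <- 0
  for (j in 1:s) ss_b <- ss_b + r * t * (mean(x[b == j]) - grand)^2
  ss_ab <- 0; ss_e <- 0
  for (i in 1:r) {
    for (j in 1:s) {
      cell <- x[a == i & b == j]
      ss_ab <- ss_ab + t * (mean(cell) - mean(x[a == i]) -
                              mean(x[b == j]) + grand)^2
      for (v in cell) ss_e <- ss_e + (v - mean(cell))^2
    }
  }
  list(ss_a = ss_a, ss_b = ss_b, ss_ab = ss_ab, ss_e = ss_e)
}

# central finite-difference gradient oracle for the BP network
fd_gradient <- function(net, x, y, eps = 1e-6) {
  th <- bp_encode(net)
  vapply(seq_along(th), function(i) {
    up <- th; up[i] <- up[i] + eps
    dn <- th; dn[i] <- dn[i] - eps
    (bp_mean_error(bp_decode(up), x, y) -
       bp_mean_error(bp_decode(dn), x, y)) / (2 * eps)
  }, numeric(1))
}
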