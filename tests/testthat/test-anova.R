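test_that("two_way_anova vanishes on constant data and errors on bad designs", {
  grid <- expand.grid(a = 1:2, b = 1:3, k = 1:2)
  tab <- factorial_table(grid$a, grid$b, rep(1.5, nrow(grid)))
  res <- two_way_anova(tab)
  expect_equal(res$ss_a + res$ss_b + res$ss_ab + res$ss_e, 0)
  expect_equal(res$df_a, 1)
  expect_equal(res$df_b, 2)
  expect_equal(res$df_ab, 2)
  expect_equal(res$df_e, 2 * 3 * 1)

  expect_error(factorial_table(c(1, 1, 2), c(1, 2, 1), rnorm(3)), "unbalanced")
  t1 <- factorial_table(c(1, 1, 2, 2), c(1, 2, 1, 2), rnorm(4))
  expect_error(two_way_anova(t1), "interaction inestimable")
})

test_that("the sum-of-squares partition is an identity on random tables", {
  withr::with_seed(21, {
    for (i in 1:100) {
      tab <- random_table(r = sample(2:4, 1), s = sample(2:4, 1),
                          t = sample(2:3, 1))
      res <- two_way_anova(tab)
      expect_equal(res$ss_a + res$ss_b + res$ss_ab + res$ss_e, res$ss_total,
                   tolerance = 1e-10)
    }
  })
})

test_that("two_way_anova agrees with the naive-loop oracle and with aov", {
  withr::with_seed(33, {
    for (dims in list(c(2, 2, 2), c(3, 3, 3))) {
      tab <- random_table(dims[1], dims[2], dims[3],
                          effect_a = 0.5, effect_b = 1)
      res <- two_way_anova(tab)
      ora <- naive_two_way(tab)
      expect_equal(res$ss_a, ora$ss_a)
      expect_equal(res$ss_b, ora$ss_b)
      expect_equal(res$ss_ab, ora$ss_ab)
      expect_equal(res$ss_e, ora$ss_e)
      # cross-check F and p against the standard fitter
      fit <- stats::aov(response ~ a * b, data = tab)
      sm <- summary(fit)[[1]]
      rownames(sm) <- trimws(rownames(sm))
      expect_equal(res$f_a, sm["a", "F value"], tolerance = 1e-10)
      expect_equal(res$f_b, sm["b", "F value"], tolerance = 1e-10)
      expect_equal(res$f_ab, sm["a:b", "F value"], tolerance = 1e-10)
      expect_equal(res$p_ab, sm["a:b", "Pr(>F)"], tolerance = 1e-10)
    }
  })
})

test_that("F statistics are shift invariant and SS scale quadratically", {
  withr::with_seed(9, {
    tab <- random_table(3, 2, 2, effect_a = 0.3)
    res <- two_way_anova(tab)
    shifted <- factorial_table(tab$a, tab$b, tab$response + 100)
    res_s <- two_way_anova(shifted)
    expect_equal(res_s$f_a, res$f_a)
    expect_equal(res_s$f_ab, res$f_ab)
    scaled <- factorial_table(tab$a, tab$b, tab$response * 3)
    res_c <- two_way_anova(scaled)
    expect_equal(res_c$ss_a, 9 * res$ss_a)
    expect_equal(res_c$ss_e, 9 * res$ss_e)
  })
})

test_that("lsd_subsets groups levels by the least significant difference", {
  # equal level means: one subset holding every level
  grid <- expand.grid(a = 1:3, b = 1:2, k = 1:3)
  resp <- rep(c(1, 2), each = 3, times = 3) + rep(c(0.01, -0.01, 0), 6)
  withr::with_seed(2, resp <- resp + rnorm(length(resp), 0, 1e-6))
  tab <- factorial_table(grid$a, grid$b, resp)

  withr::with_seed(4, {
    grid2 <- expand.grid(a = 1:4, b = 1:2, k = 1:5)
    base <- rnorm(nrow(grid2), 0, 0.5)
    tab2 <- factorial_table(grid2$a, grid2$b, base)
    res2 <- lsd_subsets(tab2, "A")
    # every level is covered
    expect_setequal(unlist(res2$subsets), levels(tab2$a))
    # shift one level far beyond the LSD: it must sit alone
    shift <- ifelse(grid2$a == 2, 100 * res2$lsd, 0)
    tab3 <- factorial_table(grid2$a, grid2$b, base + shift)
    res3 <- lsd_subsets(tab3, "A")
    expect_true(any(vapply(res3$subsets,
                           function(s) identical(s, "2"), logical(1))))
    # hand-computed LSD from the ANOVA of the same table
    aov3 <- two_way_anova(tab3)
    expect_equal(res3$lsd,
                 qt(0.975, aov3$df_e) * sqrt(2 * aov3$ms_e / 10))
  })
  expect_error(lsd_subsets(tab, "A", alpha = 1.2), "alpha")
})

test_that("identical level means fall into a single subset", {
  grid <- expand.grid(a = 1:3, b = 1:2, k = 1:3)
  # responses depend on B only: all A-level means identical
  resp <- ifelse(grid$b == 1, 0, 1) + rep(c(-0.01, 0.01), length.out = nrow(grid))
  tab <- factorial_table(grid$a, grid$b, resp)
  res <- lsd_subsets(tab, "A")
  expect_length(res$subsets, 1)
  expect_setequal(res$subsets[[1]], levels(tab$a))
})

test_that("homogeneity and normality wrappers behave on known inputs", {
  # identical groups: statistic 0, p = 1
  h0 <- variance_homogeneity_test(rep(c(1, 2), each = 10),
                                  rep(c("g1", "g2"), each = 10))
  expect_equal(h0$statistic, 0)
  expect_equal(h0$p_value, 1)
  # 100x spread difference is detected
  withr::with_seed(14, {
    x <- c(rnorm(50, 0, 1), rnorm(50, 0, 100))
    h1 <- variance_homogeneity_test(x, rep(c("a", "b"), each = 50))
    expect_lt(h1$p_value, 0.01)
  })
  expect_error(variance_homogeneity_test(rnorm(5), rep("a", 5)), ">= 2 groups")

  # normality test calibration: standard normal residuals rarely rejected
  hits <- 0
  for (seed in 1:100) {
    withr::with_seed(seed, r <- rnorm(100))
    if (normality_test(r)$p_value > 0.05) hits <- hits + 1
  }
  expect_gte(hits, 90)
  expect_error(normality_test(c(1, 2)), ">= 3")
})
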