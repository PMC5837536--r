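test_that("wald_estimate equals the ratio of sub-sample mean differences", {
  # ybar1=0.3, ybar0=0.2, xbar1=0.6, xbar0=0.2 -> (0.1)/(0.4) = 0.25
  co <- means_cohort(ybar1 = 0.3, ybar0 = 0.2, xbar1 = 0.6, xbar0 = 0.2)
  est <- wald_estimate(co, "y")
  expect_equal(est$estimate, 0.25, tolerance = 1e-12)
  expect_equal(est$n_used, 20)
  # CI is the normal-quantile construction around the point estimate
  expect_equal(est$ci_high - est$ci_low, 2 * qnorm(0.975) * est$se,
               tolerance = 1e-12)
  expect_true(est$ci_low <= est$estimate && est$estimate <= est$ci_high)

  # zero numerator -> zero estimate
  co0 <- means_cohort(ybar1 = 0.3, ybar0 = 0.3, xbar1 = 0.6, xbar0 = 0.2)
  expect_equal(wald_estimate(co0, "y")$estimate, 0)

  # zero first stage -> degenerate-instrument error
  cod <- means_cohort(ybar1 = 0.3, ybar0 = 0.2, xbar1 = 0.4, xbar0 = 0.4)
  expect_error(wald_estimate(cod, "y"), class = "ivb_degenerate_instrument")
})

test_that("ols bias component is the covariate mean difference across exposure arms", {
  d <- data.frame(x = rep(c(1, 0), each = 4), z = rep(c(1, 0), 4),
                  c = c(0.9, 0.5, 0.4, 0.2, 0.7, 0.3, 0.1, 0.1),
                  y = 0, doc = 1:8)
  co <- cohort_table(d, default_roles())
  est <- ols_bias_component(co, "c")
  expect_equal(est$estimate, mean(d$c[d$x == 1]) - mean(d$c[d$x == 0]),
               tolerance = 1e-12)
  # identical covariate across arms -> 0
  d$c <- rep(c(0.5, 0.3, 0.2, 0.1), 2)
  co <- cohort_table(d, default_roles())
  expect_equal(ols_bias_component(co, "c")$estimate, 0, tolerance = 1e-12)
})

test_that("iv bias component is the Wald ratio with the covariate as outcome", {
  # C means by Z: 0.26 vs 0.24; X means by Z: 0.6 vs 0.2 -> 0.02/0.4 = 0.05
  co <- means_cohort(ybar1 = 0.26, ybar0 = 0.24, xbar1 = 0.6, xbar0 = 0.2,
                     arm_n = 50)
  co$roles$covariates <- "y"
  est <- iv_bias_component(co, "y")
  expect_equal(est$estimate, 0.05, tolerance = 1e-12)
  expect_error(
    iv_bias_component(means_cohort(0.3, 0.2, 0.5, 0.5), "y"),
    class = "ivb_degenerate_instrument")
})

test_that("group-mean and regression-slope formulations agree on random tables", {
  for (seed in 1:25) {
    co <- random_cohort(seed = seed)
    d <- co$data
    # OLS component vs brute-force group means
    expect_equal(ols_bias_component(co, "c")$estimate,
                 mean(d$c[d$x == 1]) - mean(d$c[d$x == 0]), tolerance = 1e-10)
    # OLS component vs lm slope
    expect_equal(ols_bias_component(co, "c")$estimate,
                 unname(coef(lm(c ~ x, data = d))[2]), tolerance = 1e-10)
    # IV component vs Wald-ratio oracle
    wald_oracle <- (mean(d$c[d$z == 1]) - mean(d$c[d$z == 0])) /
      (mean(d$x[d$z == 1]) - mean(d$x[d$z == 0]))
    expect_equal(iv_bias_component(co, "c")$estimate, wald_oracle,
                 tolerance = 1e-10)
    # wald_estimate on a covariate is the same operation as iv_bias_component
    expect_equal(wald_estimate(co, "c")$estimate,
                 iv_bias_component(co, "c")$estimate, tolerance = 1e-12)
    expect_equal(wald_estimate(co, "c")$se, iv_bias_component(co, "c")$se,
                 tolerance = 1e-12)
  }
})

test_that("cluster-robust variance matches the sandwich-package oracle", {
  skip_if_not_installed("sandwich")
  for (seed in c(3, 11, 27)) {
    co <- random_cohort(n = 120, n_clusters = 15, seed = seed)
    d <- co$data
    m <- lm(c ~ x, data = d)
    v <- sandwich::vcovCL(m, cluster = d$doc, type = "HC0", cadjust = TRUE)
    expect_equal(ols_bias_component(co, "c")$se, sqrt(v[2, 2]),
                 tolerance = 1e-10)
    mfs <- lm(x ~ z, data = d)
    vfs <- sandwich::vcovCL(mfs, cluster = d$doc, type = "HC0", cadjust = TRUE)
    fs <- first_stage(co)
    expect_equal(fs$risk_difference$se, sqrt(vfs[2, 2]), tolerance = 1e-10)
    expect_equal(fs$partial_F, (coef(mfs)[[2]] / sqrt(vfs[2, 2]))^2,
                 tolerance = 1e-8)
  }
})

test_that("with instrument identical to exposure the two components coincide", {
  set.seed(5)
  d <- data.frame(x = rbinom(40, 1, 0.5), c = rnorm(40), y = 0,
                  doc = rep(1:8, 5))
  d$z <- d$x
  co <- cohort_table(d, default_roles())
  o <- ols_bias_component(co, "c")
  i <- iv_bias_component(co, "c")
  expect_equal(i$estimate, o$estimate, tolerance = 1e-12)
  expect_equal(i$se, o$se, tolerance = 1e-12)
})

test_that("first stage: trivial identities and independence behaviour", {
  set.seed(8)
  d <- data.frame(x = rbinom(60, 1, 0.5), c = 0, y = 0, doc = 1:60)
  d$z <- d$x
  co <- cohort_table(d, default_roles())
  expect_equal(first_stage(co)$risk_difference$estimate, 1)

  # perfectly balanced toy table: xbar identical in both arms -> 0
  d2 <- data.frame(x = rep(c(1, 0), 10), z = rep(c(1, 1, 0, 0), 5),
                   c = 0, y = 0, doc = 1:20)
  co2 <- cohort_table(d2, default_roles())
  expect_equal(first_stage(co2)$risk_difference$estimate, 0)

  # independent instrument: risk difference near 0, partial F small
  set.seed(123)
  n <- 10000
  d3 <- data.frame(x = rbinom(n, 1, 0.2), z = rbinom(n, 1, 0.2),
                   c = 0, y = 0, doc = seq_len(n))
  co3 <- cohort_table(d3, default_roles())
  fs <- first_stage(co3)
  expect_lt(abs(fs$risk_difference$estimate), 3 * fs$risk_difference$se)
  expect_lt(fs$partial_F, 10)
})

test_that("estimators are invariant to row order and cluster relabeling", {
  co <- random_cohort(n = 80, seed = 13)
  d <- co$data
  perm <- sample(nrow(d))
  d_perm <- d[perm, ]
  d_relab <- d
  d_relab$doc <- paste0("dr_", 1000L - as.integer(factor(d$doc)))
  for (dd in list(d_perm, d_relab)) {
    co2 <- cohort_table(dd, default_roles())
    expect_equal(iv_bias_component(co2, "c")$estimate,
                 iv_bias_component(co, "c")$estimate, tolerance = 1e-10)
    expect_equal(iv_bias_component(co2, "c")$se,
                 iv_bias_component(co, "c")$se, tolerance = 1e-10)
    expect_equal(ols_bias_component(co2, "c")$se,
                 ols_bias_component(co, "c")$se, tolerance = 1e-10)
  }
})

test_that("bias components are equivariant under covariate scaling", {
  co <- random_cohort(n = 60, seed = 21)
  k <- 7.3
  d <- co$data
  d$c <- d$c * k
  co_k <- cohort_table(d, default_roles())
  expect_equal(ols_bias_component(co_k, "c")$estimate,
               k * ols_bias_component(co, "c")$estimate, tolerance = 1e-10)
  expect_equal(ols_bias_component(co_k, "c")$se,
               k * ols_bias_component(co, "c")$se, tolerance = 1e-10)
  expect_equal(iv_bias_component(co_k, "c")$estimate,
               k * iv_bias_component(co, "c")$estimate, tolerance = 1e-10)
  expect_equal(iv_bias_component(co_k, "c")$se,
               k * iv_bias_component(co, "c")$se, tolerance = 1e-10)
})

test_that("a constant covariate yields a flagged degenerate component", {
  d <- data.frame(x = rep(c(1, 0), 5), z = rep(c(1, 0), each = 5),
                  c = 1, y = 0, doc = 1:10)
  co <- cohort_table(d, default_roles())
  est <- ols_bias_component(co, "c")
  expect_true(est$degenerate)
  expect_equal(est$estimate, 0)
  expect_equal(est$se, 0)
})
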