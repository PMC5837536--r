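test_that("threshold calibration has the right closed forms and solves the mixture", {
  # gamma = 0: instrument drops out, d = sqrt(2) * qnorm(1 - target)
  expect_equal(calibrate_threshold(0, 0.2, 0.2), sqrt(2) * qnorm(0.8),
               tolerance = 1e-9)
  # symmetric target: d = 0 for any instrument prevalence
  expect_equal(calibrate_threshold(0, 0.37, 0.5), 0, tolerance = 1e-9)
  expect_equal(calibrate_threshold(0, 0.8, 0.5), 0, tolerance = 1e-9)
  # the returned d satisfies the mixture equation to 1e-10
  d <- calibrate_threshold(0.5, 0.2, 0.2)
  mix <- 0.2 * pnorm((0.5 - d) / sqrt(2)) + 0.8 * pnorm(-d / sqrt(2))
  expect_equal(mix, 0.2, tolerance = 1e-10)
  expect_error(calibrate_threshold(0.5, 0.2, 0), class = "ivb_config_error")
})

test_that("calibrated threshold reproduces the target prevalence empirically", {
  co <- simulate_validity_dgp(sim_config(n = 200000, seed = 14))
  expect_lt(abs(mean(co$data$x) - 0.2), 0.005)
  expect_lt(abs(mean(co$data$z) - 0.2), 0.005)
  expect_true(all(abs(colMeans(co$data[paste0("c", 1:10)]) - 0.2) < 0.01))
})

test_that("generators are reproducible under a fixed seed", {
  a <- simulate_validity_dgp(sim_config(n = 500, seed = 99))
  b <- simulate_validity_dgp(sim_config(n = 500, seed = 99))
  expect_identical(a$data, b$data)
  a2 <- simulate_collider_dgp(sim_config(n = 500, seed = 99))
  b2 <- simulate_collider_dgp(sim_config(n = 500, seed = 99))
  expect_identical(a2$data, b2$data)
  s1 <- simulate_preference_cohort(sim_config(seed = 99), n_physicians = 20,
                                   patients_per_physician = 10)
  s2 <- simulate_preference_cohort(sim_config(seed = 99), n_physicians = 20,
                                   patients_per_physician = 10)
  expect_identical(s1$index$data, s2$index$data)
  expect_identical(s1$nc_population$data, s2$nc_population$data)
  # different seed -> different draws
  c2 <- simulate_validity_dgp(sim_config(n = 500, seed = 100))
  expect_false(identical(a$data$y, c2$data$y))
})

test_that("generated tables survive a write/read/validate round trip", {
  co <- simulate_validity_dgp(sim_config(n = 300, seed = 5))
  f <- withr::local_tempfile(fileext = ".csv")
  write_simulated_cohort(co, f)
  expect_true(file.exists(paste0(f, ".config.yaml")))
  roles <- column_roles("x", "z", outcomes = "y",
                        covariates = paste0("c", 1:10), cluster = "cluster")
  back <- read_cohort(f, roles)
  expect_equal(back$n, co$n)
  expect_identical(back$data$x, co$data$x)
  expect_equal(back$data$y, co$data$y, tolerance = 1e-12)
  cfg <- yaml::read_yaml(paste0(f, ".config.yaml"))
  expect_equal(cfg$seed, 5)
})

test_that("collider proxy has the configured correlation with the true confounder", {
  co <- simulate_collider_dgp(sim_config(n = 200000, seed = 4, proxy_r2 = 0.25))
  r2 <- cor(co$data$proxy, co$data$true_confounder)^2
  expect_lt(abs(r2 - 0.25), 0.01)
  # degenerate mixing: proxy independent of the confounder
  co0 <- simulate_collider_dgp(sim_config(n = 200000, seed = 4, proxy_r2 = 0))
  expect_lt(abs(cor(co0$data$proxy, co0$data$true_confounder)), 0.01)
})

test_that("treated-only restriction keeps only treated rows and flags them", {
  cfg <- sim_config(n = 5000, seed = 6, restrict_to_treated = TRUE)
  co <- simulate_collider_dgp(cfg)
  expect_true(all(co$data$treated == 1))
  full <- simulate_collider_dgp(sim_config(n = 5000, seed = 6))
  expect_equal(co$n, sum(full$data$treated))
})

test_that("preference cohort: instrument is the physician's previous prescription", {
  sim <- simulate_preference_cohort(sim_config(seed = 23), n_physicians = 40,
                                    patients_per_physician = 12)
  d <- sim$index$data
  # recompute the lag directly per physician (first patient already dropped)
  for (ph in unique(d$physician)[1:10]) {
    rows <- d[d$physician == ph, ]
    if (nrow(rows) > 1)
      expect_identical(rows$z[-1], rows$x[-nrow(rows)])
  }
  # preference transmits: positive first stage on a large draw
  big <- simulate_preference_cohort(sim_config(seed = 24), n_physicians = 300,
                                    patients_per_physician = 40)
  fs <- first_stage(big$index)
  expect_gt(fs$risk_difference$ci_low, 0)
  # negative control population is clustered on the same physicians
  expect_true(all(sim$nc_population$data$physician %in% seq_len(40)))
})

test_that("nc population built by the generator shows null associations", {
  sim <- simulate_preference_cohort(sim_config(seed = 31), n_physicians = 250,
                                    patients_per_physician = 30,
                                    nc_patients_per_physician = 40)
  rep <- nc_population_test(sim$nc_population)
  df <- as.data.frame(rep)
  expect_equal(nrow(df), 26)  # 24 binary + age + visits
  cover <- mean(df$ci_low <= 0 & df$ci_high >= 0)
  expect_gte(cover, 0.85)
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(n = 5), class = "ivb_config_error")
  expect_error(sim_config(instrument_prevalence = 0), class = "ivb_config_error")
  expect_error(sim_config(instrument_prevalence = 1), class = "ivb_config_error")
  expect_error(sim_config(proxy_r2 = 1), class = "ivb_config_error")
  expect_error(sim_config(n_pseudo_confounders = 0), class = "ivb_config_error")
})
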