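# Fixtures built in code: small cohorts used across test files.

# random small table with binary exposure/instrument, both arms guaranteed
random_cohort <- function(n = 50, n_clusters = 8, seed = NULL,
                          covariate = rnorm(n)) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    d <- data.frame(
      x = rbinom(n, 1, 0.4),
      z = rbinom(n, 1, 0.3),
      c = covariate,
      y = rnorm(n),
      doc = sample(seq_len(n_clusters), n, replace = TRUE)
    )
    dx <- mean(d$x[d$z == 1]) - mean(d$x[d$z == 0])
    ok <- all(c(0, 1) %in% d$x) && all(c(0, 1) %in% d$z) && !is.na(dx) && dx != 0
    if (ok) break
    covariate <- rnorm(n)
    d$c <- covariate
  }
  cohort_table(d, column_roles("x", "z", outcomes = "y", covariates = "c",
                               cluster = "doc"))
}

default_roles <- function(...) {
  column_roles(exposure = "x", instrument = "z", outcomes = "y",
               covariates = "c", cluster = "doc", ...)
}

# cohort with exactly the requested sub-sample means:
# ybar1/ybar0 are outcome means, xbar1/xbar0 exposure means by instrument arm
means_cohort <- function(ybar1, ybar0, xbar1, xbar0, arm_n = 10) {
  stopifnot(arm_n * c(xbar1, xbar0) == round(arm_n * c(xbar1, xbar0)))
  mk_y <- function(m) m + c(rep(0.5, arm_n / 2), rep(-0.5, arm_n / 2))
  d <- data.frame(
    z = rep(c(1, 0), each = arm_n),
    x = c(rep(1, arm_n * xbar1), rep(0, arm_n * (1 - xbar1)),
          rep(1, arm_n * xbar0), rep(0, arm_n * (1 - xbar0))),
    y = c(mk_y(ybar1), mk_y(ybar0)),
    doc = seq_len(2 * arm_n)
  )
  cohort_table(d, column_roles("x", "z", outcomes = "y", cluster = "doc"))
}
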