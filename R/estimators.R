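# Wald/2SLS estimator, OLS and IV bias components, first-stage strength.
#
# All variances use the one-way cluster-robust sandwich
#   V = A^{-1} [ sum_g s_g s_g' ] A^{-T} * G/(G-1),
# where s_g are within-cluster sums of per-row moment contributions and
# A is the Jacobian of the moment conditions.  With every row its own
# cluster this degenerates to a heteroskedasticity-robust estimator.

# -- core fits -----------------------------------------------------------

# sum over clusters of outer products of within-cluster moment sums
.cluster_meat <- function(U, cluster) {
  Ug <- rowsum(U, group = cluster, reorder = FALSE)
  crossprod(as.matrix(Ug))
}

# method-of-moments linear fit: solves W'(y - Xb) = 0 with clustered
# sandwich.  W == X gives OLS; W = [1, z] gives the just-identified IV fit.
.mm_fit <- function(y, X, W, cluster) {
  A <- crossprod(W, X)
  if (abs(det(A)) < .Machine$double.eps * max(abs(A))^ncol(A) * nrow(X))
    .stop_degenerate("moment Jacobian is singular (degenerate instrument or regressor)")
  b <- drop(solve(A, crossprod(W, y)))
  e <- drop(y - X %*% b)
  S <- .cluster_meat(W * e, cluster)
  G <- length(unique(cluster))
  Ainv <- solve(A)
  V <- Ainv %*% S %*% t(Ainv)
  if (G > 1L) V <- V * G / (G - 1)
  list(coef = b, vcov = V, resid = e, n = length(y), n_clusters = G)
}

# -- EstimateWithCI ------------------------------------------------------

.estimate_ci <- function(estimate, se, level, n_used, n_clusters,
                         method, degenerate = FALSE) {
  zq <- qnorm(1 - (1 - level) / 2)
  structure(list(
    estimate = estimate, se = se,
    ci_low = estimate - zq * se, ci_high = estimate + zq * se,
    level = level, n_used = n_used, n_clusters = n_clusters,
    method = method, degenerate = degenerate
  ), class = "estimate_ci")
}

#' @export
print.estimate_ci <- function(x, ...) {
  cat(sprintf("%s: %.6g (se %.4g) [%g%% CI %.6g, %.6g] n=%d clusters=%d%s\n",
              x$method, x$estimate, x$se, 100 * x$level, x$ci_low, x$ci_high,
              x$n_used, x$n_clusters,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

# complete-case extraction of (value, x, z, cluster) for one analysis column
.cc_frame <- function(cohort, column) {
  v <- .colname(cohort, column)
  x <- .col(cohort, "exposure")
  z <- .col(cohort, "instrument")
  g <- .col(cohort, "cluster")
  keep <- !is.na(v)
  list(v = v[keep], x = x[keep], z = z[keep], g = g[keep], n = sum(keep))
}

.check_arms <- function(ind, what) {
  if (!any(ind == 1) || !any(ind == 0))
    .stop_validation(sprintf("%s must have observations in both arms", what))
}

# -- Wald / 2SLS effect estimate ----------------------------------------

#' Wald (two-stage least squares) estimate of the exposure effect
#'
#' For a single binary instrument Z the Wald estimator is the ratio of the
#' instrument-arm difference in outcome means to the instrument-arm
#' difference in exposure means,
#' \deqn{\hat\psi = (\bar y_1 - \bar y_0) / (\bar x_1 - \bar x_0),}
#' identical to the 2SLS estimate of the effect of X on the risk-difference
#' scale.  The standard error is the cluster-robust 2SLS sandwich on the
#' cohort's cluster id; the confidence interval uses normal quantiles.
#'
#' @param cohort a \code{\link{cohort_table}}.
#' @param outcome name of the outcome column.
#' @param level confidence level, default 0.95.
#' @return an \code{estimate_ci}.
#' @examples
#' d <- data.frame(z = rep(c(1, 0), each = 5),
#'                 x = c(1, 1, 1, 0, 0, 1, 0, 0, 0, 0),
#'                 y = c(2, 1, 1, 0, 1, 1, 0, 1, 0, 0),
#'                 doc = 1:10)
#' co <- cohort_table(d, column_roles("x", "z", outcomes = "y", cluster = "doc"))
#' wald_estimate(co, "y")
#' @export
wald_estimate <- function(cohort, outcome, level = 0.95) {
  cc <- .cc_frame(cohort, outcome)
  .check_arms(cc$z, "instrument")
  dx <- mean(cc$x[cc$z == 1]) - mean(cc$x[cc$z == 0])
  if (dx == 0)
    .stop_degenerate("zero first stage: exposure means are identical across instrument arms")
  dy <- mean(cc$v[cc$z == 1]) - mean(cc$v[cc$z == 0])
  psi <- dy / dx
  fit <- .mm_fit(cc$v, cbind(1, cc$x), cbind(1, cc$z), cc$g)
  .estimate_ci(psi, sqrt(fit$vcov[2, 2]), level, cc$n, fit$n_clusters,
               method = "wald_2sls")
}

# -- bias components -----------------------------------------------------

#' OLS bias component of a covariate
#'
#' The confounding bias a covariate C would contribute to a conventional
#' (OLS) treatment-outcome regression if omitted, normalized to a unit
#' direct effect of C on the outcome:
#' \deqn{bias(OLS)/\beta_C = E[C | X=1] - E[C | X=0],}
#' i.e. the covariate mean difference across exposure arms, equal to the
#' least-squares slope of C on X.  Cluster-robust standard error.
#'
#' A covariate with zero variance yields a flagged degenerate result
#' (estimate 0, se 0) rather than an error, so report rows are preserved.
#'
#' @inheritParams wald_estimate
#' @param covariate name of the covariate column.
#' @return an \code{estimate_ci}.
#' @export
ols_bias_component <- function(cohort, covariate, level = 0.95) {
  cc <- .cc_frame(cohort, covariate)
  .check_arms(cc$x, "exposure")
  if (length(unique(cc$v)) < 2L) {
    g <- length(unique(cc$g))
    return(.estimate_ci(0, 0, level, cc$n, g, "ols_bias_component",
                        degenerate = TRUE))
  }
  est <- mean(cc$v[cc$x == 1]) - mean(cc$v[cc$x == 0])
  X <- cbind(1, cc$x)
  fit <- .mm_fit(cc$v, X, X, cc$g)
  .estimate_ci(est, sqrt(fit$vcov[2, 2]), level, cc$n, fit$n_clusters,
               method = "ols_bias_component")
}

#' IV bias component of a covariate
#'
#' The confounding bias a covariate C would contribute to the Wald/IV
#' estimate if omitted, normalized to a unit direct effect of C on the
#' outcome:
#' \deqn{bias(IV)/\beta_C = \frac{E[C|Z=1]-E[C|Z=0]}{E[X|Z=1]-E[X|Z=0]},}
#' the Wald ratio with the covariate in place of the outcome -- the
#' covariate imbalance across instrument arms scaled up by the first-stage
#' strength.  Equal to the 2SLS slope of C on X instrumented by Z.
#' Cluster-robust standard error.
#'
#' @inheritParams ols_bias_component
#' @return an \code{estimate_ci}.
#' @export
iv_bias_component <- function(cohort, covariate, level = 0.95) {
  cc <- .cc_frame(cohort, covariate)
  .check_arms(cc$z, "instrument")
  if (length(unique(cc$v)) < 2L) {
    g <- length(unique(cc$g))
    return(.estimate_ci(0, 0, level, cc$n, g, "iv_bias_component",
                        degenerate = TRUE))
  }
  dx <- mean(cc$x[cc$z == 1]) - mean(cc$x[cc$z == 0])
  if (dx == 0)
    .stop_degenerate("zero first stage: exposure means are identical across instrument arms")
  est <- (mean(cc$v[cc$z == 1]) - mean(cc$v[cc$z == 0])) / dx
  fit <- .mm_fit(cc$v, cbind(1, cc$x), cbind(1, cc$z), cc$g)
  .estimate_ci(est, sqrt(fit$vcov[2, 2]), level, cc$n, fit$n_clusters,
               method = "iv_bias_component")
}

# -- first stage ---------------------------------------------------------

#' First-stage strength of the instrument
#'
#' Regresses the exposure on the instrument.  The slope is the risk
#' difference \eqn{E[X|Z=1]-E[X|Z=0]} (how much more likely patients of a
#' physician whose previous prescription was the index drug are to receive
#' it), with a cluster-robust CI.  The partial F statistic is the squared
#' cluster-robust t-ratio of the instrument coefficient, the standard gauge
#' of instrument strength for a single instrument.
#'
#' @inheritParams wald_estimate
#' @return an object of class \code{first_stage}: list with
#'   \code{risk_difference} (an \code{estimate_ci}) and \code{partial_F}.
#' @export
first_stage <- function(cohort, level = 0.95) {
  x <- .col(cohort, "exposure")
  z <- .col(cohort, "instrument")
  g <- .col(cohort, "cluster")
  .check_arms(z, "instrument")
  est <- mean(x[z == 1]) - mean(x[z == 0])
  Z <- cbind(1, z)
  fit <- .mm_fit(x, Z, Z, g)
  se <- sqrt(fit$vcov[2, 2])
  rd <- .estimate_ci(est, se, level, length(x), fit$n_clusters,
                     method = "first_stage_risk_difference")
  structure(list(risk_difference = rd,
                 partial_F = if (se > 0) (est / se)^2 else Inf),
            class = "first_stage")
}

#' @export
print.first_stage <- function(x, ...) {
  cat(sprintf(
    "First stage: risk difference %.4f [%g%% CI %.4f, %.4f], partial F = %.1f\n",
    x$risk_difference$estimate, 100 * x$risk_difference$level,
    x$risk_difference$ci_low, x$risk_difference$ci_high, x$partial_F))
  invisible(x)
}
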