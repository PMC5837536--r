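# Modified Hausman test for the difference between OLS and IV bias
# components, via jointly stacked estimating equations, and the full
# covariate balance report.

#' Modified Hausman test for one covariate's bias components
#'
#' Tests whether the OLS and IV bias components of a covariate differ, i.e.
#' whether the covariate is informative about the relative confounding bias
#' of the two analyses.  Both slopes are estimated \emph{jointly} from
#' stacked moment conditions on the same sample: for each row i with
#' covariate c, exposure x, instrument z,
#' \deqn{E[(c_i - a_1 - b_{ols} x_i)(1, x_i)'] = 0, \quad
#'       E[(c_i - a_2 - b_{iv} x_i)(1, z_i)'] = 0.}
#' The system is exactly identified (one-step GMM, identity weighting), so
#' the point estimates coincide with the single-equation OLS and IV bias
#' components; the joint clustered sandwich over stacked per-cluster moment
#' sums supplies \eqn{var(\hat\beta_{iv} - \hat\beta_{ols})} \emph{including
#' the covariance} between the two slopes.  The test statistic
#' \deqn{(\hat\beta_{iv} - \hat\beta_{ols}) /
#'       \sqrt{\widehat{var}(\hat\beta_{iv} - \hat\beta_{ols})}}
#' is referred to N(0,1); the null hypothesis is no difference between the
#' bias components.
#'
#' @inheritParams ols_bias_component
#' @return an object of class \code{bias_component_pair}: list with
#'   \code{covariate}, \code{ols} and \code{iv} (\code{estimate_ci}),
#'   \code{test} (list with \code{difference}, \code{se_difference},
#'   \code{statistic}, \code{p_value}, \code{method}), \code{binary} and
#'   \code{degenerate} flags.
#' @export
hausman_bias_test <- function(cohort, covariate, level = 0.95) {
  cc <- .cc_frame(cohort, covariate)
  .check_arms(cc$z, "instrument")
  .check_arms(cc$x, "exposure")
  binary <- .is_binary01(cc$v)

  if (length(unique(cc$v)) < 2L) {
    g <- length(unique(cc$g))
    deg <- .estimate_ci(0, 0, level, cc$n, g, "ols_bias_component", degenerate = TRUE)
    deg_iv <- .estimate_ci(0, 0, level, cc$n, g, "iv_bias_component", degenerate = TRUE)
    return(structure(list(
      covariate = covariate, ols = deg, iv = deg_iv,
      test = list(difference = NA_real_, se_difference = NA_real_,
                  statistic = NA_real_, p_value = NA_real_,
                  method = "modified_hausman_gmm (suppressed: constant covariate)"),
      binary = binary, degenerate = TRUE), class = "bias_component_pair"))
  }

  dx <- mean(cc$x[cc$z == 1]) - mean(cc$x[cc$z == 0])
  if (dx == 0)
    .stop_degenerate("zero first stage: exposure means are identical across instrument arms")

  X <- cbind(1, cc$x)
  W <- cbind(1, cc$z)
  fit_ols <- .mm_fit(cc$v, X, X, cc$g)
  fit_iv <- .mm_fit(cc$v, X, W, cc$g)

  # joint clustered sandwich of theta = (a1, b_ols, a2, b_iv).
  # The Jacobian is block diagonal, so its inverse is the two per-equation
  # inverses and the diagonal blocks reproduce the single-equation vcovs.
  U <- cbind(X * fit_ols$resid, W * fit_iv$resid)
  S <- .cluster_meat(U, cc$g)
  G <- length(unique(cc$g))
  Ainv <- matrix(0, 4, 4)
  Ainv[1:2, 1:2] <- solve(crossprod(X, X))
  Ainv[3:4, 3:4] <- solve(crossprod(W, X))
  V <- Ainv %*% S %*% t(Ainv)
  if (G > 1L) V <- V * G / (G - 1)

  b_ols <- fit_ols$coef[2]
  b_iv <- fit_iv$coef[2]
  diff <- b_iv - b_ols
  var_diff <- max(V[2, 2] + V[4, 4] - 2 * V[2, 4], 0)
  se_diff <- sqrt(var_diff)
  stat <- if (se_diff > 0) diff / se_diff else if (abs(diff) < 1e-12) 0 else Inf
  p <- 2 * pnorm(-abs(stat))

  ols <- .estimate_ci(b_ols, sqrt(V[2, 2]), level, cc$n, G, "ols_bias_component")
  iv <- .estimate_ci(b_iv, sqrt(V[4, 4]), level, cc$n, G, "iv_bias_component")
  structure(list(
    covariate = covariate, ols = ols, iv = iv,
    test = list(difference = diff, se_difference = se_diff,
                statistic = stat, p_value = p,
                method = "modified_hausman_gmm (one-step, identity weighting, clustered sandwich)"),
    binary = binary, degenerate = FALSE), class = "bias_component_pair")
}

#' @export
print.bias_component_pair <- function(x, ...) {
  cat(sprintf("Bias components for '%s'%s\n", x$covariate,
              if (x$degenerate) " [degenerate]" else ""))
  print(x$ols); print(x$iv)
  if (!x$degenerate)
    cat(sprintf("  difference (iv - ols) = %.6g, z = %.3f, p = %.4g\n",
                x$test$difference, x$test$statistic, x$test$p_value))
  invisible(x)
}

#' Covariate balance report comparing OLS and IV bias components
#'
#' Runs \code{\link{hausman_bias_test}} for each requested covariate and
#' attaches the first-stage strength, producing the standard balance table:
#' one row per covariate with both bias components, their cluster-robust
#' CIs, and the two-sided difference p-value.  P-values are reported raw
#' (no multiplicity adjustment).  Degenerate covariates (e.g. an indicator
#' that never occurs) are flagged but never abort the table.
#'
#' @inheritParams ols_bias_component
#' @param covariates character vector of covariate column names.
#' @return an object of class \code{balance_report}: list with \code{pairs}
#'   (named list of \code{bias_component_pair}, input order preserved),
#'   \code{first_stage}, \code{n}, \code{n_clusters} and \code{metadata}.
#' @export
balance_table <- function(cohort, covariates = cohort$roles$covariates,
                          level = 0.95) {
  covariates <- as.character(covariates)
  if (length(covariates) == 0L)
    .stop_config("no covariates requested for the balance table")
  pairs <- lapply(covariates, function(cv) hausman_bias_test(cohort, cv, level))
  names(pairs) <- covariates
  structure(list(
    pairs = pairs,
    first_stage = first_stage(cohort, level),
    n = cohort$n,
    n_clusters = length(unique(.col(cohort, "cluster"))),
    metadata = list(
      level = level,
      variance = "one-way cluster-robust sandwich, G/(G-1) small-sample factor",
      joint_estimation = "stacked moment conditions, one-step GMM, identity weighting",
      missing_data = "complete-case per covariate",
      multiplicity = "none (raw p-values)")
  ), class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  cat(sprintf("<balance_report> %d covariates, N = %d, %d clusters\n",
              length(x$pairs), x$n, x$n_clusters))
  print(x$first_stage)
  print(as.data.frame(x, scale_binary = TRUE), digits = 3)
  invisible(x)
}

#' Flatten a balance report to a data frame
#'
#' One row per covariate.  With \code{scale_binary = TRUE} (the reporting
#' convention) estimates and CI bounds of \emph{binary} covariates are
#' multiplied by 100 (risk differences per 100 patients); continuous
#' covariates stay on their own scale as mean differences.
#'
#' @param x a \code{balance_report}.
#' @param row.names,optional ignored (S3 signature).
#' @param scale_binary multiply binary-covariate rows by 100.
#' @param ... ignored.
#' @export
as.data.frame.balance_report <- function(x, row.names = NULL, optional = FALSE,
                                         scale_binary = FALSE, ...) {
  rows <- lapply(x$pairs, function(p) {
    k <- if (scale_binary && p$binary) 100 else 1
    data.frame(
      covariate = p$covariate,
      binary = p$binary,
      scale = if (scale_binary && p$binary) "risk difference x 100" else "mean difference",
      ols_estimate = k * p$ols$estimate, ols_se = k * p$ols$se,
      ols_low = k * p$ols$ci_low, ols_high = k * p$ols$ci_high,
      iv_estimate = k * p$iv$estimate, iv_se = k * p$iv$se,
      iv_low = k * p$iv$ci_low, iv_high = k * p$iv$ci_high,
      difference = k * p$test$difference,
      se_difference = k * p$test$se_difference,
      statistic = p$test$statistic,
      p_value = p$test$p_value,
      degenerate = p$degenerate,
      n_used = p$ols$n_used,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
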