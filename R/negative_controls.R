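# Negative control outcome and negative control population tests.

#' Negative control outcome test
#'
#' Estimates the association of the exposure with a negative-control
#' outcome -- an outcome plausibly affected by the same confounders as the
#' outcome of interest (e.g. urinary tract infection in a smoking-cessation
#' cohort) but not by the treatment itself -- side by side with the
#' conventional (OLS) and the instrumental-variable (Wald/2SLS) analysis on
#' the same complete-case sample.  A conventional estimate away from zero
#' with an IV estimate near zero suggests residual confounding in the
#' conventional analysis; the function reports estimates only and leaves
#' interpretation to the user.
#'
#' @inheritParams wald_estimate
#' @param nc_outcome name of the negative-control outcome column.
#' @return an object of class \code{nc_outcome_result}: list with
#'   \code{outcome}, \code{conventional} and \code{iv} (\code{estimate_ci};
#'   the IV element carries a degenerate flag instead of an estimate when
#'   the instrument has no first stage), \code{binary} and \code{n}.
#' @export
nc_outcome_test <- function(cohort, nc_outcome, level = 0.95) {
  cc <- .cc_frame(cohort, nc_outcome)
  .check_arms(cc$x, "exposure")
  binary <- .is_binary01(cc$v)

  if (length(unique(cc$v)) < 2L) {
    g <- length(unique(cc$g))
    conv <- .estimate_ci(0, 0, level, cc$n, g, "ols_exposure_association",
                         degenerate = TRUE)
    ivd <- .estimate_ci(0, 0, level, cc$n, g, "wald_2sls", degenerate = TRUE)
    return(structure(list(outcome = nc_outcome, conventional = conv, iv = ivd,
                          binary = binary, n = cc$n),
                     class = "nc_outcome_result"))
  }

  X <- cbind(1, cc$x)
  fit <- .mm_fit(cc$v, X, X, cc$g)
  conv <- .estimate_ci(mean(cc$v[cc$x == 1]) - mean(cc$v[cc$x == 0]),
                       sqrt(fit$vcov[2, 2]), level, cc$n, fit$n_clusters,
                       "ols_exposure_association")

  dx <- mean(cc$x[cc$z == 1]) - mean(cc$x[cc$z == 0])
  if (any(cc$z == 1) && any(cc$z == 0) && dx != 0) {
    fiv <- .mm_fit(cc$v, X, cbind(1, cc$z), cc$g)
    est <- (mean(cc$v[cc$z == 1]) - mean(cc$v[cc$z == 0])) / dx
    iv <- .estimate_ci(est, sqrt(fiv$vcov[2, 2]), level, cc$n,
                       fiv$n_clusters, "wald_2sls")
  } else {
    iv <- .estimate_ci(NA_real_, NA_real_, level, cc$n,
                       length(unique(cc$g)), "wald_2sls", degenerate = TRUE)
  }
  structure(list(outcome = nc_outcome, conventional = conv, iv = iv,
                 binary = binary, n = cc$n),
            class = "nc_outcome_result")
}

#' @export
print.nc_outcome_result <- function(x, ...) {
  cat(sprintf("Negative control outcome '%s' (n = %d)\n", x$outcome, x$n))
  print(x$conventional); print(x$iv)
  invisible(x)
}

#' @export
as.data.frame.nc_outcome_result <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  one <- function(e, label) data.frame(
    outcome = x$outcome, analysis = label, estimate = e$estimate, se = e$se,
    ci_low = e$ci_low, ci_high = e$ci_high, n = e$n_used,
    degenerate = e$degenerate, stringsAsFactors = FALSE)
  out <- rbind(one(x$conventional, "conventional"), one(x$iv, "instrumental_variable"))
  rownames(out) <- NULL
  out
}

#' Negative control population test
#'
#' In a negative control population -- patients who saw the same physicians
#' but were not candidates for the treatment of interest (e.g. non-smokers
#' consulting on the day the GP issued a smoking-cessation prescription to
#' another patient) -- the proposed instrument should not be associated with
#' any outcome, because the physician's preference cannot act through a
#' prescription these patients never received.  For each outcome the
#' function fits a linear (risk-difference) regression of the outcome on the
#' instrument with a physician-clustered robust CI.  Binary outcomes are
#' reported on the risk-difference-times-100 scale; continuous outcomes as
#' raw mean differences.
#'
#' @param nc_cohort a \code{\link{cohort_table}} for the negative control
#'   population; its exposure role is unused.
#' @param outcomes character vector of outcome column names.
#' @param level confidence level.
#' @return an object of class \code{nc_report}: list with \code{rows} (named
#'   list of \code{estimate_ci} on the reporting scale), \code{scales},
#'   \code{n} and \code{n_clusters}.
#' @export
nc_population_test <- function(nc_cohort, outcomes = nc_cohort$roles$outcomes,
                               level = 0.95) {
  outcomes <- as.character(outcomes)
  if (length(outcomes) == 0L)
    .stop_config("no outcomes requested for the negative control population test")
  z_all <- .col(nc_cohort, "instrument")
  g_all <- .col(nc_cohort, "cluster")
  rows <- list(); scales <- character(length(outcomes)); names(scales) <- outcomes
  for (oc in outcomes) {
    v <- .colname(nc_cohort, oc)
    keep <- !is.na(v)
    v <- v[keep]; z <- z_all[keep]; g <- g_all[keep]
    .check_arms(z, "instrument")
    binary <- .is_binary01(v)
    k <- if (binary) 100 else 1
    scales[oc] <- if (binary) "risk difference x 100" else "mean difference"
    if (length(unique(v)) < 2L) {
      rows[[oc]] <- .estimate_ci(0, 0, level, length(v), length(unique(g)),
                                 "nc_population_association", degenerate = TRUE)
      next
    }
    est <- mean(v[z == 1]) - mean(v[z == 0])
    Z <- cbind(1, z)
    fit <- .mm_fit(v, Z, Z, g)
    se <- sqrt(fit$vcov[2, 2])
    rows[[oc]] <- .estimate_ci(k * est, k * se, level, length(v),
                               fit$n_clusters, "nc_population_association",
                               degenerate = se == 0)
  }
  structure(list(rows = rows, scales = scales,
                 n = nc_cohort$n,
                 n_clusters = length(unique(g_all))),
            class = "nc_report")
}

#' @export
print.nc_report <- function(x, ...) {
  cat(sprintf("<nc_report> instrument-outcome associations in negative control population (n = %d, %d clusters)\n",
              x$n, x$n_clusters))
  print(as.data.frame(x), digits = 3)
  invisible(x)
}

#' @export
as.data.frame.nc_report <- function(x, row.names = NULL, optional = FALSE, ...) {
  out <- do.call(rbind, lapply(names(x$rows), function(oc) {
    e <- x$rows[[oc]]
    data.frame(outcome = oc, scale = unname(x$scales[oc]),
               estimate = e$estimate, se = e$se,
               ci_low = e$ci_low, ci_high = e$ci_high,
               n = e$n_used, degenerate = e$degenerate,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
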