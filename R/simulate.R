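# Simulation generators: valid-instrument DGP, collider/selection DGP,
# and a clustered physician-preference cohort with negative controls.

#' Simulation configuration
#'
#' Bundles every data-generating-process parameter.  The defaults are the
#' study conditions of the package's reference simulation: instrument
#' strength \code{gamma = 0.5} on the latent exposure index, treatment
#' effect \code{beta = 0.5}, \code{n = 10000}, ten pseudo-confounders, and
#' all prevalences (instrument, pseudo-confounder, target exposure) equal to
#' 0.2.  \code{proxy_r2 = 0.01} is the squared correlation between the
#' measured proxy confounder and the true confounder in the collider DGP.
#'
#' \code{collider} holds the remaining constants of the
#' selection-on-treatment process (see
#' \code{\link{simulate_collider_dgp}}): \code{selection_instrument} and
#' \code{selection_confounder} (effects of instrument and true confounder on
#' the probit index of receiving any treatment, defaults 2 and 2),
#' \code{selection_threshold} (default 0), \code{choice_gamma} (instrument
#' effect on the drug-choice index among the treated, default 0.5) and
#' \code{choice_threshold} (default 0.5).
#'
#' @param n number of patients.
#' @param gamma instrument strength on the exposure index.
#' @param beta treatment effect on the outcome.
#' @param n_pseudo_confounders number of independent binary
#'   pseudo-confounders c1, c2, ...
#' @param instrument_prevalence Pr(Z = 1).
#' @param pseudo_confounder_prevalence Pr(c_j = 1).
#' @param target_exposure_prevalence desired Pr(X = 1); the exposure
#'   threshold d is calibrated to hit it.
#' @param seed integer seed; every generator is reproducible under it.
#' @param proxy_r2 squared proxy-confounder correlation (collider DGP).
#' @param restrict_to_treated restrict the collider cohort to treated rows.
#' @param collider named list of collider-DGP constants (see Details).
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(n = 10000, gamma = 0.5, beta = 0.5,
                       n_pseudo_confounders = 10,
                       instrument_prevalence = 0.2,
                       pseudo_confounder_prevalence = 0.2,
                       target_exposure_prevalence = 0.2,
                       seed = 1L,
                       proxy_r2 = 0.01,
                       restrict_to_treated = FALSE,
                       collider = list()) {
  cfg <- list(n = as.integer(n), gamma = gamma, beta = beta,
              n_pseudo_confounders = as.integer(n_pseudo_confounders),
              instrument_prevalence = instrument_prevalence,
              pseudo_confounder_prevalence = pseudo_confounder_prevalence,
              target_exposure_prevalence = target_exposure_prevalence,
              seed = as.integer(seed), proxy_r2 = proxy_r2,
              restrict_to_treated = isTRUE(restrict_to_treated),
              collider = utils::modifyList(
                list(selection_instrument = 2, selection_confounder = 2,
                     selection_threshold = 0, choice_gamma = 0.5,
                     choice_threshold = 0.5),
                collider))
  if (cfg$n < 10L) .stop_config("n must be at least 10")
  for (p in c("instrument_prevalence", "pseudo_confounder_prevalence",
              "target_exposure_prevalence")) {
    if (!is.numeric(cfg[[p]]) || cfg[[p]] <= 0 || cfg[[p]] >= 1)
      .stop_config(sprintf("%s must lie strictly in (0, 1)", p))
  }
  if (!is.numeric(cfg$proxy_r2) || cfg$proxy_r2 < 0 || cfg$proxy_r2 >= 1)
    .stop_config("proxy_r2 must lie in [0, 1)")
  if (cfg$n_pseudo_confounders < 1L)
    .stop_config("n_pseudo_confounders must be at least 1")
  structure(cfg, class = "sim_config")
}

#' Calibrate the exposure threshold of the validity DGP
#'
#' The simulated exposure is \code{x = 1(z*gamma + u + w > d)} with u, w
#' independent standard normals, so the latent index given z is normal with
#' mean \code{z*gamma} and variance 2.  The marginal exposure prevalence is
#' the two-arm mixture
#' \deqn{p_z \Phi((\gamma - d)/\sqrt2) + (1-p_z)\Phi(-d/\sqrt2),}
#' and \code{calibrate_threshold} solves it for d by bracketed root-finding
#' (to |f(d)| < 1e-10) so that the configured target prevalence is attained.
#'
#' @param gamma instrument strength on the exposure index.
#' @param instrument_prevalence Pr(Z = 1).
#' @param target_exposure_prevalence desired Pr(X = 1).
#' @return the threshold d (numeric scalar).
#' @examples
#' # with gamma = 0 the instrument drops out and d has a closed form
#' all.equal(calibrate_threshold(0, 0.2, 0.2), sqrt(2) * qnorm(0.8))
#' @export
calibrate_threshold <- function(gamma, instrument_prevalence,
                                target_exposure_prevalence) {
  p_z <- instrument_prevalence
  target <- target_exposure_prevalence
  if (target <= 0 || target >= 1) .stop_config("target prevalence must be in (0, 1)")
  f <- function(d) {
    p_z * pnorm((gamma - d) / sqrt(2)) + (1 - p_z) * pnorm(-d / sqrt(2)) - target
  }
  lo <- -10; hi <- 10 + abs(gamma)
  if (f(lo) < 0 || f(hi) > 0)
    .ivb_stop("no sign change for the threshold equation on [-10, 10 + |gamma|]",
              "ivb_numerical_error")
  root <- uniroot(f, c(lo, hi), tol = .Machine$double.eps^0.75)$root
  if (abs(f(root)) > 1e-10)
    .ivb_stop("threshold root-finding did not converge to |f(d)| < 1e-10",
              "ivb_numerical_error")
  root
}

.as_cohort <- function(df, outcomes, covariates) {
  roles <- column_roles(exposure = "x", instrument = "z",
                        outcomes = outcomes, covariates = covariates,
                        cluster = "cluster")
  cohort_table(df, roles)
}

#' Simulate the valid-instrument reference DGP
#'
#' Generates the hypothetical-analysis simulation in which the instrument is
#' valid by construction, so any apparent excess in the IV bias components
#' is sampling noise.  With configured prevalences and strengths:
#' \code{z ~ bernoulli(0.2)}; ten pseudo-confounders
#' \code{cj ~ bernoulli(0.2)} independent of everything (potential but not
#' true confounders); latent normals u, v, w;
#' \code{x = 1(z*gamma + u + w > d)} with d calibrated by
#' \code{\link{calibrate_threshold}}; and continuous outcome
#' \code{y = x*beta + u + v}.  The confounder u affects both exposure and
#' outcome, so conventional regression of y on x is biased upward while the
#' IV analysis is consistent.  Sampling order is fixed (z, then the c's,
#' then u, w, v) so a seed fully determines the table.  Each row is its own
#' cluster: the DGP has no grouping, and the cluster-robust machinery then
#' degenerates to a heteroskedasticity-robust estimator.
#'
#' @param config a \code{\link{sim_config}}.
#' @return a \code{\link{cohort_table}} with columns z, x, y, c1..cK and a
#'   per-row cluster id; the generating config is attached as attribute
#'   \code{"sim_config"}.
#' @export
simulate_validity_dgp <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n
  d <- calibrate_threshold(config$gamma, config$instrument_prevalence,
                           config$target_exposure_prevalence)
  z <- rbinom(n, 1L, config$instrument_prevalence)
  K <- config$n_pseudo_confounders
  cmat <- matrix(rbinom(n * K, 1L, config$pseudo_confounder_prevalence),
                 nrow = n, ncol = K)
  colnames(cmat) <- paste0("c", seq_len(K))
  u <- rnorm(n); w <- rnorm(n); v <- rnorm(n)
  x <- as.integer(z * config$gamma + u + w > d)
  y <- x * config$beta + u + v
  df <- data.frame(z = z, x = x, y = y, cmat, cluster = seq_len(n))
  out <- .as_cohort(df, outcomes = "y", covariates = colnames(cmat))
  attr(out, "sim_config") <- config
  attr(out, "threshold_d") <- d
  out
}

#' Simulate the collider-bias (selection-on-treatment) DGP
#'
#' A synthetic stand-in process, designed within this package, that
#' reproduces the two features of the selection-on-treatment problem: a
#' measured proxy confounder only weakly correlated with the true
#' confounder (squared correlation \code{proxy_r2}, default 0.01), and
#' restriction of the analysis to treated patients, which conditions on a
#' collider and induces instrument-confounder association.
#'
#' Structure: instrument \code{z ~ bernoulli(instrument_prevalence)}
#' (physician preference, valid in the full population); true confounder
#' \code{u ~ N(0,1)} (e.g. underlying health); observed proxy
#' \code{proxy = sqrt(r2)*u + sqrt(1-r2)*noise}; receipt of \emph{any}
#' treatment \code{treated = 1(a_z (z - p_z) + a_u u + e > s)} -- caused by
#' both the instrument and the confounder, hence a collider; drug choice
#' among the treated \code{x = treated * 1(g z + e' > t)} driven by
#' preference only; outcome \code{y = x*beta + u + noise}.  Restricting to
#' \code{treated == 1} makes z and u dependent, so the IV bias component of
#' the proxy becomes detectable and much larger than the OLS component,
#' while in the unrestricted cohort the two are of comparable size.
#'
#' @param config a \code{\link{sim_config}}; the constants live in
#'   \code{config$collider}, and \code{config$restrict_to_treated} selects
#'   the treated-only subset.
#' @return a \code{\link{cohort_table}} with columns z, x, y, proxy,
#'   true_confounder, treated and per-row cluster id.  The \code{treated}
#'   column is always emitted; when \code{restrict_to_treated} is set the
#'   returned table contains the treated rows only.
#' @export
simulate_collider_dgp <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n
  cc <- config$collider
  p_z <- config$instrument_prevalence
  z <- rbinom(n, 1L, p_z)
  u <- rnorm(n)
  proxy <- sqrt(config$proxy_r2) * u + sqrt(1 - config$proxy_r2) * rnorm(n)
  treated <- as.integer(cc$selection_instrument * (z - p_z) +
                          cc$selection_confounder * u + rnorm(n) >
                          cc$selection_threshold)
  choice <- as.integer(cc$choice_gamma * z + rnorm(n) > cc$choice_threshold)
  x <- treated * choice
  y <- x * config$beta + u + rnorm(n)
  df <- data.frame(z = z, x = x, y = y, proxy = proxy, true_confounder = u,
                   treated = treated, cluster = seq_len(n))
  if (config$restrict_to_treated) {
    df <- df[df$treated == 1L, , drop = FALSE]
    rownames(df) <- NULL
  }
  out <- .as_cohort(df, outcomes = "y",
                    covariates = c("proxy", "true_confounder"))
  attr(out, "sim_config") <- config
  out
}

#' Simulate a clustered physician-preference cohort with negative controls
#'
#' Emulates the design of a primary-care prescribing study: physicians carry
#' a latent preference for the index drug; each patient's instrument is the
#' prescription the \emph{same physician issued to their previous patient}
#' (the first patient of every physician is dropped, having no
#' predecessor); the prescription received depends on the physician's
#' preference and on a patient-level confounder (healthy-user bias); the
#' outcome of interest carries a true treatment effect plus confounding; a
#' negative-control outcome (\code{nc_uti}, an infection-like indicator) is
#' driven by the confounder only.  Observed covariates (\code{comorbidity},
#' \code{visits}) are noisy reflections of the confounder.
#'
#' A matching negative control population is generated on the same
#' physicians: patients who were never candidates for the treatment, whose
#' instrument is a fresh draw from their physician's prescribing process and
#' whose outcomes (\code{m01..m24} binary indicators at varying prevalences
#' plus continuous \code{age} and \code{visits}) depend only on their own
#' confounder -- so every instrument-outcome association in it is null by
#' construction.
#'
#' @param config a \code{\link{sim_config}}; \code{beta} is the treatment
#'   effect and \code{seed} the master seed.  \code{n} is ignored in favour
#'   of the physician-level sizes below.
#' @param n_physicians number of physicians (clusters).
#' @param patients_per_physician average index patients per physician
#'   (Poisson-distributed, minimum 2).
#' @param preference_sd standard deviation of the physician latent
#'   preference on the log-odds scale.
#' @param confounding_strength effect of the patient confounder on the
#'   prescription log-odds.
#' @param nc_patients_per_physician average negative-control patients per
#'   physician.
#' @return a list with elements \code{index} and \code{nc_population}, both
#'   \code{\link{cohort_table}}s clustered on \code{physician}.
#' @export
simulate_preference_cohort <- function(config = sim_config(),
                                       n_physicians = 150,
                                       patients_per_physician = 30,
                                       preference_sd = 1,
                                       confounding_strength = 0.5,
                                       nc_patients_per_physician = 20) {
  stopifnot(inherits(config, "sim_config"))
  if (n_physicians < 2L) .stop_config("need at least 2 physicians")
  if (patients_per_physician < 2)
    .stop_config("need at least 2 patients per physician on average")
  set.seed(config$seed)

  m <- as.integer(n_physicians)
  base_logit <- qlogis(0.3)
  pref <- rnorm(m, 0, preference_sd)
  n_pat <- pmax(2L, rpois(m, patients_per_physician))
  phys <- rep(seq_len(m), n_pat)
  n <- length(phys)

  h <- rnorm(n)  # patient confounder (healthy-user axis)
  x <- rbinom(n, 1L, plogis(base_logit + pref[phys] + confounding_strength * h))
  # instrument: the same physician's previous prescription (lag-1 within
  # physician; ave keeps original row positions)
  z <- stats::ave(x, phys, FUN = function(xi) c(NA, xi[-length(xi)]))
  y <- config$beta * x - 0.5 * h + rnorm(n)
  nc_uti <- rbinom(n, 1L, plogis(-2.5 - 0.7 * h))
  comorbidity <- rbinom(n, 1L, plogis(-1.5 - h))
  visits <- rpois(n, exp(1.2 - 0.3 * h))
  idx <- data.frame(physician = phys, x = x, z = z, y = y, nc_uti = nc_uti,
                    comorbidity = comorbidity, visits = visits)
  idx <- idx[!is.na(idx$z), , drop = FALSE]  # first patient per physician
  if (nrow(idx) == 0L) .stop_validation("no patients remain after dropping first-per-physician")
  rownames(idx) <- NULL
  index <- cohort_table(idx, column_roles(
    exposure = "x", instrument = "z", outcomes = c("y", "nc_uti"),
    covariates = c("comorbidity", "visits"), cluster = "physician"))

  # negative control population on the same physicians
  n_nc <- pmax(1L, rpois(m, nc_patients_per_physician))
  phys_nc <- rep(seq_len(m), n_nc)
  nn <- length(phys_nc)
  z_nc <- rbinom(nn, 1L, plogis(base_logit + pref[phys_nc]))
  h_nc <- rnorm(nn)
  prev <- seq(0.02, 0.30, length.out = 24)
  mmat <- sapply(seq_along(prev), function(j)
    rbinom(nn, 1L, plogis(qlogis(prev[j]) + 0.5 * h_nc)))
  colnames(mmat) <- sprintf("m%02d", seq_along(prev))
  ncdf <- data.frame(physician = phys_nc, x = 0L, z = z_nc,
                     age = 45 + 15 * h_nc + rnorm(nn, 0, 5),
                     visits = rpois(nn, exp(1.2 - 0.3 * h_nc)),
                     mmat)
  nc_population <- cohort_table(ncdf, column_roles(
    exposure = "x", instrument = "z",
    outcomes = c(colnames(mmat), "age", "visits"),
    covariates = character(), cluster = "physician"))

  out <- list(index = index, nc_population = nc_population)
  attr(out, "sim_config") <- config
  out
}

#' Write a generated cohort plus a sidecar config echo
#'
#' Serializes a simulated cohort as CSV together with a YAML sidecar
#' recording the exact generator parameters and seed, for provenance.
#'
#' @param cohort a \code{\link{cohort_table}} carrying a
#'   \code{"sim_config"} attribute.
#' @param path output CSV path; the sidecar is written to
#'   \code{paste0(path, ".config.yaml")}.
#' @return the CSV path, invisibly.
#' @export
write_simulated_cohort <- function(cohort, path) {
  write_cohort(cohort, path)
  cfg <- attr(cohort, "sim_config")
  if (!is.null(cfg))
    yaml::write_yaml(unclass(cfg), paste0(path, ".config.yaml"))
  invisible(path)
}
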