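---
title: "Comparing the confounding bias of IV and conventional regression analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing the confounding bias of IV and conventional regression analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivbalance)
```

## The estimands and their assumptions

Consider a cohort of treated patients with binary exposure $X$ (index drug
versus comparator), binary instrument $Z$ (the physician's previous
prescription, a proxy for latent prescribing preference), outcome $Y$, and
covariates $C_j$, clustered by physician. With a single binary instrument
the IV estimand on the risk-difference scale is the Wald ratio

$$\hat\psi = \frac{\bar y_1 - \bar y_0}{\bar x_1 - \bar x_0},$$

where subscripts denote instrument arms. Its validity needs the usual
three assumptions: $Z$ predicts $X$; $Z$ is independent of confounders; and
$Z$ affects $Y$ only through $X$. `ivbalance` quantifies the *relative*
confounding bias of this estimator and of the conventional OLS regression
of $Y$ on $X$, using only observed covariates and negative controls, under
two substantive assumptions that the user must keep in mind:

* the observed covariates are informative about the structure of the
  *unobserved* confounding, and
* treatment effects are constant (the bias-component algebra is derived
  under homogeneity; with strongly heterogeneous effects or non-collapsible
  binary-outcome models the comparison is not sharp).

For a covariate with unit outcome effect the omitted-covariate bias of OLS
is the covariate mean difference across exposure arms, and that of the Wald
estimator is the mean difference across instrument arms divided by the
first-stage risk difference. We normalise the covariate's outcome effect
to one, so components are reported on the covariate's own scale; the
reporting layer multiplies binary covariates by 100 (risk differences per
100 patients) and leaves continuous covariates as raw mean differences.
Bias components are deliberately univariate — one covariate at a time, no
mutual adjustment — matching how balance tables are read.

## The modified Hausman test

Point differences between the two components are uninterpretable without
sampling uncertainty, and the IV components are much noisier (their
variance scales with the inverse squared first stage). For each covariate
$c$ we therefore estimate the two slopes *jointly* from stacked moment
conditions

$$E[(c_i - a_1 - \beta_{ols} x_i)(1, x_i)'] = 0, \qquad
  E[(c_i - a_2 - \beta_{iv} x_i)(1, z_i)'] = 0,$$

an exactly identified system, so one-step GMM with identity weighting
reproduces the single-equation estimates (asserted to $10^{-10}$ in the
test suite) and the choice of weighting matrix is immaterial. The joint
covariance of $(\beta_{ols}, \beta_{iv})$ is the clustered sandwich over
stacked per-cluster moment sums; its off-diagonal block is what makes
$\mathrm{var}(\hat\beta_{iv} - \hat\beta_{ols})$ honest for two estimators
computed on the same sample. The z statistic is referred to $N(0,1)$ and
p-values are two-sided and unadjusted for multiplicity, as balance tables
conventionally report them.

### Variance conventions

All variances in the package are one-way cluster-robust sandwiches on the
cohort's cluster id with the $G/(G-1)$ small-sample factor ($G$ = number of
clusters) and no further degrees-of-freedom correction; confidence
intervals use normal quantiles, consistent with the $N(0,1)$ reference of
the test. When every row is its own cluster — the default for simulated
tables without physician structure — the same formula degenerates to a
heteroskedasticity-robust estimator. The test suite cross-checks the
clustered variances against an independent implementation
(`sandwich::vcovCL`, HC0 with cluster adjustment).

Degenerate inputs are handled so that report rows survive: a covariate
with zero variance (a diagnosis nobody has) yields a flagged component of
0 with se 0 and a suppressed test, never a dropped row; a zero first stage
raises a degenerate-instrument error, since no IV quantity is defined.
Missing covariate or outcome values are handled per operation by
complete-case analysis on the columns that operation uses, and every
estimate records the N actually used; rows missing exposure, instrument or
cluster id are rejected at validation with a count.

## Negative controls

`nc_outcome_test()` reports the OLS and IV estimates of the exposure's
association with an outcome chosen to be unaffected by the treatment but
confounded like the outcome of interest (a urinary-tract-infection-style
indicator in a smoking-cessation cohort). A conventional estimate away
from zero alongside an IV interval covering zero is the signature of
residual confounding that the instrument escapes. `nc_population_test()`
fits linear (risk-difference) regressions of each outcome on the
instrument in a population that shares the physicians and the confounding
structure but received no treatment; because preference cannot act through
a prescription these patients never got, every association should be null.
Both functions only report estimates; judging what "passes" is left to the
analyst, since power depends on the negative control's prevalence.

## The simulation generators

### Valid-instrument reference DGP

`simulate_validity_dgp()` draws, in a fixed order so a seed determines the
table: $z \sim \mathrm{Bernoulli}(0.2)$; ten pseudo-confounders
$c_j \sim \mathrm{Bernoulli}(0.2)$ independent of everything (covariates an
analyst might *suspect*, none truly confounding); latent
$u, w, v \sim N(0,1)$; exposure $x = 1(z\gamma + u + w > d)$ with
$\gamma = 0.5$; outcome $y = x\beta + u + v$ with $\beta = 0.5$ and
$N = 10{,}000$ by default. The confounder $u$ drives both $x$ and $y$, so
OLS is biased upward while IV is consistent. The threshold $d$ is set by
`calibrate_threshold()`, which solves the closed-form mixture

$$p_z\,\Phi\!\left(\tfrac{\gamma - d}{\sqrt 2}\right) +
  (1 - p_z)\,\Phi\!\left(\tfrac{-d}{\sqrt 2}\right) = 0.2$$

by bracketed root-finding to $|f(d)| < 10^{-10}$ (the latent index has
variance 2); the tests verify the calibration against a $10^6$-draw
empirical oracle. On one $N = 10{,}000$ draw, every pseudo-confounder's IV
interval is wider than its OLS interval and the IV intervals cover zero at
their nominal rate — the demonstration that bias component plots without
CIs would wrongly indict the IV analysis. Under replication the modified
Hausman test holds its 5% size and the Monte Carlo mean of the Wald
estimate recovers $\beta$.

What this generator does *not* emulate: physician clustering (each row is
its own cluster), covariate correlation, binary outcomes, effect
heterogeneity, or realistic covariate prevalences. Passing tests on it
show the estimators and test are correct and calibrated under clean
conditions, not that the diagnostics are powerful in any particular real
cohort.

### Collider (selection-on-treatment) DGP

Restricting an analysis to treated patients conditions on a collider when
treatment receipt is caused by both the instrument and the confounder, and
induces instrument–confounder association. `simulate_collider_dgp()` is a
synthetic stand-in designed for this package that reproduces the two
features that matter: a *weak proxy* for the true confounder, with squared
correlation $r^2 = 0.01$ by construction
($\mathrm{proxy} = \sqrt{r^2}\,u + \sqrt{1 - r^2}\,\varepsilon$), and a
treated-only restriction flag. Receipt of any treatment follows
$1(a_z(z - p_z) + a_u u + e > 0)$ with $a_z = a_u = 2$; drug choice among
the treated, $1(0.5\,z + e' > 0.5)$, is driven by preference only. The
constants were chosen once, when the generator was designed, to make the
collider strong and the within-treated first stage moderate
(${\approx}0.19$), and they live in `sim_config()$collider` rather than in
hidden code. In the restricted cohort the IV bias component of the proxy
is an order of magnitude larger than the OLS component (the acceptance
suite measures a mean-absolute ratio around 19 at $n = 50{,}000$ over 100
seeds); unrestricted, the two are of comparable size. The package asserts
the qualitative contrast (ratio $\ge 10$ restricted, $\le 3$ unrestricted)
rather than any constant-specific number.

### Physician-preference cohort

`simulate_preference_cohort()` emulates the study design the diagnostics
were built for: physicians with a latent log-odds preference, patients
with a healthy-user confounder, prescriptions depending on both, the
instrument defined as the *same physician's previous prescription* (first
patient per physician dropped — an identity the tests recompute directly),
an outcome with a true effect, a negative-control outcome driven by the
confounder only, and a matching negative-control population on the same
physicians whose 24 binary outcomes and two continuous outcomes are null
for the instrument by construction. Default sizes (150 physicians, ~30
index patients each) keep a single draw under a second while leaving
enough clusters for the sandwich variance to be trustworthy.

## Numerical and design choices

* **Point estimates via group means.** For binary $X$ and $Z$ every
  estimator here is a mean difference or a ratio of mean differences; the
  package computes point estimates from those closed forms and solves the
  2×2 moment systems only for residuals and variances, so estimates match
  the printed formulas exactly and the regression formulations to
  $10^{-10}$ (tested).
* **Exact identification.** Because both moment blocks are exactly
  identified, one-step versus two-step GMM weighting cannot change the
  point estimates; the metadata records "one-step, identity weighting".
* **Ties and degeneracies.** `var(diff)` is clamped at zero before the
  square root; when the instrument *is* the exposure the difference is
  exactly zero and the statistic is defined as 0 with p = 1.
* **Scale conventions.** Programmatic interfaces return raw scales;
  only the reporting layer (`as.data.frame(..., scale_binary = TRUE)`,
  `write_report`, `nc_population_test`) applies ×100, and only to binary
  columns, flagged in a `scale` column.
* **Problem sizes.** The shipped test suite uses 200 replicates of
  $N = 10{,}000$ for effect recovery, 1,000 replicates of $N = 2{,}000$
  for test size, $10^6$ draws for prevalence and proxy-$r^2$ checks, and
  100 seeds of $n = 50{,}000$ for the collider contrast — sizes at which
  the Monte Carlo error of each check is far below its tolerance.

## Known limitations

Single binary instrument and linear-probability scale only: no
multi-instrument 2SLS, overidentification tests, or logistic link. Bias
components assume constant treatment effects. The weights column of the
cohort container is validated and carried but not used by the v1
estimators. Negative-control selection is the analyst's task; the package
computes, it does not choose.
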