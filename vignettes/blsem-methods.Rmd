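---
title: "Bayesian life-course SEM: model, priors, imputation and effect decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian life-course SEM: model, priors, imputation and effect decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Life-course epidemiology asks how exposures acting at different life
stages — prenatal environment, infant growth, childhood adiposity
rebound, adolescent lifestyle, adult metabolic state — combine to shape a
distal outcome such as middle-age BMI. `blsem` implements a Bayesian
linear structural equation model for this setting: variables are grouped
into `Q` chronologically ordered blocks, and every variable of an earlier
block is a *candidate* covariate in the regression of every endogenous
(continuous) variable of a later block. Instead of pre-specifying a path
diagram, the model places spike-and-slab variable-selection priors on
every candidate coefficient and lets joint MCMC estimation discover a
sparse DAG, quantify the evidence for each arrow, and propagate parameter
uncertainty into mediation-style effect estimates.

## Model

For endogenous response $k$ in block $q$, with candidate covariate vector
$x$ (all variables of blocks $1..q-1$, the exogenous variables of block
$q$, and the forced covariates),

$$y_k = \alpha_k + \textstyle\sum_j \gamma_{kj}\,\beta_{kj}\,x_j +
\varepsilon_k, \qquad \varepsilon_k \sim N(0, \sigma^2_k),$$

with priors

* $\beta_{kj}\mid\gamma_{kj}=1 \sim N(0, \tau^2\sigma^2_k)$, point mass at
  zero otherwise (`tau2`, default 10 — a weak slab on the standardised
  scale);
* $\gamma_{kj}\sim\text{Bernoulli}(\pi_k)$,
  $\pi_k\sim\text{Beta}(1,1)$ (`pi_a`, `pi_b`) — the per-response
  inclusion rate is learnt, which adapts the multiplicity penalty to each
  regression's candidate count;
* $\sigma^2_k\sim\text{IG}(0.01, 0.01)$ (`a0`, `b0`);
* intercepts $\alpha_k$ carry a flat prior (data are standardised, so
  $\alpha_k\approx 0$; intercepts are kept for imputation coherence);
* forced covariates (e.g. sex) have $\gamma\equiv 1$: every regression is
  adjusted for them and they are excluded from MPPI reporting.

Continuous columns are standardised to observed-cell mean 0, SD 1
(denominator $n-1$); binary indicator columns stay on the 0/1 scale.
Coefficients are therefore in SD units of the response per 1-SD change of
a continuous predictor and per 0-to-1 change of a binary predictor.
Categorical variables are expanded at load time into reference-coded
indicators (reference = first declared level). Within a block, endogenous
variables never predict each other, and no edge points backwards in time,
so the candidate graph is acyclic by construction (verified by
topological sort via igraph at load).

## Sampling

One Gibbs sweep (`gibbs_step()`) updates each response in chronological
order and then the imputation model. For each response the sampler makes
a single-site pass over the candidates: $(\gamma_{kj}, \beta_{kj})$ are
drawn jointly from their bivariate full conditional — $\gamma_{kj}$ from
its marginal with $\beta_{kj}$ integrated out analytically under the
conjugate slab, then $\beta_{kj}\mid\gamma_{kj}$ from its normal full
conditional — after which the whole active coefficient vector is redrawn
jointly from its multivariate normal full conditional (Cholesky; a
$10^{-8}$ ridge is added on failure and the event counted in
`ridge_count`). $\sigma^2_k$ and $\pi_k$ follow from conjugate
inverse-gamma and beta full conditionals. The scan order is systematic
(candidate order) by default for reproducibility; `scan = "random"` is
available. The sweep is implemented in C++ (Rcpp/RcppArmadillo) with R's
RNG, so runs are bit-reproducible from `seed`, which `run_chain()`
requires. Defaults are 20 000 iterations, 5 000 burn-in, thinning 5; the
package's own test and acceptance runs use 300–1 000 iteration chains on
cohorts of 300–4 000 subjects, which the wide recovery margins of the
synthetic designs support.

Initialisation: all selectable indicators 0, coefficients 0,
$\sigma^2_k$ = sample variance of the response, missing continuous cells
at the observed mean, missing binary cells at the modal category.

## Missing data

All missingness is assumed MAR, and imputation happens inside the chain
(no separate multiple-imputation step).

*Endogenous cells.* Each missing cell is redrawn from its exact Gaussian
full conditional, which combines the predictive distribution of its own
regression with the likelihood contributions of every downstream
regression in which the variable currently appears with a non-zero
coefficient. `predictive_only = TRUE` drops the downstream terms — the
literal posterior-predictive reading — and the two coincide whenever the
variable has no included downstream edges (a tested contract).

*Exogenous cells.* All exogenous columns (continuous, binary, forced)
share a joint latent multivariate normal: observed binary cells constrain
their latents to the half-line matching the observed category (threshold
fixed at 0; truncated-normal full conditionals), missing cells' latents
are drawn unconstrained, and $(\mu, \Sigma)$ are refreshed from an
unrestricted conjugate normal–inverse-Wishart full conditional
($\kappa_0 = 0.01$, $\nu_0 = p_E + 2$, $S_0 = I$). We deliberately do not
restrict latent conditional variances to 1: the latent scale is not
identified by binary margins, but only thresholded categories and
continuous draws re-enter the model, so the unrestricted conjugate update
is exact and simpler. Multi-level categoricals are imputed through their
indicator columns, each with its own latent — a simplification that can
momentarily propose two active indicators for one variable; thresholding
keeps rows valid on write-back. Observed cells are never modified
(tested). Variables flagged `no_impute` (e.g. growth-curve parameters
that carry too little information to impute) cause rows missing them to
be dropped at load, with a logged count.

## Model output

* **MPPI** — the marginal posterior probability of inclusion of each
  candidate edge is the mean of its indicator over stored draws
  (`compute_mppi()`).
* **DAG** — `threshold_dag(tau = 0.5)` keeps edges with MPPI ≥ τ; 0.8 or
  0.9 give more conservative graphs. Raising τ can only remove edges
  (tested monotonicity).
* **Effects** — for an exposure–outcome pair, `effect_decomposition()`
  works per stored draw: direct = model-averaged coefficient of the
  exposure in the outcome's regression (zero in draws where excluded);
  each qualifying path of length ≥ 2 contributes the product of that
  draw's coefficients along its edges; total = direct + sum of path
  effects. The identity holds exactly per draw, so posterior mean,
  median and equal-tailed 95% credible intervals of all three are
  mutually coherent. Model-averaged draws give honest intervals that
  include exclusion uncertainty; `conditional = TRUE` restricts to draws
  with all path edges included. Identification as causal mediation
  requires the usual assumptions (no unmeasured confounding, no
  exposure–mediator interaction, correct temporal ordering), which the
  print method states.
* **Scale conversions** — `destandardize()` maps SD-unit effects back to
  original units: × SD(outcome)/SD(exposure) per exposure unit and
  × SD(outcome) per exposure SD for continuous exposures; binary
  exposures only get the SD(outcome) conversion.
* **Bayesian R²** — per draw, $R^2 = V_{\text{fit}}/(V_{\text{fit}} +
  \sigma^2_k)$ with $V_{\text{fit}}$ the sample variance of fitted values
  over subjects on the completed data (the residual-variance-based,
  Gelman-style definition; draws lie in $[0,1)$ by construction).
* **Convergence** — split-chain $\hat R$ (flag > 1.1) and a Geyer
  initial-positive-sequence ESS on every continuous parameter;
  indicators are monitored by first- vs second-half MPPI stability
  (flag > 0.05).

## The synthetic cohort generator

`simulate_cohort()` is the test bed standing in for restricted cohort
data. Exogenous sources each own one latent dimension of a correlated
standard normal; binary sources are thresholded at a quantile matching
their prevalence, and categorical sources are cut at quantile cutpoints
(one latent, so generated rows are always valid one-hot). Endogenous
variables are built block by block as sparse linear combinations plus
Gaussian noise. Residual SDs default to the unit-total-variance solution
(floor 0.2 on the residual variance), so generator-scale and
standardised coefficients nearly coincide.

The truth record is analytic, not Monte Carlo: covariances between
thresholded and continuous columns use the Stein identity
($\mathrm{Cov}(1\{a<Z\le b\}, X) = \rho\,(\varphi(a)-\varphi(b))$), and
binary–binary covariances integrate the bivariate-normal rectangle
probability by univariate quadrature. From it the package computes true
per-response $R^2$, true standardised coefficients, and exact
direct/indirect/total effects for any pair by path products
(`true_effects()`), which is what the recovery and calibration tests
check against.

`nfbc_like_spec()` ships the default preset: 6 blocks, 24 variables
(25 model columns), 11 endogenous responses, 29 selectable true edges
with standardised effects of magnitude 0.30–0.50 plus 3 forced-sex
effects, default n = 4000 (500–2000 used in fast tests), and MAR
missingness driven by sex (rates 10–15% on seven variables, log-odds
difference 0.5). MAR masking uses
$\mathrm{logit}\,P(\text{miss}) = \mathrm{qlogis}(r) - b/2 + b\,z$ for
driver $z$, so the declared log-odds gap is recoverable by a logistic
fit on the mask (tested).

What the generator does *not* emulate: real marginal distributions or
effect sizes of any cohort, non-linear or interaction effects,
measurement error, within-block residual correlation, and
missing-not-at-random mechanisms. Passing recovery tests therefore shows
correctness of the machinery under the model's own assumptions, not
robustness to their violation.

## Numerical choices and edge cases

* Zero-variance continuous columns are a hard standardisation error;
  wholly missing columns are a hard validation error; all-zero candidate
  columns are never selected.
* Cholesky failures in the joint coefficient draw get a $10^{-8}$
  relative ridge (counted and reported); the inverse-Wishart scatter
  matrix gets jittered retries before erroring.
* $\pi_k$ is clamped to $[10^{-12}, 1-10^{-12}]$ to keep log-odds
  finite; truncated-normal draws use inverse-CDF sampling with the sign
  enforced at extreme means.
* Stored draw count is $\lfloor(\text{iterations}-\text{burn-in})/
  \text{thin}\rfloor$; quantiles are type-7 throughout, equal-tailed 95%
  intervals.
* Paths are enumerated by depth-first search with successors sorted
  lexicographically, so path lists are deterministic; counts are
  cross-checked against the adjacency-matrix-power oracle in tests.

## Known limitations

Only continuous endogenous variables are supported (binary outcomes
would need a probit layer). The spike-and-slab form is a standard
conjugate choice, not a reconstruction of any particular published
sampler; g-prior slabs, joint indicator moves and within-block residual
correlation are out of scope. Effect estimates are linear path algebra —
no interventional simulation, no sensitivity analysis for unmeasured
confounding. Ordinal categoricals are handled as reference-coded
indicators rather than ordered cutpoints.
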