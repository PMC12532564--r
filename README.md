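# blsem

Bayesian life-course linear structural equation models with
spike-and-slab variable selection, within-chain MAR imputation and
path-based effect decomposition.

## What it is for

Life-course studies measure exposures and intermediate phenotypes over
decades — prenatal environment, birth size, infant and childhood growth,
adolescent lifestyle, adult metabolic traits — and ask how they combine
to shape a distal outcome such as middle-age BMI. `blsem` models such
cohorts as a system of linear regressions over chronologically ordered
blocks: every variable of an earlier block is a candidate covariate for
every endogenous (continuous) variable of a later block, and
spike-and-slab priors let the data choose a sparse path diagram instead
of the analyst pre-specifying one.

For response $k$ with candidate covariates $x_j$,

$$y_k = \alpha_k + \sum_j \gamma_{kj}\beta_{kj}x_j + \varepsilon_k,
\qquad \varepsilon_k \sim N(0,\sigma^2_k),$$

with $\beta_{kj}\mid\gamma_{kj}{=}1 \sim N(0,\tau^2\sigma^2_k)$, a point
mass at zero otherwise, $\gamma_{kj}\sim\mathrm{Bern}(\pi_k)$,
$\pi_k\sim\mathrm{Beta}(1,1)$ and
$\sigma^2_k\sim\mathrm{IG}(0.01,0.01)$. A joint Gibbs sampler estimates
all regressions simultaneously, imputing missing cells inside the chain
(posterior-predictive draws for endogenous variables; a joint latent
normal/probit model over the exogenous covariates). The posterior mean
of each indicator — the **marginal posterior probability of inclusion
(MPPI)** — measures the model-averaged evidence for each arrow; edges
with MPPI ≥ 0.5 (or a stricter threshold) form the estimated DAG, and
for any exposure–outcome pair the per-draw path algebra

$$\text{total} = \text{direct} + \sum_{\text{paths}} \prod_{\text{edges}}
\beta$$

yields direct, indirect and total effects with coherent 95% credible
intervals, in SD units of the outcome. A per-response Bayesian
$R^2 = V_\text{fit}/(V_\text{fit}+\sigma^2)$ summarises explained
variation, and a synthetic cohort generator with analytic ground truth
makes every stage testable without access-restricted cohort data.

## Worked example

Simulate the bundled six-block life-course preset (24 variables, 29 true
edges, MAR missingness driven by sex), fit the model, and decompose the
effect of maternal smoking on middle-age BMI:

```r
library(blsem)

spec   <- nfbc_like_spec(n = 600)
sim    <- simulate_cohort(spec, seed = 1)
masked <- apply_missingness(sim$data, spec, seed = 2)

fit <- run_chain(masked$table, spec$bs, iterations = 600, burn_in = 200,
                 thin = 2, seed = 3)
fit
#> Bayesian life-course SEM chain:
#>    11 responses, 174 candidate edges
#>    200 stored draws (iterations 600 , burn-in 200 , thin 2 , seed 3 )
#>    600 subjects; 543 imputed cells

dag <- threshold_dag(fit, tau = 0.5)
dag
#> Estimated DAG (MPPI >= 0.5 ): 24 nodes, 29 edges

effect_decomposition(fit, dag, "matSmoke", "bmi46")
#> Effect decomposition: matSmoke -> bmi46 (sd units)
#>   [assumes no unmeasured confounding and no exposure-mediator interaction]
#>   direct:         0.262 (0.165, 0.373)
#>   total indirect: 0.0581 (0.0258, 0.0929)
#>   total:          0.32 (0.224, 0.421)
#>   paths:          7
```

The fitted DAG recovers exactly the generator's 29 true edges, and the
decomposition brackets the analytic truth, which the truth record gives
by path products: direct 0.30, indirect 0.048, total 0.348 through the
same 7 paths (`true_effects(sim$truth, "matSmoke", "bmi46")`). Effects
read as SD units of BMI-at-46 per 0-to-1 change of the binary exposure.
Explained variation:

```r
round(bayes_r2(fit, "bmi46")$summary, 3)
#>   mean median  lower  upper
#>  0.655  0.656  0.616  0.689     # analytic truth: 0.669
```

`summarize_chain(fit)` tabulates posterior summaries with split-chain
Rhat/ESS, `imputation_diagnostics(fit)` reports every imputed cell, and
`export_dag(dag, "dag.graphml", "graphml")` /
`subgraph(dag, "matSmoke", "bmi46")` export the graph and the
per-exposure pathway diagram.

## Command line

A thin wrapper over the same functions lives in
`inst/scripts/blsem.R`:

```sh
Rscript inst/scripts/blsem.R simulate --n 600 --seed 1 --out sim
Rscript inst/scripts/blsem.R fit --data sim/data.csv \
    --blocks sim/blocks.json --seed 3 --iterations 600 \
    --burn-in 200 --thin 2 --out run
Rscript inst/scripts/blsem.R effects --run run --outcome bmi46 \
    --all-exposures
```

`fit` writes the persisted chain, `mppi.csv`, `summary.csv`, `r2.csv`
and a config-echo log; `effects` writes a results table (effects
× 1000), a per-path breakdown and DOT/GraphML graphs.

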