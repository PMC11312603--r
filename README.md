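# concindex

Measuring — and explaining — socioeconomic inequality in the use of health
services from person-wave survey data.

Health-equity studies routinely ask two questions about a binary utilization
outcome (did this person get a routine health examination this year?):
*how unequally* is utilization distributed across the economic spectrum, and
*which factors* drive that inequality once unavoidable differences in need
are set aside. `concindex` implements the standard toolkit for both, aimed at
epidemiologists and health economists analysing ageing-cohort surveys such as
CHARLS-style panels.

## The statistics at the core

**Concentration index.** Rank every individual by living standard (here:
per-capita household consumption expenditure net of health spending) and let
R_i be the fractional rank in (0, 1), poorest first. For an outcome Y with
mean μ,

    C = (2 / μ) · cov(Y, R)

C is twice the area between the concentration curve (cumulative outcome share
vs. cumulative population share, poorest first) and the 45° equality line.
C ∈ [−1, 1]; C = 0 is perfect equality, C > 0 means utilization concentrates
among the better-off (pro-rich). The package uses weighted midpoint fractional
ranks — with equal weights these are (i − ½)/n, a constant shift of the
textbook i/N rank that leaves C unchanged (covariance is shift-invariant)
while handling ties and sampling weights coherently. Standard errors come
from the heteroskedasticity-robust "convenient regression".

**Wagstaff decomposition.** Fit a probit of Y on need variables x_j (age
group, sex, disability, chronic disease) and controls z_k (residence, region,
education, marital status, insurance, economic-status tertile, smoking,
drinking). With average marginal effects β_j, γ_k, the index splits as

    C = Σ_j (β_j · x̄_j / μ) C_j + Σ_k (γ_k · z̄_k / μ) C_k + GC_ε / μ

where C_j is the concentration index of regressor j over the same ranks and
GC_ε is the generalized concentration index of the residual. Each term —
elasticity × regressor index — is a factor's *contribution* to inequality.

**Horizontal inequity.** HI = C − Σ (need contributions): the inequality
remaining after the legitimate, need-driven part is removed. HI > 0 means
equally needy richer people use more services.

A synthetic panel generator with a numeric-integration oracle for the *true*
index closes the loop: every estimator in the package can be checked against
known ground truth.

## Worked example

```r
library(concindex)

cfg <- synthetic_config(n_individuals = 11496,
                        waves = c(2011, 2013, 2015, 2018), seed = 2024)
ds  <- assign_tertiles(generate_panel(cfg))

utilization_rates(ds, by = "wave")
#>    wave     n rate_pct
#> 1  2011 11496     28.7
#> 2  2013 11496     21.7
#> 3  2015 11496     27.3
#> 4  2018 11496     35.2

d1 <- filter_wave(ds, 2011)
d  <- dataset_records(d1)
concentration_index(d$health_exam, living_standard = d$pce_net,
                    weights = d$weight)
#> Concentration index: 0.0066 (95% CI -0.0099, 0.0232)
#>   outcome mean 0.2868, n = 11496

decompose_ci(d1)
#> <ci_decomposition> total CI 0.0066, HI 0.0095, n = 11496
#>             variable    role contribution pct_contribution
#>              sexmale    need      -0.0002            -2.63
#>       age_group61-70    need      -0.0025           -37.91
#>     econ_tertilehigh control       0.0088           132.30
#>                  ...     ...          ...              ...
#> residual: 0.0006 (9.76%)

true_ci_oracle(cfg)   # generator ground truth for wave 1
#> [1] 0.00955606
```

Reading this: utilization runs near 29% in the first wave; the concentration
index 0.0066 is slightly pro-rich and statistically indistinguishable from 0;
the horizontal inequity index 0.0095 exceeds the raw index because the need
variables (older age groups) contribute *negatively* — need-driven use leans
pro-poor, so removing it reveals more pro-rich inequity. The high
economic-status tertile is the dominant single contributor. The estimate
brackets the generator's true index 0.0096.

`run_pipeline(pipeline_config(synthetic = cfg, outdir = "out"))` writes the
full bundle — rate tables, odds-ratio tables from stratified year-fixed-effect
logits, CI/HI tables, per-wave decompositions, concentration-curve data and
figure, and a JSON manifest. A thin command-line wrapper with `simulate`,
`describe`, `rates`, `ci`, `decompose` and `report` subcommands lives at
`inst/cli/concindex.R`.

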