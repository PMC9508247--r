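# sgcreg — spatial Gaussian copula regression

`sgcreg` is for analysts whose spatially referenced response — disease
counts by municipality, binary presence on a grid, overdispersed counts at
monitoring sites — must be *regressed* on spatially patterned covariates,
not smoothed or interpolated. The usual spatial mixed model (a GLM with
spatial random effects in the linear predictor) gives coefficients a
conditional interpretation and suffers from spatial confounding, where the
random effects compete with the covariates and can wash out real
associations. `sgcreg` implements the marginal alternative: a **spatial
Gaussian copula regression model** in which ordinary GLM marginals are
joined by a latent Gaussian field,

```
Z ~ N(0, Ω),   U_i = Φ(Z_i),   Y_i = F_i⁻¹(U_i),
E(Y_i | x_i) = g⁻¹(x_i'β),
```

with Ω a spatial correlation matrix — a proper CAR `(D − ρA)` or Leroux
`((1−λ)I + λ(D−A))` precision on an adjacency graph, or an exponential /
powered exponential / Matérn kernel (optionally tapered) over planar
distances. Each Y_i keeps exactly its GLM marginal law; the copula carries
the extra-regression spatial dependence. β has the same interpretation as
in an ordinary GLM, and there is nothing in the linear predictor for the
spatial structure to confound.

Inference is a unified two-stage procedure, identical for continuous and
discrete responses:

1. fit the ordinary GLM (this alone determines the point estimates);
2. estimate the copula parameters by maximizing the Gaussian
   log-likelihood `−½log|Ω| − ½r'Ω⁻¹r` of the standardized residuals
   `r_i = e_i/√(1−h_i)`;
3. draw a parametric bootstrap (`Z* → U* → Y* →` GLM refit) from the
   fitted model and take percentile intervals of the refitted
   coefficients.

Under positive spatial dependence the effective sample size shrinks, the
bootstrap sample spreads out, and the intervals widen accordingly — which
is precisely what ordinary GLM Wald intervals fail to do.

## Worked example: disease-mapping analogue

An offset Poisson regression with a CAR copula on a 12×12 lattice —
structurally the classic small-area incidence analysis (observed counts,
expected counts as offset, one socioeconomic covariate):

```r
library(sgcreg)
set.seed(10)
g        <- square_lattice(12, 12)
xy       <- lattice_coordinates(12, 12)
ses      <- drop(scale(xy[, 1] + 0.5 * xy[, 2]))   # smooth covariate
expected <- exp(rnorm(g$n, 3, 0.2))                # expected case counts
mspec    <- marginal_spec("poisson", offset = log(expected))
X        <- cbind(intercept = 1, ses = ses)

# generate data with strong extra-regression dependence (rho = 0.9)
truth <- copula_spec("car", g, list(rho = 0.9))
y     <- simulate_sgcrm(copula_structure(truth), mspec, X, c(0.15, -0.14))

fit <- fit_sgcrm(X, y, mspec, copula_spec("car", g))
fit
#> Spatial Gaussian copula regression fit
#> Stage 1 (poisson GLM):
#> intercept       ses
#>    0.1187   -0.1363
#> Stage 2 (car copula, deviance residuals):
#>   rho = 0.8781
#> AIC_glm: 839.321  AIC_cop: 104.43

boot <- sgcrm_bootstrap(fit, n_boot = 1000, levels = 0.95, seed = 1)
boot$intervals$level_0.95
#>             lower   upper
#> intercept  0.0275  0.1879
#> ses       -0.2196 -0.0645

wald_intervals(fit, 0.95)
#>             lower   upper
#> intercept  0.0842  0.1533
#> ses       -0.1710 -0.1016
```

The stage-1 coefficients are the ordinary GLM estimates (here close to the
generating (0.15, −0.14)); the fitted `rho = 0.878` recovers the strong
generating dependence from the residuals alone; and the bootstrap interval
for the covariate effect is roughly twice as wide as the Wald interval —
the honest price of n = 144 spatially dependent observations — while still
excluding zero.

Six preset simulation scenarios (`scenario_config(1..6)`) cover
Poisson/CAR, binomial/Leroux, Bernoulli/exponential-kernel, and negative
binomial/Matérn designs; `run_scenario()` runs full coverage/type-II
studies over them, and `copula_selection_study()`,
`misspecification_study()` and `family_selection_study()` drive the
model-choice experiments. A thin command-line wrapper with `simulate`,
`fit` and `simstudy` subcommands ships in `inst/cli/sgcreg`.

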