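# amhsurv

Bayesian estimation for bivariate right-censored survival data whose
dependence is modelled by the Ali–Mikhail–Haq (AMH) Archimedean copula
with Weibull margins. The intended users are survival analysts working
with paired lifetimes — two eyes of one patient, paired organs, twin
components — where the association between the two times is real but
weak, and where each margin may be heavily right-censored.

## Model

The joint survival function is

    S(t1, t2) = S1(t1) S2(t2) / [1 − φ (1 − S1(t1)) (1 − S2(t2))],   φ ∈ [−1, 1)

with rate-type Weibull margins `Sj(t) = exp(−βj t^αj)` (note: this β is
**not** the `pweibull` scale; `λj = βj^(−1/αj)` converts). The AMH
copula covers Kendall's τ in (−0.18, 1/3) and Spearman's ρ in
(−0.2711, 0.4784), monotone in φ with independence at φ = 0.

Each subject contributes the joint density, a partial survival
derivative, or the joint survival function according to its censoring
pattern. Priors are vague Gammas (shape/rate 0.01/0.01) on the Weibull
parameters and U(−1, 1) on φ. Posterior simulation is
Metropolis-within-Gibbs; three algorithms differ only in the shape
updates:

| Algorithm | Shape (αj) update | Scales (βj) | Dependence (φ) |
|-----------|-------------------|-------------|----------------|
| A1 | independence MH from the prior | Gamma-candidate MH | grid independence MH |
| A2 | random-walk Metropolis, σ² = 1 | Gamma-candidate MH | grid independence MH |
| A3 | slice sampling, step λ = 0.01 | Gamma-candidate MH | grid independence MH |

Slice sampling (A3) is the practical recommendation for small samples;
A1 is the textbook baseline it looks like (its acceptance rate collapses
under vague priors).

The package also ships a conditional-inversion simulator with censoring
calibration, a benchmark harness for parameter RMSE by design/sample
size/censoring/algorithm, Kaplan–Meier-based distributional RMSE, and
MCMC diagnostics (effective sample size, integrated autocorrelation
time, Gelman–Rubin factor).

## Worked example

```r
library(amhsurv)

set.seed(1)
d <- amh_simulate(120, "D1", censor_pct = 10)   # truth: α=(2,3), β=(1,1), φ=0.5
fit <- amh_fit(d, algorithm = "A3",
               control = amh_control(L = 5500, B = 500, J = 10), seed = 2)
tidy(fit)
#> # A tibble: 5 × 5
#>   term   estimate std.error conf.low conf.high
#>   <chr>     <dbl>     <dbl>    <dbl>     <dbl>
#> 1 alpha1    2.24    0.00796    1.92      2.57
#> 2 beta1     1.08    0.00449    0.891     1.28
#> 3 alpha2    3.34    0.0115     2.85      3.87
#> 4 beta2     1.04    0.00483    0.842     1.26
#> 5 phi       0.670   0.0189     0.195     0.940

diagnose(fit)
#> # A tibble: 5 × 4
#>   term     ess   iat  psrf
#>   <chr>  <dbl> <dbl> <dbl>
#> 1 alpha1  435. 1.15     NA
#> 2 beta1   513. 0.975    NA
#> 3 alpha2  502. 0.995    NA
#> 4 beta2   474. 1.06     NA
#> 5 phi     109. 4.57     NA
```

Every 95% credible interval covers its true value; the implied rank
correlation at the posterior mean is `amh_kendall_tau(0.670) ≈ 0.18`.
The ESS column shows the slice sampler's signature: the shape chains are
essentially uncorrelated (IAT ≈ 1), while φ — updated by small grid
moves — mixes more slowly. `autoplot(fit)` draws traceplots and
`plot_survival_fit(fit)` overlays the fitted margins on the
Kaplan–Meier curves.

A thin command-line front end with `simulate`, `fit`, `diagnose` and
`benchmark` subcommands is installed at `inst/cli/amhsurv.R`.

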