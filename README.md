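# dosewise

Individualized optimal dose selection when treatment carries both a binary
efficacy outcome E and a binary toxicity outcome T. The package is aimed at
biostatisticians working with existing dosed cohorts (several trials, a
registry, real-world data) who want a per-patient dose recommendation
rather than one population dose — for example radiation oncology settings
where both tumor control and liver toxicity rise with dose.

## The criterion

Clinician-elicited utilities for the four bivariate outcomes form a 2×2
matrix with `u10 = 1` (efficacy, no toxicity), `u01 = 0` (toxicity, no
efficacy) and interior weights `ω₁ = u00`, `ω₂ = u11`. The utility of a
dose d for a patient with covariates x is the expectation of this matrix
under the joint outcome distribution:

    Ū(p(d,x), ω) = ω₁ p00 + p10 + ω₂ p11
                 = ω₁ + (1−ω₁) pE − ω₁ pT + (ω₁+ω₂−1) p11

and the individualized optimal dose is `d_opt(x) = argmax_d Ū(p(d,x), ω)`
over a dose grid. When `ω₁ + ω₂ = 1` only the marginals matter; otherwise
the E–T association enters through `p11`. Variants add a toxicity cap
(extra penalty `2 ω₁ pT` once `pT ≥ 0.3`) or a quadratic penalty
`δ (d − d_fix)²` toward a population reference dose. For Bayesian fits the
dose can instead maximize the posterior mean of Ū, or the posterior
probability that Ū beats its value at `d_fix`.

Joint probabilities come from three model families, all behind the same
surface:

* random forests on each marginal (optionally constrained nondecreasing in
  dose) linked by a Gaussian copula `p00 = Φ₂[Φ⁻¹(1−pE), Φ⁻¹(1−pT) | α]`
  with α estimated by pseudo-likelihood;
* a random forest on the 4-category outcome, optionally monotonized by a
  pool-adjacent-violators projection of the marginal curves plus a
  Fréchet-constrained adjustment of `p11`;
* Bayesian Gaussian-process probit models with ARD Gaussian kernels and
  horseshoe priors on the inverse length-scales, sampled by elliptical
  slice sampling within Gibbs.

A simulation engine benchmarks each rule against the oracle (the true
generative model) and a fixed-dose baseline (4-category multinomial on
dose only), reporting mean dose, dose spread, mean efficacy/toxicity and
the percent of the oracle-minus-fixed utility gap recovered.

## Worked example

Fit monotone marginal forests on a simulated cohort of 200 patients,
link them with the estimated copula, and dose one patient:

```r
library(dosewise)
spec  <- scenario_spec("S1")          # benchmark generative model
train <- generate_dataset(spec, 200, seed = 1)
cfg   <- utility_config(utility_matrix(0.3, 0.5))
grid  <- dose_grid()                  # 201 points on [-1, 1]

fd <- fixed_dose_rule(train, grid, cfg)
fd$d_fix
#> [1] 0.26

mE <- fit_marginal_rf(train, "E", monotone_in_dose = TRUE, seed = 2)
mT <- fit_marginal_rf(train, "T", monotone_in_dose = TRUE, seed = 3)
alpha_hat <- estimate_alpha(train$E, train$T, mE$oob, mT$oob)
alpha_hat
#> [1] 0.274

patient <- train[7, paste0("x", 1:5)]
curve <- joint_from_marginals(
  predict_marginal_curve(mE, patient, grid),
  predict_marginal_curve(mT, patient, grid),
  copula_spec(alpha_hat), dose = grid)
optimal_dose_pointwise(curve, cfg)$dose
#> [1] 0
```

The fixed-dose model would give everyone dose 0.26 with an estimated
population utility of 0.598; the individualized rule gives this patient
dose 0 with estimated utility 0.764 (the oracle dose for this patient is
0.39 — forest estimates at n = 200 are noisy, which is exactly what the
simulation study quantifies). A small oracle-vs-fixed study:

```r
res <- run_study(study_config("S1", methods = c("M1", "M12"),
  utilities = list(c(0.3, 0.5)), R = 20, n_train = 200, seed = 42))
res[, 1:8]
#>   utility method mean_dose sd_dose mean_E mean_T mean_utility pct_improvement
#> 1      U1     M1     0.232   0.654  0.717  0.276           67             100
#> 2      U1    M12     0.464   0.000  0.672  0.409           60               0
```

Individualizing the dose raises mean efficacy (0.72 vs 0.67) while
*lowering* mean toxicity (0.28 vs 0.41) — the gap the model-based rules
try to close.

A command-line wrapper for simulate / fit / recommend / study lives at
`inst/cli/dosewise.R`:

```sh
Rscript inst/cli/dosewise.R simulate --config study.yaml --seed 7 --out runs/
```

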