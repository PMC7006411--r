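# dmtrank

Personalized prediction of treatment response in relapsing-remitting
multiple sclerosis (RRMS).

## What problem this solves, and for whom

When an RRMS therapy fails and a switch is considered, the clinician has to
choose among several disease-modifying therapies (DMTs) using group-level
trial evidence that says little about *this* patient. `dmtrank` is aimed at
biostatisticians and registry methodologists building clinical decision
support from observational therapy-cycle data. It implements, end to end:

1. **Cohort construction** — derivation of the two effectiveness endpoints
   (on-therapy relapse count; confirmed disability progression, CDP, from
   timestamped EDSS trajectories) and the quality/inclusion filters that turn
   a raw cycle table into an analysis cohort, with itemized filter reports.
2. **Hierarchical Bayesian outcome models** — negative binomial (relapses)
   and binomial (CDP) GLMs with clinical-site random intercepts and a
   log-exposure offset:

   `y_i ~ NB(mu_i = T_i * exp(x_i' beta + u_s), phi)`,
   `z_i ~ Bernoulli(invlogit(x_i' gamma + u_s + log T_i))`,
   `u_s ~ N(0, sigma^2)`,

   with weakly-informative priors N(0, 10) / N(0, 2.5) / Half-Cauchy(0, 5) /
   Gamma(1, 1), fitted by an in-package adaptive MCMC sampler (C++), in three
   strictly nested complexities (non-personalized, prognostic, predictive).
3. **Counterfactual therapy ranking** — per patient, predictions for all six
   DMTs with site intercepts zeroed; the lowest predicted relapse count or
   CDP probability defines the highest ranked therapy DMT\*.
4. **Validation** — equally-populated-bin calibration; MSE, pointwise
   negative log-likelihood and Harrell's C-Index over duration-matched
   pairs; repeated patient-level 10-fold CV, leave-one-site-out CV, and a
   held-out test set; forecast-window stratification; nested-model
   comparison; prior/sample-size sensitivity of the ranking.
5. **Adherence comparison** — propensity-score ATE weighting (logistic
   propensity model, balance diagnostics) and survey-weighted NB /
   quasi-binomial outcome GLMs with sandwich standard errors, comparing
   observed outcomes between receivers and non-receivers of their DMT\*.
6. **Synthetic registry** — a seeded generator with known ground truth
   (coefficients, site intercepts, expected outcome per therapy) so that
   every stage is testable without access to any proprietary registry.

## Worked example

```r
library(dmtrank)

reg    <- generate_registry(sim_config(n_patients = 800, n_sites = 10, seed = 1))
q      <- apply_quality_criteria(reg$cycles)
cohort <- apply_inclusion_criteria(q$cycles, seed = 2)$cycles

fit <- fit_hbglm(model_spec("relapse", "predictive"), cohort,
                 chains = 2, iter = 400, warmup = 400, seed = 3)
print(fit)
#> Hierarchical Bayesian RELAPSE model ( predictive )
#>   46 fixed effects, 10 site intercepts, 800 posterior draws
#>   max split R-hat: 1.081

ranking <- rank_therapies(counterfactual_grid(fit, cohort))
table(ranking$dmt_star)
#>
#>  DMF  FTY   GA  NA. TERI
#>   80  161   31  500   27

run_adherence_comparison(cohort, ranking, "relapse")
#>   dmt_star      slope      p_value n_received n_not_received          excluded_reason
#> 1      DMF -0.4465289 4.746507e-01         11             69                     <NA>
#> 2      FTY -0.8720820 2.052298e-02         24            137                     <NA>
#> 3       GA -0.1647758 5.969291e-01         11             20                     <NA>
#> 4      NA. -0.9402271 4.409589e-07         90            410                     <NA>
#> 5     TERI         NA           NA          7             20 fewer than 10 obser...
```

The fitted relapse model ranks the high-efficacy therapies (Natalizumab,
Fingolimod) first for most simulated patients — they were planted with the
lowest relapse rates — and the weighted comparison shows lower observed
relapse activity among patients who actually received their highest ranked
therapy (negative slopes on the log-rate scale for every assessed DMT\*
level; significant here for Natalizumab and Fingolimod, the levels with the
largest samples).

See the vignette (`vignettes/personalized-dmt-ranking.Rmd`) for the models,
endpoint definitions, sampler design, validation suite and the documented
design choices.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's main pipeline from scratch on a seeded synthetic
registry — simulation, cohort filtering, the hierarchical Bayesian fit,
test-set validation (MSE / NLL / C-Index), counterfactual ranking and the
propensity-weighted adherence comparison — logging the key numbers and
writing the JSON result summary to `--out`.
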