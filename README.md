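# dietdimorph

Statistical pipeline for experimental-evolution studies of **sexual
dimorphism in diet choice** measured with CAFE-style capillary feeding
assays in *Drosophila* (or any system where per-individual intake of two
liquid foods is read from microcapillary tubes).

The scientific setting: replicate populations evolve for a few generations
under contrasting resource-availability regimes (high competition / low
food vs low competition / high food), and the question is whether resource
competition drives ecological character displacement *between the sexes* —
an increase in the male−female difference of the sucrose:yeast intake
ratio — together with adaptation measures (fitness trajectories,
starvation survival, evolutionary rates).

## What it computes

For per-fly raw fluid losses `s_raw`, `y_raw` and fly-free control vials
estimating evaporation `ē_s`, `ē_y`:

* **Evaporation correction**, on two scales:
  ratio `(s_raw/y_raw − ē_s/ē_y) + 1` (undefined denominators flagged and
  counted, never silently dropped) and bivariate `(s_raw − ē_s, y_raw − ē_y)`
  with negatives preserved; volumes convert to masses at 90 µg/µl.
* **Sexual dimorphism** `δ = mean(M) − mean(F)` of the corrected ratio:
  per-population OLS tests, and treatment-pooled estimates from a
  **stratified bootstrap** (resampling flies within population × sex
  strata, default 10,000 replicates) with two-tailed p-values read
  directly off the sampling distribution, `p = 2·min(Pr*[δ*≤0], Pr*[δ*≥0])`
  floored at `2/n_boot`.
* A **measurement-error (meta-analytic) linear mixed model** on the
  population × sex mean ratios — sex, treatment and sex×treatment fixed
  effects, a population random intercept estimated by profiled REML, and
  each mean's bootstrap sampling variance supplied as a known error
  variance — with containment denominator df (F(1, 4) in the
  six-population design).
* A **Bayesian bivariate mixed model** of per-fly (sucrose, yeast) masses:
  a bespoke conjugate Gibbs sampler (C++) with trait-specific population
  intercepts and an unstructured residual covariance, five nested
  fixed-effect structures ranked by **DIC**, and effects summarised with
  posterior means, 95% intervals and pMCMC.
* **Adaptation metrics**: mean fitness (recruits per female), a binomial
  GLM of starvation survival on treatment (Wald Z), and evolutionary rates
  in **Haldanes** `|z̄_evolved − z̄_anc| / s_anc / generations` with a
  per-trait between-sex F test.
* A **synthetic-experiment generator** reproducing the full design
  (vials, treatments, assays, mortality thinning, evaporation controls,
  census) with known ground truth, so every stage is validated end to end.

## Worked example

```r
library(dietdimorph)

res <- run_full_analysis(sim_config(seed = 1), n_boot = 2000,
                         mcmc = list(n_iter = 2600, burnin = 600,
                                     thin = 2, chains = 2))
res
#> Diet-dimorphism analysis
#>   563 flies in, 563 analysed on the ratio scale (0 excluded)
#>   ancestor                   delta = -0.031 (SE 0.149, p = 0.85)
#>   high_competition_low_food  delta = +0.438 (SE 0.092, p = 0.001)
#>   low_competition_high_food  delta = -0.048 (SE 0.112, p = 0.66)
#>   sex x treatment: F_1,4 = 12.4, p = 0.024
#>   best bivariate spec: sex_x_trait_plus_treatment (delta-DIC 1.31)
#>   survival Z = 4.12; mean rates: sucrose 0.070, yeast 0.112 Haldanes
```

Reading the output: the ancestor shows no significant dimorphism (δ within
sampling error of zero), the three pooled high-competition populations
show a large male-biased sucrose:yeast difference (δ ≈ 0.44, bootstrap
p = 0.001), the low-competition populations remain near the ancestral
state, and the measurement-error mixed model confirms the
**treatment effect on dimorphism** (sex×treatment F(1, 4), p = 0.024 on
the population means). DIC ranks the bivariate model with a sex×trait
interaction plus a treatment main effect best — dimorphism arises from
*both* sexes moving (males toward sucrose, females toward yeast) on top of
an overall consumption increase under competition — and survival under
food deprivation is higher in high-competition populations (Z = 4.1).

Every result family is a tibble (`tidy()`/`glance()` methods on the model
objects, `autoplot()`/`plot_*()` for the standard figures), and
`run_full_analysis(..., out_dir = "...")` writes one CSV per family plus a
JSON manifest with seed, config hash and record-count accounting.
External data in any CSV dialect map onto the canonical schemas via
`read_consumption_table(path, column_map = ...)`.

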