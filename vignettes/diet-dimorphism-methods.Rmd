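---
title: "Models and methods: sexual dimorphism in diet from capillary feeding assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: sexual dimorphism in diet from capillary feeding assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

dietdimorph analyses experimental-evolution studies in which adult diet
choice is measured with CAFE-style assays: each fly sits in its own vial
with two microcapillary tubes, one of sucrose solution and one of
yeast-extract solution (both 90 g/L by default), and consumption is read as
the drop in fluid level over 24 h. The scientific question is whether an
ecological manipulation — here, resource availability and hence the
intensity of adult resource competition — changes the *sexual dimorphism*
of diet, i.e. the male−female difference in the sucrose:yeast intake ratio,
within a handful of generations.

This vignette explains each statistical component, its assumptions, the
tunable parameters, and the numerical choices made where the design was
genuinely open. It states no empirical result beyond what the package's own
tests and the acceptance script recompute.

## The experimental design being modelled

The synthetic generator (`sim_config()`, `simulate_experiment()`) emulates a
two-treatment design:

* an **ancestral population**, assayed once (50 flies per sex in individual
  vials) at generation 0;
* three replicate populations per treatment — **high competition / low
  food** and **low competition / high food** — each founded with seven
  vials of eight males and eight females and evolved for three generations;
* a **common-garden offspring assay**: 50 flies per sex per population,
  held without food for 48 h (during which some die; survival is itself an
  adaptation measure) before the 24 h feeding assay;
* twenty **fly-free control vials** whose fluid loss estimates evaporation;
* a **census** per population and generation: females, recruits to the next
  generation, assay and deprivation-survival counts.

## Generator semantics: why the ratio is drawn directly

Each fly carries a latent diet ratio
$r_i \sim \mathcal N(\mu_{r}, \sigma_r^2)$ with a sex- and
treatment-specific mean $\mu_r = \mu_s/\mu_y$, and a yeast volume
$y_i \sim \mathcal N(\mu_y, \sigma_y^2)$; its sucrose volume is
$s_i = r_i\,y_i$. Raw fluid losses add an evaporation draw and caliper
measurement noise per tube, floored at zero (fluid cannot rise, so the
floor is a physical property of the measurement; with the default means it
binds with negligible probability).

Drawing the ratio directly — rather than drawing two volumes and dividing —
makes the configured mean ratio *exactly* the mean-of-ratios estimand that
every downstream stage analyses. A ratio of two independent normals has
`E[s/y] > E[s]/E[y]` (convexity of `1/y`), so a volume-first generator would
make "parameter recovery" ill-defined at the few-percent level. With the
ratio-first construction, noise-free simulations recover every generating
parameter exactly, and noisy simulations are unbiased up to the (documented)
properties of the published correction itself.

Key defaults, with the reasoning:

* **Mean ratios** per sex and treatment default to values near 1.4–1.7,
  with males consistently above females — the range reported for
  *D. melanogaster* choice assays (sucrose:yeast ≈ 1.5:1, i.e.
  carbohydrate:protein ≈ 3:1–4:1).
* **`sigma_ratio = 0.8`** (dimensionless). The within-population SD of
  individual feeding ratios is rarely reported; this value is calibrated so
  that bootstrap standard errors of treatment-pooled dimorphism land in the
  0.10–0.22 range typical of published CAFE experiments at these sample
  sizes. It is a tunable, not a fact about flies.
* **`sigma_yeast = 0.55` µl** on a ~2 µl mean: an individual-intake
  coefficient of variation near 25%, realistic for per-fly consumption.
* **Evaporation** defaults to 0.10 µl per tube (SD 0.04). This is modest
  relative to consumption, which keeps the published ratio correction
  near-exact on synthetic data (see below); real assays can have much
  larger evaporative loss, in which case the correction's attenuation is a
  property of the estimator the user should be aware of, not of this
  package.
* **Mortality** during deprivation defaults to 20% (high competition) and
  33.7% (low), chosen so the expected survivor counts match the scale of a
  ~600-fly offspring assay yielding ~440 measurable flies.
* **Recruitment rates** rise 0.5 → 5 recruits per female across
  generations 0–3: a ten-fold ("order of magnitude") fitness increase,
  with Poisson noise around rate × females.

## Evaporation correction, two scales

Let $\bar e_s, \bar e_y$ be mean fluid losses over the control vials.

**Ratio scale.** The corrected ratio is
$(s_{raw}/y_{raw} - \bar e_s/\bar e_y) + 1$: the raw ratio is shifted by the
evaporation ratio, and the `+1` offset re-centres cancellation at 1. The
offset is irrelevant for male−female *differences*. When the raw and
evaporation ratios coincide, the corrected value is exactly 1. Flies with a
non-positive yeast denominator have an undefined ratio; they are set to
`NA`, excluded from ratio analyses, and counted in the run manifest — never
silently dropped.

Two quantitative properties worth knowing (both exercised by the tests):
`corrected − 1` is invariant to common rescaling of raw and evaporation
values, and when evaporation is *large* relative to intake the correction
attenuates true mean-ratio differences by roughly
$\mu_y/(\mu_y + \mu_{e_y})$ — about 5% at the defaults.

**Bivariate scale.** For the two-trait analysis the correction is simply
componentwise subtraction of the mean evaporative loss; negative corrected
values (measurement error in flies that drank little) are preserved, since
they pose no problem on this scale. Volumes convert to solute masses at
90 µg per µl (90 g/L).

A one-sample t test per population (`test_positive_consumption()`) checks
that corrected consumption is significantly positive — the sanity check
that the assay measures drinking, not noise.

## Dimorphism: per-population models and the stratified bootstrap

Within each population, an OLS regression of the corrected ratio on a sex
indicator gives the per-population dimorphism and its t-test p-value
(equivalent to a pooled-variance two-sample t test).

Treatment-level inference uses a **stratified bootstrap**: each of
`n_boot` (default 10,000) replicates resamples flies with replacement
within every population × sex stratum, computes per-population male−female
mean differences, and averages them across the treatment's populations.
The individual fly is the resampling unit because each fly was assayed in
its own vial. The two-tailed p-value is read directly off the sampling
distribution as $2\min(\Pr^*[\hat\delta \le 0], \Pr^*[\hat\delta \ge 0])$,
floored at `2/n_boot` — the floor is a resolution statement, not evidence
of p = 0 — and capped at 1. With a single population the pooled procedure
reduces to the per-population bootstrap by construction.

## The measurement-error mixed model

Because population is the unit of replication, the treatment effect on
dimorphism is tested on the 12 population × sex mean ratios, not on
individual flies. The model is meta-analytic:

$$\bar y_{ps} = \beta_0 + \beta_1 \mathrm{sex} + \beta_2 \mathrm{trt}
 + \beta_3 \mathrm{sex{\times}trt} + b_p + \varepsilon_{ps},
 \quad b_p \sim \mathcal N(0, \sigma^2_{pop}),\;
 \varepsilon_{ps} \sim \mathcal N(0, v_{ps})$$

where each $v_{ps}$ is the *known* bootstrap sampling variance of that
mean. The single free variance $\sigma^2_{pop}$ is profiled by REML with a
bounded one-dimensional search on the log scale (tolerance 1e-10); a
boundary solution is clamped to zero and flagged. Fixed effects are the
GLS solution at the optimum.

F tests use **containment denominator degrees of freedom**, stated
explicitly because software conventions differ: between-population
contrasts (treatment) get `n_populations − n_treatments`; within-population
contrasts (sex, sex×treatment) get
`n_obs − n_populations − n_within_parameters`. In the balanced
six-population design both rules give 4, so every printed test is
F(1, 4). The test of interest — "does treatment change dimorphism?" — is
read as the **sex × treatment interaction**; the treatment main effect is
also reported, since the two readings are sometimes conflated. The
ancestral population is excluded by default (a single unreplicated
"treatment" would contribute no information about the contrast and would
change the containment df).

## The bivariate Bayesian mixed model

Ratios cannot say *which* trait moved. The bivariate model analyses each
fly's corrected (sucrose, yeast) masses jointly:

$$\mathbf y_i = X_i\boldsymbol\beta + \mathbf u_{p(i)} + \mathbf e_i,
\quad \mathbf u_p \sim \mathcal N_2(\mathbf 0,
\mathrm{diag}(\sigma^2_{u,s},\sigma^2_{u,y})), \quad
\mathbf e_i \sim \mathcal N_2(\mathbf 0, R)$$

with trait-specific population intercepts (independent variances — the
random structure deliberately does not correlate traits across populations,
which would be weakly identified with six populations) and an unstructured
2×2 residual covariance. Five nested fixed-effect structures are compared:
trait intercepts only; + treatment; + sex; treatment×trait + sex;
sex×trait + treatment. All coefficients are in µg.

Every full conditional is conjugate, so the sampler is plain Gibbs
(implemented in C++): multivariate-normal updates for $\boldsymbol\beta$
and $\mathbf u_p$, inverse-gamma for the intercept variances,
inverse-Wishart (Bartlett construction) for $R$. Priors are weakly
informative in the style such models conventionally use: fixed effects
$\mathcal N(0, 10^{10})$, variances with unit scale and 0.002 degrees of
belief. The default schedule — 13,000 iterations, 3,000 burn-in, thinning
10 — follows the conventions of the mixed-model MCMC literature; because
the updates are conjugate, mixing is fast and much shorter chains give
equivalent summaries. Two chains run by default and a potential
scale-reduction factor above 1.1 on any fixed effect raises a warning. Any
non-positive-definite update aborts with the iteration index.

Model comparison uses **DIC** conditional on the random effects:
$\mathrm{DIC} = \bar D + p_D$, $p_D = \bar D - D(\bar\theta)$, with the
deviance from the bivariate normal likelihood and $\bar\theta$ the
posterior means of fixed effects, random intercepts and residual
covariance. Ties are broken toward the spec with fewer parameters. Effects
are summarised by posterior means, central 95% intervals and `pMCMC`
($2\min(\Pr[>0],\Pr[<0])$, floored at `2/n_draws`).

## Adaptation metrics

* **Mean fitness**: recruits to the next generation per female, per
  population and generation. Zero females is an extinction event and an
  explicit error, not a silent `NaN`.
* **Starvation survival**: binomial logistic regression (IRLS via
  `stats::glm`) of each population's survived/died counts on treatment;
  the Wald Z for the treatment coefficient is reported, with a
  likelihood-ratio fallback under complete separation.
* **Evolutionary rates in Haldanes**: for each population, sex and trait,
  $|\bar z_{g3} - \bar z_{anc}| / s_{anc} / 3$ — divergence in ancestral
  phenotypic SDs per generation. The ancestral SD is **sex- and
  trait-specific**, matching the sex-specific rates being compared, and
  the rate is invariant to unit changes (µl vs µg). Rates are summarised
  both over all 12 sex × population values per trait and within treatment,
  since "the average rate" admits both readings. Sexes are compared per
  trait by a one-way F test on the 12 rates (df 1, 10).

## Numerical and degenerate-input policy

* Undefined ratios: flagged `NA`, excluded from ratio analyses only,
  counted in the manifest (`flies_in = analyzed + excluded` is asserted).
* Zero-variance positivity input, empty bootstrap strata, a population
  missing one sex, zero ancestral SD, zero females: explicit errors naming
  the offending unit.
* One-fly strata bootstrap to a point mass (variance 0) rather than
  erroring; the p-value floor prevents literal zeros.
* REML at the boundary: $\sigma^2_{pop} = 0$, flagged, never negative.
* All randomness flows from one integer seed; module sub-streams are
  derived deterministically, so standalone generator calls reproduce the
  corresponding slices of the full experiment, and reruns write
  byte-identical tables.

## What the synthetic world does and does not show

The generator reproduces the design's statistical structure: stratified
sampling, evaporation and measurement noise, mortality thinning, known
effect sizes. Passing tests therefore demonstrate that the estimators are
correctly implemented and calibrated *under the stated model* — normal
latent ratios, independent flies, homogeneous evaporation. They cannot
certify properties the synthetic world lacks: skewed or heavy-tailed
individual ratios (the motivation for analysing population means), vial- or
chamber-position effects on evaporation, non-independence from shared
rearing, or selection dynamics (trait trajectories are specified, not
emergent). Analyses of real deposits should treat the column-mapping layer
and those caveats accordingly.

## Problem sizes used in the validation suite

The test suite validates at the design's own scale: 3 populations per
treatment and ~40–50 flies per sex for bootstrap calibration (500 null
experiments at 1,000 replicates each), power and recovery (200
experiments), mixed-model recovery (200 simulated mean tables), sampler
coverage (100 fits) and DIC model recovery (50 five-spec comparisons), and
survival-GLM calibration (1,000 tables). MCMC validation runs use 2,500
iterations — the conjugate updates make longer default chains statistically
redundant there — while the pipeline default remains 13,000/3,000/10.

```{r, eval = FALSE}
library(dietdimorph)
res <- run_full_analysis(sim_config(seed = 1))
res                       # headline summary
tidy(res$dimorphism)      # per-population and pooled estimates
tidy(res$mixed_model)     # measurement-error model fixed effects
res$dic_table             # bivariate model ranking
autoplot(res$dimorphism)  # sampling distributions
```
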