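test_that("design builder encodes each spec's fixed effects", {
  d <- tibble::tibble(
    population = c("HC1", "HC1", "LC1", "LC1"),
    treatment = rep(c("high_competition_low_food",
                      "low_competition_high_food"), each = 2),
    sex = c("M", "F", "M", "F"),
    sucrose_ug = 1, yeast_ug = 1)
  d0 <- dietdimorph:::build_bivariate_design(d, "intercepts_only")
  expect_equal(d0$coef_names, c("(Intercept)", "traitY"))
  expect_equal(d0$Xs[, 2], rep(0, 4))
  expect_equal(d0$Xy[, 2], rep(1, 4))

  ds <- dietdimorph:::build_bivariate_design(d, "sex_x_trait_plus_treatment")
  expect_equal(ds$coef_names,
               c("(Intercept)", "traitY", "sexM", "traitY:sexM", "trtHigh"))
  # the trait-by-sex column is male-specific and yeast-specific
  expect_equal(ds$Xs[, "traitY:sexM"], rep(0, 4))
  expect_equal(ds$Xy[, "traitY:sexM"], c(1, 0, 1, 0))
  expect_equal(ds$Xs[, "trtHigh"], c(1, 1, 0, 0))

  dt <- dietdimorph:::build_bivariate_design(d, "treatment_x_trait_plus_sex")
  expect_equal(dt$coef_names,
               c("(Intercept)", "traitY", "trtHigh", "traitY:trtHigh", "sexM"))
})

test_that("pmcmc matches its definition and the normal tail", {
  expect_equal(pmcmc(rep(1, 500)), 2 / 500)          # all positive: floor
  expect_equal(pmcmc(c(rep(1, 250), rep(-1, 250))), 1)
  set.seed(88)
  draws <- rnorm(10000, 1, 1)
  expect_lt(abs(pmcmc(draws) - 2 * pnorm(-1)), 0.02)
  expect_error(pmcmc(rnorm(50)), "100")
})

test_that("the sampler is reproducible given the seed", {
  d <- sim_biv_data(1, n_per_pop = 20)
  f1 <- fit_bivariate_mm(d, n_iter = 300, burnin = 100, thin = 1,
                         chains = 1, seed = 2)
  f2 <- fit_bivariate_mm(d, n_iter = 300, burnin = 100, thin = 1,
                         chains = 1, seed = 2)
  expect_identical(f1$draws$beta, f2$draws$beta)
  expect_identical(f1$dic, f2$dic)
})

test_that("null data give posterior means near zero for all effects", {
  d <- sim_biv_data(3, n_per_pop = 200, trait_sex = 0, treatment_effect = 0,
                    sd_pop = 5)
  f <- fit_bivariate_mm(d, n_iter = 1500, burnin = 500, thin = 1, chains = 1,
                        seed = 4)
  td <- tidy(f)
  eff <- td[td$term %in% c("sexM", "traitY:sexM", "trtHigh"), ]
  expect_true(all(abs(eff$estimate) < 2.5 * eff$std_error))
})

test_that("with the random effect suppressed the sampler matches an independent conjugate sampler", {
  # single population, prior forcing the intercept variance to zero:
  # the model reduces to a bivariate regression with unstructured residual
  # covariance, for which the reference sampler is written independently
  set.seed(10)
  n <- 60
  sex <- rep(c("M", "F"), each = n / 2)
  d <- tibble::tibble(
    population = "HC1", treatment = "high_competition_low_food", sex = sex,
    sucrose_ug = 280 + 15 * (sex == "M") + rnorm(n, 0, 40),
    yeast_ug = 190 - 30 * (sex == "M") + rnorm(n, 0, 30))
  f <- fit_bivariate_mm(d, spec = "plus_sex", n_iter = 6000, burnin = 1000,
                        thin = 1, chains = 1, seed = 5,
                        nu_g = 1e8, V_g = 1e-12)
  des <- dietdimorph:::build_bivariate_design(d, "plus_sex")
  set.seed(6)
  ref <- ref_mvreg_gibbs(d$sucrose_ug, d$yeast_ug, des$Xs, des$Xy,
                         n_iter = 6000, burnin = 1000)
  for (j in seq_along(f$coef_names)) {
    mcse <- sd(ref[, j]) / sqrt(400) + sd(f$draws$beta[, j]) / sqrt(400)
    expect_lt(abs(mean(f$draws$beta[, j]) - mean(ref[, j])), 5 * mcse)
    expect_lt(abs(sd(f$draws$beta[, j]) / sd(ref[, j]) - 1), 0.15)
  }
})

test_that("residual covariance draws are symmetric positive definite", {
  d <- sim_biv_data(7, n_per_pop = 30)
  f <- fit_bivariate_mm(d, n_iter = 500, burnin = 100, thin = 1, chains = 1,
                        seed = 8)
  rc <- f$draws$rcov
  expect_true(all(rc[, "sucrose"] > 0))
  expect_true(all(rc[, "yeast"] > 0))
  # positive determinant = positive definite for a symmetric 2x2
  expect_true(all(rc[, "sucrose"] * rc[, "yeast"] - rc[, "covariance"]^2 > 0))
  expect_true(all(f$draws$sigma_pop > 0))
})

test_that("constant draws give pD of zero and DIC equal to the deviance", {
  d <- sim_biv_data(9, n_per_pop = 20)
  f <- fit_bivariate_mm(d, n_iter = 300, burnin = 100, thin = 1, chains = 1,
                        seed = 10)
  # collapse the posterior to a point: every draw equals the first
  for (nm in c("beta", "sigma_pop", "rcov", "u_sucrose", "u_yeast")) {
    f$draws[[nm]] <- f$draws[[nm]][rep(1, nrow(f$draws[[nm]])), ]
  }
  f$draws$deviance <- rep(f$draws$deviance[1], length(f$draws$deviance))
  out <- compute_dic(f)
  expect_equal(out$pD, 0, tolerance = 1e-6)
  expect_equal(out$dic, f$draws$deviance[1], tolerance = 1e-6)
})

test_that("model selection picks minimum DIC with ties to the simpler spec", {
  d <- sim_biv_data(11, n_per_pop = 20)
  f1 <- fit_bivariate_mm(d, "intercepts_only", n_iter = 300, burnin = 100,
                         thin = 1, chains = 1, seed = 1)
  f2 <- fit_bivariate_mm(d, "plus_sex", n_iter = 300, burnin = 100,
                         thin = 1, chains = 1, seed = 1)
  f1$dic <- 100; f2$dic <- 102.7
  sel <- select_bivariate_model(list(a = f1, b = f2))
  expect_equal(sel$best, "intercepts_only")
  expect_equal(sel$delta_dic, 2.7, tolerance = 1e-12)
  # tie: the spec with fewer parameters wins
  f2$dic <- 100
  sel2 <- select_bivariate_model(list(a = f2, b = f1))
  expect_equal(sel2$best, "intercepts_only")
  # single candidate: no delta
  sel3 <- select_bivariate_model(list(only = f1))
  expect_true(is.na(sel3$delta_dic))
  expect_equal(sel3$best, "intercepts_only")
})

test_that("swapping trait order transposes the fit without changing DIC", {
  d <- sim_biv_data(13, n_per_pop = 60)
  swapped <- dplyr::rename(d, sucrose_ug = yeast_ug, yeast_ug = sucrose_ug)
  f1 <- fit_bivariate_mm(d, "sex_x_trait_plus_treatment", n_iter = 3000,
                         burnin = 1000, thin = 1, chains = 1, seed = 14)
  f2 <- fit_bivariate_mm(swapped, "sex_x_trait_plus_treatment", n_iter = 3000,
                         burnin = 1000, thin = 1, chains = 1, seed = 15)
  t1 <- tidy(f1); t2 <- tidy(f2)
  g <- function(td, term) td$estimate[td$term == term]
  # the trait-by-sex interaction negates; the sex main effect moves to the
  # other trait's scale (sexM' = sexM + interaction)
  tol <- 3 * (t1$std_error[t1$term == "traitY:sexM"] / sqrt(100))
  expect_equal(g(t2, "traitY:sexM"), -g(t1, "traitY:sexM"), tolerance = 0.2)
  expect_equal(g(t2, "sexM"), g(t1, "sexM") + g(t1, "traitY:sexM"),
               tolerance = 0.2)
  expect_lt(abs(f1$dic - f2$dic), 8)
  # residual variances swap roles
  expect_equal(mean(f2$draws$rcov[, "sucrose"]),
               mean(f1$draws$rcov[, "yeast"]), tolerance = 0.1)
})

test_that("two chains are pooled and R-hat is reported", {
  d <- sim_biv_data(16, n_per_pop = 25)
  f <- fit_bivariate_mm(d, n_iter = 400, burnin = 100, thin = 1, chains = 2,
                        seed = 17)
  expect_equal(length(f$draws$deviance), 600)
  expect_true(all(is.finite(f$rhat)))
  expect_true(all(f$rhat < 1.2))
})
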