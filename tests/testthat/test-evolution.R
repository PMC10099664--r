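census_row <- function(pop, trt, gen, females, recruits, assayed = NA,
                       survived = NA) {
  tibble::tibble(population = pop, treatment = trt, generation = gen,
                 n_females = females, n_recruits_next_generation = recruits,
                 n_assayed = assayed, n_survived_deprivation = survived)
}

test_that("mean fitness is recruits per female", {
  cen <- dplyr::bind_rows(
    census_row("P1", "high_competition_low_food", 0, 50, 500),
    census_row("P1", "high_competition_low_food", 1, 56, 0),
    census_row("P2", "low_competition_high_food", 0, 10, NA))
  out <- mean_fitness(cen)
  expect_equal(out$mean_fitness, c(10, 0))
  expect_equal(nrow(out), 2)  # NA recruit rows dropped
  expect_error(
    mean_fitness(census_row("P3", "high_competition_low_food", 0, 0, 5)),
    "zero females")
})

test_that("simulated fitness trajectories recover the configured fold change", {
  cfg <- sim_config(seed = 20)
  expt <- simulate_experiment(cfg)
  fit <- mean_fitness(expt$census)
  by_gen <- fit %>%
    dplyr::group_by(generation) %>%
    dplyr::summarise(f = mean(mean_fitness))
  # configured rates rise 0.5 -> 5.0 recruits per female (10x)
  expect_equal(by_gen$f, cfg$recruitment_rate, tolerance = 0.25)
  fold <- by_gen$f[by_gen$generation == 3] / by_gen$f[by_gen$generation == 0]
  expect_gt(fold, 5)
  expect_lt(fold, 20)
  # pooling subgroups equals the population-level ratio: splitting a
  # population's counts in two and recombining recovers the same fitness
  row <- expt$census[expt$census$generation == 0 &
                       expt$census$population == "HC1", ]
  half <- row; half$n_females <- row$n_females / 2
  half$n_recruits_next_generation <- row$n_recruits_next_generation / 2
  expect_equal(mean_fitness(half)$mean_fitness,
               mean_fitness(row)$mean_fitness)
})

test_that("haldane rate matches hand arithmetic and its invariances", {
  expect_equal(haldane_rate(1.2, 1.0, 0.5, 3), 0.2 / 0.5 / 3)
  expect_equal(haldane_rate(1.0, 1.0, 0.5, 3), 0)
  # unit change (volume to mass at 90 g/L) leaves the rate unchanged
  expect_equal(haldane_rate(1.2 * 90, 1.0 * 90, 0.5 * 90, 3),
               haldane_rate(1.2, 1.0, 0.5, 3))
  # divergence direction does not matter
  expect_equal(haldane_rate(0.8, 1.0, 0.5, 3), haldane_rate(1.2, 1.0, 0.5, 3))
  expect_error(haldane_rate(1, 1, 0, 3), "sd_ancestor")
  expect_error(haldane_rate(1, 1, 0.5, 0), "n_generations")
})

test_that("haldane_rates standardises by the sex-specific ancestral SD", {
  set.seed(30)
  anc_m <- rnorm(200, 270, 90)
  anc_f <- rnorm(200, 270, 45)
  ev_m <- rnorm(50, 300, 90)
  yst <- function(n) rnorm(n, 180, 30)
  mk <- function(vals, trt, sex, pop) {
    tibble::tibble(population = pop, treatment = trt, sex = sex,
                   sucrose_ug = vals, yeast_ug = yst(length(vals)))
  }
  d <- dplyr::bind_rows(mk(anc_m, "ancestor", "M", "ANC"),
                        mk(anc_f, "ancestor", "F", "ANC"),
                        mk(ev_m, "high_competition_low_food", "M", "HC1"),
                        mk(ev_m, "high_competition_low_food", "F", "HC1"))
  rates <- haldane_rates(d, n_generations = 3)
  m_rate <- rates$rate[rates$sex == "M" & rates$trait == "sucrose"]
  f_rate <- rates$rate[rates$sex == "F" & rates$trait == "sucrose"]
  expect_equal(m_rate, abs(mean(ev_m) - mean(anc_m)) / sd(anc_m) / 3)
  expect_equal(f_rate, abs(mean(ev_m) - mean(anc_f)) / sd(anc_f) / 3)
  # the same divergence scaled by half the ancestral SD doubles the rate
  expect_equal(f_rate / m_rate, sd(anc_m) / sd(anc_f) *
                 abs(mean(ev_m) - mean(anc_f)) / abs(mean(ev_m) - mean(anc_m)))
  expect_error(haldane_rates(dplyr::filter(d, treatment != "ancestor")),
               "ancestor")
})

test_that("survival GLM equals the closed-form 2x2 log odds ratio", {
  cen <- dplyr::bind_rows(
    census_row("HC1", "high_competition_low_food", 3, 50, 10, 100, 90),
    census_row("LC1", "low_competition_high_food", 3, 50, 10, 100, 60))
  out <- survival_glm(cen)
  expect_equal(out$estimate, log((90 / 10) / (60 / 40)), tolerance = 1e-8)
  se_hand <- sqrt(1 / 90 + 1 / 10 + 1 / 60 + 1 / 40)
  expect_equal(out$std_error, se_hand, tolerance = 1e-8)
  expect_equal(out$statistic, out$estimate / se_hand, tolerance = 1e-8)
  expect_equal(out$p_value, 2 * pnorm(-abs(out$statistic)), tolerance = 1e-8)
  expect_false(out$separation)
  expect_equal(out$prop_high, 0.9)
  expect_equal(out$prop_low, 0.6)
})

test_that("identical survival gives a coefficient and Z near zero", {
  cen <- dplyr::bind_rows(
    census_row("HC1", "high_competition_low_food", 3, 50, 10, 100, 75),
    census_row("LC1", "low_competition_high_food", 3, 50, 10, 100, 75))
  out <- survival_glm(cen)
  expect_equal(out$estimate, 0, tolerance = 1e-10)
  expect_equal(out$statistic, 0, tolerance = 1e-8)
})

test_that("complete separation falls back to a likelihood-ratio p", {
  cen <- dplyr::bind_rows(
    census_row("HC1", "high_competition_low_food", 3, 50, 10, 100, 100),
    census_row("LC1", "low_competition_high_food", 3, 50, 10, 100, 0))
  out <- suppressWarnings(survival_glm(cen))
  expect_true(out$separation)
  expect_lt(out$p_value, 1e-10)
})

test_that("rate comparison equals a hand-computed one-way ANOVA", {
  set.seed(41)
  rates <- tibble::tibble(
    population = rep(paste0("P", 1:6), 2),
    treatment = "high_competition_low_food",
    sex = rep(c("M", "F"), each = 6),
    trait = "sucrose",
    rate = abs(rnorm(12, 0.07, 0.03)))
  out <- compare_rate_sexes(rates)
  g1 <- rates$rate[rates$sex == "M"]
  g2 <- rates$rate[rates$sex == "F"]
  gm <- mean(rates$rate)
  ssb <- 6 * ((mean(g1) - gm)^2 + (mean(g2) - gm)^2)
  ssw <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)
  f_hand <- (ssb / 1) / (ssw / 10)
  expect_equal(out$statistic, f_hand, tolerance = 1e-10)
  expect_equal(out$df_num, 1)
  expect_equal(out$df_den, 10)
  expect_equal(out$p_value, pf(f_hand, 1, 10, lower.tail = FALSE),
               tolerance = 1e-10)
  # identical rates across sexes: F = 0, p = 1
  rates$rate <- rep(0.07, 12)
  out0 <- compare_rate_sexes(rates)
  expect_equal(out0$statistic, 0)
  expect_equal(out0$p_value, 1)
})
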