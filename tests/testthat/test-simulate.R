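test_that("config validation names the offending field", {
  expect_error(sim_config(n_vials = 0), "n_vials")
  expect_error(sim_config(evap_sucrose_mean = -0.1), "evap_sucrose_mean")
  expect_error(sim_config(sigma_ratio = -1), "sigma_ratio")
  expect_error(sim_config(mortality_prob = c(
    high_competition_low_food = 1.2, low_competition_high_food = 0.3)),
    "mortality_prob")
  expect_error(sim_config(mu_yeast = list(
    ancestor = c(M = 0, F = 2),
    high_competition_low_food = c(M = 2, F = 2),
    low_competition_high_food = c(M = 2, F = 2))), "strictly positive")
  expect_error(sim_config(recruitment_rate = c(1, 2)), "recruitment_rate")
})

test_that("the same seed reproduces the dataset; different seeds differ", {
  e1 <- simulate_experiment(fast_cfg(seed = 11))
  e2 <- simulate_experiment(fast_cfg(seed = 11))
  e3 <- simulate_experiment(fast_cfg(seed = 12))
  expect_identical(e1$consumption, e2$consumption)
  expect_identical(e1$controls, e2$controls)
  expect_identical(e1$census, e2$census)
  expect_false(identical(e1$consumption$sucrose_raw,
                         e3$consumption$sucrose_raw))
})

test_that("noise-free limit: raw losses equal the configured means exactly", {
  cfg <- fast_cfg(seed = 2, sigma_ratio = 0, sigma_yeast = 0,
                  sigma_measurement = 0,
                  evap_sucrose_mean = 0, evap_sucrose_sd = 0,
                  evap_yeast_mean = 0, evap_yeast_sd = 0)
  expt <- simulate_experiment(cfg)
  for (trt in unique(expt$consumption$treatment)) {
    for (sx in c("M", "F")) {
      rows <- dplyr::filter(expt$consumption, treatment == trt, sex == sx)
      expect_equal(rows$sucrose_raw,
                   rep(cfg$mu_sucrose[[trt]][[sx]], nrow(rows)))
      expect_equal(rows$yeast_raw,
                   rep(cfg$mu_yeast[[trt]][[sx]], nrow(rows)))
    }
  }
})

test_that("evaporation controls follow the configured distribution", {
  cfg0 <- fast_cfg(seed = 5, evap_sucrose_sd = 0, evap_yeast_sd = 0,
                   evap_sucrose_mean = 0.4, evap_yeast_mean = 0.25)
  ctr0 <- simulate_evaporation_controls(cfg0)
  expect_equal(ctr0$sucrose_loss, rep(0.4, 10))
  expect_equal(ctr0$yeast_loss, rep(0.25, 10))

  # 20 vials: empirical mean within 3 SE of the configured mean
  cfg <- sim_config(seed = 5)
  ctr <- simulate_evaporation_controls(cfg)
  expect_equal(nrow(ctr), 20)
  se <- cfg$evap_sucrose_sd / sqrt(20)
  expect_lt(abs(mean(ctr$sucrose_loss) - cfg$evap_sucrose_mean), 3 * se)
  expect_true(all(ctr$sucrose_loss >= 0, ctr$yeast_loss >= 0))
})

test_that("ancestor assay carries generation 0, both sexes, ancestor label", {
  anc <- simulate_ancestor_assay(fast_cfg(seed = 3,
                                          ancestor_assay_n_per_sex = 1))
  expect_equal(nrow(anc), 2)
  expect_setequal(anc$sex, c("M", "F"))
  expect_true(all(anc$generation == 0L))
  expect_true(all(anc$treatment == "ancestor"))

  anc50 <- simulate_ancestor_assay(sim_config(seed = 3))
  expect_equal(nrow(anc50), 100)
})

test_that("empirical intake moments converge to the configured values", {
  cfg <- sim_config(ancestor_assay_n_per_sex = 10000, seed = 9)
  anc <- simulate_ancestor_assay(cfg)
  m <- dplyr::filter(anc, sex == "M")
  r_mu <- cfg$mu_sucrose$ancestor[["M"]] / cfg$mu_yeast$ancestor[["M"]]
  expect_lt(abs(mean(m$true_ratio) - r_mu),
            3 * cfg$sigma_ratio / sqrt(10000))
  expect_lt(abs(sd(m$true_ratio) - cfg$sigma_ratio), 0.03)
  expect_lt(abs(mean(m$true_yeast) - cfg$mu_yeast$ancestor[["M"]]),
            3 * cfg$sigma_yeast / sqrt(10000))
  # sucrose volume mean is ratio mean x yeast mean (independent draws)
  expect_lt(abs(mean(m$true_sucrose) - cfg$mu_sucrose$ancestor[["M"]]), 0.06)
})

test_that("mortality thinning controls the number of assayed offspring", {
  cfg <- fast_cfg(seed = 21,
                  mortality_prob = c(high_competition_low_food = 0,
                                     low_competition_high_food = 1))
  expt <- simulate_experiment(cfg)
  hc <- dplyr::filter(expt$consumption,
                      treatment == "high_competition_low_food")
  lc <- dplyr::filter(expt$consumption,
                      treatment == "low_competition_high_food")
  expect_equal(nrow(hc), 3 * 2 * cfg$offspring_assay_n_per_sex)
  expect_equal(nrow(lc), 0)
  gen3 <- dplyr::filter(expt$census, generation == 3,
                        treatment == "high_competition_low_food")
  expect_equal(gen3$n_survived_deprivation, gen3$n_assayed)
})

test_that("experiment invariants hold: populations in census, labels valid", {
  expt <- simulate_experiment(fast_cfg(seed = 4))
  expect_true(all(expt$consumption$population %in% expt$census$population))
  anc <- dplyr::filter(expt$consumption, treatment == "ancestor")
  expect_true(all(anc$generation == 0L))
  expect_true(all(expt$consumption$sucrose_raw >= 0))
  # survivor counts in census match the consumption records
  surv <- dplyr::count(dplyr::filter(expt$consumption,
                                     treatment != "ancestor"), population)
  gen3 <- dplyr::filter(expt$census, !is.na(n_survived_deprivation))
  expect_equal(surv$n[match(gen3$population, surv$population)],
               gen3$n_survived_deprivation)
})

test_that("YAML round trip reproduces a configuration", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_control_vials: 12",
    "seed: 77",
    "mortality_prob:",
    "  high_competition_low_food: 0.1",
    "  low_competition_high_food: 0.2"), path)
  cfg <- read_sim_config(path)
  expect_equal(cfg$n_control_vials, 12)
  expect_equal(cfg$seed, 77L)
  expect_equal(unname(cfg$mortality_prob["high_competition_low_food"]), 0.1)
  writeLines("not_a_field: 3", path)
  expect_error(read_sim_config(path), "unknown configuration field")
})
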