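#' Simulate a complete feeding-assay experiment
#'
#' Generates every table the analysis pipeline consumes: per-fly raw fluid
#' losses for the ancestor assay and the offspring assay (after mortality
#' thinning during the 48 h deprivation period), fly-free evaporation-control
#' vials, and per-population census records (females, recruits to the next
#' generation, assay and deprivation-survival counts). The generating
#' parameters are attached as `truth` so downstream estimators can be checked
#' against ground truth.
#'
#' All randomness derives from `config$seed`; the same configuration always
#' yields an identical dataset. Sub-streams for the control vials, the
#' ancestor assay and the evolved populations are derived deterministically
#' from the global seed, so [simulate_evaporation_controls()] and
#' [simulate_ancestor_assay()] called standalone reproduce the corresponding
#' components exactly.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `"diet_experiment"`: a list with tibbles
#'   `consumption`, `controls`, `census`, and `truth` (the config).
#'   `consumption` carries the observed columns (`fly_id`, `population`,
#'   `treatment`, `generation`, `sex`, `sucrose_raw`, `yeast_raw`,
#'   `survived_deprivation`) plus simulation-truth columns `true_sucrose`,
#'   `true_yeast`, `true_ratio` (ul / dimensionless).
#' @examples
#' expt <- simulate_experiment(sim_config(seed = 42))
#' dplyr::count(expt$consumption, treatment, sex)
#' @export
simulate_experiment <- function(config) {
  config <- validate_sim_config(config)
  controls <- simulate_evaporation_controls(config)
  ancestor <- simulate_ancestor_assay(config)
  evolved <- simulate_evolved_populations(config)

  consumption <- dplyr::bind_rows(ancestor, evolved$consumption)
  census <- dplyr::bind_rows(
    tibble(population = "ANC", treatment = "ancestor", generation = 0L,
           n_females = config$ancestor_assay_n_per_sex,
           n_recruits_next_generation = NA_integer_,
           n_assayed = 2L * config$ancestor_assay_n_per_sex,
           n_survived_deprivation = NA_integer_),
    evolved$census
  )
  structure(list(consumption = consumption, controls = controls,
                 census = census, truth = config),
            class = "diet_experiment")
}

#' @export
print.diet_experiment <- function(x, ...) {
  cat("<diet_experiment>\n")
  cat(sprintf("  %d consumption records (%d populations), %d control vials\n",
              nrow(x$consumption), dplyr::n_distinct(x$consumption$population),
              nrow(x$controls)))
  cat(sprintf("  census: %d population x generation rows\n", nrow(x$census)))
  invisible(x)
}

#' Simulate fly-free evaporation-control vials
#'
#' Draws per-vial 24 h fluid losses for the sucrose and yeast tubes from the
#' configured normal distributions, truncated at zero.
#'
#' @inheritParams simulate_experiment
#' @return A tibble with columns `vial_id`, `sucrose_loss`, `yeast_loss` (ul).
#' @export
simulate_evaporation_controls <- function(config) {
  config <- validate_sim_config(config)
  set.seed(config$seed + 1L)
  n <- config$n_control_vials
  tibble(
    vial_id = sprintf("CTRL%02d", seq_len(n)),
    sucrose_loss = pmax(0, rnorm(n, config$evap_sucrose_mean,
                                 config$evap_sucrose_sd)),
    yeast_loss = pmax(0, rnorm(n, config$evap_yeast_mean,
                               config$evap_yeast_sd))
  )
}

#' Simulate the ancestor diet assay
#'
#' Generation-0 flies from the ancestral population, assayed individually
#' before the evolution experiment starts.
#'
#' @inheritParams simulate_experiment
#' @return A tibble of per-fly consumption records (see
#'   [simulate_experiment()]).
#' @export
simulate_ancestor_assay <- function(config) {
  config <- validate_sim_config(config)
  set.seed(config$seed + 2L)
  n <- config$ancestor_assay_n_per_sex
  sim_assay_flies(config, population = "ANC", treatment = "ancestor",
                  generation = 0L, n_by_sex = c(M = n, F = n), survived = NA)
}

# Per-fly draws for one population's assay. The latent diet ratio is drawn
# directly (its mean is the ratio of configured mean volumes), the yeast
# volume independently; sucrose volume is their product. Raw losses add an
# evaporation draw and caliper noise per tube, floored at 0 (fluid cannot
# rise).
sim_assay_flies <- function(config, population, treatment, generation,
                            n_by_sex, survived) {
  purrr::map_dfr(SEX_LEVELS, function(sx) {
    n <- n_by_sex[[sx]]
    if (n == 0L) return(NULL)
    mu_s <- config$mu_sucrose[[treatment]][[sx]]
    mu_y <- config$mu_yeast[[treatment]][[sx]]
    r <- rnorm(n, mu_s / mu_y, config$sigma_ratio)
    y <- pmax(rnorm(n, mu_y, config$sigma_yeast), 1e-8)
    s <- r * y
    evap_s <- pmax(0, rnorm(n, config$evap_sucrose_mean, config$evap_sucrose_sd))
    evap_y <- pmax(0, rnorm(n, config$evap_yeast_mean, config$evap_yeast_sd))
    tibble(
      fly_id = sprintf("%s_g%d_%s%03d", population, generation, sx, seq_len(n)),
      population = population,
      treatment = treatment,
      generation = as.integer(generation),
      sex = sx,
      sucrose_raw = pmax(0, s + evap_s + rnorm(n, 0, config$sigma_measurement)),
      yeast_raw = pmax(0, y + evap_y + rnorm(n, 0, config$sigma_measurement)),
      survived_deprivation = survived,
      true_sucrose = s,
      true_yeast = y,
      true_ratio = r
    )
  })
}

# Census trajectories and the generation-n offspring assay for the evolved
# populations. Recruitment counts are Poisson around rate x females and are
# recorded uncapped (the fitness measure); the flies carried forward are
# capped at vial capacity. Deprivation mortality thins the assayed offspring
# independently per fly; only survivors yield consumption records.
simulate_evolved_populations <- function(config) {
  set.seed(config$seed + 3L)
  n_rep <- config$n_populations_per_treatment
  pops <- tibble(
    treatment = rep(EVOLVED_TREATMENTS, each = n_rep),
    population = paste0(rep(c("HC", "LC"), each = n_rep), seq_len(n_rep))
  )
  res <- purrr::pmap(pops, function(treatment, population) {
    n_flies <- config$n_vials * config$flies_per_vial
    n_females <- n_flies %/% 2L
    census <- vector("list", config$n_generations + 1L)
    for (g in 0:config$n_generations) {
      recruits <- rpois(1L, config$recruitment_rate[[g + 1L]] * n_females)
      census[[g + 1L]] <- tibble(
        population = population, treatment = treatment, generation = g,
        n_females = as.integer(n_females),
        n_recruits_next_generation = as.integer(recruits),
        n_assayed = NA_integer_, n_survived_deprivation = NA_integer_)
      carried <- min(recruits, config$vial_capacity)
      n_females <- max(1L, rbinom(1L, carried, 0.5))
    }
    census <- dplyr::bind_rows(census)

    n_assay <- config$offspring_assay_n_per_sex
    p_die <- config$mortality_prob[[treatment]]
    surv_m <- rbinom(1L, n_assay, 1 - p_die)
    surv_f <- rbinom(1L, n_assay, 1 - p_die)
    cons <- sim_assay_flies(config, population, treatment,
                            generation = config$n_generations,
                            n_by_sex = c(M = surv_m, F = surv_f),
                            survived = TRUE)
    gidx <- census$generation == config$n_generations
    census$n_assayed[gidx] <- 2L * n_assay
    census$n_survived_deprivation[gidx] <- surv_m + surv_f
    list(census = census, consumption = cons)
  })
  list(census = purrr::map_dfr(res, "census"),
       consumption = purrr::map_dfr(res, "consumption"))
}
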