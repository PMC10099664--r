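#' Configuration for a synthetic feeding-assay experiment
#'
#' Builds (and validates) the parameter set for [simulate_experiment()]. The
#' defaults describe a two-treatment experimental-evolution design: an
#' ancestral population assayed at generation 0, and three replicate
#' populations per resource-availability treatment evolved for three
#' generations, whose common-garden offspring are assayed after a 48 h
#' starvation period. Consumption is measured as fluid loss from two 5 ul
#' microcapillary tubes (90 g/L sucrose and 90 g/L yeast-extract solution)
#' over 24 h, alongside fly-free control vials that capture evaporative loss.
#'
#' Each fly's latent diet is simulated as a sucrose:yeast ratio drawn from a
#' normal distribution with a sex- and treatment-specific mean (the ratio of
#' the configured mean volumes), so the configured mean ratio is exactly the
#' mean-of-ratios estimand used downstream. The yeast volume is drawn
#' independently and the sucrose volume is their product. Raw fluid losses add
#' an evaporation draw and measurement noise, truncated at zero (fluid cannot
#' rise).
#'
#' @param n_populations_per_treatment Replicate populations per evolved
#'   treatment (survivors, after any founding losses).
#' @param n_vials Vials per population; 28 mm vials hold `flies_per_vial`
#'   flies at fixed density.
#' @param flies_per_vial Flies per vial (half of each sex).
#' @param n_generations Generations of treatment exposure before the
#'   offspring assay.
#' @param ancestor_assay_n_per_sex,offspring_assay_n_per_sex Flies of each
#'   sex placed in individual assay vials for the ancestor and the
#'   generation-`n_generations` offspring assays.
#' @param n_control_vials Fly-free vials used to estimate evaporative loss.
#' @param mu_sucrose,mu_yeast Named lists (one element per treatment level,
#'   each a named numeric with elements `M` and `F`) of mean consumed volumes
#'   in ul per 24 h. Treatment levels are `ancestor`,
#'   `high_competition_low_food` and `low_competition_high_food`.
#' @param sigma_ratio SD of the latent individual sucrose:yeast ratio
#'   (dimensionless).
#' @param sigma_yeast SD of individual consumed yeast volume (ul).
#' @param sigma_measurement SD of caliper measurement error per tube (ul).
#' @param evap_sucrose_mean,evap_sucrose_sd,evap_yeast_mean,evap_yeast_sd
#'   Mean and SD of 24 h evaporative loss per tube (ul); draws are truncated
#'   at zero.
#' @param mortality_prob Named numeric: probability an assayed offspring dies
#'   during the 48 h food deprivation preceding the assay, per evolved
#'   treatment.
#' @param recruitment_rate Numeric vector of expected recruits per female for
#'   generations `0:n_generations` (offspring counted into the next
#'   generation; the last element is measured from an extra round of
#'   offspring counting).
#' @param vial_capacity Maximum flies carried into the next generation
#'   (`n_vials * flies_per_vial`); recruitment counts themselves are not
#'   capped.
#' @param seed Integer seed; all randomness in [simulate_experiment()]
#'   derives from it.
#'
#' @return A list of class `"sim_config"`.
#' @seealso [simulate_experiment()]
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$mu_sucrose$ancestor
#' @export
sim_config <- function(n_populations_per_treatment = 3,
                       n_vials = 7,
                       flies_per_vial = 16,
                       n_generations = 3,
                       ancestor_assay_n_per_sex = 50,
                       offspring_assay_n_per_sex = 50,
                       n_control_vials = 20,
                       mu_sucrose = list(
                         ancestor                  = c(M = 3.078, F = 3.000),
                         high_competition_low_food = c(M = 3.3735, F = 3.2195),
                         low_competition_high_food = c(M = 3.097, F = 3.040)),
                       mu_yeast = list(
                         ancestor                  = c(M = 1.90, F = 2.00),
                         high_competition_low_food = c(M = 1.95, F = 2.35),
                         low_competition_high_food = c(M = 1.90, F = 2.00)),
                       sigma_ratio = 0.8,
                       sigma_yeast = 0.55,
                       sigma_measurement = 0.05,
                       evap_sucrose_mean = 0.10,
                       evap_sucrose_sd = 0.04,
                       evap_yeast_mean = 0.10,
                       evap_yeast_sd = 0.04,
                       mortality_prob = c(
                         high_competition_low_food = 0.200,
                         low_competition_high_food = 0.337),
                       recruitment_rate = c(0.5, 1.5, 3.0, 5.0),
                       vial_capacity = n_vials * flies_per_vial,
                       seed = 1L) {
  cfg <- list(
    n_populations_per_treatment = n_populations_per_treatment,
    n_vials = n_vials,
    flies_per_vial = flies_per_vial,
    n_generations = n_generations,
    ancestor_assay_n_per_sex = ancestor_assay_n_per_sex,
    offspring_assay_n_per_sex = offspring_assay_n_per_sex,
    n_control_vials = n_control_vials,
    mu_sucrose = mu_sucrose,
    mu_yeast = mu_yeast,
    sigma_ratio = sigma_ratio,
    sigma_yeast = sigma_yeast,
    sigma_measurement = sigma_measurement,
    evap_sucrose_mean = evap_sucrose_mean,
    evap_sucrose_sd = evap_sucrose_sd,
    evap_yeast_mean = evap_yeast_mean,
    evap_yeast_sd = evap_yeast_sd,
    mortality_prob = mortality_prob,
    recruitment_rate = recruitment_rate,
    vial_capacity = vial_capacity,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  chk_count <- function(x, field) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 ||
        x != round(x)) {
      abort(sprintf("`%s` must be a single integer >= 1", field),
            class = "dietdimorph_config_error")
    }
  }
  chk_nonneg <- function(x, field) {
    if (!is.numeric(x) || any(is.na(x)) || any(x < 0)) {
      abort(sprintf("`%s` must be non-negative", field),
            class = "dietdimorph_config_error")
    }
  }
  for (f in c("n_populations_per_treatment", "n_vials", "flies_per_vial",
              "n_generations", "ancestor_assay_n_per_sex",
              "offspring_assay_n_per_sex", "n_control_vials")) {
    chk_count(cfg[[f]], f)
  }
  if (cfg$flies_per_vial %% 2L != 0L) {
    abort("`flies_per_vial` must be even (equal sex ratio per vial)",
          class = "dietdimorph_config_error")
  }
  for (f in c("sigma_ratio", "sigma_yeast", "sigma_measurement",
              "evap_sucrose_sd", "evap_yeast_sd",
              "evap_sucrose_mean", "evap_yeast_mean")) {
    chk_nonneg(cfg[[f]], f)
  }
  for (f in c("mu_sucrose", "mu_yeast")) {
    m <- cfg[[f]]
    if (!is.list(m) || !all(TREATMENT_LEVELS %in% names(m))) {
      abort(sprintf("`%s` must be a named list with elements %s", f,
                    paste(TREATMENT_LEVELS, collapse = ", ")),
            class = "dietdimorph_config_error")
    }
    vals <- unlist(m[TREATMENT_LEVELS])
    if (any(!is.finite(vals)) || any(vals <= 0)) {
      abort(sprintf("`%s`: mean intakes must be strictly positive", f),
            class = "dietdimorph_config_error")
    }
    for (trt in TREATMENT_LEVELS) {
      if (!all(SEX_LEVELS %in% names(m[[trt]]))) {
        abort(sprintf("`%s$%s` must have named elements M and F", f, trt),
              class = "dietdimorph_config_error")
      }
    }
  }
  mp <- cfg$mortality_prob
  if (!all(EVOLVED_TREATMENTS %in% names(mp)) ||
      any(mp < 0) || any(mp > 1) || any(is.na(mp))) {
    abort("`mortality_prob` must give probabilities in [0, 1] for both evolved treatments",
          class = "dietdimorph_config_error")
  }
  rr <- cfg$recruitment_rate
  if (length(rr) != cfg$n_generations + 1L || any(rr < 0) || any(is.na(rr))) {
    abort("`recruitment_rate` must be a non-negative vector of length n_generations + 1",
          class = "dietdimorph_config_error")
  }
  if (length(cfg$seed) != 1L || is.na(cfg$seed)) {
    abort("`seed` must be a single integer", class = "dietdimorph_config_error")
  }
  cfg
}

#' Read a simulation configuration from a YAML file
#'
#' Any field of [sim_config()] may be given in the file; unspecified fields
#' keep their defaults. Nested maps (`mu_sucrose`, `mu_yeast`,
#' `mortality_prob`) are converted to the internal representation.
#'
#' @param path Path to a YAML file.
#' @return A validated `"sim_config"` object.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    abort(paste0("unknown configuration field(s): ",
                 paste(bad, collapse = ", ")),
          class = "dietdimorph_config_error")
  }
  for (f in c("mu_sucrose", "mu_yeast")) {
    if (!is.null(raw[[f]])) raw[[f]] <- lapply(raw[[f]], unlist)
  }
  if (!is.null(raw$mortality_prob)) raw$mortality_prob <- unlist(raw$mortality_prob)
  if (!is.null(raw$recruitment_rate)) raw$recruitment_rate <- unlist(raw$recruitment_rate)
  do.call(sim_config, raw)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d populations/treatment x %d vials x %d flies, %d generations\n",
              x$n_populations_per_treatment, x$n_vials, x$flies_per_vial,
              x$n_generations))
  cat(sprintf("  assays: ancestor %d/sex, offspring %d/sex; %d control vials\n",
              x$ancestor_assay_n_per_sex, x$offspring_assay_n_per_sex,
              x$n_control_vials))
  for (trt in TREATMENT_LEVELS) {
    r <- x$mu_sucrose[[trt]] / x$mu_yeast[[trt]]
    cat(sprintf("  %-26s mean sucrose:yeast  M %.3f  F %.3f\n", trt,
                r[["M"]], r[["F"]]))
  }
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}
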