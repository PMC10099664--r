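#' Mean fitness per population and generation
#'
#' Mean absolute fitness measured as recruitment to the next generation per
#' female. Census rows without a recruit count (e.g. the ancestral baseline
#' row) are dropped.
#'
#' @param census Census table with columns `population`, `treatment`,
#'   `generation`, `n_females`, `n_recruits_next_generation`.
#' @return A tibble: `population`, `treatment`, `generation`,
#'   `mean_fitness` (recruits per female).
#' @export
mean_fitness <- function(census) {
  req_cols(census, c("population", "treatment", "generation", "n_females",
                     "n_recruits_next_generation"), "census")
  census <- dplyr::filter(census, !is.na(.data$n_recruits_next_generation))
  if (any(census$n_females <= 0)) {
    bad <- census$population[census$n_females <= 0]
    abort(paste0("population(s) with zero females (extinction): ",
                 paste(unique(bad), collapse = ", ")),
          class = "dietdimorph_input_error")
  }
  dplyr::transmute(census, .data$population, .data$treatment,
                   .data$generation,
                   mean_fitness = .data$n_recruits_next_generation /
                     .data$n_females)
}

#' Evolutionary rate in Haldanes
#'
#' Absolute phenotypic divergence in ancestral standard deviations per
#' generation: `|mean_evolved - mean_ancestor| / sd_ancestor /
#' n_generations`. Invariant to any common rescaling of the two means and
#' the SD (e.g. ul versus ug).
#'
#' @param mean_evolved,mean_ancestor Trait means (same units), vectorised.
#' @param sd_ancestor Ancestral phenotypic SD (same units), > 0.
#' @param n_generations Elapsed generations, >= 1.
#' @return Rate(s) in Haldanes (>= 0).
#' @examples
#' haldane_rate(1.2, 1.0, 0.5, 3)  # 0.1333...
#' @export
haldane_rate <- function(mean_evolved, mean_ancestor, sd_ancestor,
                         n_generations) {
  if (any(!is.finite(sd_ancestor)) || any(sd_ancestor <= 0)) {
    abort("`sd_ancestor` must be positive", class = "dietdimorph_input_error")
  }
  if (any(n_generations < 1)) {
    abort("`n_generations` must be >= 1", class = "dietdimorph_input_error")
  }
  abs(mean_evolved - mean_ancestor) / sd_ancestor / n_generations
}

#' Haldane rates for sucrose and yeast intake, per population and sex
#'
#' Computes, for each evolved population and sex, the evolutionary rate of
#' corrected sucrose and yeast intake relative to the ancestral assay. The
#' ancestral mean and SD are sex- and trait-specific (matching the
#' sex-specific rates being compared); divergence is scaled by the number of
#' generations of treatment exposure.
#'
#' @param data Corrected consumption table (see [correct_consumption()])
#'   containing the ancestor (treatment `"ancestor"`) and evolved offspring
#'   records, with `sucrose_ug` and `yeast_ug` columns.
#' @param n_generations Generations between the ancestral and evolved
#'   assays.
#' @return A tibble: `population`, `treatment`, `sex`, `trait`
#'   (`"sucrose"`/`"yeast"`), `rate` (Haldanes).
#' @export
haldane_rates <- function(data, n_generations = 3) {
  req_cols(data, c("population", "treatment", "sex", "sucrose_ug",
                   "yeast_ug"), "data")
  long <- tidyr::pivot_longer(
    dplyr::select(data, "population", "treatment", "sex",
                  sucrose = "sucrose_ug", yeast = "yeast_ug"),
    cols = c("sucrose", "yeast"), names_to = "trait", values_to = "mass")
  long <- dplyr::filter(long, is.finite(.data$mass))
  anc <- dplyr::filter(long, .data$treatment == "ancestor") %>%
    dplyr::group_by(.data$sex, .data$trait) %>%
    dplyr::summarise(anc_mean = mean(.data$mass), anc_sd = sd(.data$mass),
                     .groups = "drop")
  if (nrow(anc) == 0L) {
    abort("no ancestor records found (treatment == \"ancestor\")",
          class = "dietdimorph_input_error")
  }
  dplyr::filter(long, .data$treatment != "ancestor") %>%
    dplyr::group_by(.data$population, .data$treatment, .data$sex,
                    .data$trait) %>%
    dplyr::summarise(evolved_mean = mean(.data$mass), .groups = "drop") %>%
    dplyr::inner_join(anc, by = c("sex", "trait")) %>%
    dplyr::mutate(rate = haldane_rate(.data$evolved_mean, .data$anc_mean,
                                      .data$anc_sd, n_generations)) %>%
    dplyr::select("population", "treatment", "sex", "trait", "rate")
}

#' Binomial GLM for starvation survival by treatment
#'
#' Logistic regression of each population's survived/died counts during the
#' 48 h food-deprivation period on treatment (reference: the low-competition,
#' high-food regime, so a positive coefficient means better survival under
#' high competition). Fit by [stats::glm()] (IRLS); the treatment effect is
#' reported with its Wald Z and two-sided p. Under complete separation the
#' Wald test degenerates, so the fit is flagged and the p-value is replaced
#' by a likelihood-ratio test.
#'
#' @param census Census table with `population`, `treatment`, `n_assayed`,
#'   `n_survived_deprivation`; rows with missing counts are dropped.
#' @return A one-row tibble: `term`, `estimate` (log odds ratio),
#'   `std_error`, `statistic` (Z), `p_value`, `separation`, plus per-group
#'   survival proportions `prop_high`, `prop_low`.
#' @export
survival_glm <- function(census) {
  req_cols(census, c("population", "treatment", "n_assayed",
                     "n_survived_deprivation"), "census")
  d <- dplyr::filter(census, !is.na(.data$n_survived_deprivation),
                     !is.na(.data$n_assayed))
  d <- dplyr::filter(d, .data$treatment %in% EVOLVED_TREATMENTS)
  if (length(unique(d$treatment)) < 2L) {
    abort("survival GLM needs populations from both treatments",
          class = "dietdimorph_input_error")
  }
  if (any(d$n_survived_deprivation > d$n_assayed)) {
    abort("survivors exceed assayed flies", class = "dietdimorph_input_error")
  }
  d$died <- d$n_assayed - d$n_survived_deprivation
  d$treatment <- factor(d$treatment,
                        levels = c("low_competition_high_food",
                                   "high_competition_low_food"))
  fit <- glm(cbind(n_survived_deprivation, died) ~ treatment,
             family = binomial(), data = d,
             control = stats::glm.control(epsilon = 1e-12))
  sm <- summary(fit)$coefficients
  est <- sm[2, "Estimate"]
  se <- sm[2, "Std. Error"]
  separation <- abs(est) > 15 || se > 100
  p <- sm[2, "Pr(>|z|)"]
  if (separation) {
    lrt <- anova(glm(cbind(n_survived_deprivation, died) ~ 1,
                     family = binomial(), data = d),
                 fit, test = "LRT")
    p <- lrt$`Pr(>Chi)`[2]
  }
  props <- d %>%
    dplyr::group_by(.data$treatment) %>%
    dplyr::summarise(p = sum(.data$n_survived_deprivation) /
                       sum(.data$n_assayed))
  tibble(term = "treatment_high_competition", estimate = est,
         std_error = se, statistic = sm[2, "z value"], p_value = p,
         separation = separation,
         prop_high = props$p[props$treatment == "high_competition_low_food"],
         prop_low = props$p[props$treatment == "low_competition_high_food"])
}

#' Compare evolutionary rates between the sexes
#'
#' One-way fixed-effect comparison (OLS of rate on sex) of the per-population
#' Haldane rates, separately for each trait. With six populations and both
#' sexes this is an F test on (1, 10) degrees of freedom.
#'
#' @param rates Output of [haldane_rates()].
#' @return A tibble, one row per trait: `trait`, `statistic` (F), `df_num`,
#'   `df_den`, `p_value`, `n`.
#' @export
compare_rate_sexes <- function(rates) {
  req_cols(rates, c("sex", "trait", "rate"), "rates")
  purrr::map_dfr(sort(unique(rates$trait)), function(tr) {
    d <- dplyr::filter(rates, .data$trait == !!tr)
    if (min(table(factor(d$sex, levels = SEX_LEVELS))) < 2L) {
      abort(sprintf("trait %s needs at least two rates per sex", tr),
            class = "dietdimorph_input_error")
    }
    if (var(d$rate) == 0) {
      return(tibble(trait = tr, statistic = 0, df_num = 1L,
                    df_den = nrow(d) - 2L, p_value = 1, n = nrow(d)))
    }
    d$sex <- factor(d$sex, levels = c("F", "M"))
    av <- anova(lm(rate ~ sex, data = d))
    tibble(trait = tr, statistic = av$`F value`[1],
           df_num = av$Df[1], df_den = av$Df[2],
           p_value = av$`Pr(>F)`[1], n = nrow(d))
  })
}
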