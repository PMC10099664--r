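#' Per-population linear-model test of sexual dimorphism
#'
#' Ordinary least squares of the corrected sucrose:yeast ratio on a sex
#' indicator, fit separately within each population. The sex coefficient is
#' the male minus female difference in mean ratio; its t test gives the
#' per-population significance of dimorphism (equivalent to a two-sample
#' equal-variance t test).
#'
#' @param data Corrected consumption table with columns `population`, `sex`
#'   (`"M"`/`"F"`) and `ratio_corrected`. Rows with undefined ratios are
#'   dropped.
#' @return A tibble with one row per population: `population`, `delta`
#'   (male - female mean ratio), `se`, `statistic`, `p_lm`, `n_M`, `n_F`.
#' @export
dimorphism_lm <- function(data) {
  req_cols(data, c("population", "sex", "ratio_corrected"), "data")
  data <- dplyr::filter(data, is.finite(.data$ratio_corrected))
  data %>%
    dplyr::group_by(.data$population) %>%
    dplyr::group_modify(function(df, key) {
      counts <- table(factor(df$sex, levels = SEX_LEVELS))
      if (any(counts < 2L)) {
        abort(sprintf("population %s needs at least two flies of each sex (M = %d, F = %d)",
                      key$population, counts[["M"]], counts[["F"]]),
              class = "dietdimorph_input_error")
      }
      df$sex <- factor(df$sex, levels = c("F", "M"))
      fit <- lm(ratio_corrected ~ sex, data = df)
      sm <- summary(fit)$coefficients
      tibble(delta = sm["sexM", "Estimate"], se = sm["sexM", "Std. Error"],
             statistic = sm["sexM", "t value"], p_lm = sm["sexM", "Pr(>|t|)"],
             n_M = counts[["M"]], n_F = counts[["F"]])
    }) %>%
    dplyr::ungroup()
}

# Bootstrap draws of the stratum mean: resample the stratum's flies with
# replacement n_boot times. Returns a vector of n_boot means.
boot_mean_draws <- function(x, n_boot) {
  n <- length(x)
  idx <- sample.int(n, n * n_boot, replace = TRUE)
  rowMeans(matrix(x[idx], nrow = n_boot, ncol = n))
}

#' Bootstrap sampling distributions of per-sex mean ratios
#'
#' Resamples flies with replacement within each population x sex stratum.
#' The bootstrap variance of each stratum mean is the "known" sampling
#' variance later supplied to the measurement-error mixed model
#' ([fit_dimorphism_lmm()]).
#'
#' @inheritParams dimorphism_lm
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed.
#' @return A tibble with one row per population x sex: `population`,
#'   (`treatment` if present), `sex`, `n`, `mean_ratio`, `sampling_variance`,
#'   and a list-column `draws` of the `n_boot` bootstrap means.
#' @export
bootstrap_sex_means <- function(data, n_boot = 10000, seed = 1) {
  req_cols(data, c("population", "sex", "ratio_corrected"), "data")
  data <- dplyr::filter(data, is.finite(.data$ratio_corrected))
  strata <- dplyr::distinct(data, .data$population, .data$sex) %>%
    dplyr::arrange(.data$population, factor(.data$sex, levels = SEX_LEVELS))
  if (nrow(strata) == 0L) {
    abort("no finite ratio records to bootstrap", class = "dietdimorph_input_error")
  }
  set.seed(seed)
  out <- purrr::pmap_dfr(strata, function(population, sex) {
    x <- data$ratio_corrected[data$population == population & data$sex == sex]
    if (length(x) < 1L) {
      abort(sprintf("empty stratum: population %s sex %s", population, sex),
            class = "dietdimorph_input_error")
    }
    draws <- boot_mean_draws(x, n_boot)
    tibble(population = population, sex = sex, n = length(x),
           mean_ratio = mean(x), sampling_variance = var(draws),
           draws = list(draws))
  })
  if ("treatment" %in% names(data)) {
    out <- dplyr::left_join(
      out, dplyr::distinct(data, .data$population, .data$treatment),
      by = "population") %>%
      dplyr::relocate("treatment", .after = "population")
  }
  out
}

#' Stratified-bootstrap estimate of pooled sexual dimorphism
#'
#' Each bootstrap replicate resamples flies with replacement within every
#' population x sex stratum, computes the male minus female mean-ratio
#' difference per population, and averages those differences across
#' populations. With a single population this reduces to the per-population
#' bootstrap. The two-tailed p-value is read directly off the sampling
#' distribution as `2 * min(fraction <= 0, fraction >= 0)`, floored at
#' `2 / n_boot` (a resolution limit, not evidence of p = 0) and capped at 1.
#'
#' @inheritParams bootstrap_sex_means
#' @param scope Optional label for the set of populations being pooled
#'   (e.g. a treatment name); defaults to the populations pasted together.
#' @return A one-row tibble of class `"dimorph_boot"`: `scope`,
#'   `n_populations`, `delta` (observed pooled male - female difference),
#'   `se_boot`, `p_boot`, `n_boot`, and a list-column `draws` with the full
#'   sampling distribution.
#' @examples
#' expt <- simulate_experiment(sim_config(seed = 7))
#' cor <- correct_consumption(expt$consumption, expt$controls)
#' dimorphism_bootstrap(dplyr::filter(cor, treatment == "ancestor"),
#'                      n_boot = 500, seed = 1)
#' @export
dimorphism_bootstrap <- function(data, n_boot = 10000, seed = 1, scope = NULL) {
  req_cols(data, c("population", "sex", "ratio_corrected"), "data")
  data <- dplyr::filter(data, is.finite(.data$ratio_corrected))
  pops <- sort(unique(data$population))
  if (length(pops) < 1L) {
    abort("no populations with finite ratios", class = "dietdimorph_input_error")
  }
  set.seed(seed)
  per_pop <- purrr::map(pops, function(p) {
    xm <- data$ratio_corrected[data$population == p & data$sex == "M"]
    xf <- data$ratio_corrected[data$population == p & data$sex == "F"]
    if (length(xm) < 1L || length(xf) < 1L) {
      abort(sprintf("population %s lacks flies of one sex", p),
            class = "dietdimorph_input_error")
    }
    list(delta = mean(xm) - mean(xf),
         draws = boot_mean_draws(xm, n_boot) - boot_mean_draws(xf, n_boot))
  })
  delta <- mean(purrr::map_dbl(per_pop, "delta"))
  draws <- rowMeans(do.call(cbind, purrr::map(per_pop, "draws")))
  p_boot <- boot_two_tailed_p(draws)
  out <- tibble(
    scope = scope %||% paste(pops, collapse = "+"),
    n_populations = length(pops),
    delta = delta,
    se_boot = sd(draws),
    p_boot = p_boot,
    n_boot = n_boot,
    draws = list(draws)
  )
  class(out) <- c("dimorph_boot", class(out))
  out
}

# Two-tailed percentile p with floor 2/n and cap 1.
boot_two_tailed_p <- function(draws) {
  p <- 2 * min(mean(draws <= 0), mean(draws >= 0))
  min(1, max(p, 2 / length(draws)))
}

#' Full dimorphism summary: per population and pooled per treatment
#'
#' Combines the per-population linear-model tests ([dimorphism_lm()]) with
#' stratified-bootstrap estimates ([dimorphism_bootstrap()]) for every
#' population and every treatment group, mirroring the layout of a
#' sampling-distribution figure: one panel per population plus a pooled
#' panel per treatment.
#'
#' @inheritParams bootstrap_sex_means
#' @return A tibble of class `"dimorph_est"`, one row per scope, with
#'   columns `scope`, `scope_type` (`"population"` or `"treatment"`),
#'   `treatment`, `delta`, `se_boot`, `p_boot`, `p_lm` (population scopes
#'   only), `n_boot` and the `draws` list-column.
#' @export
dimorphism_estimates <- function(data, n_boot = 10000, seed = 1) {
  req_cols(data, c("population", "treatment", "sex", "ratio_corrected"), "data")
  lm_tab <- dimorphism_lm(data)
  pop_info <- dplyr::distinct(data, .data$population, .data$treatment) %>%
    dplyr::arrange(.data$population)
  pop_est <- purrr::pmap_dfr(pop_info, function(population, treatment) {
    bt <- dimorphism_bootstrap(
      dplyr::filter(data, .data$population == !!population),
      n_boot = n_boot, seed = seed, scope = population)
    bt$scope_type <- "population"
    bt$treatment <- treatment
    bt
  })
  trt_est <- purrr::map_dfr(unique(pop_info$treatment), function(trt) {
    bt <- dimorphism_bootstrap(
      dplyr::filter(data, .data$treatment == !!trt),
      n_boot = n_boot, seed = seed, scope = trt)
    bt$scope_type <- "treatment"
    bt$treatment <- trt
    bt
  })
  out <- dplyr::bind_rows(pop_est, trt_est) %>%
    dplyr::left_join(dplyr::select(lm_tab, scope = "population", "p_lm"),
                     by = "scope") %>%
    dplyr::relocate("scope", "scope_type", "treatment", "delta", "se_boot",
                    "p_boot", "p_lm", "n_boot")
  class(out) <- c("dimorph_est", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
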