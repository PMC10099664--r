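#' Run the full diet-dimorphism analysis pipeline
#'
#' Orchestrates every stage on either a simulated or an externally loaded
#' dataset: evaporation estimation and correction, per-population positivity
#' checks, per-population and pooled stratified-bootstrap dimorphism
#' estimates, the measurement-error mixed model for the treatment effect on
#' dimorphism, the Bayesian bivariate intake models with DIC selection,
#' the starvation-survival GLM, mean-fitness trajectories, and Haldane
#' evolutionary rates with the between-sex comparison.
#'
#' @param config A [sim_config()]; supplies the seed and (when `data` is
#'   `NULL`) the synthetic experiment.
#' @param data `NULL` to simulate from `config`, or a list with elements
#'   `consumption`, `controls`, `census` (e.g. from
#'   [read_consumption_table()] and friends).
#' @param n_boot Bootstrap replicates for dimorphism estimates and the
#'   mixed-model sampling variances.
#' @param mcmc List of MCMC settings for [fit_bivariate_mm()] (`n_iter`,
#'   `burnin`, `thin`, `chains`).
#' @param specs Bivariate model specs to fit and compare.
#' @param out_dir If non-`NULL`, results are written there via
#'   [write_results_tables()].
#' @param quiet Suppress stage messages.
#' @return An object of class `"dimorph_analysis"`: a list with
#'   `evaporation`, `corrected` (per-fly table), `positivity`,
#'   `dimorphism` (a `"dimorph_est"` table), `means`, `mixed_model`
#'   (`"dimorph_lmm"`), `bivariate_fits`, `dic_table`, `best_spec`,
#'   `delta_dic`, `bivariate_summary`, `survival`, `fitness`, `rates`,
#'   `rate_summary`, `rate_sex_comparison`, `counts`, `seed`.
#' @examples
#' \donttest{
#' res <- run_full_analysis(sim_config(seed = 1), n_boot = 200,
#'                          mcmc = list(n_iter = 600, burnin = 100,
#'                                      thin = 1, chains = 1))
#' res$dimorphism
#' }
#' @export
run_full_analysis <- function(config = sim_config(), data = NULL,
                              n_boot = 10000,
                              mcmc = list(n_iter = 13000, burnin = 3000,
                                          thin = 10, chains = 2),
                              specs = bivariate_model_specs(),
                              out_dir = NULL, quiet = TRUE) {
  config <- validate_sim_config(config)
  seed <- config$seed
  say <- function(...) if (!quiet) message(sprintf(...))

  if (is.null(data)) {
    say("simulating experiment (seed %d)", seed)
    data <- simulate_experiment(config)
  }
  for (el in c("consumption", "controls", "census")) {
    if (is.null(data[[el]])) {
      abort(sprintf("stage input: `data` lacks element `%s`", el),
            class = "dietdimorph_input_error")
    }
  }
  missing_pops <- setdiff(unique(data$consumption$population),
                          unique(data$census$population))
  if (length(missing_pops)) {
    abort(paste0("consumption records reference populations absent from census: ",
                 paste(missing_pops, collapse = ", ")),
          class = "dietdimorph_input_error")
  }

  say("stage: evaporation correction")
  evap <- estimate_evaporation(data$controls)
  corrected <- correct_consumption(data$consumption, evap)
  n_in <- nrow(corrected)
  n_excluded <- sum(!is.finite(corrected$ratio_corrected))
  counts <- list(flies_in = n_in,
                 ratio_analyzed = n_in - n_excluded,
                 ratio_excluded = n_excluded)

  say("stage: positivity checks")
  positivity <- corrected %>%
    tidyr::pivot_longer(cols = c("sucrose_ul", "yeast_ul"),
                        names_to = "fluid", values_to = "value") %>%
    dplyr::group_by(.data$population, .data$fluid) %>%
    dplyr::group_modify(~ test_positive_consumption(.x$value)) %>%
    dplyr::ungroup()

  say("stage: dimorphism bootstrap (%d replicates)", n_boot)
  dimorphism <- dimorphism_estimates(corrected, n_boot = n_boot,
                                     seed = seed + 10L)

  say("stage: measurement-error mixed model")
  evolved <- dplyr::filter(corrected, .data$treatment != "ancestor")
  means <- bootstrap_sex_means(evolved, n_boot = n_boot, seed = seed + 11L)
  mixed_model <- fit_dimorphism_lmm(means)

  say("stage: bivariate mixed models (%d specs)", length(specs))
  bivariate_fits <- lapply(specs, function(sp) {
    fit_bivariate_mm(evolved, spec = sp, n_iter = mcmc$n_iter,
                     burnin = mcmc$burnin, thin = mcmc$thin,
                     chains = mcmc$chains, seed = seed + 12L)
  })
  names(bivariate_fits) <- specs
  sel <- select_bivariate_model(bivariate_fits)

  say("stage: adaptation metrics")
  surv <- survival_glm(data$census)
  fitness <- mean_fitness(data$census)
  rates <- haldane_rates(corrected, n_generations = config$n_generations)
  rate_summary <- dplyr::bind_rows(
    rates %>% dplyr::group_by(.data$trait) %>%
      dplyr::summarise(mean_rate = mean(.data$rate), .groups = "drop") %>%
      dplyr::mutate(scope = "all", .before = 1),
    rates %>% dplyr::group_by(.data$trait, scope = .data$treatment) %>%
      dplyr::summarise(mean_rate = mean(.data$rate), .groups = "drop")
  )
  rate_cmp <- compare_rate_sexes(rates)

  out <- structure(list(
    evaporation = evap,
    corrected = corrected,
    positivity = positivity,
    dimorphism = dimorphism,
    means = means,
    mixed_model = mixed_model,
    bivariate_fits = bivariate_fits,
    dic_table = sel$table,
    best_spec = sel$best,
    delta_dic = sel$delta_dic,
    bivariate_summary = tidy(bivariate_fits[[sel$best]]),
    survival = surv,
    fitness = fitness,
    rates = rates,
    rate_summary = rate_summary,
    rate_sex_comparison = rate_cmp,
    counts = counts,
    seed = seed,
    config = config
  ), class = "dimorph_analysis")

  if (!is.null(out_dir)) {
    say("stage: writing results to %s", out_dir)
    out$manifest <- write_results_tables(result_tables(out), out_dir,
                                         seed = seed, config = config,
                                         counts = counts)
  }
  out
}

#' Collect the flat result tables of an analysis
#'
#' @param x A `"dimorph_analysis"` object.
#' @return Named list of tibbles suitable for [write_results_tables()].
#' @export
result_tables <- function(x) {
  stopifnot(inherits(x, "dimorph_analysis"))
  list(
    evaporation = x$evaporation,
    positivity = x$positivity,
    dimorphism = dplyr::select(as_tibble(x$dimorphism), -"draws"),
    means = dplyr::select(as_tibble(x$means), -"draws"),
    mixed_model_fixef = tidy(x$mixed_model),
    mixed_model_tests = x$mixed_model$f_tests,
    dic_table = x$dic_table,
    bivariate_summary = x$bivariate_summary,
    survival = x$survival,
    fitness = x$fitness,
    rates = x$rates,
    rate_summary = x$rate_summary,
    rate_sex_comparison = x$rate_sex_comparison
  )
}

#' @export
print.dimorph_analysis <- function(x, ...) {
  cat("Diet-dimorphism analysis\n")
  cat(sprintf("  %d flies in, %d analysed on the ratio scale (%d excluded)\n",
              x$counts$flies_in, x$counts$ratio_analyzed,
              x$counts$ratio_excluded))
  pooled <- dplyr::filter(as_tibble(x$dimorphism),
                          .data$scope_type == "treatment")
  for (i in seq_len(nrow(pooled))) {
    cat(sprintf("  %-26s delta = %+.3f (SE %.3f, p = %.2g)\n",
                pooled$scope[i], pooled$delta[i], pooled$se_boot[i],
                pooled$p_boot[i]))
  }
  it <- dplyr::filter(x$mixed_model$f_tests, .data$effect == "sex:treatment")
  cat(sprintf("  sex x treatment: F_%d,%d = %.1f, p = %.2g\n",
              it$df_num, it$df_den, it$statistic, it$p_value))
  cat(sprintf("  best bivariate spec: %s (delta-DIC %.2f)\n", x$best_spec,
              x$delta_dic))
  cat(sprintf("  survival Z = %.2f; mean rates: sucrose %.3f, yeast %.3f Haldanes\n",
              x$survival$statistic,
              x$rate_summary$mean_rate[x$rate_summary$scope == "all" &
                                         x$rate_summary$trait == "sucrose"],
              x$rate_summary$mean_rate[x$rate_summary$scope == "all" &
                                         x$rate_summary$trait == "yeast"]))
  invisible(x)
}
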