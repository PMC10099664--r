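#' Candidate fixed-effect structures for the bivariate intake model
#'
#' Five nested fixed-effect structures for the bivariate (sucrose mass,
#' yeast mass) mixed model, from trait-specific intercepts only up to
#' trait-by-sex or trait-by-treatment interactions. All share the same
#' random structure: a trait-specific population intercept (independent
#' variances per trait) and an unstructured 2x2 residual covariance.
#'
#' @return Character vector of spec names accepted by
#'   [fit_bivariate_mm()]: `intercepts_only`, `plus_treatment`, `plus_sex`,
#'   `treatment_x_trait_plus_sex`, `sex_x_trait_plus_treatment`.
#' @export
bivariate_model_specs <- function() {
  c("intercepts_only", "plus_treatment", "plus_sex",
    "treatment_x_trait_plus_sex", "sex_x_trait_plus_treatment")
}

# Stacked design matrices (one row set per trait) for a given spec.
# Reference levels: female sex, low-competition/high-food treatment, sucrose
# trait; so `traitY:sexM` is the male shift in yeast relative to his shift
# in sucrose, and `trtHigh` the common consumption shift under high
# competition.
build_bivariate_design <- function(data, spec) {
  spec <- match.arg(spec, bivariate_model_specs())
  n <- nrow(data)
  one <- rep(1, n)
  zero <- rep(0, n)
  sexm <- as.numeric(data$sex == "M")
  trt <- as.numeric(data$treatment == "high_competition_low_food")
  cols <- switch(spec,
    intercepts_only = list(),
    plus_treatment = list(trtHigh = list(trt, trt)),
    plus_sex = list(sexM = list(sexm, sexm)),
    treatment_x_trait_plus_sex = list(trtHigh = list(trt, trt),
                                      `traitY:trtHigh` = list(zero, trt),
                                      sexM = list(sexm, sexm)),
    sex_x_trait_plus_treatment = list(sexM = list(sexm, sexm),
                                      `traitY:sexM` = list(zero, sexm),
                                      trtHigh = list(trt, trt))
  )
  base <- list(`(Intercept)` = list(one, one), traitY = list(zero, one))
  cols <- c(base, cols)
  list(
    Xs = do.call(cbind, lapply(cols, `[[`, 1L)),
    Xy = do.call(cbind, lapply(cols, `[[`, 2L)),
    coef_names = names(cols)
  )
}

#' Fit the Bayesian bivariate intake mixed model by Gibbs sampling
#'
#' Multiresponse linear mixed model for per-fly corrected sucrose and yeast
#' intake (ug), with one of the fixed-effect structures of
#' [bivariate_model_specs()], a trait-specific random intercept among
#' populations, and an unstructured residual covariance. All full
#' conditionals are conjugate and the sampler is a plain Gibbs scheme:
#' multivariate-normal updates for fixed and random effects, inverse-gamma
#' for the two random-intercept variances, inverse-Wishart for the residual
#' covariance.
#'
#' Default priors are weakly informative: fixed effects N(0, 1e10);
#' (co)variances inverse-Wishart/inverse-gamma with unit scale and 0.002
#' degrees of belief. The default chain length is 13,000 iterations with
#' 3,000 burn-in and thinning 10; two chains are run so a potential
#' scale-reduction diagnostic can be computed (a warning is raised when any
#' fixed effect has R-hat > 1.1). DIC is computed from the deviance of the
#' bivariate normal likelihood conditional on the random effects:
#' `DIC = Dbar + pD`, `pD = Dbar - D(posterior means)`.
#'
#' @param data Corrected consumption table for the evolved populations, with
#'   columns `population`, `treatment`, `sex`, `sucrose_ug`, `yeast_ug`.
#' @param spec One of [bivariate_model_specs()].
#' @param n_iter,burnin,thin MCMC schedule per chain.
#' @param chains Number of chains (seeds `seed`, `seed + 1`, ...).
#' @param seed Integer seed.
#' @param beta_prior_var Prior variance of each fixed effect (ug^2).
#' @param nu_r,V_r Inverse-Wishart prior degrees of freedom and 2x2 scale for
#'   the residual covariance.
#' @param nu_g,V_g Prior degrees of freedom and scale for each
#'   random-intercept variance.
#' @return An object of class `"bivariate_mm"`: draws (`beta`, `sigma_pop`,
#'   `rcov`, `u_sucrose`, `u_yeast`, `deviance`, pooled across chains),
#'   `dic`, `pD`, `rhat`, `spec`, `coef_names`, and the data used. Methods:
#'   [tidy()], [glance()], [autoplot.bivariate_mm()].
#' @examples
#' expt <- simulate_experiment(sim_config(seed = 5))
#' cor <- correct_consumption(
#'   dplyr::filter(expt$consumption, treatment != "ancestor"),
#'   expt$controls)
#' fit <- fit_bivariate_mm(cor, "sex_x_trait_plus_treatment",
#'                         n_iter = 600, burnin = 100, thin = 1, chains = 1)
#' tidy(fit)
#' @export
fit_bivariate_mm <- function(data, spec = "sex_x_trait_plus_treatment",
                             n_iter = 13000, burnin = 3000, thin = 10,
                             chains = 2, seed = 1,
                             beta_prior_var = 1e10,
                             nu_r = 0.002, V_r = diag(2),
                             nu_g = 0.002, V_g = 1) {
  req_cols(data, c("population", "treatment", "sex", "sucrose_ug",
                   "yeast_ug"), "data")
  spec <- match.arg(spec, bivariate_model_specs())
  data <- dplyr::filter(data, is.finite(.data$sucrose_ug),
                        is.finite(.data$yeast_ug))
  bad_trt <- setdiff(unique(data$treatment), EVOLVED_TREATMENTS)
  if (length(bad_trt)) {
    abort(paste0("bivariate model expects evolved treatments only; found: ",
                 paste(bad_trt, collapse = ", ")),
          class = "dietdimorph_input_error")
  }
  if (n_iter <= burnin) {
    abort("`n_iter` must exceed `burnin`", class = "dietdimorph_input_error")
  }
  pop_f <- factor(data$population)
  des <- build_bivariate_design(data, spec)

  run_chain <- function(chain_seed) {
    set.seed(chain_seed)
    gibbs_bivariate_cpp(data$sucrose_ug, data$yeast_ug, des$Xs, des$Xy,
                        as.integer(pop_f) - 1L, nlevels(pop_f),
                        as.integer(n_iter), as.integer(burnin),
                        as.integer(thin), beta_prior_var, nu_r, V_r,
                        nu_g, V_g)
  }
  runs <- lapply(seq_len(chains), function(ch) run_chain(seed + ch - 1L))

  pool <- function(name) do.call(rbind, lapply(runs, `[[`, name))
  draws <- list(beta = pool("beta"), sigma_pop = pool("sigma_pop"),
                rcov = pool("rcov"), u_sucrose = pool("u_sucrose"),
                u_yeast = pool("u_yeast"),
                deviance = unlist(lapply(runs, `[[`, "deviance")))
  colnames(draws$beta) <- des$coef_names
  colnames(draws$rcov) <- c("sucrose", "yeast", "covariance")
  colnames(draws$sigma_pop) <- c("sucrose", "yeast")

  rhat <- if (chains >= 2L) {
    vapply(seq_along(des$coef_names), function(j) {
      gelman_rhat(lapply(runs, function(r) r$beta[, j]))
    }, numeric(1))
  } else {
    rep(NA_real_, length(des$coef_names))
  }
  names(rhat) <- des$coef_names
  if (any(!is.na(rhat) & rhat > 1.1)) {
    warn(paste0("possible non-convergence: R-hat > 1.1 for ",
                paste(des$coef_names[!is.na(rhat) & rhat > 1.1],
                      collapse = ", ")))
  }

  fit <- structure(list(
    spec = spec, coef_names = des$coef_names, draws = draws,
    n_iter = n_iter, burnin = burnin, thin = thin, chains = chains,
    rhat = rhat, n_obs = nrow(data), n_populations = nlevels(pop_f),
    data = list(sucrose = data$sucrose_ug, yeast = data$yeast_ug,
                Xs = des$Xs, Xy = des$Xy, pop = as.integer(pop_f))
  ), class = "bivariate_mm")
  dic <- compute_dic(fit)
  fit$dic <- dic$dic
  fit$pD <- dic$pD
  fit
}

# Gelman-Rubin potential scale reduction for a list of chains.
gelman_rhat <- function(chain_list) {
  m <- length(chain_list)
  n <- length(chain_list[[1]])
  means <- vapply(chain_list, mean, numeric(1))
  vars <- vapply(chain_list, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Deviance information criterion for a fitted bivariate model
#'
#' `DIC = Dbar + pD` with `pD = Dbar - D(theta_bar)`, where the deviance is
#' minus twice the bivariate-normal log-likelihood conditional on the random
#' effects, `Dbar` its posterior mean, and `theta_bar` the posterior means of
#' the fixed effects, random intercepts and residual covariance.
#'
#' @param fit A `"bivariate_mm"` object.
#' @return A one-row tibble: `dic`, `pD`, `Dbar`, `Dhat`.
#' @export
compute_dic <- function(fit) {
  stopifnot(inherits(fit, "bivariate_mm"))
  d <- fit$draws
  Dbar <- mean(d$deviance)
  beta_bar <- colMeans(d$beta)
  us_bar <- colMeans(d$u_sucrose)
  uy_bar <- colMeans(d$u_yeast)
  R_bar <- matrix(c(mean(d$rcov[, 1]), mean(d$rcov[, 3]),
                    mean(d$rcov[, 3]), mean(d$rcov[, 2])), 2, 2)
  dat <- fit$data
  es <- dat$sucrose - drop(dat$Xs %*% beta_bar) - us_bar[dat$pop]
  ey <- dat$yeast - drop(dat$Xy %*% beta_bar) - uy_bar[dat$pop]
  W <- solve(R_bar)
  quad <- W[1, 1] * sum(es^2) + 2 * W[1, 2] * sum(es * ey) +
    W[2, 2] * sum(ey^2)
  Dhat <- length(es) * (2 * log(2 * pi) + determinant(R_bar)$modulus[1]) + quad
  pD <- Dbar - Dhat
  tibble(dic = Dbar + pD, pD = pD, Dbar = Dbar, Dhat = Dhat)
}

#' Posterior two-tailed tail probability (pMCMC)
#'
#' `2 * min(fraction of draws > 0, fraction < 0)`, floored at `2 / n_draws`
#' and capped at 1.
#'
#' @param draws Numeric vector of posterior draws for one effect (>= 100).
#' @return A single probability.
#' @examples
#' pmcmc(rnorm(1000, 1))
#' @export
pmcmc <- function(draws) {
  if (length(draws) < 100L) {
    abort("pMCMC needs at least 100 draws", class = "dietdimorph_input_error")
  }
  p <- 2 * min(mean(draws > 0), mean(draws < 0))
  min(1, max(p, 2 / length(draws)))
}

#' Rank candidate bivariate models by DIC
#'
#' @param fits A named list of `"bivariate_mm"` objects (typically one per
#'   spec in [bivariate_model_specs()]).
#' @return A list: `table` (tibble sorted by DIC with `spec`, `dic`, `pD`,
#'   `n_params`), `best` (spec name), `delta_dic` (runner-up DIC minus best;
#'   `NA` with a single candidate). Ties are broken toward the spec with
#'   fewer fixed-effect parameters.
#' @export
select_bivariate_model <- function(fits) {
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, logical(1),
                                           "bivariate_mm")))
  tab <- purrr::map_dfr(fits, function(f) {
    tibble(spec = f$spec, dic = f$dic, pD = f$pD,
           n_params = length(f$coef_names))
  })
  tab <- dplyr::arrange(tab, .data$dic, .data$n_params)
  delta <- if (nrow(tab) >= 2L) tab$dic[2] - tab$dic[1] else NA_real_
  list(table = tab, best = tab$spec[1], delta_dic = delta)
}

#' @export
print.bivariate_mm <- function(x, ...) {
  cat(sprintf("Bivariate intake mixed model [%s]\n", x$spec))
  cat(sprintf("  %d flies, %d populations; %d draws (%d chain%s)\n",
              x$n_obs, x$n_populations, length(x$draws$deviance),
              x$chains, if (x$chains > 1) "s" else ""))
  cat(sprintf("  DIC %.1f (pD %.1f)\n", x$dic, x$pD))
  print(as.data.frame(tidy(x)), row.names = FALSE, digits = 3)
  invisible(x)
}

#' @rdname fit_bivariate_mm
#' @param x A `"bivariate_mm"` object.
#' @param ... Unused.
#' @export
tidy.bivariate_mm <- function(x, ...) {
  b <- x$draws$beta
  purrr::map_dfr(colnames(b), function(nm) {
    v <- b[, nm]
    tibble(term = nm, estimate = mean(v), std_error = sd(v),
           conf_low = unname(quantile(v, 0.025)),
           conf_high = unname(quantile(v, 0.975)),
           p_mcmc = pmcmc(v))
  })
}

#' @rdname fit_bivariate_mm
#' @export
glance.bivariate_mm <- function(x, ...) {
  tibble(spec = x$spec, dic = x$dic, pD = x$pD,
         n_draws = length(x$draws$deviance), chains = x$chains,
         max_rhat = if (all(is.na(x$rhat))) NA_real_ else max(x$rhat,
                                                              na.rm = TRUE),
         n_obs = x$n_obs, n_populations = x$n_populations)
}
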