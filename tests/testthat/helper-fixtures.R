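# Shared fixture builders. Everything is generated in code; no files.

# An evaporation estimate row without running estimate_evaporation().
evap_row <- function(s, y, n = 1L) {
  tibble::tibble(sucrose_evap = s, yeast_evap = y, n_controls = n)
}

# Small, fast configuration used where the experiment's size is irrelevant.
fast_cfg <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(ancestor_assay_n_per_sex = 20, offspring_assay_n_per_sex = 15,
         n_control_vials = 10, seed = seed),
    list(...))
  do.call(sim_config, args)
}

# A configuration with no sexual dimorphism anywhere and no deprivation
# mortality: the null world for calibration runs.
null_dimorphism_cfg <- function(seed, n_per_sex = 40) {
  flat_s <- list(ancestor = c(M = 3, F = 3),
                 high_competition_low_food = c(M = 3, F = 3),
                 low_competition_high_food = c(M = 3, F = 3))
  flat_y <- list(ancestor = c(M = 2, F = 2),
                 high_competition_low_food = c(M = 2, F = 2),
                 low_competition_high_food = c(M = 2, F = 2))
  sim_config(offspring_assay_n_per_sex = n_per_sex,
             mu_sucrose = flat_s, mu_yeast = flat_y,
             mortality_prob = c(high_competition_low_food = 0,
                                low_competition_high_food = 0),
             seed = seed)
}

# A configuration whose high-competition populations carry a known
# male-female mean-ratio difference `delta`; everything else is null.
dimorphism_effect_cfg <- function(seed, delta = 0.35, n_per_sex = 40) {
  mu_s <- list(ancestor = c(M = 3, F = 3),
               high_competition_low_food = c(M = 3 + 2 * delta, F = 3),
               low_competition_high_food = c(M = 3, F = 3))
  mu_y <- list(ancestor = c(M = 2, F = 2),
               high_competition_low_food = c(M = 2, F = 2),
               low_competition_high_food = c(M = 2, F = 2))
  sim_config(offspring_assay_n_per_sex = n_per_sex,
             mu_sucrose = mu_s, mu_yeast = mu_y,
             mortality_prob = c(high_competition_low_food = 0,
                                low_competition_high_food = 0),
             seed = seed)
}

# Population x sex mean ratios simulated from the measurement-error model
# itself (known fixed effects, population SD, observation variances).
sim_lmm_means <- function(seed, beta = c(intercept = 1.45, sexM = 0.11,
                                         trtHigh = 0, interaction = 0.25),
                          sd_pop = 0.05, v_range = c(0.008, 0.014)) {
  set.seed(seed)
  d <- tidyr::expand_grid(
    population = paste0(rep(c("HC", "LC"), each = 3), 1:3),
    sex = c("F", "M"))
  d$treatment <- ifelse(grepl("^HC", d$population),
                        "high_competition_low_food",
                        "low_competition_high_food")
  b_pop <- stats::rnorm(6, 0, sd_pop)
  names(b_pop) <- unique(d$population)
  v <- stats::runif(nrow(d), v_range[1], v_range[2])
  hi <- d$treatment == "high_competition_low_food"
  mu <- beta[["intercept"]] + beta[["sexM"]] * (d$sex == "M") +
    beta[["trtHigh"]] * hi +
    beta[["interaction"]] * (d$sex == "M") * hi
  d$mean_ratio <- mu + b_pop[d$population] + stats::rnorm(nrow(d), 0, sqrt(v))
  d$sampling_variance <- v
  d
}

# Per-fly bivariate masses simulated directly from the bivariate mixed
# model: trait-specific population intercepts, unstructured residual
# covariance, and a sex-by-trait effect of `trait_sex` ug.
sim_biv_data <- function(seed, n_per_pop = 73, trait_sex = -48,
                         treatment_effect = 25.9, sd_pop = 10,
                         sd_s = 162, sd_y = 49.5, corr = 0.45) {
  set.seed(seed)
  pops <- paste0(rep(c("HC", "LC"), each = 3), 1:3)
  Rr <- matrix(c(sd_s^2, corr * sd_s * sd_y, corr * sd_s * sd_y, sd_y^2), 2)
  L <- chol(Rr)
  purrr::map_dfr(pops, function(p) {
    trt <- ifelse(grepl("^HC", p), "high_competition_low_food",
                  "low_competition_high_food")
    u <- stats::rnorm(2, 0, sd_pop)
    sex <- rep(c("M", "F"), length.out = n_per_pop)
    hi <- trt == "high_competition_low_food"
    sex_s <- 10
    mu_s <- 280 + sex_s * (sex == "M") + treatment_effect * hi + u[1]
    mu_y <- 190 + (sex_s + trait_sex) * (sex == "M") + treatment_effect * hi +
      u[2]
    e <- matrix(stats::rnorm(2 * n_per_pop), ncol = 2) %*% L
    tibble::tibble(population = p, treatment = trt, sex = sex,
                   sucrose_ug = mu_s + e[, 1], yeast_ug = mu_y + e[, 2])
  })
}

# Independent reference Gibbs sampler for the bivariate regression without
# random effects (flat fixed-effect prior limit of the single-population
# model): builds the stacked 2n system with dense kronecker algebra and
# draws the residual covariance with stats::rWishart. Shares no code with
# the package's sampler.
ref_mvreg_gibbs <- function(ys, yy, Xs, Xy, n_iter = 3000, burnin = 500,
                            beta_prior_var = 1e10, nu_r = 0.002,
                            V_r = diag(2)) {
  n <- length(ys)
  k <- ncol(Xs)
  y2 <- as.vector(rbind(ys, yy))               # interleaved (s1, y1, s2, ...)
  X2 <- matrix(0, 2 * n, k)
  X2[seq(1, 2 * n, 2), ] <- Xs
  X2[seq(2, 2 * n, 2), ] <- Xy
  beta <- rep(0, k)
  Rr <- diag(c(stats::var(ys), stats::var(yy)))
  keep <- matrix(NA_real_, n_iter - burnin, k)
  for (it in seq_len(n_iter)) {
    W <- kronecker(diag(n), solve(Rr))
    A <- t(X2) %*% W %*% X2 + diag(1 / beta_prior_var, k)
    b <- t(X2) %*% W %*% y2
    Ainv <- solve(A)
    beta <- drop(Ainv %*% b) +
      drop(t(chol(Ainv)) %*% stats::rnorm(k))
    E <- cbind(ys - Xs %*% beta, yy - Xy %*% beta)
    S <- nu_r * V_r + t(E) %*% E
    Wdraw <- stats::rWishart(1, nu_r + n, solve(S))[, , 1]
    Rr <- solve(Wdraw)
    if (it > burnin) keep[it - burnin, ] <- beta
  }
  keep
}
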