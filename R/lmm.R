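#' Measurement-error linear mixed model for treatment effects on dimorphism
#'
#' Fits a linear mixed model to the population x sex mean sucrose:yeast
#' ratios, with sex, treatment and their interaction as fixed effects, a
#' population random intercept, and each observation's bootstrap sampling
#' variance supplied as a known error variance (the meta-analytic
#' construction: population means, not flies, are the unit of replication).
#'
#' The marginal covariance is `V = diag(sampling_variance) + s2 * Z Z'` with
#' `Z` the population incidence matrix. The single free variance component
#' `s2` is estimated by restricted maximum likelihood, profiled to a bounded
#' one-dimensional search on the log-variance scale (tolerance 1e-10); the
#' fixed effects are the generalized-least-squares solution at the optimum.
#' A boundary solution is clamped to `s2 = 0` and flagged. Fixed effects are
#' tested with Wald F statistics using containment denominator degrees of
#' freedom: treatment (a between-population contrast) uses
#' `n_populations - n_treatments`; sex and sex:treatment (within-population
#' contrasts) use `n_obs - n_populations - n_within_parameters`. In the
#' balanced two-treatment, six-population design both rules give 4.
#'
#' @param means Output of [bootstrap_sex_means()]: one row per population x
#'   sex with `population`, `treatment`, `sex`, `mean_ratio`,
#'   `sampling_variance`. Ancestor rows (treatment `"ancestor"`) are dropped
#'   unless `include_ancestor = TRUE`: with a single ancestral population the
#'   printed between-treatment degrees of freedom imply the evolved
#'   populations only.
#' @param sigma2_pop If `NULL` (default) the population variance is
#'   estimated by REML; a non-negative number fixes it (giving the pure GLS
#'   fit, used for closed-form checks).
#' @param include_ancestor Keep ancestor rows in the fit.
#' @return An object of class `"dimorph_lmm"` with components `fixef`
#'   (tibble: term, estimate, se), `sigma2_pop`, `f_tests` (tibble: effect,
#'   statistic, df_num, df_den, p_value), `converged`, `boundary`,
#'   `vcov_fixef`, `reml_loglik`, `means`. Methods: [tidy()], [glance()].
#' @examples
#' expt <- simulate_experiment(sim_config(seed = 3))
#' cor <- correct_consumption(expt$consumption, expt$controls)
#' mt <- bootstrap_sex_means(dplyr::filter(cor, treatment != "ancestor"),
#'                           n_boot = 500, seed = 1)
#' fit <- fit_dimorphism_lmm(mt)
#' tidy(fit)
#' @export
fit_dimorphism_lmm <- function(means, sigma2_pop = NULL,
                               include_ancestor = FALSE) {
  req_cols(means, c("population", "treatment", "sex", "mean_ratio",
                    "sampling_variance"), "means")
  if (!include_ancestor) {
    means <- dplyr::filter(means, .data$treatment != "ancestor")
  }
  means <- dplyr::arrange(means, .data$population,
                          factor(.data$sex, levels = SEX_LEVELS))
  if (any(means$sampling_variance < 0)) {
    abort("sampling variances must be non-negative",
          class = "dietdimorph_input_error")
  }
  dup <- duplicated(means[c("population", "sex")])
  if (any(dup)) {
    abort("`means` must have exactly one row per population x sex",
          class = "dietdimorph_input_error")
  }
  trts <- sort(unique(means$treatment))
  if (length(trts) < 2L) {
    abort("need at least two treatments to estimate a treatment effect",
          class = "dietdimorph_input_error")
  }

  means$sex <- factor(means$sex, levels = c("F", "M"))
  # reference: low-competition regime, so treatment terms read as the
  # high-competition shift
  if ("low_competition_high_food" %in% trts) {
    trts <- c("low_competition_high_food",
              setdiff(trts, "low_competition_high_food"))
  }
  means$treatment <- factor(means$treatment, levels = trts)
  y <- means$mean_ratio
  v <- means$sampling_variance
  X <- stats::model.matrix(~ sex * treatment, data = means)
  pop <- factor(means$population)
  Z <- stats::model.matrix(~ pop - 1)
  ZZt <- tcrossprod(Z)
  n <- length(y)
  q <- nlevels(pop)

  # -2 * restricted log-likelihood (up to a constant) at population
  # variance s2; also returns the GLS pieces.
  gls_at <- function(s2) {
    V <- diag(v, n) + s2 * ZZt
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vi <- chol2inv(ch)
    XtVi <- crossprod(X, Vi)
    XtViX <- XtVi %*% X
    beta <- solve(XtViX, XtVi %*% y)
    r <- y - X %*% beta
    nll2 <- 2 * sum(log(diag(ch))) + determinant(XtViX)$modulus[1] +
      drop(crossprod(r, Vi %*% r))
    list(nll2 = nll2, beta = drop(beta), C = solve(XtViX), s2 = s2)
  }

  boundary <- FALSE
  if (is.null(sigma2_pop)) {
    f <- function(ls2) gls_at(exp(ls2))$nll2
    upper <- log(100 * (var(y) + mean(v)) + 1e-8)
    opt <- optimize(f, interval = c(log(1e-12), upper), tol = 1e-10)
    s2_hat <- exp(opt$minimum)
    # compare against the s2 = 0 boundary
    at0 <- gls_at(0)
    if (!is.null(at0) && at0$nll2 <= opt$objective + 1e-8) {
      s2_hat <- 0
      boundary <- TRUE
    }
    if (s2_hat < 1e-10) {
      s2_hat <- max(s2_hat, 0)
      boundary <- boundary || s2_hat == 0
    }
  } else {
    if (sigma2_pop < 0) {
      warn("negative `sigma2_pop` clamped to 0")
      sigma2_pop <- 0
      boundary <- TRUE
    }
    s2_hat <- sigma2_pop
  }
  fit <- gls_at(s2_hat)
  if (is.null(fit)) {
    abort("mixed-model covariance matrix is not positive definite",
          class = "dietdimorph_fit_error")
  }

  terms_ <- attr(X, "assign")          # 0 = intercept, 1 = sex, 2 = trt, 3 = int
  labels_ <- c("sex", "treatment", "sex:treatment")
  n_within <- sum(terms_ %in% c(1L, 3L))
  df_between <- q - length(trts)
  df_within <- n - q - n_within
  f_tests <- purrr::map_dfr(1:3, function(a) {
    idx <- which(terms_ == a)
    Lb <- fit$beta[idx]
    Cs <- fit$C[idx, idx, drop = FALSE]
    Fstat <- drop(crossprod(Lb, solve(Cs, Lb))) / length(idx)
    df_den <- if (a == 2L) df_between else df_within
    tibble(effect = labels_[a], statistic = Fstat,
           df_num = length(idx), df_den = df_den,
           p_value = pf(Fstat, length(idx), df_den, lower.tail = FALSE))
  })

  structure(list(
    fixef = tibble(term = colnames(X), estimate = unname(fit$beta),
                   se = unname(sqrt(diag(fit$C)))),
    sigma2_pop = s2_hat,
    f_tests = f_tests,
    converged = TRUE,
    boundary = boundary,
    vcov_fixef = fit$C,
    reml_m2ll = fit$nll2,
    n_populations = q,
    n_obs = n,
    means = means
  ), class = "dimorph_lmm")
}

#' @export
print.dimorph_lmm <- function(x, ...) {
  cat("Measurement-error mixed model (REML)\n")
  cat(sprintf("  %d means from %d populations; population variance %.5g%s\n",
              x$n_obs, x$n_populations, x$sigma2_pop,
              if (x$boundary) " (boundary)" else ""))
  print(as.data.frame(x$f_tests), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @rdname fit_dimorphism_lmm
#' @param x A `"dimorph_lmm"` object.
#' @param ... Unused.
#' @export
tidy.dimorph_lmm <- function(x, ...) {
  dplyr::mutate(x$fixef,
                statistic = .data$estimate / .data$se)
}

#' @rdname fit_dimorphism_lmm
#' @export
glance.dimorph_lmm <- function(x, ...) {
  tibble(sigma2_pop = x$sigma2_pop, boundary = x$boundary,
         converged = x$converged, n_obs = x$n_obs,
         n_populations = x$n_populations, reml_m2ll = x$reml_m2ll)
}
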