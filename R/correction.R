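#' Estimate evaporative loss from control vials
#'
#' Arithmetic mean fluid loss per tube over all fly-free control vials; a
#' single grand mean is used for the whole assay (controls are dispersed
#' through the chamber, not paired with fly vials).
#'
#' @param controls Data frame with columns `sucrose_loss` and `yeast_loss`
#'   (ul), one row per control vial.
#' @return A one-row tibble: `sucrose_evap`, `yeast_evap` (ul), `n_controls`.
#' @examples
#' estimate_evaporation(tibble::tibble(sucrose_loss = c(0.2, 0.4),
#'                                     yeast_loss = c(0.4, 0.2)))
#' @export
estimate_evaporation <- function(controls) {
  req_cols(controls, c("sucrose_loss", "yeast_loss"), "controls")
  if (nrow(controls) < 1L) {
    abort("at least one control vial is required to estimate evaporation",
          class = "dietdimorph_input_error")
  }
  if (any(controls$sucrose_loss < 0) || any(controls$yeast_loss < 0)) {
    abort("control fluid losses must be non-negative",
          class = "dietdimorph_input_error")
  }
  tibble(sucrose_evap = mean(controls$sucrose_loss),
         yeast_evap = mean(controls$yeast_loss),
         n_controls = nrow(controls))
}

#' Evaporation-corrected sucrose:yeast ratio
#'
#' Corrects each fly's raw fluid-loss ratio by the ratio of evaporative
#' losses: `(sucrose_raw/yeast_raw - sucrose_evap/yeast_evap) + 1`. When raw
#' and evaporation ratios coincide the corrected value is exactly 1. The
#' additive offset cancels from any male-female difference.
#'
#' Flies with a non-positive yeast denominator (or a degenerate evaporation
#' denominator) get `NA`: the ratio is undefined for them and they are
#' excluded from ratio-scale analyses (callers count the exclusions; see
#' [run_full_analysis()]).
#'
#' @param sucrose_raw,yeast_raw Raw fluid losses (ul), vectorised.
#' @param evap One-row data frame from [estimate_evaporation()].
#' @return Numeric vector of corrected ratios (dimensionless), `NA` where
#'   undefined.
#' @examples
#' ev <- tibble::tibble(sucrose_evap = 0.5, yeast_evap = 1, n_controls = 1)
#' correct_ratio(3, 1.5, ev)  # 2 - 0.5 + 1 = 2.5
#' @export
correct_ratio <- function(sucrose_raw, yeast_raw, evap) {
  req_cols(evap, c("sucrose_evap", "yeast_evap"), "evap")
  if (evap$yeast_evap <= 0) {
    warn("yeast evaporation estimate is non-positive; corrected ratios are undefined")
    return(rep(NA_real_, length(sucrose_raw)))
  }
  out <- (sucrose_raw / yeast_raw - evap$sucrose_evap / evap$yeast_evap) + 1
  out[!is.finite(out) | yeast_raw <= 0] <- NA_real_
  out
}

#' Evaporation-corrected bivariate consumption
#'
#' Subtracts the mean evaporative loss of each fluid from the corresponding
#' raw value. Negative corrected values (from measurement error in flies that
#' drank little) are preserved: on the bivariate scale they pose none of the
#' problems they would for ratios.
#'
#' @inheritParams correct_ratio
#' @return A tibble with columns `sucrose_ul` and `yeast_ul`.
#' @export
correct_bivariate <- function(sucrose_raw, yeast_raw, evap) {
  req_cols(evap, c("sucrose_evap", "yeast_evap"), "evap")
  tibble(sucrose_ul = sucrose_raw - evap$sucrose_evap,
         yeast_ul = yeast_raw - evap$yeast_evap)
}

#' Convert consumed solution volume to solute mass
#'
#' @param volume Volume in ul.
#' @param concentration Solution concentration in g/L; 1 g/L is 1 ug/ul, so
#'   the default 90 g/L sucrose or yeast-extract solution gives 90 ug per ul
#'   consumed.
#' @return Mass in ug.
#' @examples
#' volume_to_mass(5)  # 450 ug
#' @export
volume_to_mass <- function(volume, concentration = 90) {
  if (!is.numeric(concentration) || length(concentration) != 1L ||
      is.na(concentration) || concentration <= 0) {
    abort("`concentration` must be a single positive number (g/L)",
          class = "dietdimorph_input_error")
  }
  volume * concentration
}

#' Apply both evaporation corrections to a consumption table
#'
#' Adds `ratio_corrected` (dimensionless, `NA` where undefined),
#' `sucrose_ul`/`yeast_ul` (evaporation-subtracted volumes) and
#' `sucrose_ug`/`yeast_ug` (masses at the configured concentrations) to a
#' per-fly consumption table.
#'
#' @param data Consumption table with `sucrose_raw` and `yeast_raw` columns.
#' @param controls Control-vial table (see [estimate_evaporation()]), or an
#'   already-computed evaporation estimate.
#' @param sucrose_conc,yeast_conc Solution concentrations (g/L).
#' @return `data` with the five corrected columns appended, as a tibble.
#' @export
correct_consumption <- function(data, controls, sucrose_conc = 90,
                                yeast_conc = 90) {
  req_cols(data, c("sucrose_raw", "yeast_raw"), "data")
  evap <- if (all(c("sucrose_evap", "yeast_evap") %in% names(controls))) {
    controls
  } else {
    estimate_evaporation(controls)
  }
  biv <- correct_bivariate(data$sucrose_raw, data$yeast_raw, evap)
  out <- as_tibble(data)
  out$ratio_corrected <- correct_ratio(data$sucrose_raw, data$yeast_raw, evap)
  out$sucrose_ul <- biv$sucrose_ul
  out$yeast_ul <- biv$yeast_ul
  out$sucrose_ug <- volume_to_mass(biv$sucrose_ul, sucrose_conc)
  out$yeast_ug <- volume_to_mass(biv$yeast_ul, yeast_conc)
  out
}

#' One-sample test that corrected consumption exceeds zero
#'
#' A positive mean corrected fluid loss is the sanity check that the assay
#' measures consumption rather than evaporation noise. One-sample t test of
#' mean zero, two-sided.
#'
#' @param values Numeric vector of corrected consumption values for one
#'   population (either fluid, either scale).
#' @return A one-row tibble: `estimate` (mean), `statistic` (t), `df`,
#'   `p_value`, `n`.
#' @export
test_positive_consumption <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) {
    abort("need at least two finite values for the positivity test",
          class = "dietdimorph_input_error")
  }
  if (sd(values) == 0) {
    abort("positivity test undefined for zero-variance input",
          class = "dietdimorph_input_error")
  }
  tt <- t.test(values, mu = 0)
  tibble(estimate = unname(tt$estimate), statistic = unname(tt$statistic),
         df = unname(tt$parameter), p_value = tt$p.value,
         n = length(values))
}

# shared column check
req_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("`%s` is missing required column(s): %s", what,
                  paste(missing, collapse = ", ")),
          class = "dietdimorph_schema_error")
  }
  invisible(df)
}
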