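# Canonical CSV schemas. External data (e.g. a repository deposit with
# different column names) is adapted via `column_map`, a named character
# vector mapping canonical names to the file's names.

SEX_ALIASES <- c(m = "M", male = "M", f = "F", female = "F")
TREATMENT_ALIASES <- c(
  ancestor = "ancestor", anc = "ancestor", ancestral = "ancestor",
  high_competition_low_food = "high_competition_low_food",
  high_competition = "high_competition_low_food",
  high_comp = "high_competition_low_food", hc = "high_competition_low_food",
  low_food = "high_competition_low_food",
  low_competition_high_food = "low_competition_high_food",
  low_competition = "low_competition_high_food",
  low_comp = "low_competition_high_food", lc = "low_competition_high_food",
  high_food = "low_competition_high_food")

read_schema_csv <- function(path, mandatory, column_map = NULL, what) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  names(df) <- tolower(names(df))
  if (!is.null(column_map)) {
    column_map <- setNames(tolower(column_map), tolower(names(column_map)))
    for (canon in names(column_map)) {
      if (column_map[[canon]] %in% names(df)) {
        names(df)[names(df) == column_map[[canon]]] <- canon
      }
    }
  }
  if (nrow(df) == 0L) {
    abort(sprintf("%s file `%s` contains no data rows", what, path),
          class = "dietdimorph_io_error")
  }
  missing <- setdiff(mandatory, names(df))
  if (length(missing)) {
    abort(sprintf("%s file `%s` is missing required column(s): %s", what,
                  path, paste(missing, collapse = ", ")),
          class = "dietdimorph_schema_error")
  }
  as_tibble(df)
}

# Coerce character columns to numeric, dropping (with a warning naming the
# row numbers) rows where a mandatory numeric field fails to parse.
coerce_numeric_rows <- function(df, num_cols, what) {
  bad <- rep(FALSE, nrow(df))
  for (cl in num_cols) {
    raw <- df[[cl]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- bad | (is.na(val) & !is.na(raw) & trimws(raw) != "")
    df[[cl]] <- val
  }
  # mandatory numerics may not be missing either
  for (cl in num_cols) bad <- bad | is.na(df[[cl]])
  if (any(bad)) {
    warn(sprintf("%s: dropped %d row(s) with unparseable or missing numeric fields (rows %s)",
                 what, sum(bad),
                 paste(utils::head(which(bad), 10L), collapse = ", ")))
    df <- df[!bad, , drop = FALSE]
  }
  if (nrow(df) == 0L) {
    abort(sprintf("%s: no valid rows remain after parsing", what),
          class = "dietdimorph_io_error")
  }
  df
}

normalize_enum <- function(x, aliases, levels, field, what) {
  key <- tolower(trimws(x))
  out <- ifelse(key %in% names(aliases), aliases[key],
                ifelse(x %in% levels, x, NA_character_))
  if (any(is.na(out) & !is.na(x))) {
    bad <- unique(x[is.na(out) & !is.na(x)])
    abort(sprintf("%s: unrecognised %s value(s): %s", what, field,
                  paste(bad, collapse = ", ")),
          class = "dietdimorph_io_error")
  }
  unname(out)
}

#' Read a per-fly consumption table
#'
#' Reads the canonical comma-separated consumption schema (header matched
#' case-insensitively): `fly_id`, `population`, `treatment`, `generation`,
#' `sex`, `sucrose_raw`, `yeast_raw`, and optionally `survived_deprivation`.
#' Common aliases for `sex` (`male`, `m`, ...) and `treatment`
#' (`high_competition`, `hc`, `low_food`, ...) are normalised to the
#' canonical levels. Rows whose numeric fields fail to parse are dropped
#' with a warning naming the rows; files missing a mandatory column raise a
#' schema error naming it. Extra columns are passed through untouched.
#'
#' @param path CSV file path.
#' @param column_map Optional named character vector mapping canonical
#'   column names to the file's column names, for adapting external data.
#' @return A tibble of typed consumption records.
#' @export
read_consumption_table <- function(path, column_map = NULL) {
  mandatory <- c("fly_id", "population", "treatment", "generation", "sex",
                 "sucrose_raw", "yeast_raw")
  df <- read_schema_csv(path, mandatory, column_map, "consumption")
  df <- coerce_numeric_rows(df, c("generation", "sucrose_raw", "yeast_raw"),
                            "consumption")
  df$generation <- as.integer(df$generation)
  if (any(df$generation < 0)) {
    abort("consumption: `generation` must be >= 0",
          class = "dietdimorph_io_error")
  }
  df$sex <- normalize_enum(df$sex, SEX_ALIASES, SEX_LEVELS, "sex",
                           "consumption")
  df$treatment <- normalize_enum(df$treatment, TREATMENT_ALIASES,
                                 TREATMENT_LEVELS, "treatment", "consumption")
  if ("survived_deprivation" %in% names(df)) {
    df$survived_deprivation <- as.logical(df$survived_deprivation)
  } else {
    df$survived_deprivation <- NA
  }
  for (cl in intersect(c("true_sucrose", "true_yeast", "true_ratio"),
                       names(df))) {
    df[[cl]] <- suppressWarnings(as.numeric(df[[cl]]))
  }
  df
}

#' Read an evaporation-control table
#'
#' Canonical columns: `vial_id`, `sucrose_loss`, `yeast_loss` (ul, >= 0).
#'
#' @inheritParams read_consumption_table
#' @return A tibble of control-vial records.
#' @export
read_control_table <- function(path, column_map = NULL) {
  df <- read_schema_csv(path, c("vial_id", "sucrose_loss", "yeast_loss"),
                        column_map, "controls")
  df <- coerce_numeric_rows(df, c("sucrose_loss", "yeast_loss"), "controls")
  if (any(df$sucrose_loss < 0) || any(df$yeast_loss < 0)) {
    abort("controls: fluid losses must be >= 0",
          class = "dietdimorph_io_error")
  }
  df
}

#' Read a population census table
#'
#' Canonical columns: `population`, `treatment`, `generation`, `n_females`,
#' `n_recruits_next_generation`, `n_assayed`, `n_survived_deprivation`
#' (the last three may be empty where not measured).
#'
#' @inheritParams read_consumption_table
#' @return A tibble of census records.
#' @export
read_census_table <- function(path, column_map = NULL) {
  df <- read_schema_csv(path, c("population", "treatment", "generation",
                                "n_females"), column_map, "census")
  df <- coerce_numeric_rows(df, c("generation", "n_females"), "census")
  for (cl in c("n_recruits_next_generation", "n_assayed",
               "n_survived_deprivation")) {
    if (!cl %in% names(df)) df[[cl]] <- NA_integer_
    df[[cl]] <- as.integer(suppressWarnings(as.numeric(df[[cl]])))
  }
  df$generation <- as.integer(df$generation)
  df$n_females <- as.integer(df$n_females)
  df$treatment <- normalize_enum(df$treatment, TREATMENT_ALIASES,
                                 TREATMENT_LEVELS, "treatment", "census")
  ok <- is.na(df$n_survived_deprivation) | is.na(df$n_assayed) |
    df$n_survived_deprivation <= df$n_assayed
  if (!all(ok)) {
    abort("census: n_survived_deprivation exceeds n_assayed",
          class = "dietdimorph_io_error")
  }
  df
}

#' Write a simulated experiment to the canonical CSV files
#'
#' Writes `consumption.csv`, `controls.csv` and `census.csv` (the schemas
#' read back by [read_consumption_table()] and friends, simulation-truth
#' columns included) into `dir`.
#'
#' @param experiment A `"diet_experiment"` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "diet_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("consumption.csv", "controls.csv", "census.csv"))
  readr::write_csv(experiment$consumption, paths[1], progress = FALSE)
  readr::write_csv(experiment$controls, paths[2], progress = FALSE)
  readr::write_csv(experiment$census, paths[3], progress = FALSE)
  invisible(paths)
}

#' Write analysis result tables and a run manifest
#'
#' Writes one CSV per result family and a JSON manifest recording the files
#' (with row counts), the seed, a configuration hash, record-count
#' accounting, and software versions. List-columns (e.g. bootstrap draws)
#' are dropped from the CSVs. Rerunning with the same seed and
#' configuration yields byte-identical tables.
#'
#' @param results Named list of data frames (empty entries are skipped).
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed used for the run (recorded in the manifest).
#' @param config Configuration object; hashed into the manifest.
#' @param counts Optional named list of record counts (e.g. flies in /
#'   analysed / excluded) to record.
#' @return Invisibly, the manifest as a list.
#' @export
write_results_tables <- function(results, out_dir, seed = NULL,
                                 config = NULL, counts = NULL) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!ok) {
      abort(sprintf("cannot create output directory `%s`", out_dir),
            class = "dietdimorph_io_error")
    }
  }
  results <- purrr::compact(results)
  files <- purrr::imap(results, function(df, nm) {
    df <- as_tibble(df)
    df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
    path <- file.path(out_dir, paste0(nm, ".csv"))
    readr::write_csv(df, path, progress = FALSE)
    list(file = basename(path), rows = nrow(df), cols = ncol(df))
  })
  manifest <- list(
    package = "dietdimorph",
    package_version = as.character(utils::packageVersion("dietdimorph")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    config_hash = if (!is.null(config)) rlang::hash(config) else NULL,
    counts = counts,
    tables = unname(purrr::imap(files, function(f, nm) c(name = nm, f)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
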