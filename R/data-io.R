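#' Assemble a longitudinal growth dataset
#'
#' Bundles per-capture length-at-age records and (optionally) per-cohort
#' covariates into a validated `growth_data` object, the container every
#' fitting, selection and validation function in the package consumes.
#'
#' Records come from annual mark-recapture sampling: one row per capture of a
#' tagged individual, with its year-of-birth cohort, age (years) and length
#' (mm). At most one measurement per individual per age is allowed. Cohort
#' covariates carry the population density experienced by each cohort in its
#' first year of life (individuals per hectare), used when density enters a
#' model as predictor.
#'
#' @param records A data frame with columns `fish_id`, `cohort_id`, `age`
#'   (years, non-negative) and `length` (mm, positive). Rows with missing age
#'   or length are dropped with a message.
#' @param covariates Optional data frame with columns `cohort_id` and
#'   `density` (ind ha^-1, non-negative), one row per cohort.
#' @return An object of class `growth_data`: a list with tibbles `records`
#'   (sorted by fish and age) and `covariates` (or `NULL`).
#' @examples
#' d <- growth_data(data.frame(
#'   fish_id = "f1", cohort_id = "2001", age = 1:3,
#'   length = c(115, 180, 225)
#' ))
#' d
#' @export
growth_data <- function(records, covariates = NULL) {
  records <- tibble::as_tibble(records)
  required <- c("fish_id", "cohort_id", "age", "length")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("`records` is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "vbgrowth_schema_error")
  }
  records <- dplyr::mutate(records,
    fish_id = as.character(.data$fish_id),
    cohort_id = as.character(.data$cohort_id),
    age = as.numeric(.data$age),
    length = as.numeric(.data$length)
  )
  n_in <- nrow(records)
  records <- dplyr::filter(records, !is.na(.data$age), !is.na(.data$length))
  n_dropped <- n_in - nrow(records)
  if (n_dropped > 0) {
    inform(sprintf("Dropped %d record(s) with missing age or length.", n_dropped))
  }
  if (nrow(records) == 0) {
    abort("No valid records remain.", class = "vbgrowth_validation_error")
  }
  if (any(records$length <= 0)) {
    bad <- records[records$length <= 0, ][1, ]
    abort(sprintf("Non-positive length for fish '%s' at age %g.",
                  bad$fish_id, bad$age),
          class = "vbgrowth_validation_error")
  }
  if (any(records$age < 0) || any(!is.finite(records$age))) {
    abort("Ages must be finite and non-negative.",
          class = "vbgrowth_validation_error")
  }
  dup <- duplicated(records[, c("fish_id", "age")])
  if (any(dup)) {
    bad <- records[dup, ][1, ]
    abort(sprintf("Duplicate (fish_id, age) pair: fish '%s' at age %g.",
                  bad$fish_id, bad$age),
          class = "vbgrowth_validation_error")
  }
  records <- dplyr::arrange(records, .data$fish_id, .data$age)

  if (!is.null(covariates)) {
    covariates <- tibble::as_tibble(covariates)
    if (!all(c("cohort_id", "density") %in% names(covariates))) {
      abort("`covariates` must have columns cohort_id and density.",
            class = "vbgrowth_schema_error")
    }
    covariates <- dplyr::mutate(covariates,
      cohort_id = as.character(.data$cohort_id),
      density = as.numeric(.data$density)
    )
    if (anyDuplicated(covariates$cohort_id)) {
      abort("`covariates` must have one row per cohort.",
            class = "vbgrowth_validation_error")
    }
    if (any(!is.finite(covariates$density)) || any(covariates$density < 0)) {
      abort("Densities must be finite and non-negative.",
            class = "vbgrowth_validation_error")
    }
  }
  structure(
    list(records = records, covariates = covariates),
    n_dropped = n_dropped,
    class = "growth_data"
  )
}

#' Coerce to a growth dataset
#'
#' @param x A `growth_data` object or a data frame of capture records
#'   (see [growth_data()]).
#' @param covariates Optional cohort covariate table, ignored when `x` is
#'   already a `growth_data`.
#' @return A `growth_data` object.
#' @export
as_growth_data <- function(x, covariates = NULL) {
  if (inherits(x, "growth_data")) return(x)
  growth_data(x, covariates)
}

#' @export
print.growth_data <- function(x, ...) {
  counts <- capture_counts(x)
  cat(sprintf(
    "<growth_data: %d records, %d fish, %d cohort(s), %.1f captures/fish>\n",
    nrow(x$records), nrow(counts),
    dplyr::n_distinct(x$records$cohort_id), mean(counts$n_captures)
  ))
  if (!is.null(x$covariates)) {
    cat(sprintf("  cohort covariates: density for %d cohort(s)\n",
                nrow(x$covariates)))
  }
  print(head(x$records, 5))
  invisible(x)
}

#' Number of captures per individual
#'
#' @param data A `growth_data` object or coercible data frame.
#' @return A tibble with columns `fish_id` and `n_captures`.
#' @export
capture_counts <- function(data) {
  data <- as_growth_data(data)
  dplyr::count(data$records, .data$fish_id, name = "n_captures")
}

#' Read a longitudinal growth table from delimited text
#'
#' Reads one-row-per-capture tables (CSV/TSV; the delimiter is guessed) and
#' validates them into a [growth_data()] object. Column names are mapped
#' through `dialect`, so tables using e.g. `Mark`/`Year_class` headers can be
#' read without renaming.
#'
#' @param path Path to the capture table.
#' @param covariates_path Optional path to a per-cohort covariate table with
#'   columns (after dialect mapping) `cohort` and `density`.
#' @param dialect Named list mapping the canonical names `id`, `cohort`,
#'   `age`, `length`, `density` to the column names in the files.
#' @return A `growth_data` object.
#' @export
read_growth_table <- function(path, covariates_path = NULL,
                              dialect = list(id = "id", cohort = "cohort",
                                             age = "age", length = "length",
                                             density = "density")) {
  defaults <- list(id = "id", cohort = "cohort", age = "age",
                   length = "length", density = "density")
  dialect <- utils::modifyList(defaults, as.list(dialect))
  raw <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  need <- unlist(dialect[c("id", "cohort", "age", "length")])
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("File ", path, " is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "vbgrowth_schema_error")
  }
  records <- tibble::tibble(
    fish_id = raw[[dialect$id]],
    cohort_id = raw[[dialect$cohort]],
    age = raw[[dialect$age]],
    length = raw[[dialect$length]]
  )
  covariates <- NULL
  if (!is.null(covariates_path)) {
    cov_raw <- readr::read_delim(covariates_path, show_col_types = FALSE,
                                 progress = FALSE)
    cov_need <- unlist(dialect[c("cohort", "density")])
    if (!all(cov_need %in% names(cov_raw))) {
      abort(paste0("Covariate file is missing column(s): ",
                   paste(setdiff(cov_need, names(cov_raw)), collapse = ", ")),
            class = "vbgrowth_schema_error")
    }
    covariates <- tibble::tibble(
      cohort_id = cov_raw[[dialect$cohort]],
      density = cov_raw[[dialect$density]]
    )
  }
  growth_data(records, covariates)
}

#' Write a growth dataset to delimited text
#'
#' Inverse of [read_growth_table()] with the default dialect; `read(write(d))`
#' reproduces `d`.
#'
#' @param data A `growth_data` object.
#' @param path Output path for the capture table (CSV).
#' @param covariates_path Optional output path for the covariate table.
#' @return `data`, invisibly.
#' @export
write_growth_table <- function(data, path, covariates_path = NULL) {
  data <- as_growth_data(data)
  out <- dplyr::rename(data$records, id = "fish_id", cohort = "cohort_id")
  readr::write_csv(out, path)
  if (!is.null(covariates_path)) {
    if (is.null(data$covariates)) {
      abort("Dataset has no covariates to write.")
    }
    readr::write_csv(dplyr::rename(data$covariates, cohort = "cohort_id"),
                     covariates_path)
  }
  invisible(data)
}

#' Write a machine-readable fit report
#'
#' Serializes a fitted model to JSON: population-parameter estimates with
#' standard errors and confidence intervals, log-likelihood, AIC/BIC,
#' maximum gradient component, convergence flag, and the Empirical Bayes
#' random-effect modes per individual. Non-converged fits are written too,
#' flagged `converged: false`.
#'
#' @param fit A `vbgf_fit` object from [fit_vbgf()].
#' @param path Output path.
#' @return `fit`, invisibly.
#' @seealso [read_fit_report()]
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "vbgf_fit"))
  g <- glance(fit)
  report <- list(
    package = "vbgrowth",
    model = list(
      k_predictor = fit$spec$k_predictor,
      linf_predictor = fit$spec$linf_predictor,
      log_density = fit$spec$log_density,
      random_effects = fit$spec$random_effects
    ),
    converged = fit$converged,
    max_gradient = fit$max_gradient,
    loglik = fit$loglik,
    n_parameters = fit$n_parameters,
    n_obs = fit$n_obs,
    n_fish = fit$n_fish,
    AIC = g$AIC,
    BIC = g$BIC,
    estimates = as.data.frame(tidy(fit)),
    eb_modes = as.data.frame(eb_random_effects(fit))
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(fit)
}

#' Read a fit report written by [write_fit_report()]
#'
#' @param path Path to a JSON fit report.
#' @return A list with the report fields; `estimates` and `eb_modes` are
#'   returned as tibbles.
#' @export
read_fit_report <- function(path) {
  report <- jsonlite::read_json(path, simplifyVector = TRUE)
  report$estimates <- tibble::as_tibble(report$estimates)
  report$eb_modes <- tibble::as_tibble(report$eb_modes)
  report
}
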