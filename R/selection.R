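#' Fit and rank a grid of growth models by AIC
#'
#' Fits each specification with [fit_vbgf()] and assembles a selection table:
#' parameter counts, log-likelihood, AIC with the difference to the best
#' model, and BIC as a consistency check on the ranking. Non-converged fits
#' are retained and flagged rather than dropped, so the table always covers
#' the full grid; fits that error outright get `NA` rows.
#'
#' @param data A [growth_data()] object (with covariates when any density
#'   model is in `specs`).
#' @param specs List of [vb_model_spec()] objects; defaults to the full
#'   nine-model grid of [model_spec_grid()].
#' @param control A [vb_control()] shared across fits.
#' @return A tibble of class `vbgf_selection`, sorted by AIC, with columns
#'   `model`, `k_predictor`, `linf_predictor`, `n_parameters`, `logLik`,
#'   `AIC`, `delta_AIC`, `BIC`, `converged`, `max_gradient`. The fitted
#'   models are attached as attribute `"fits"` (named by `model`).
#' @export
select_growth_models <- function(data, specs = model_spec_grid(),
                                 control = vb_control()) {
  data <- as_growth_data(data)
  n_obs <- nrow(data$records)
  fits <- purrr::map(specs, function(sp) {
    tryCatch(suppressWarnings(fit_vbgf(data, sp, control)),
             error = function(e) e)
  })
  rows <- purrr::map2(specs, fits, function(sp, f) {
    if (inherits(f, "error")) {
      return(tibble::tibble(
        model = spec_label(sp), k_predictor = sp$k_predictor,
        linf_predictor = sp$linf_predictor,
        n_parameters = count_parameters(sp, dplyr::n_distinct(data$records$cohort_id)),
        logLik = NA_real_, AIC = NA_real_, BIC = NA_real_,
        converged = FALSE, max_gradient = NA_real_
      ))
    }
    tibble::tibble(
      model = spec_label(sp), k_predictor = sp$k_predictor,
      linf_predictor = sp$linf_predictor,
      n_parameters = f$n_parameters,
      logLik = f$loglik,
      AIC = vb_aic(f$loglik, f$n_parameters),
      BIC = vb_bic(f$loglik, f$n_parameters, n_obs),
      converged = f$converged, max_gradient = f$max_gradient
    )
  })
  tab <- dplyr::bind_rows(rows)
  if (all(is.na(tab$AIC))) {
    abort("All model fits failed.", class = "vbgrowth_fit_error")
  }
  tab <- dplyr::arrange(tab, .data$AIC)
  tab$delta_AIC <- tab$AIC - min(tab$AIC, na.rm = TRUE)
  tab <- dplyr::relocate(tab, "delta_AIC", .after = "AIC")
  ok <- !purrr::map_lgl(fits, inherits, "error")
  fit_list <- fits[ok]
  names(fit_list) <- purrr::map_chr(specs[ok], spec_label)
  attr(tab, "fits") <- fit_list
  class(tab) <- c("vbgf_selection", class(tab))
  tab
}

#' Best model of a selection table
#'
#' @param selection A `vbgf_selection` from [select_growth_models()].
#' @return The `vbgf_fit` with the lowest AIC.
#' @export
best_model <- function(selection) {
  stopifnot(inherits(selection, "vbgf_selection"))
  attr(selection, "fits")[[selection$model[1]]]
}

#' Write a selection table as delimited text
#'
#' Exports the table in the conventional layout: one row per model with AIC
#' followed by "(parameters, delta AIC)".
#'
#' @param selection A `vbgf_selection`.
#' @param path Output path (CSV).
#' @return `selection`, invisibly.
#' @export
write_selection_table <- function(selection, path) {
  out <- dplyr::mutate(
    tibble::as_tibble(selection),
    summary = sprintf("(%d, %.1f)", .data$n_parameters, .data$delta_AIC)
  )
  readr::write_csv(out, path)
  invisible(selection)
}
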