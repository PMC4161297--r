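#' Specify which predictors enter the growth model
#'
#' A model is defined by which shared predictor (none, first-year density, or
#' year-of-birth cohort) enters log k and which enters log L-infinity; at most
#' one predictor per parameter. All models carry individual random effects on
#' both parameters unless `random_effects = FALSE` (a degenerate variant used
#' to compare against plain nonlinear least squares).
#'
#' @param k_predictor,linf_predictor One of `"none"`, `"density"`, `"cohort"`.
#' @param log_density Use log-transformed density as the continuous predictor.
#' @param random_effects Include individual random effects (default `TRUE`).
#' @return A `vb_model_spec` object.
#' @examples
#' vb_model_spec("cohort", "cohort")
#' @export
vb_model_spec <- function(k_predictor = c("none", "density", "cohort"),
                          linf_predictor = c("none", "density", "cohort"),
                          log_density = FALSE, random_effects = TRUE) {
  k_predictor <- match.arg(k_predictor)
  linf_predictor <- match.arg(linf_predictor)
  structure(list(k_predictor = k_predictor, linf_predictor = linf_predictor,
                 log_density = log_density, random_effects = random_effects),
            class = "vb_model_spec")
}

#' @export
print.vb_model_spec <- function(x, ...) {
  cat("<vb_model_spec:", spec_label(x),
      if (!x$random_effects) "(no random effects)", ">\n")
  invisible(x)
}

#' Human-readable label for a model specification
#'
#' @param spec A [vb_model_spec()].
#' @return A short string such as `"k=f(coh), Linf=f(D)"`.
#' @export
spec_label <- function(spec) {
  lab <- function(p) switch(p, none = NULL, density = "f(D)", cohort = "f(coh)")
  parts <- c(
    if (!is.null(lab(spec$k_predictor))) paste0("k=", lab(spec$k_predictor)),
    if (!is.null(lab(spec$linf_predictor))) paste0("Linf=", lab(spec$linf_predictor))
  )
  if (length(parts) == 0) "no predictors" else paste(parts, collapse = ", ")
}

#' The nine-model predictor grid
#'
#' Enumerates the full grid of model specifications with at most one predictor
#' (none, density, cohort) for each of the two growth parameters, in the
#' conventional selection-table column order: no predictors, then single
#' predictors on L-infinity and on k, then the two-predictor combinations.
#'
#' @param log_density Use log-transformed density in the density models.
#' @return A list of 9 [vb_model_spec()] objects.
#' @export
model_spec_grid <- function(log_density = FALSE) {
  combos <- list(
    c("none", "none"),
    c("none", "density"),
    c("none", "cohort"),
    c("density", "none"),
    c("cohort", "none"),
    c("cohort", "cohort"),
    c("cohort", "density"),
    c("density", "density"),
    c("density", "cohort")
  )
  purrr::map(combos, function(x) {
    vb_model_spec(k_predictor = x[1], linf_predictor = x[2],
                  log_density = log_density)
  })
}

#' Number of free parameters of a model specification
#'
#' Counts the maximum-likelihood parameters: the shared `t0`, the three
#' standard deviations (random effects on log k and log L-infinity, residual),
#' plus one block per growth parameter — 1 for an intercept only, 2 for
#' intercept + density slope, and J for a cohort model (intercept + J-1
#' corner-constrained effects). A cohort model for both parameters with J
#' cohorts therefore has 2J + 4 parameters.
#'
#' @param spec A [vb_model_spec()].
#' @param n_cohorts Number of cohorts J in the dataset (J >= 1).
#' @return Integer parameter count, equal to the length of the free parameter
#'   vector built by [fit_vbgf()] for the same specification.
#' @examples
#' count_parameters(vb_model_spec("cohort", "cohort"), n_cohorts = 11)
#' @export
count_parameters <- function(spec, n_cohorts) {
  stopifnot(inherits(spec, "vb_model_spec"))
  if (!is.numeric(n_cohorts) || n_cohorts < 1) {
    abort("`n_cohorts` must be >= 1.")
  }
  block <- function(p) switch(p, none = 1L, density = 2L,
                              cohort = as.integer(n_cohorts))
  base <- if (spec$random_effects) 4L else 2L  # t0 + sigmas
  base + block(spec$k_predictor) + block(spec$linf_predictor)
}

#' Akaike and Bayesian information criteria
#'
#' `vb_aic(ll, p) = 2p - 2 ll`; `vb_bic(ll, p, n) = p log(n) - 2 ll`, with `n`
#' the total number of length measurements.
#'
#' @param loglik Maximized log-likelihood.
#' @param n_parameters Number of free parameters.
#' @param n_obs Total number of observations (BIC only).
#' @return A numeric scalar.
#' @export
vb_aic <- function(loglik, n_parameters) {
  stopifnot(is.finite(loglik))
  2 * n_parameters - 2 * loglik
}

#' @rdname vb_aic
#' @export
vb_bic <- function(loglik, n_parameters, n_obs) {
  stopifnot(is.finite(loglik), n_obs >= 1)
  n_parameters * log(n_obs) - 2 * loglik
}
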