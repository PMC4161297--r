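#' Plot observed growth trajectories
#'
#' Spaghetti plot of length-at-age, one line per fish, coloured by cohort.
#'
#' @param object A [growth_data()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.growth_data <- function(object, ...) {
  ggplot2::ggplot(object$records,
                  ggplot2::aes(x = .data$age, y = .data$length,
                               group = .data$fish_id,
                               colour = .data$cohort_id)) +
    ggplot2::geom_line(alpha = 0.35) +
    ggplot2::geom_point(size = 0.7, alpha = 0.5) +
    ggplot2::labs(x = "Age (years)", y = "Length (mm)", colour = "Cohort") +
    ggplot2::theme_minimal()
}

#' Plot a fitted growth model
#'
#' Observed trajectories (grey) with the fitted mean growth curve per cohort
#' (random effects set to 0).
#'
#' @param object A `vbgf_fit`.
#' @param ages Ages at which to draw the fitted curves.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vbgf_fit <- function(object, ages = NULL, ...) {
  rec <- object$data$records
  ages <- ages %||% seq(min(rec$age), max(rec$age), length.out = 80)
  curves <- purrr::map_dfr(object$lvls, function(cid) {
    p <- cohort_mean_params(object$theta, object$spec, object$lvls, cid)
    tibble::tibble(cohort_id = cid, age = ages,
                   length = vbgf_length(ages, p[["linf"]], p[["k"]], p[["t0"]]))
  })
  ggplot2::ggplot(rec, ggplot2::aes(x = .data$age, y = .data$length)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$fish_id),
                       alpha = 0.2, colour = "grey50") +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(colour = .data$cohort_id),
                       linewidth = 0.9) +
    ggplot2::labs(x = "Age (years)", y = "Length (mm)", colour = "Cohort") +
    ggplot2::theme_minimal()
}

#' Plot a model-selection table
#'
#' Dot plot of the AIC difference to the best model for each specification.
#'
#' @param object A `vbgf_selection` from [select_growth_models()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vbgf_selection <- function(object, ...) {
  tab <- tibble::as_tibble(object)
  tab$model <- factor(tab$model, levels = rev(tab$model))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$delta_AIC, y = .data$model)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$delta_AIC,
                                       yend = .data$model),
                          linewidth = 0.3, colour = "grey60") +
    ggplot2::labs(x = expression(Delta * AIC), y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot hold-out validation results
#'
#' Paired model-versus-baseline mean absolute error across validation
#' replicates; points below the diagonal favour the growth model.
#'
#' @param object A `vbgf_validation` from [validate_growth_model()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vbgf_validation <- function(object, ...) {
  tab <- tibble::as_tibble(object)
  lim <- range(c(tab$model_MAE, tab$baseline_MAE))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$baseline_MAE,
                                    y = .data$model_MAE)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::coord_equal(xlim = lim, ylim = lim) +
    ggplot2::labs(x = "Baseline MAE (mm)", y = "Model MAE (mm)") +
    ggplot2::theme_minimal()
}
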