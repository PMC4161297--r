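#' von Bertalanffy length-at-age
#'
#' Evaluates the three-parameter von Bertalanffy growth function
#' \deqn{L(t) = L_\infty \, (1 - e^{-k (t - t_0)})}
#' where `linf` is the asymptotic length (mm), `k` (1/year) sets how fast the
#' asymptote is approached, and `t0` is the hypothetical age at which length
#' is zero. The curve is strictly increasing and concave for `t > t0`.
#'
#' Arguments are recycled to a common length, so a vector of ages can be
#' combined with per-individual parameter vectors.
#'
#' @param age Age(s), years.
#' @param linf Asymptotic length(s), mm, positive.
#' @param k Growth coefficient(s), 1/year, positive.
#' @param t0 Age(s) at length zero, years.
#' @return Length(s) in mm.
#' @examples
#' vbgf_length(1:8, linf = 330, k = 0.37, t0 = -0.38)
#' @export
vbgf_length <- function(age, linf, k, t0) {
  if (any(!is.finite(age)) || any(!is.finite(linf)) ||
      any(!is.finite(k)) || any(!is.finite(t0))) {
    abort("All arguments to vbgf_length() must be finite.")
  }
  if (any(linf <= 0) || any(k <= 0)) {
    abort("`linf` and `k` must be strictly positive.")
  }
  linf * (1 - exp(-k * (age - t0)))
}

#' Build a linear predictor specification for log k or log L-infinity
#'
#' The population parameters `k` and `L_inf` are modelled on the log scale as
#' an intercept plus (optionally) a cohort fixed effect, a density slope, and
#' a standardized individual random effect scaled by `sd_random`. The first
#' cohort (alphabetically) is the reference with effect 0 (corner-point
#' constraint), which keeps the intercept identifiable.
#'
#' @param intercept Intercept on the log scale.
#' @param cohort_effects Named numeric vector of cohort effects (reference
#'   cohort must be 0), or `NULL`.
#' @param density_coef Slope on density (per ind ha^-1), or `NULL`.
#' @param sd_random Standard deviation of the individual random effect,
#'   non-negative.
#' @return A `linear_predictor` list.
#' @export
linear_predictor <- function(intercept, cohort_effects = NULL,
                             density_coef = NULL, sd_random = 0) {
  stopifnot(is.numeric(intercept), length(intercept) == 1,
            is.numeric(sd_random), sd_random >= 0)
  if (!is.null(cohort_effects)) {
    if (is.null(names(cohort_effects)) || any(names(cohort_effects) == "")) {
      abort("`cohort_effects` must be a named vector (names = cohort ids).")
    }
    ref <- sort(names(cohort_effects))[1]
    if (abs(cohort_effects[[ref]]) > 1e-12) {
      abort(sprintf("Reference cohort '%s' must have effect 0.", ref))
    }
  }
  structure(list(intercept = intercept, cohort_effects = cohort_effects,
                 density_coef = density_coef, sd_random = sd_random),
            class = "linear_predictor")
}

#' Individual von Bertalanffy parameters from population parameters
#'
#' Assembles per-individual `(k, L_inf)` through the log link:
#' \deqn{\log k = \beta_0 + \beta_{coh} + \beta_2 x + \sigma_u u, \quad
#'       \log L_\infty = \alpha_0 + \alpha_{coh} + \alpha_2 x + \sigma_v v}
#' with standardized random effects `(u, v)`; `t0` is a shared
#' population-level parameter passed through unchanged. The log link
#' guarantees positive `k` and `L_inf` for any finite inputs.
#'
#' Vectorized over `cohort_id`, `density`, `u` and `v`.
#'
#' @param pred_k,pred_linf [linear_predictor()] specifications for log k and
#'   log L-infinity.
#' @param t0 Shared age at length zero, years.
#' @param cohort_id Cohort label(s); required when either predictor carries
#'   cohort effects.
#' @param density First-year density value(s) (already log-transformed if the
#'   model uses log density).
#' @param u,v Standardized random effects (dimensionless).
#' @return A tibble with columns `k`, `linf`, `t0` (one row per individual).
#' @examples
#' pk <- linear_predictor(log(0.37), sd_random = 0.22)
#' pl <- linear_predictor(log(330), sd_random = 0.22)
#' individual_params(pk, pl, t0 = -0.38, u = c(-1, 0, 1), v = c(0, 0, 0))
#' @export
individual_params <- function(pred_k, pred_linf, t0, cohort_id = NULL,
                              density = 0, u = 0, v = 0) {
  stopifnot(inherits(pred_k, "linear_predictor"),
            inherits(pred_linf, "linear_predictor"))
  n <- max(length(cohort_id %||% 1), length(density), length(u), length(v))
  density <- rep_len(density, n)
  u <- rep_len(u, n)
  v <- rep_len(v, n)
  eta <- function(pred, re, sd_re) {
    val <- rep_len(pred$intercept, n)
    if (!is.null(pred$cohort_effects)) {
      if (is.null(cohort_id)) {
        abort("`cohort_id` required when cohort effects are present.")
      }
      ids <- rep_len(as.character(cohort_id), n)
      unknown <- setdiff(unique(ids), names(pred$cohort_effects))
      if (length(unknown) > 0) {
        abort(paste0("Unknown cohort(s): ", paste(unknown, collapse = ", ")))
      }
      val <- val + unname(pred$cohort_effects[ids])
    }
    if (!is.null(pred$density_coef)) val <- val + pred$density_coef * density
    val + sd_re * re
  }
  tibble::tibble(
    k = exp(eta(pred_k, u, pred_k$sd_random)),
    linf = exp(eta(pred_linf, v, pred_linf$sd_random)),
    t0 = t0
  )
}
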