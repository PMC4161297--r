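#' Joint negative log-likelihood of one individual's data and random effects
#'
#' The integrand (on the negative log scale) of the per-individual marginal
#' likelihood: Gaussian observation terms around the individual growth curve
#' plus standard-normal prior terms for the two random effects,
#' \deqn{-\sum_l \log N(L_l \mid L(t_l; k_i, L_{\infty i}), \sigma_\epsilon^2)
#'       - \log N(u \mid 0,1) - \log N(v \mid 0,1)}
#' with \eqn{\log k_i = a + \sigma_u u} and
#' \eqn{\log L_{\infty i} = b + \sigma_v v}.
#'
#' @param ages,lengths The individual's observation vectors (years, mm).
#' @param u,v Standardized random effects.
#' @param k_linpred,linf_linpred Fixed-effect linear predictor values `a`, `b`
#'   (log scale) for this individual.
#' @param t0 Shared age at length zero, years.
#' @param sigma_u,sigma_v Random-effect standard deviations (non-negative).
#' @param sigma_eps Residual standard deviation, mm. A value of 0 with any
#'   nonzero residual yields `Inf`, not an error.
#' @return The joint negative log-likelihood (scalar).
#' @export
joint_negloglik <- function(ages, lengths, u = 0, v = 0,
                            k_linpred, linf_linpred, t0,
                            sigma_u, sigma_v, sigma_eps) {
  stopifnot(length(ages) == length(lengths))
  joint_nll_cpp(as.numeric(ages), as.numeric(lengths), u, v,
                k_linpred, linf_linpred, t0, sigma_u, sigma_v, sigma_eps)
}

#' Posterior mode of one individual's random effects
#'
#' Minimizes [joint_negloglik()] over `(u, v)` by damped Newton iteration with
#' analytic gradient and Hessian (a positive-definite ridge safeguard and a
#' backtracking line search keep the steps monotone). With the population
#' parameters held at their maximum-likelihood estimates this is the
#' Empirical Bayes estimate of the individual's random effects.
#'
#' An individual with zero observations returns the prior mode `(0, 0)` with
#' identity curvature.
#'
#' @inheritParams joint_negloglik
#' @param start Starting value `c(u, v)`.
#' @param tol Convergence tolerance on the inner gradient norm.
#' @param max_iter Maximum Newton iterations.
#' @return A list with `mode` (length 2), `hessian` (2x2 curvature at the
#'   mode), `value`, `gradient` and `converged`.
#' @export
inner_mode <- function(ages, lengths, k_linpred, linf_linpred, t0,
                       sigma_u, sigma_v, sigma_eps,
                       start = c(0, 0), tol = 1e-8, max_iter = 100) {
  stopifnot(length(ages) == length(lengths), length(start) == 2)
  f0 <- joint_negloglik(ages, lengths, start[1], start[2], k_linpred,
                        linf_linpred, t0, sigma_u, sigma_v, sigma_eps)
  res <- inner_mode_cpp(as.numeric(ages), as.numeric(lengths),
                        k_linpred, linf_linpred, t0,
                        sigma_u, sigma_v, sigma_eps,
                        start[1], start[2], tol, as.integer(max_iter))
  if (!res$converged) {
    abort("Inner Newton solver did not converge.",
          class = "vbgrowth_inner_error",
          body = c(sprintf("value = %.6g", res$value),
                   sprintf("gradient = (%.3g, %.3g)",
                           res$gradient[1], res$gradient[2])))
  }
  res
}

#' Laplace-approximated marginal negative log-likelihood
#'
#' The marginal likelihood integrates the two individual random effects out of
#' each individual's joint likelihood; the model's likelihood is the product
#' of these per-individual integrals. Each 2-D integral is approximated by
#' Laplace's method around the posterior mode:
#' \deqn{-\log \int e^{-f(u,v)}\,du\,dv \approx f(\hat u,\hat v)
#'       - \log(2\pi) + \tfrac12 \log \det H(\hat u,\hat v).}
#' In the degenerate limit \eqn{\sigma_u = \sigma_v = 0} this reduces exactly
#' to the plain Gaussian negative log-likelihood of all residuals.
#'
#' @param data A [growth_data()] (or coercible data frame).
#' @param par Named parameter vector in the layout used by [fit_vbgf()]
#'   (see the `theta` element of a fitted model).
#' @param spec A [vb_model_spec()].
#' @param warm_starts Optional list with numeric vectors `u`, `v` (one entry
#'   per fish) used to warm-start the inner solver.
#' @param inner_tol Inner Newton gradient tolerance.
#' @param control A [vb_control()] list (used for density transforms).
#' @return A list with `value` (total negative log-likelihood), `per_fish`
#'   contributions, and `modes` — a tibble of per-fish posterior modes and
#'   curvatures, reusable as warm starts.
#' @export
laplace_negloglik <- function(data, par, spec = vb_model_spec(),
                              warm_starts = NULL, inner_tol = 1e-8,
                              control = vb_control()) {
  frame <- build_model_frame(data, spec, control)
  nm <- par_names(spec, frame$lvls)
  if (is.null(names(par))) {
    stopifnot(length(par) == length(nm))
    names(par) <- nm
  }
  res <- laplace_frame_nll(frame, par, warm_starts, inner_tol)
  modes <- tibble::tibble(
    fish_id = frame$fish_ids, u = res$u, v = res$v,
    huu = res$huu, huv = res$huv, hvv = res$hvv
  )
  list(value = res$value, per_fish = res$per_fish, modes = modes,
       n_fail = res$n_fail)
}

# Hot path: evaluate the Laplace objective on a prebuilt frame.
laplace_frame_nll <- function(frame, par, warm_starts = NULL,
                              inner_tol = 1e-8) {
  sp <- par_split(par, frame)
  n <- length(frame$fish_ids)
  u0 <- warm_starts$u %||% rep(0, n)
  v0 <- warm_starts$v %||% rep(0, n)
  laplace_nll_cpp(frame$fish_start, frame$age, frame$len, sp$a, sp$b,
                  sp$t0, sp$su, sp$sv, sp$se, u0, v0, inner_tol, 100L)
}
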