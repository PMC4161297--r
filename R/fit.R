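#' Control options for model fitting
#'
#' @param tol Outer convergence tolerance: the fit is declared converged when
#'   the maximum absolute gradient component of the marginal log-likelihood
#'   falls below `tol` (default `1e-4`, the conventional strict criterion for
#'   this model class).
#' @param inner_tol Gradient tolerance of the per-individual Newton solver.
#' @param max_iter Maximum outer quasi-Newton iterations per start.
#' @param starts Number of starting points. The first is the scale-aware
#'   default; the rest jitter it with a seeded RNG. The best optimum is kept;
#'   ties in log-likelihood (within 1e-6) are broken by the smaller maximum
#'   gradient.
#' @param seed Seed for the start jitter (and nothing else).
#' @param center_density Center the density covariate before fitting (an
#'   optimizer-conditioning device; the maximized likelihood is unchanged,
#'   only the intercept's interpretation moves to the mean density).
#' @return A list of class `vb_control`.
#' @export
vb_control <- function(tol = 1e-4, inner_tol = 1e-8, max_iter = 500,
                       starts = 1, seed = NULL, center_density = FALSE) {
  structure(list(tol = tol, inner_tol = inner_tol, max_iter = max_iter,
                 starts = starts, seed = seed,
                 center_density = center_density),
            class = "vb_control")
}

#' Fit a random-effects von Bertalanffy growth model
#'
#' Maximizes the Laplace-approximated marginal likelihood (see
#' [laplace_negloglik()]) over the population parameters: the fixed-effect
#' blocks on log k and log L-infinity selected by `spec`, the shared `t0`,
#' and the three standard deviations (random effects and residual, optimized
#' on the log scale). The outer problem is solved by BFGS with
#' central-difference gradients and warm-started inner modes, followed by a
#' `nlminb` polish whenever the maximum gradient component still exceeds
#' `control$tol`. Individual random effects are recovered as Empirical Bayes
#' posterior modes at the maximum-likelihood estimates.
#'
#' @param data A [growth_data()] object or a data frame of capture records.
#' @param spec A [vb_model_spec()]; default has no predictors.
#' @param control A [vb_control()] list.
#' @param start Optional named starting vector overriding the default.
#' @return An object of class `vbgf_fit` with elements `theta` (named
#'   estimates), `loglik`, `max_gradient`, `converged`, `hessian`, `vcov`,
#'   `eb` (per-fish posterior modes and individual parameters),
#'   `eb_curvatures`, `n_parameters`, and bookkeeping fields. Supports
#'   [tidy()], [glance()], [predict()], [autoplot()], `logLik()`, `coef()`.
#' @examples
#' sim <- simulate_growth(sim_config(n_fish = 40, ages = 1:6, seed = 7))
#' fit <- fit_vbgf(sim$data)
#' glance(fit)
#' @export
fit_vbgf <- function(data, spec = vb_model_spec(), control = vb_control(),
                     start = NULL) {
  data <- as_growth_data(data)
  frame <- build_model_frame(data, spec, control)
  nm <- par_names(spec, frame$lvls)

  starts <- list(start %||% default_start(frame))
  if (control$starts > 1) {
    base <- starts[[1]]
    if (!is.null(control$seed)) set.seed(control$seed)
    for (s in seq_len(control$starts - 1)) {
      j <- base + rnorm(length(base), sd = 0.25)
      j[["t0"]] <- base[["t0"]] + rnorm(1, sd = 0.25)
      starts[[s + 1]] <- j
    }
  }

  # warm-start cache shared across all objective evaluations
  cache <- new.env(parent = emptyenv())
  cache$u <- rep(0, length(frame$fish_ids))
  cache$v <- rep(0, length(frame$fish_ids))

  fn <- function(p) {
    names(p) <- nm
    res <- laplace_frame_nll(frame, p, list(u = cache$u, v = cache$v),
                             control$inner_tol)
    if (!isTRUE(res$finite) || !is.finite(res$value)) return(1e10)
    cache$u <- res$u
    cache$v <- res$v
    res$value
  }
  gr <- function(p) fd_gradient(fn, p)

  bounds <- par_bounds(nm)
  run_start <- function(p0) {
    p0 <- pmin(pmax(p0, bounds$lower + 1e-6), bounds$upper - 1e-6)
    opt <- tryCatch(
      nlminb(p0, fn, gradient = gr,
             lower = bounds$lower, upper = bounds$upper,
             control = list(iter.max = control$max_iter,
                            eval.max = 4 * control$max_iter,
                            rel.tol = 1e-12)),
      error = function(e) NULL
    )
    if (is.null(opt)) {
      opt2 <- tryCatch(
        optim(p0, fn, gr, method = "BFGS",
              control = list(maxit = control$max_iter, reltol = 1e-12)),
        error = function(e) NULL
      )
      if (is.null(opt2)) return(NULL)
      opt <- list(par = opt2$par, objective = opt2$value)
    }
    par <- opt$par
    val <- opt$objective
    # polish until the max-gradient criterion holds (or we give up)
    for (round in 1:6) {
      g <- gr(par)
      if (max(abs(g)) < control$tol) break
      pol <- tryCatch(
        nlminb(par, fn, gradient = gr,
               lower = bounds$lower, upper = bounds$upper,
               control = list(iter.max = control$max_iter,
                              eval.max = 4 * control$max_iter,
                              rel.tol = 1e-14, x.tol = 1e-12)),
        error = function(e) NULL
      )
      if (is.null(pol) || pol$objective > val + 1e-8) break
      par <- pol$par
      val <- pol$objective
    }
    # quasi-Newton polishers stall on flat collinear ridges (e.g. intercept
    # vs cohort effects); finish with full Newton steps on the FD Hessian
    g <- gr(par)
    for (round in 1:3) {
      if (max(abs(g)) < control$tol) break
      H <- tryCatch(optimHess(par, fn, gr), error = function(e) NULL)
      if (is.null(H)) break
      delta <- tryCatch(solve(H + diag(1e-8, nrow(H)), -g),
                        error = function(e) NULL)
      if (is.null(delta)) break
      step <- 1
      improved <- FALSE
      for (h in 1:20) {
        cand <- pmin(pmax(par + step * delta, bounds$lower), bounds$upper)
        v_new <- fn(cand)
        if (is.finite(v_new) && v_new <= val + 1e-9) {
          par <- cand; val <- v_new; improved <- TRUE
          break
        }
        step <- step / 2
      }
      if (!improved) break
      g <- gr(par)
    }
    list(par = setNames(par, nm), value = val, max_gradient = max(abs(g)))
  }

  results <- purrr::compact(purrr::map(starts, run_start))
  if (length(results) == 0) {
    abort("All starting points failed.", class = "vbgrowth_fit_error")
  }
  values <- purrr::map_dbl(results, "value")
  grads <- purrr::map_dbl(results, "max_gradient")
  near_best <- values <= min(values) + 1e-6
  best <- which(near_best)[which.min(grads[near_best])]
  if (diff(range(values)) > 1e-2 && length(results) > 1) {
    warn(sprintf(
      "Starting points reached optima differing by %.4g in log-likelihood; keeping the best.",
      diff(range(values))))
  }
  res <- results[[best]]
  par <- res$par
  converged <- res$max_gradient < control$tol
  if (!converged) {
    warn(sprintf("Fit did not reach max-gradient < %g (got %.3g).",
                 control$tol, res$max_gradient))
  }

  hess <- tryCatch(optimHess(par, fn, gr), error = function(e) NULL)
  vcov <- NULL
  if (!is.null(hess)) {
    vcov <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(vcov) && any(diag(vcov) <= 0)) vcov <- NULL
  }
  if (is.null(vcov)) {
    warn("Hessian is singular or not positive definite; standard errors unavailable.")
  }

  # final inner solve at the optimum: EB modes and curvatures
  final <- laplace_frame_nll(frame, par, list(u = cache$u, v = cache$v),
                             control$inner_tol)
  sp <- par_split(par, frame)
  counts <- diff(frame$fish_start)
  eb <- tibble::tibble(
    fish_id = frame$fish_ids,
    cohort_id = frame$fish_cohort,
    n_captures = as.integer(counts),
    u = final$u,
    v = final$v,
    k = exp(sp$a + sp$su * final$u),
    linf = exp(sp$b + sp$sv * final$v)
  )
  curv <- purrr::pmap(list(final$huu, final$huv, final$hvv), function(a, b, c) {
    matrix(c(a, b, b, c), 2, 2)
  })
  names(curv) <- frame$fish_ids

  structure(list(
    theta = par,
    spec = spec,
    loglik = -res$value,
    max_gradient = res$max_gradient,
    converged = converged,
    hessian = hess,
    vcov = vcov,
    eb = eb,
    eb_curvatures = curv,
    n_parameters = length(par),
    n_obs = length(frame$age),
    n_fish = length(frame$fish_ids),
    lvls = frame$lvls,
    data = data,
    control = control,
    start_values = values
  ), class = "vbgf_fit")
}

# Central finite-difference gradient; the inner tolerance (1e-8) keeps the
# objective smooth well below the step size used here.
fd_gradient <- function(fn, par, h_rel = 1e-5) {
  g <- numeric(length(par))
  for (i in seq_along(par)) {
    h <- h_rel * (1 + abs(par[i]))
    up <- par; up[i] <- par[i] + h
    dn <- par; dn[i] <- par[i] - h
    g[i] <- (fn(up) - fn(dn)) / (2 * h)
  }
  g
}

#' @export
print.vbgf_fit <- function(x, ...) {
  cat(sprintf("<vbgf_fit: %s%s>\n", spec_label(x$spec),
              if (!x$spec$random_effects) ", no random effects" else ""))
  cat(sprintf("  logLik %.2f | AIC %.1f | %d parameters | %d fish, %d obs\n",
              x$loglik, vb_aic(x$loglik, x$n_parameters), x$n_parameters,
              x$n_fish, x$n_obs))
  cat(sprintf("  converged: %s (max gradient %.2e)\n",
              x$converged, x$max_gradient))
  pop <- population_parameters(x)
  cat(sprintf("  L_inf %.1f mm | k %.3f 1/y | t0 %.2f y\n",
              pop$estimate[pop$parameter == "L_inf"],
              pop$estimate[pop$parameter == "k"],
              pop$estimate[pop$parameter == "t0"]))
  invisible(x)
}

#' @export
logLik.vbgf_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_parameters,
            nobs = object$n_obs, class = "logLik")
}

#' @export
coef.vbgf_fit <- function(object, ...) object$theta

#' @rdname fit_vbgf
#' @param x A `vbgf_fit` object.
#' @param conf.level Confidence level for the intervals.
#' @param transform Back-transform log-scale terms (`log_sigma_*`) to their
#'   natural scale with delta-method standard errors.
#' @param ... Unused.
#' @export
tidy.vbgf_fit <- function(x, conf.level = 0.95, transform = FALSE, ...) {
  se <- if (!is.null(x$vcov)) sqrt(diag(x$vcov)) else rep(NA_real_, x$n_parameters)
  z <- qnorm(1 - (1 - conf.level) / 2)
  out <- tibble::tibble(
    term = names(x$theta),
    estimate = unname(x$theta),
    std.error = unname(se),
    conf.low = unname(x$theta - z * se),
    conf.high = unname(x$theta + z * se)
  )
  if (transform) {
    is_log <- grepl("^log_", out$term)
    out <- dplyr::mutate(out,
      term = ifelse(is_log, sub("^log_", "", .data$term), .data$term),
      std.error = ifelse(is_log, exp(.data$estimate) * .data$std.error,
                         .data$std.error),
      conf.low = ifelse(is_log, exp(.data$conf.low), .data$conf.low),
      conf.high = ifelse(is_log, exp(.data$conf.high), .data$conf.high),
      estimate = ifelse(is_log, exp(.data$estimate), .data$estimate)
    )
  }
  out
}

#' @rdname fit_vbgf
#' @export
glance.vbgf_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik,
    AIC = vb_aic(x$loglik, x$n_parameters),
    BIC = vb_bic(x$loglik, x$n_parameters, x$n_obs),
    n_parameters = x$n_parameters,
    n_obs = x$n_obs,
    n_fish = x$n_fish,
    converged = x$converged,
    max_gradient = x$max_gradient,
    sigma_u = if (x$spec$random_effects) exp(x$theta[["log_sigma_u"]]) else 0,
    sigma_v = if (x$spec$random_effects) exp(x$theta[["log_sigma_v"]]) else 0,
    sigma_eps = exp(x$theta[["log_sigma_eps"]])
  )
}

#' Population-level growth parameters with confidence intervals
#'
#' Back-transforms the intercepts of the fitted log-linear predictors to the
#' natural scale: `L_inf = exp(linf_intercept)`, `k = exp(k_intercept)`
#' (reference cohort, zero/observed-scale density), plus the shared `t0`.
#' Standard errors use the delta method; intervals exponentiate the
#' log-scale Wald interval.
#'
#' @param fit A `vbgf_fit`.
#' @param conf.level Confidence level.
#' @return A tibble with columns `parameter`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`.
#' @export
population_parameters <- function(fit, conf.level = 0.95) {
  stopifnot(inherits(fit, "vbgf_fit"))
  z <- qnorm(1 - (1 - conf.level) / 2)
  idx <- match(c("linf_intercept", "k_intercept", "t0"), names(fit$theta))
  se <- if (!is.null(fit$vcov)) sqrt(diag(fit$vcov))[idx] else rep(NA_real_, 3)
  est_log <- unname(fit$theta[idx])
  tibble::tibble(
    parameter = c("L_inf", "k", "t0"),
    estimate = c(exp(est_log[1]), exp(est_log[2]), est_log[3]),
    std.error = c(exp(est_log[1]) * se[1], exp(est_log[2]) * se[2], se[3]),
    conf.low = c(exp(est_log[1] - z * se[1]), exp(est_log[2] - z * se[2]),
                 est_log[3] - z * se[3]),
    conf.high = c(exp(est_log[1] + z * se[1]), exp(est_log[2] + z * se[2]),
                  est_log[3] + z * se[3])
  )
}

#' Standard errors and confidence intervals of the population parameters
#'
#' Thin wrapper over [tidy()] that fails loudly when the Hessian at the
#' optimum was singular (in which case uncertainty is unavailable).
#'
#' @inheritParams population_parameters
#' @return The [tidy()] tibble (internal scale).
#' @export
standard_errors <- function(fit, conf.level = 0.95) {
  stopifnot(inherits(fit, "vbgf_fit"))
  if (is.null(fit$vcov)) {
    abort("Standard errors unavailable: Hessian not positive definite.",
          class = "vbgrowth_se_error")
  }
  tidy(fit, conf.level = conf.level)
}

#' Empirical Bayes random-effect estimates per individual
#'
#' Posterior modes of the standardized random effects `(u, v)` at the
#' maximum-likelihood population parameters, together with the implied
#' individual `(k, L_inf)`. The standard-normal prior shrinks each mode
#' toward 0, most strongly for sparsely observed fish.
#'
#' @param fit A converged `vbgf_fit`.
#' @return A tibble with columns `fish_id`, `cohort_id`, `n_captures`, `u`,
#'   `v`, `k`, `linf`.
#' @export
eb_random_effects <- function(fit) {
  stopifnot(inherits(fit, "vbgf_fit"))
  fit$eb
}

#' Predict lengths-at-age for individual fish
#'
#' Evaluates the von Bertalanffy curve at an individual's Empirical Bayes
#' `(k, L_inf)` and the shared `t0`. Fish absent from the fit are an error
#' unless a `cohort_id` is supplied, in which case the cohort mean curve
#' (random effects 0) is used.
#'
#' @param fit A `vbgf_fit`.
#' @param fish_id Single fish identifier (or `NULL` with `cohort_id` set).
#' @param ages Ages at which to predict, years.
#' @param cohort_id Optional cohort for mean-curve fallback.
#' @return Numeric vector of predicted lengths, mm.
#' @export
predict_lengths <- function(fit, fish_id = NULL, ages, cohort_id = NULL) {
  stopifnot(inherits(fit, "vbgf_fit"))
  if (!is.null(fish_id)) {
    row <- fit$eb[fit$eb$fish_id == fish_id, ]
    if (nrow(row) == 1) {
      return(vbgf_length(ages, row$linf, row$k, fit$theta[["t0"]]))
    }
    if (is.null(cohort_id)) {
      abort(sprintf("Fish '%s' not in the fitted dataset; supply `cohort_id` for a mean-curve prediction.",
                    fish_id))
    }
  }
  if (is.null(cohort_id)) abort("Supply `fish_id` and/or `cohort_id`.")
  p <- cohort_mean_params(fit$theta, fit$spec, fit$lvls, cohort_id)
  vbgf_length(ages, p[["linf"]], p[["k"]], p[["t0"]])
}

#' @rdname predict_lengths
#' @param object A `vbgf_fit`.
#' @param newdata Data frame with columns `fish_id` and `age` (optionally
#'   `cohort_id` for fish not in the fit).
#' @param ... Unused.
#' @export
predict.vbgf_fit <- function(object, newdata, ...) {
  stopifnot(is.data.frame(newdata), all(c("fish_id", "age") %in% names(newdata)))
  idx <- match(as.character(newdata$fish_id), object$eb$fish_id)
  out <- numeric(nrow(newdata))
  known <- !is.na(idx)
  if (any(known)) {
    out[known] <- vbgf_length(newdata$age[known],
                              object$eb$linf[idx[known]],
                              object$eb$k[idx[known]],
                              object$theta[["t0"]])
  }
  if (any(!known)) {
    if (!"cohort_id" %in% names(newdata)) {
      abort("`newdata` contains fish not in the fit and no `cohort_id` column.")
    }
    for (i in which(!known)) {
      out[i] <- predict_lengths(object, ages = newdata$age[i],
                                cohort_id = as.character(newdata$cohort_id[i]))
    }
  }
  out
}

#' Monte Carlo confidence bands for a mean growth trajectory
#'
#' Draws population-parameter vectors from the asymptotic normal distribution
#' at the maximum-likelihood estimates, evaluates the cohort (or population)
#' mean curve — random effects set to 0 — at each age, and returns the
#' pointwise quantile envelope.
#'
#' @param fit A converged `vbgf_fit` with an available Hessian.
#' @param ages Ages at which to evaluate the band.
#' @param cohort_id Cohort whose mean trajectory is wanted; `NULL` for the
#'   reference/population curve.
#' @param density Density value for density models.
#' @param n_draws Number of Monte Carlo draws.
#' @param level Band level (default 0.95).
#' @param seed Optional RNG seed.
#' @return A tibble with columns `age`, `estimate`, `lower`, `upper`.
#' @export
mc_confidence_bands <- function(fit, ages, cohort_id = NULL, density = 0,
                                n_draws = 1000, level = 0.95, seed = NULL) {
  stopifnot(inherits(fit, "vbgf_fit"))
  if (is.null(fit$vcov)) {
    abort("Confidence bands unavailable: Hessian not positive definite.",
          class = "vbgrowth_se_error")
  }
  if (!is.null(seed)) set.seed(seed)
  cohort_id <- cohort_id %||% fit$lvls[1]
  L <- chol(fit$vcov)
  p <- length(fit$theta)
  draws <- matrix(rnorm(n_draws * p), n_draws, p) %*% L
  curves <- matrix(NA_real_, n_draws, length(ages))
  for (i in seq_len(n_draws)) {
    th <- fit$theta + draws[i, ]
    pars <- cohort_mean_params(th, fit$spec, fit$lvls, cohort_id, density)
    curves[i, ] <- vbgf_length(ages, pars[["linf"]], pars[["k"]], pars[["t0"]])
  }
  est <- cohort_mean_params(fit$theta, fit$spec, fit$lvls, cohort_id, density)
  alpha <- (1 - level) / 2
  tibble::tibble(
    age = ages,
    estimate = vbgf_length(ages, est[["linf"]], est[["k"]], est[["t0"]]),
    lower = apply(curves, 2, quantile, probs = alpha),
    upper = apply(curves, 2, quantile, probs = 1 - alpha)
  )
}
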