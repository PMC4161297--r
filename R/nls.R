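#' Nonlinear least-squares fit of the von Bertalanffy curve
#'
#' Fits `(L_inf, k, t0)` to pooled length-at-age observations by minimizing
#' the residual sum of squares with a Levenberg–Marquardt iteration using the
#' analytic Jacobian. Because different `(L_inf, k)` combinations can give
#' nearly identical fits on a sparse age range, several deterministic
#' starting points are tried and the best kept. Asymptotic 95% confidence
#' intervals come from the Jacobian at the optimum.
#'
#' This is the no-random-effects baseline: it ignores the autocorrelation of
#' repeated measures on the same individual.
#'
#' @param ages,lengths Observation vectors (years, mm); at least 4
#'   observations spanning at least 3 distinct ages.
#' @param starts Optional list of starting vectors `c(linf, k, t0)`.
#' @param max_iter Maximum Levenberg–Marquardt iterations per start.
#' @param conf.level Level for the asymptotic intervals.
#' @return A list of class `vbgf_nls`: `par` (named estimates), `vcov`,
#'   `sigma` (residual SD, mm), `conf.int` (matrix), `n_obs`, `converged`.
#' @export
fit_growth_nls <- function(ages, lengths, starts = NULL, max_iter = 200,
                           conf.level = 0.95) {
  stopifnot(length(ages) == length(lengths))
  ok <- is.finite(ages) & is.finite(lengths)
  ages <- ages[ok]; lengths <- lengths[ok]
  n <- length(ages)
  if (n < 4 || length(unique(ages)) < 3) {
    abort("Need >= 4 observations spanning >= 3 distinct ages.",
          class = "vbgrowth_validation_error")
  }
  if (is.null(starts)) {
    lmax <- max(lengths)
    starts <- list(c(1.1 * lmax, 0.3, -0.5),
                   c(1.5 * lmax, 0.15, -1.0),
                   c(1.05 * lmax, 0.6, -0.2))
  }

  resid_fun <- function(p) lengths - p[1] * (1 - exp(-p[2] * (ages - p[3])))
  jac_fun <- function(p) {
    E <- exp(-p[2] * (ages - p[3]))
    # d(residual)/d(par) = -d(mu)/d(par)
    cbind(-(1 - E), -p[1] * (ages - p[3]) * E, p[1] * p[2] * E)
  }

  lm_run <- function(p) {
    r <- resid_fun(p)
    ss <- sum(r^2)
    lambda <- 1e-3
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      J <- jac_fun(p)
      g <- crossprod(J, r)          # gradient of SS/2
      if (max(abs(2 * g)) < 1e-10 * (1 + ss)) { converged <- TRUE; break }
      JtJ <- crossprod(J)
      improved <- FALSE
      for (tries in 1:30) {
        A <- JtJ + lambda * diag(diag(JtJ) + 1e-12)
        delta <- tryCatch(solve(A, -g), error = function(e) NULL)
        if (!is.null(delta)) {
          p_new <- p + as.numeric(delta)
          if (p_new[1] > 0 && p_new[2] > 0) {
            r_new <- resid_fun(p_new)
            ss_new <- sum(r_new^2)
            if (is.finite(ss_new) && ss_new < ss) {
              p <- p_new; r <- r_new
              if (ss - ss_new < 1e-12 * (1 + ss)) { ss <- ss_new; converged <- TRUE }
              ss <- ss_new
              lambda <- max(lambda / 4, 1e-12)
              improved <- TRUE
              break
            }
          }
        }
        lambda <- lambda * 10
      }
      if (converged) break
      if (!improved) break
    }
    list(par = p, ss = ss, converged = converged)
  }

  runs <- purrr::map(starts, lm_run)
  best <- runs[[which.min(purrr::map_dbl(runs, "ss"))]]
  p <- best$par
  J <- jac_fun(p)
  qrJ <- qr(J)
  if (qrJ$rank < 3) {
    abort("Model not identifiable from these data (rank-deficient Jacobian).",
          class = "vbgrowth_validation_error")
  }
  sigma2 <- best$ss / (n - 3)
  vcov <- sigma2 * chol2inv(qr.R(qrJ))
  se <- sqrt(diag(vcov))
  tq <- qt(1 - (1 - conf.level) / 2, df = n - 3)
  ci <- cbind(lower = p - tq * se, upper = p + tq * se)
  names(p) <- rownames(ci) <- c("linf", "k", "t0")
  dimnames(vcov) <- list(names(p), names(p))
  structure(list(par = p, vcov = vcov, sigma = sqrt(sigma2),
                 conf.int = ci, n_obs = n, converged = best$converged),
            class = "vbgf_nls")
}

#' @export
print.vbgf_nls <- function(x, ...) {
  cat(sprintf(
    "<vbgf_nls: L_inf %.1f mm, k %.3f 1/y, t0 %.2f y | sigma %.1f mm, n %d, converged %s>\n",
    x$par[["linf"]], x$par[["k"]], x$par[["t0"]], x$sigma, x$n_obs,
    x$converged))
  invisible(x)
}

#' Per-cohort nonlinear least-squares fits
#'
#' Applies [fit_growth_nls()] separately to each cohort's pooled records,
#' mirroring the classical per-group curve fit without random effects.
#' Cohorts whose fit fails (too few data, non-identifiable) are returned
#' with `NA` estimates and flagged.
#'
#' @param data A [growth_data()] object or data frame of records.
#' @return A tibble with one row per cohort: estimates, 95% CI bounds,
#'   residual SD, `n_obs`, `converged`.
#' @export
fit_nls_cohorts <- function(data) {
  data <- as_growth_data(data)
  purrr::map_dfr(split(data$records, data$records$cohort_id), function(rec) {
    base <- tibble::tibble(cohort_id = rec$cohort_id[1], n_obs = nrow(rec))
    fit <- tryCatch(fit_growth_nls(rec$age, rec$length),
                    error = function(e) NULL)
    if (is.null(fit)) {
      return(dplyr::mutate(base, linf = NA_real_, linf_low = NA_real_,
                           linf_high = NA_real_, k = NA_real_,
                           k_low = NA_real_, k_high = NA_real_, t0 = NA_real_,
                           t0_low = NA_real_, t0_high = NA_real_,
                           sigma = NA_real_, converged = FALSE))
    }
    dplyr::mutate(base,
      linf = fit$par[["linf"]], linf_low = fit$conf.int["linf", "lower"],
      linf_high = fit$conf.int["linf", "upper"],
      k = fit$par[["k"]], k_low = fit$conf.int["k", "lower"],
      k_high = fit$conf.int["k", "upper"],
      t0 = fit$par[["t0"]], t0_low = fit$conf.int["t0", "lower"],
      t0_high = fit$conf.int["t0", "upper"],
      sigma = fit$sigma, converged = fit$converged)
  })
}

#' Compare per-cohort least-squares and random-effects estimates
#'
#' Side-by-side cohort growth parameters from the per-cohort least-squares
#' fit and from a random-effects fit (cohort mean curve, random effects 0).
#' Ignoring the autocorrelation of repeated individual measures tends to
#' inflate the least-squares asymptotic length and deflate its growth
#' coefficient relative to the random-effects model.
#'
#' @param data A [growth_data()] object.
#' @param fit A `vbgf_fit`, typically with cohort predictors on both
#'   parameters; defaults to fitting one.
#' @param control Fit options used when `fit` is `NULL`.
#' @return A tibble with one row per cohort and columns `*_nls` and `*_re`.
#' @export
compare_cohort_fits <- function(data, fit = NULL, control = vb_control()) {
  data <- as_growth_data(data)
  if (is.null(fit)) {
    fit <- fit_vbgf(data, vb_model_spec("cohort", "cohort"), control)
  }
  nls_tab <- fit_nls_cohorts(data)
  re_tab <- purrr::map_dfr(fit$lvls, function(cid) {
    p <- cohort_mean_params(fit$theta, fit$spec, fit$lvls, cid)
    tibble::tibble(cohort_id = cid, linf_re = p[["linf"]], k_re = p[["k"]],
                   t0_re = p[["t0"]])
  })
  dplyr::left_join(
    dplyr::select(nls_tab, "cohort_id", linf_nls = "linf", k_nls = "k",
                  t0_nls = "t0", "n_obs", nls_converged = "converged"),
    re_tab, by = "cohort_id"
  )
}
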