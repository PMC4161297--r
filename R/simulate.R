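#' Configuration for the mark-recapture growth simulator
#'
#' Describes a simulated study: cohorts with first-year densities, true
#' population parameters on the log-link scale's natural values, correlated
#' individual random effects, an annual sampling schedule with imperfect
#' capture, and optional survival truncation of individual histories.
#'
#' Defaults reproduce the reference simulation scenario used throughout the
#' package's recovery tests: 500 fish in one cohort, true
#' `L_inf` = 330 mm, `k` = 0.37 1/y, `t0` = -0.38 y,
#' `sigma_u` = `sigma_v` = 0.22, annual sampling at ages 1–9 with capture
#' probability 0.5, and a measurement error of 8 mm.
#'
#' @param n_fish Fish per cohort (recycled over cohorts).
#' @param cohorts Character vector of cohort labels.
#' @param density First-year density per cohort, ind ha^-1 (recycled).
#' @param linf,k,t0 True population-level parameters (reference cohort).
#' @param sigma_u,sigma_v Random-effect standard deviations on log k and
#'   log L-infinity.
#' @param sigma_eps Residual (measurement) SD, mm.
#' @param k_cohort,linf_cohort Optional named cohort-effect vectors on the
#'   log scale (first cohort alphabetically must be 0).
#' @param k_density,linf_density Optional density slopes on the log scale.
#' @param re_correlation Correlation r between the two random effects,
#'   in `[-1, 1]`. The fitted model still assumes independent effects; the
#'   correlation is recovered empirically from the Empirical Bayes modes.
#' @param ages Annual sampling ages.
#' @param capture_prob Per-occasion capture probability, in (0, 1].
#' @param annual_survival Per-year survival probability truncating each
#'   fish's history (1 = no truncation). Survival is independent of size.
#' @param seed RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_fish = 500, cohorts = "2000", density = 0,
                       linf = 330, k = 0.37, t0 = -0.38,
                       sigma_u = 0.22, sigma_v = 0.22, sigma_eps = 8,
                       k_cohort = NULL, linf_cohort = NULL,
                       k_density = NULL, linf_density = NULL,
                       re_correlation = 0, ages = 1:9, capture_prob = 0.5,
                       annual_survival = 1, seed = NULL) {
  if (abs(re_correlation) > 1) abort("`re_correlation` must be in [-1, 1].")
  if (capture_prob <= 0 || capture_prob > 1) {
    abort("`capture_prob` must be in (0, 1].")
  }
  if (annual_survival <= 0 || annual_survival > 1) {
    abort("`annual_survival` must be in (0, 1].")
  }
  if (sigma_u < 0 || sigma_v < 0 || sigma_eps < 0) {
    abort("Standard deviations must be non-negative.")
  }
  cohorts <- as.character(cohorts)
  check_eff <- function(eff, what) {
    if (is.null(eff)) return(NULL)
    if (!setequal(names(eff), cohorts)) {
      abort(sprintf("`%s` must be named by the cohort labels.", what))
    }
    ref <- sort(cohorts)[1]
    if (abs(eff[[ref]]) > 1e-12) {
      abort(sprintf("`%s`: reference cohort '%s' must be 0.", what, ref))
    }
    eff
  }
  structure(list(
    n_fish = rep_len(n_fish, length(cohorts)),
    cohorts = cohorts,
    density = rep_len(density, length(cohorts)),
    linf = linf, k = k, t0 = t0,
    sigma_u = sigma_u, sigma_v = sigma_v, sigma_eps = sigma_eps,
    k_cohort = check_eff(k_cohort, "k_cohort"),
    linf_cohort = check_eff(linf_cohort, "linf_cohort"),
    k_density = k_density, linf_density = linf_density,
    re_correlation = re_correlation, ages = sort(ages),
    capture_prob = capture_prob, annual_survival = annual_survival,
    seed = seed
  ), class = "sim_config")
}

# Normal-scale correlation rho such that the bivariate lognormal
# (e^{s_u U}, e^{s_v V}) has Pearson correlation r. Clipped to [-1, 1].
lognormal_to_normal_corr <- function(r, sigma_u, sigma_v) {
  if (sigma_u == 0 || sigma_v == 0 || r == 0) return(r)
  spread <- sqrt(expm1(sigma_u^2) * expm1(sigma_v^2))
  arg <- 1 + r * spread
  if (arg <= 0) return(-1)
  max(-1, min(1, log(arg) / (sigma_u * sigma_v)))
}

# The model spec a config's truth corresponds to.
config_spec <- function(config) {
  pred <- function(coh, dens) {
    if (!is.null(coh)) "cohort" else if (!is.null(dens)) "density" else "none"
  }
  vb_model_spec(k_predictor = pred(config$k_cohort, config$k_density),
                linf_predictor = pred(config$linf_cohort, config$linf_density))
}

# True parameter vector in the layout used by fit_vbgf() for config_spec().
true_theta <- function(config) {
  lvls <- sort(config$cohorts)
  spec <- config_spec(config)
  nm <- par_names(spec, lvls)
  par <- setNames(rep(0, length(nm)), nm)
  par[["k_intercept"]] <- log(config$k)
  par[["linf_intercept"]] <- log(config$linf)
  par[["t0"]] <- config$t0
  par[["log_sigma_u"]] <- log(config$sigma_u)
  par[["log_sigma_v"]] <- log(config$sigma_v)
  par[["log_sigma_eps"]] <- log(config$sigma_eps)
  if (!is.null(config$k_cohort)) {
    par[paste0("k_cohort_", lvls[-1])] <- config$k_cohort[lvls[-1]]
  }
  if (!is.null(config$linf_cohort)) {
    par[paste0("linf_cohort_", lvls[-1])] <- config$linf_cohort[lvls[-1]]
  }
  if (!is.null(config$k_density)) par[["k_density"]] <- config$k_density
  if (!is.null(config$linf_density)) par[["linf_density"]] <- config$linf_density
  par
}

#' Simulate a mark-recapture growth dataset with known truth
#'
#' Draws standardized random effects `(u, v)` from a bivariate standard
#' normal with correlation `re_correlation`, builds each fish's `(k, L_inf)`
#' through the log link (via [individual_params()]), truncates each fish's
#' history by size-independent annual survival, retains each sampling
#' occasion independently with probability `capture_prob`, and adds Gaussian
#' measurement error to the von Bertalanffy lengths. Fish with no retained
#' captures are dropped (and counted). The same seed reproduces the dataset
#' exactly.
#'
#' @param config A [sim_config()].
#' @return A list of class `vbgf_sim` with `data` (a [growth_data()] with
#'   covariates) and `truth` — a list carrying the generating parameter
#'   vector `theta` (in the fitted-model layout), the per-fish effects table
#'   (`u`, `v`, `k`, `linf`, `max_age`), the implied [vb_model_spec()], the
#'   config, and `n_dropped`.
#' @examples
#' sim <- simulate_growth(sim_config(n_fish = 20, seed = 1))
#' sim$data
#' @export
simulate_growth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  J <- length(config$cohorts)
  n_total <- sum(config$n_fish)
  cohort_of <- rep(config$cohorts, config$n_fish)
  density_of <- rep(config$density, config$n_fish)
  fish_id <- sprintf("f%04d", seq_len(n_total))

  # `re_correlation` targets the Pearson correlation between L_inf and k at
  # the individual level; convert to the normal-scale correlation of (u, v)
  # (inverse of the bivariate-lognormal correlation map; identical at r = 0
  # and nearly identical for small sigmas).
  rho <- lognormal_to_normal_corr(config$re_correlation,
                                  config$sigma_u, config$sigma_v)
  z1 <- rnorm(n_total); z2 <- rnorm(n_total)
  u <- z1
  v <- rho * z1 + sqrt(1 - rho^2) * z2

  lvls <- sort(config$cohorts)
  zero_eff <- setNames(rep(0, J), config$cohorts)
  pred_k <- linear_predictor(log(config$k),
    cohort_effects = if (!is.null(config$k_cohort)) config$k_cohort[lvls],
    density_coef = config$k_density, sd_random = config$sigma_u)
  pred_linf <- linear_predictor(log(config$linf),
    cohort_effects = if (!is.null(config$linf_cohort)) config$linf_cohort[lvls],
    density_coef = config$linf_density, sd_random = config$sigma_v)
  pars <- individual_params(pred_k, pred_linf, config$t0,
                            cohort_id = cohort_of, density = density_of,
                            u = u, v = v)

  max_sample_age <- max(config$ages)
  max_age <- if (config$annual_survival < 1) {
    pmin(max_sample_age, 1 + rgeom(n_total, 1 - config$annual_survival))
  } else {
    rep(max_sample_age, n_total)
  }

  occasions <- tidyr::expand_grid(idx = seq_len(n_total), age = config$ages)
  occasions <- occasions[occasions$age <= max_age[occasions$idx], ]
  keep <- runif(nrow(occasions)) < config$capture_prob
  occasions <- occasions[keep, ]
  mu <- vbgf_length(occasions$age, pars$linf[occasions$idx],
                    pars$k[occasions$idx], config$t0)
  len <- mu + rnorm(nrow(occasions), sd = config$sigma_eps)

  records <- tibble::tibble(
    fish_id = fish_id[occasions$idx],
    cohort_id = cohort_of[occasions$idx],
    age = as.numeric(occasions$age),
    length = len
  )
  observed <- fish_id %in% records$fish_id
  n_dropped <- sum(!observed)
  if (n_dropped > 0) {
    inform(sprintf("%d simulated fish had no retained captures and were dropped.",
                   n_dropped))
  }
  covariates <- tibble::tibble(cohort_id = config$cohorts,
                               density = config$density)
  data <- growth_data(records, covariates)
  effects <- tibble::tibble(
    fish_id = fish_id, cohort_id = cohort_of, u = u, v = v,
    k = pars$k, linf = pars$linf, max_age = max_age, observed = observed
  )
  structure(list(
    data = data,
    truth = list(theta = true_theta(config), effects = effects,
                 spec = config_spec(config), config = config,
                 n_dropped = n_dropped)
  ), class = "vbgf_sim")
}

#' @export
print.vbgf_sim <- function(x, ...) {
  cat("<vbgf_sim>\n")
  print(x$data)
  invisible(x)
}

#' Preset simulation configs emulating stream-salmonid mark-recapture studies
#'
#' Two ready-made [sim_config()]s with 11 year-of-birth cohorts, cohort
#' effects on both growth parameters (negatively correlated across cohorts),
#' positively correlated individual random effects, and survival-truncated
#' capture histories whose capture-count histogram decreases monotonically
#' from a mode at one capture — the sparsity signature of annual
#' electrofishing studies. `"sparse"` mimics a small population (30
#' fish/cohort); `"dense"` a larger one (80 fish/cohort).
#'
#' @param population `"sparse"` or `"dense"`.
#' @param seed Seed stored in the config.
#' @return A [sim_config()].
#' @export
trout_like_preset <- function(population = c("sparse", "dense"), seed = NULL) {
  population <- match.arg(population)
  cohorts <- as.character(1998:2008)
  linf_eff <- setNames(
    c(0, 0.06, -0.05, 0.09, -0.07, 0.03, -0.02, 0.07, -0.09, 0.04, -0.06),
    cohorts)
  k_eff <- setNames(
    c(0, -0.05, 0.06, -0.08, 0.07, -0.02, 0.03, -0.06, 0.08, -0.03, 0.05),
    cohorts)
  density <- c(520, 610, 380, 700, 300, 450, 560, 330, 640, 410, 480)
  sim_config(
    n_fish = if (population == "sparse") 30 else 80,
    cohorts = cohorts, density = density,
    linf = 310, k = 0.33, t0 = -0.6,
    sigma_u = 0.15, sigma_v = 0.12, sigma_eps = 8,
    k_cohort = k_eff, linf_cohort = linf_eff,
    re_correlation = 0.6, ages = 1:9,
    capture_prob = 0.6,
    annual_survival = if (population == "sparse") 0.5 else 0.55,
    seed = seed
  )
}
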