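# Internal machinery mapping a flat parameter vector to the structured model
# quantities (linear predictors per fish, t0, standard deviations) and back.
# Layout: [k block | linf block | t0 | log_sigma_u | log_sigma_v | log_sigma_eps]
# where each block is intercept (+ J-1 cohort effects) (+ density slope).
# Sigmas are optimized on the log scale; t0 is unconstrained.

cohort_levels <- function(data) sort(unique(data$records$cohort_id))

# Precomputed observation/fish arrays shared by all likelihood evaluations.
build_model_frame <- function(data, spec, control) {
  data <- as_growth_data(data)
  records <- data$records  # already sorted by fish_id, age
  fish_ids <- unique(records$fish_id)
  fish_index <- match(records$fish_id, fish_ids)
  counts <- tabulate(fish_index, nbins = length(fish_ids))
  fish_start <- c(0L, cumsum(counts))
  fish_cohort <- records$cohort_id[fish_start[-length(fish_start)] + 1L]
  lvls <- cohort_levels(data)

  uses_density <- spec$k_predictor == "density" || spec$linf_predictor == "density"
  x <- rep(0, length(fish_ids))
  if (uses_density) {
    if (is.null(data$covariates)) {
      abort("Density predictors require a cohort covariate table.",
            class = "vbgrowth_validation_error")
    }
    missing_coh <- setdiff(lvls, data$covariates$cohort_id)
    if (length(missing_coh) > 0) {
      abort(paste0("No density covariate for cohort(s): ",
                   paste(missing_coh, collapse = ", ")),
            class = "vbgrowth_validation_error")
    }
    dens <- data$covariates$density[match(fish_cohort, data$covariates$cohort_id)]
    if (isTRUE(spec$log_density)) {
      if (any(dens <= 0)) {
        abort("log_density requires strictly positive densities.",
              class = "vbgrowth_validation_error")
      }
      dens <- log(dens)
    }
    if (isTRUE(control$center_density)) dens <- dens - mean(dens)
    x <- dens
  }
  list(
    data = data,
    fish_ids = fish_ids,
    fish_cohort = fish_cohort,
    fish_x = x,
    fish_start = as.integer(fish_start),
    age = records$age,
    len = records$length,
    lvls = lvls,
    spec = spec
  )
}

par_names <- function(spec, lvls) {
  block <- function(prefix, p) {
    c(paste0(prefix, "_intercept"),
      if (p == "cohort" && length(lvls) > 1) paste0(prefix, "_cohort_", lvls[-1]),
      if (p == "density") paste0(prefix, "_density"))
  }
  c(block("k", spec$k_predictor), block("linf", spec$linf_predictor), "t0",
    if (spec$random_effects) c("log_sigma_u", "log_sigma_v"),
    "log_sigma_eps")
}

# Split the flat vector into per-fish linear predictors and scalars.
par_split <- function(par, frame) {
  spec <- frame$spec
  lvls <- frame$lvls
  nm <- names(par)
  blk <- function(prefix, p) {
    eta <- rep(par[[paste0(prefix, "_intercept")]], length(frame$fish_ids))
    if (p == "cohort" && length(lvls) > 1) {
      eff <- setNames(c(0, par[paste0(prefix, "_cohort_", lvls[-1])]), lvls)
      eta <- eta + unname(eff[frame$fish_cohort])
    }
    if (p == "density") {
      eta <- eta + par[[paste0(prefix, "_density")]] * frame$fish_x
    }
    eta
  }
  list(
    a = blk("k", spec$k_predictor),
    b = blk("linf", spec$linf_predictor),
    t0 = par[["t0"]],
    su = if (spec$random_effects) exp(par[["log_sigma_u"]]) else 0,
    sv = if (spec$random_effects) exp(par[["log_sigma_v"]]) else 0,
    se = exp(par[["log_sigma_eps"]])
  )
}

# Scale-aware default starting values: asymptote above the largest observed
# fish, k near a typical salmonid value, t0 slightly negative, residual SD
# from a pooled curve fit.
default_start <- function(frame) {
  spec <- frame$spec
  nm <- par_names(spec, frame$lvls)
  par <- setNames(rep(0, length(nm)), nm)
  par[["k_intercept"]] <- log(0.3)
  par[["linf_intercept"]] <- log(1.1 * max(frame$len))
  par[["t0"]] <- -0.5
  sigma_pooled <- tryCatch({
    nls_fit <- fit_growth_nls(frame$age, frame$len)
    max(nls_fit$sigma, 1e-2)
  }, error = function(e) max(sd(frame$len) / 4, 1e-2))
  par[["log_sigma_eps"]] <- log(sigma_pooled)
  if (spec$random_effects) {
    par[["log_sigma_u"]] <- log(0.1)
    par[["log_sigma_v"]] <- log(0.1)
  }
  par
}

# Loose, scientifically motivated box bounds keeping the outer optimizer out
# of degenerate regions (e.g. k -> 0 with sigma_eps absorbing all variation).
par_bounds <- function(nm) {
  lb <- setNames(rep(-10, length(nm)), nm)
  ub <- setNames(rep(10, length(nm)), nm)
  lb[nm == "k_intercept"] <- log(1e-3); ub[nm == "k_intercept"] <- log(10)
  lb[nm == "linf_intercept"] <- log(10); ub[nm == "linf_intercept"] <- log(5e3)
  lb[nm == "t0"] <- -10; ub[nm == "t0"] <- 5
  lb[grepl("^log_sigma_[uv]$", nm)] <- -12
  ub[grepl("^log_sigma_[uv]$", nm)] <- 3
  lb[nm == "log_sigma_eps"] <- -8; ub[nm == "log_sigma_eps"] <- 8
  list(lower = lb, upper = ub)
}

# Cohort-level (k, linf) with random effects set to 0, for mean trajectories.
cohort_mean_params <- function(par, spec, lvls, cohort_id, x = 0) {
  eta <- function(prefix, p) {
    val <- par[[paste0(prefix, "_intercept")]]
    if (p == "cohort" && length(lvls) > 1) {
      eff <- setNames(c(0, par[paste0(prefix, "_cohort_", lvls[-1])]), lvls)
      if (!cohort_id %in% lvls) {
        abort(paste0("Unknown cohort: ", cohort_id))
      }
      val <- val + unname(eff[[cohort_id]])
    }
    if (p == "density") val <- val + par[[paste0(prefix, "_density")]] * x
    val
  }
  c(k = exp(eta("k", spec$k_predictor)),
    linf = exp(eta("linf", spec$linf_predictor)),
    t0 = par[["t0"]])
}
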