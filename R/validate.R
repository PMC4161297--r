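#' Split a dataset for hold-out validation of growth predictions
#'
#' Implements the hold-out protocol for longitudinal growth data: fish
#' sampled more than `min_captures - 1` times are eligible; a seeded uniform
#' sample of `round(fraction * n_eligible)` of them (rounding half away from
#' zero) forms the validation sample; for each sampled fish only the first
#' (lowest-age) observation stays in the training data and every later
#' observation becomes held-out truth. All other fish are fully retained.
#' Training records and held-out records partition the original dataset.
#'
#' @param data A [growth_data()] object.
#' @param min_captures Minimum captures for eligibility (default 4, i.e.
#'   sampled more than 3 times).
#' @param fraction Fraction of eligible fish moved to the validation sample.
#' @param seed RNG seed for the sample.
#' @return A list with `training` (a `growth_data`), `heldout` (tibble of
#'   held-out records), `validation_fish` (ids), `n_eligible`.
#' @export
validation_split <- function(data, min_captures = 4, fraction = 1/3,
                             seed = NULL) {
  data <- as_growth_data(data)
  counts <- capture_counts(data)
  eligible <- counts$fish_id[counts$n_captures >= min_captures]
  if (length(eligible) == 0) {
    abort("No fish eligible for validation (too few captures).",
          class = "vbgrowth_validation_error")
  }
  if (!is.null(seed)) set.seed(seed)
  n_take <- floor(fraction * length(eligible) + 0.5)  # half away from zero
  n_take <- max(1L, min(n_take, length(eligible)))
  chosen <- sample(eligible, n_take)
  rec <- data$records
  in_validation <- rec$fish_id %in% chosen
  first_age <- dplyr::summarise(
    dplyr::group_by(rec[in_validation, ], .data$fish_id),
    first_age = min(.data$age), .groups = "drop"
  )
  fa <- setNames(first_age$first_age, first_age$fish_id)
  heldout_mask <- in_validation & rec$age > fa[rec$fish_id]
  heldout_mask[is.na(heldout_mask)] <- FALSE
  training <- growth_data(rec[!heldout_mask, ], data$covariates)
  list(training = training,
       heldout = tibble::as_tibble(rec[heldout_mask, ]),
       validation_fish = chosen,
       n_eligible = length(eligible))
}

#' Mean length-at-age baseline
#'
#' The non-model benchmark for growth prediction: the arithmetic mean of
#' observed lengths per cohort (or for the population as a whole) at each
#' integer age. Ages are binned to the nearest year, matching annual
#' sampling. Missing (cohort, age) cells fall back to the population mean at
#' that age, then to the nearest age with data.
#'
#' @param data Training data ([growth_data()] or data frame).
#' @param grouping `"cohort"` or `"population"`.
#' @return A tibble of class `vbgf_baseline` with columns `group`, `age`,
#'   `mean_length`, `n`; use [baseline_predict()] to evaluate it.
#' @export
baseline_mean_length_at_age <- function(data,
                                        grouping = c("cohort", "population")) {
  grouping <- match.arg(grouping)
  data <- as_growth_data(data)
  rec <- dplyr::mutate(data$records,
    group = if (grouping == "cohort") .data$cohort_id else "population",
    age_bin = round(.data$age)
  )
  tab <- dplyr::summarise(
    dplyr::group_by(rec, .data$group, .data$age_bin),
    mean_length = mean(.data$length), n = dplyr::n(), .groups = "drop"
  )
  tab <- dplyr::rename(tab, age = "age_bin")
  class(tab) <- c("vbgf_baseline", class(tab))
  attr(tab, "grouping") <- grouping
  tab
}

#' Evaluate a mean length-at-age baseline
#'
#' @param baseline A `vbgf_baseline` from [baseline_mean_length_at_age()].
#' @param cohort_id Cohort label(s) of the records to predict (ignored for a
#'   population baseline).
#' @param age Age(s) of the records to predict, years.
#' @return Predicted lengths, mm, using the fallback chain cell ->
#'   population-at-age -> nearest age.
#' @export
baseline_predict <- function(baseline, cohort_id, age) {
  stopifnot(inherits(baseline, "vbgf_baseline"))
  grouping <- attr(baseline, "grouping")
  n <- max(length(cohort_id), length(age))
  cohort_id <- rep_len(as.character(cohort_id), n)
  age_bin <- round(rep_len(age, n))
  group <- if (grouping == "cohort") cohort_id else rep("population", n)
  key <- paste(baseline$group, baseline$age, sep = "\r")
  pred <- baseline$mean_length[match(paste(group, age_bin, sep = "\r"), key)]
  # fallback 1: population mean at that age
  miss <- is.na(pred)
  if (any(miss)) {
    pop <- dplyr::summarise(
      dplyr::group_by(baseline, .data$age),
      mean_length = sum(.data$mean_length * .data$n) / sum(.data$n),
      .groups = "drop"
    )
    pred[miss] <- pop$mean_length[match(age_bin[miss], pop$age)]
    # fallback 2: nearest available age
    still <- is.na(pred)
    if (any(still)) {
      inform(sprintf("%d prediction(s) used the nearest available age.",
                     sum(still)))
      for (i in which(still)) {
        pred[i] <- pop$mean_length[which.min(abs(pop$age - age_bin[i]))]
      }
    }
  }
  pred
}

#' Prediction-quality metrics against the 1:1 line
#'
#' Mean absolute error (mm) and the R-squared of the 1:1 predicted-observed
#' line, `1 - SS_res / SS_tot`, with residuals taken about the identity
#' prediction and `SS_tot` about the observed mean. The R-squared can be
#' negative when predictions do worse than the observed mean.
#'
#' @param observed,predicted Numeric vectors of equal length (mm).
#' @return A one-row tibble with columns `MAE` and `R2`.
#' @export
prediction_metrics <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  ss_res <- sum((observed - predicted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  tibble::tibble(MAE = mean(abs(observed - predicted)),
                 R2 = 1 - ss_res / ss_tot)
}

#' Hold-out validation of growth predictions
#'
#' Runs the full validation protocol `n_replicates` times: split the data
#' with [validation_split()], refit the model on the training data (the
#' validation fish keep only their first observation, so their random effects
#' are estimated from a single capture), predict every held-out length from
#' the Empirical Bayes individual parameters, and score MAE and R-squared of
#' the 1:1 predicted-observed line. The same held-out records are also scored
#' against the mean length-at-age baseline (cohort means when the model has
#' cohort predictors, population means otherwise).
#'
#' @param data A [growth_data()] object.
#' @param spec Model specification to validate.
#' @param n_replicates Number of random validation samples (default 20).
#' @param control Fit options.
#' @param seed Base seed; replicate r uses `seed + r - 1`.
#' @param min_captures,fraction Passed to [validation_split()].
#' @return A tibble of class `vbgf_validation` with one row per successful
#'   replicate (`seed`, `model_MAE`, `model_R2`, `baseline_MAE`,
#'   `baseline_R2`, `n_heldout`); summary statistics via
#'   [glance.vbgf_validation()]. Failed replicates are skipped with a
#'   warning and counted in attribute `"n_failed"`.
#' @export
validate_growth_model <- function(data, spec = vb_model_spec(),
                                  n_replicates = 20, control = vb_control(),
                                  seed = 1, min_captures = 4,
                                  fraction = 1/3) {
  data <- as_growth_data(data)
  grouping <- if (spec$k_predictor == "cohort" ||
                  spec$linf_predictor == "cohort") "cohort" else "population"
  rows <- list()
  n_failed <- 0
  n_eligible <- NA_integer_
  for (r in seq_len(n_replicates)) {
    rep_seed <- seed + r - 1
    row <- tryCatch({
      split <- validation_split(data, min_captures, fraction, seed = rep_seed)
      n_eligible <- split$n_eligible
      fit <- suppressWarnings(fit_vbgf(split$training, spec, control))
      pred <- predict(fit, split$heldout)
      m_model <- prediction_metrics(split$heldout$length, pred)
      bl <- baseline_mean_length_at_age(split$training, grouping)
      bl_pred <- baseline_predict(bl, split$heldout$cohort_id,
                                  split$heldout$age)
      m_base <- prediction_metrics(split$heldout$length, bl_pred)
      tibble::tibble(
        seed = rep_seed,
        model_MAE = m_model$MAE, model_R2 = m_model$R2,
        baseline_MAE = m_base$MAE, baseline_R2 = m_base$R2,
        n_heldout = nrow(split$heldout)
      )
    }, error = function(e) {
      warn(sprintf("Validation replicate %d failed: %s", r,
                   conditionMessage(e)))
      NULL
    })
    if (is.null(row)) n_failed <- n_failed + 1 else rows[[length(rows) + 1]] <- row
  }
  if (length(rows) == 0) {
    abort("All validation replicates failed.", class = "vbgrowth_fit_error")
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "n_failed") <- n_failed
  attr(out, "n_eligible") <- n_eligible
  attr(out, "grouping") <- grouping
  class(out) <- c("vbgf_validation", class(out))
  out
}

#' @rdname validate_growth_model
#' @param x A `vbgf_validation` table.
#' @param ... Unused.
#' @export
glance.vbgf_validation <- function(x, ...) {
  tibble::tibble(
    n_replicates = nrow(x),
    n_failed = attr(x, "n_failed") %||% 0L,
    model_MAE_mean = mean(x$model_MAE), model_MAE_sd = sd(x$model_MAE),
    model_R2_mean = mean(x$model_R2), model_R2_sd = sd(x$model_R2),
    baseline_MAE_mean = mean(x$baseline_MAE),
    baseline_MAE_sd = sd(x$baseline_MAE),
    baseline_R2_mean = mean(x$baseline_R2),
    baseline_R2_sd = sd(x$baseline_R2)
  )
}

#' Empirical correlation between individual or cohort growth parameters
#'
#' At the individual level, the Pearson correlation between the Empirical
#' Bayes estimates of `L_inf` and `k` across fish, optionally restricted to
#' fish with at least `min_captures` captures — single-capture fish carry an
#' almost perfect artefactual correlation, so filtering matters. At the
#' cohort level, the correlation between cohort mean parameters (random
#' effects 0), available when the fit has cohort predictors on both
#' parameters.
#'
#' @param fit A `vbgf_fit`.
#' @param level `"individual"` or `"cohort"`.
#' @param min_captures Minimum captures filter (individual level only).
#' @return A tibble with `level`, `r`, `p.value`, `n`.
#' @export
empirical_correlation <- function(fit, level = c("individual", "cohort"),
                                  min_captures = 1) {
  stopifnot(inherits(fit, "vbgf_fit"))
  level <- match.arg(level)
  if (level == "individual") {
    eb <- fit$eb[fit$eb$n_captures >= min_captures, ]
    xs <- eb$linf; ys <- eb$k
  } else {
    if (fit$spec$k_predictor != "cohort" || fit$spec$linf_predictor != "cohort") {
      abort("Cohort-level correlation requires cohort predictors on both parameters.")
    }
    pars <- purrr::map(fit$lvls, function(cid) {
      cohort_mean_params(fit$theta, fit$spec, fit$lvls, cid)
    })
    xs <- purrr::map_dbl(pars, "linf"); ys <- purrr::map_dbl(pars, "k")
  }
  if (length(xs) < 3) {
    abort("Need at least 3 points for a correlation.",
          class = "vbgrowth_validation_error")
  }
  if (sd(xs) == 0 || sd(ys) == 0) {
    abort("Correlation undefined: zero variance in a coordinate.",
          class = "vbgrowth_validation_error")
  }
  ct <- cor.test(xs, ys, method = "pearson")
  tibble::tibble(level = level, r = unname(ct$estimate),
                 p.value = ct$p.value, n = length(xs))
}
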