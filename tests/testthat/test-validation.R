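test_that("validation_split eligibility, sizing and partition", {
  # 90 eligible fish (4 captures each) plus ineligible 3-capture fish
  rec <- dplyr::bind_rows(
    tidyr::expand_grid(fish_id = sprintf("e%02d", 1:90), age = 1:4),
    tidyr::expand_grid(fish_id = sprintf("i%02d", 1:20), age = 1:3)
  )
  rec$cohort_id <- "c"
  rec$length <- 100 + 30 * rec$age
  d <- growth_data(rec)
  split <- validation_split(d, seed = 4)
  expect_length(split$validation_fish, 30)          # round(90 / 3)
  expect_equal(split$n_eligible, 90)
  expect_false(any(grepl("^i", split$validation_fish)))  # 3 captures: never
  # partition: training + heldout = original, disjoint
  combined <- dplyr::bind_rows(split$training$records, split$heldout)
  expect_equal(dplyr::arrange(combined, fish_id, age),
               dplyr::arrange(d$records, fish_id, age))
  expect_equal(nrow(split$training$records) + nrow(split$heldout),
               nrow(d$records))
  # each validation fish keeps exactly its first (lowest-age) observation
  kept <- split$training$records[split$training$records$fish_id %in%
                                   split$validation_fish, ]
  expect_true(all(table(kept$fish_id) == 1))
  expect_true(all(kept$age == 1))
  # partition holds on every seed
  for (s in 1:5) {
    sp <- validation_split(d, seed = s)
    expect_equal(nrow(sp$training$records) + nrow(sp$heldout), nrow(d$records))
  }
})

test_that("prediction metrics match their definitions", {
  obs <- c(100, 150, 210, 260)
  expect_equal(prediction_metrics(obs, obs), tibble::tibble(MAE = 0, R2 = 1))
  pred <- obs + c(5, -5, 10, -10)
  m <- prediction_metrics(obs, pred)
  expect_equal(m$MAE, 7.5)
  expect_equal(m$R2, 1 - 250 / sum((obs - mean(obs))^2))
  # permutation invariance
  o <- sample(4)
  expect_equal(prediction_metrics(obs[o], pred[o]), m)
})

test_that("baseline mean length-at-age matches hand computation", {
  rec <- tibble::tibble(
    fish_id = paste0("f", 1:6), cohort_id = rep(c("A", "B"), each = 3),
    age = c(1, 1, 2, 1, 2, 2), length = c(100, 110, 160, 120, 170, 190)
  )
  d <- growth_data(rec)
  bl <- baseline_mean_length_at_age(d, "cohort")
  expect_equal(baseline_predict(bl, "A", 1), 105)       # (100 + 110) / 2
  expect_equal(baseline_predict(bl, "A", 2), 160)       # single record cell
  expect_equal(baseline_predict(bl, "B", 2), 180)
  # population grouping ignores cohorts
  blp <- baseline_mean_length_at_age(d, "population")
  expect_equal(baseline_predict(blp, "A", 1), mean(c(100, 110, 120)))
  expect_equal(baseline_predict(blp, "B", 1), mean(c(100, 110, 120)))
  # fallback chain: missing cohort cell -> population mean at age;
  # missing age -> nearest age
  expect_equal(baseline_predict(bl, "B", 1), 120)
  expect_message(far <- baseline_predict(bl, "A", 7), "nearest")
  expect_equal(far, mean(c(160, 170, 190)))
})

test_that("baseline R2 on constant-cohort training data is the variance ratio", {
  rec <- tibble::tibble(
    fish_id = paste0("f", 1:4), cohort_id = rep(c("A", "B"), each = 2),
    age = 1, length = c(100, 110, 200, 190)
  )
  d <- growth_data(rec)
  bl <- baseline_mean_length_at_age(d, "cohort")
  pred <- baseline_predict(bl, rec$cohort_id, rec$age)
  m <- prediction_metrics(rec$length, pred)
  ss_tot <- sum((rec$length - mean(rec$length))^2)
  ss_within <- sum((rec$length - pred)^2)
  expect_equal(m$R2, 1 - ss_within / ss_tot)
  expect_equal(m$R2, (ss_tot - ss_within) / ss_tot)  # between / total
})

test_that("hold-out validation runs replicates and summarizes them", {
  sim <- simulate_growth(sim_config(n_fish = 150, seed = 19))
  val <- suppressWarnings(
    validate_growth_model(sim$data, n_replicates = 3, seed = 10)
  )
  expect_s3_class(val, "vbgf_validation")
  expect_equal(nrow(val), 3)
  expect_equal(val$seed, 10:12)
  expect_true(all(val$model_MAE >= 0))
  g <- glance(val)
  expect_equal(g$model_MAE_mean, mean(val$model_MAE))
  expect_equal(g$model_MAE_sd, sd(val$model_MAE))
  # direction: EB individual curves beat the population mean length-at-age
  expect_lt(g$model_MAE_mean, g$baseline_MAE_mean)
})

test_that("empirical correlation filters captures and validates input", {
  # sparse histories: the single-capture inflation is a sparsity phenomenon
  sim <- suppressMessages(simulate_growth(
    sim_config(n_fish = 300, re_correlation = 0.6, capture_prob = 0.4,
               annual_survival = 0.6, seed = 23)
  ))
  fit <- suppressWarnings(fit_vbgf(sim$data))
  all_r <- empirical_correlation(fit)
  filt <- empirical_correlation(fit, min_captures = 3)
  expect_true(all_r$r > filt$r)   # single-capture fish inflate r
  expect_gt(filt$n, 3)
  expect_lt(all_r$p.value, 0.01)
  # degenerate inputs
  fit2 <- fit
  fit2$eb <- fit$eb[1:2, ]
  expect_error(empirical_correlation(fit2), "at least 3")
  fit3 <- fit
  fit3$eb$linf <- 300
  expect_error(empirical_correlation(fit3), "zero variance")
  expect_error(empirical_correlation(fit, "cohort"), "cohort predictors")
})
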