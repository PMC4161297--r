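test_that("noiseless single-curve data are recovered exactly without random effects", {
  d <- exact_curve_data()
  fit <- suppressWarnings(
    fit_vbgf(d, vb_model_spec(random_effects = FALSE))
  )
  expect_equal(exp(fit$theta[["linf_intercept"]]), 330, tolerance = 1e-4)
  expect_equal(exp(fit$theta[["k_intercept"]]), 0.37, tolerance = 1e-4)
  expect_equal(fit$theta[["t0"]], -0.38, tolerance = 1e-4)
  expect_equal(fit$n_parameters, 4L)  # two intercepts, t0, sigma_eps
})

test_that("fit_vbgf matches a black-box optimizer on the quadrature oracle", {
  sim <- simulate_growth(sim_config(n_fish = 30, ages = 1:7, seed = 77))
  fit <- suppressWarnings(fit_vbgf(sim$data))
  rec <- sim$data$records
  by_fish <- split(rec[, c("age", "length")], rec$fish_id)
  warm <- lapply(by_fish, function(x) c(0, 0))
  oracle_obj <- function(p) {
    tot <- 0
    for (id in names(by_fish)) {
      x <- by_fish[[id]]
      val <- oracle_gh_marginal_nll(x$age, x$length, p[1], p[2], p[3],
                                    exp(p[4]), exp(p[5]), exp(p[6]),
                                    n_nodes = 10, start = warm[[id]])
      tot <- tot + val
    }
    tot
  }
  p0 <- fit$theta + 0.05
  opt <- nlminb(p0, oracle_obj,
                control = list(iter.max = 200, rel.tol = 1e-10))
  expect_lt(max(abs(opt$par - fit$theta)), 1e-2)
})

test_that("multi-start fits agree and ties are resolved deterministically", {
  sim <- simulate_growth(sim_config(n_fish = 40, ages = 1:6, seed = 21))
  f1 <- suppressWarnings(fit_vbgf(sim$data, control = vb_control(starts = 3, seed = 1)))
  f2 <- suppressWarnings(fit_vbgf(sim$data))
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-5)
  expect_lt(max(abs(f1$theta - f2$theta)), 1e-3)
})

test_that("EB modes shrink toward zero and grow with replicated data", {
  a <- log(0.37); b <- log(330)
  # an observation 40 mm above the population curve at age 3
  age <- 3; len <- vbgf_length(age, 330, 0.37, -0.38) + 40
  reps <- c(1, 2, 4, 8)
  vmodes <- vapply(reps, function(m) {
    inner_mode(rep(age, m) + seq_len(m) * 1e-9, rep(len, m),
               a, b, -0.38, 0.22, 0.22, 8)$mode[2]
  }, numeric(1))
  expect_true(all(vmodes > 0))
  expect_true(all(diff(vmodes) > 0))  # more data, less shrinkage
  # fish exactly on the population curve has mode (0, 0)
  on_curve <- inner_mode(c(2, 5), vbgf_length(c(2, 5), 330, 0.37, -0.38),
                         a, b, -0.38, 0.22, 0.22, 8)
  expect_lt(max(abs(on_curve$mode)), 1e-8)
})

test_that("EB modes are standard-normal-like at the true parameters", {
  sim <- simulate_growth(sim_config(n_fish = 500, seed = 55))
  res <- laplace_negloglik(sim$data, theta_no_pred())
  expect_lt(abs(mean(res$modes$u)), 0.1)
  expect_lt(abs(mean(res$modes$v)), 0.1)
  expect_gt(sd(res$modes$v), 0.8)   # shrinkage keeps SD at or below 1
  expect_lt(sd(res$modes$v), 1.1)
})

test_that("standard errors shrink at the root-n rate", {
  width <- vapply(c(100, 400), function(n) {
    sim <- simulate_growth(sim_config(n_fish = n, seed = 400 + n))
    fit <- suppressWarnings(fit_vbgf(sim$data))
    ti <- tidy(fit)
    row <- ti[ti$term == "linf_intercept", ]
    expect_true(all(ti$conf.low < ti$estimate & ti$estimate < ti$conf.high))
    row$conf.high - row$conf.low
  }, numeric(1))
  expect_gt(width[1] / width[2], 1.4)
  expect_lt(width[1] / width[2], 2.9)
})

test_that("predictions use EB individual curves with cohort fallback", {
  sim <- simulate_growth(sim_config(n_fish = 120, seed = 66))
  fit <- suppressWarnings(fit_vbgf(sim$data))
  eb <- eb_random_effects(fit)
  # per-fish prediction is the vBGF at the EB parameters
  id <- eb$fish_id[which.max(eb$n_captures)]
  row <- eb[eb$fish_id == id, ]
  expect_equal(predict_lengths(fit, id, ages = c(2, 6)),
               vbgf_length(c(2, 6), row$linf, row$k, fit$theta[["t0"]]))
  # unknown fish: error without cohort, mean curve with cohort
  expect_error(predict_lengths(fit, "nope", ages = 3), "not in the fitted")
  mean_pred <- predict_lengths(fit, ages = 3, cohort_id = fit$lvls[1])
  p <- c(k = exp(fit$theta[["k_intercept"]]),
         linf = exp(fit$theta[["linf_intercept"]]))
  expect_equal(mean_pred,
               vbgf_length(3, p[["linf"]], p[["k"]], fit$theta[["t0"]]))
  # strongly deviating fish are predicted better by their own curves
  truth <- sim$truth$effects
  ids <- truth$fish_id[abs(truth$u) > 1 & abs(truth$v) > 1 & truth$observed]
  ids <- intersect(ids, eb$fish_id[eb$n_captures >= 2])
  rec <- sim$data$records[sim$data$records$fish_id %in% ids, ]
  model_pred <- predict(fit, rec)
  cohort_pred <- predict_lengths(fit, ages = rec$age, cohort_id = fit$lvls[1])
  expect_lt(mean(abs(rec$length - model_pred)),
            mean(abs(rec$length - cohort_pred)))
})

test_that("Monte Carlo confidence bands nest and collapse correctly", {
  sim <- simulate_growth(sim_config(n_fish = 100, seed = 88))
  fit <- suppressWarnings(fit_vbgf(sim$data))
  ages <- 1:8
  b95 <- mc_confidence_bands(fit, ages, n_draws = 400, seed = 1)
  b99 <- mc_confidence_bands(fit, ages, n_draws = 400, level = 0.99, seed = 1)
  expect_true(all(b99$lower <= b95$lower + 1e-9))
  expect_true(all(b99$upper >= b95$upper - 1e-9))
  expect_true(all(b95$lower < b95$estimate & b95$estimate < b95$upper))
  # vanishing parameter uncertainty collapses the band onto the mean curve
  fit0 <- fit
  fit0$vcov <- fit$vcov * 1e-18
  b0 <- mc_confidence_bands(fit0, ages, n_draws = 100, seed = 1)
  expect_lt(max(b0$upper - b0$lower), 1e-3)
  # unavailable Hessian is an explicit error
  fit0$vcov <- NULL
  expect_error(mc_confidence_bands(fit0, ages), class = "vbgrowth_se_error")
  expect_error(standard_errors(fit0), class = "vbgrowth_se_error")
})
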