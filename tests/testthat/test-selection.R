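test_that("parameter counts reproduce the nine-model grid", {
  grid <- model_spec_grid()
  expect_length(grid, 9)
  counts <- vapply(grid, count_parameters, integer(1), n_cohorts = 11)
  expect_equal(counts, c(6L, 7L, 16L, 7L, 16L, 26L, 17L, 8L, 17L))
  expect_error(count_parameters(grid[[1]], 0))
})

test_that("counts equal the free parameter vector length for every spec", {
  for (J in c(2, 5, 11)) {
    lvls <- paste0("c", seq_len(J))
    for (spec in model_spec_grid()) {
      expect_equal(count_parameters(spec, J),
                   length(vbgrowth:::par_names(spec, lvls)))
    }
  }
})

test_that("information criteria behave as definitions require", {
  # AIC differences are invariant to a common log-likelihood shift
  expect_equal(vb_aic(-120, 6) - vb_aic(-130, 8),
               vb_aic(-120 + 55, 6) - vb_aic(-130 + 55, 8))
  expect_equal(vb_aic(0, 6), 12)
  expect_equal(vb_bic(0, 6, 100), 6 * log(100))
})

test_that("selection table covers the grid with a zero-delta best row", {
  cfg <- sim_config(n_fish = 35, cohorts = c("2000", "2001", "2002"),
                    density = c(300, 600, 450),
                    k_cohort = c(`2000` = 0, `2001` = -0.12, `2002` = 0.1),
                    linf_cohort = c(`2000` = 0, `2001` = 0.1, `2002` = -0.08),
                    ages = 1:7, seed = 12)
  sim <- simulate_growth(cfg)
  sel <- suppressWarnings(select_growth_models(sim$data))
  expect_s3_class(sel, "vbgf_selection")
  expect_equal(nrow(sel), 9)
  expect_equal(min(sel$delta_AIC), 0)
  expect_false(is.unsorted(sel$AIC))
  expect_equal(sel$n_parameters[sel$model == "no predictors"], 6L)
  fit_best <- best_model(sel)
  expect_s3_class(fit_best, "vbgf_fit")
  # the table round-trips through its delimited export
  path <- withr::local_tempfile(fileext = ".csv")
  write_selection_table(sel, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(back$AIC, sel$AIC, tolerance = 1e-8)
})

test_that("AIC selects cohort models when cohorts truly differ", {
  wins <- 0
  for (s in 1:10) {
    cfg <- sim_config(n_fish = 25, cohorts = paste0("c", 1:4),
                      k_cohort = setNames(c(0, -0.15, 0.12, -0.08), paste0("c", 1:4)),
                      linf_cohort = setNames(c(0, 0.12, -0.1, 0.08), paste0("c", 1:4)),
                      ages = 1:7, seed = 600 + s)
    sim <- simulate_growth(cfg)
    f_coh <- suppressWarnings(fit_vbgf(sim$data, vb_model_spec("cohort", "cohort")))
    f_none <- suppressWarnings(fit_vbgf(sim$data))
    if (vb_aic(f_coh$loglik, f_coh$n_parameters) <
        vb_aic(f_none$loglik, f_none$n_parameters)) wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("density models outrank cohort models when density drives growth", {
  delta <- vapply(1:10, function(s) {
    cfg <- sim_config(n_fish = 20, cohorts = paste0("c", 1:4),
                      density = c(200, 450, 700, 950),
                      k_density = -4e-4, linf_density = -2e-4,
                      ages = 1:7, seed = 700 + s)
    sim <- simulate_growth(cfg)
    f_d <- suppressWarnings(fit_vbgf(sim$data, vb_model_spec("density", "density")))
    f_c <- suppressWarnings(fit_vbgf(sim$data, vb_model_spec("cohort", "cohort")))
    vb_aic(f_d$loglik, f_d$n_parameters) - vb_aic(f_c$loglik, f_c$n_parameters)
  }, numeric(1))
  expect_lt(mean(delta), 0)
})

test_that("density centering changes neither likelihood nor AIC ranking", {
  cfg <- sim_config(n_fish = 30, cohorts = c("a", "b", "c"),
                    density = c(250, 500, 800), k_density = -3e-4,
                    ages = 1:6, seed = 41)
  sim <- simulate_growth(cfg)
  spec <- vb_model_spec("density", "density")
  f_raw <- suppressWarnings(fit_vbgf(sim$data, spec))
  f_ctr <- suppressWarnings(fit_vbgf(sim$data, spec,
                                     vb_control(center_density = TRUE)))
  expect_equal(f_raw$loglik, f_ctr$loglik, tolerance = 1e-6)
  # slopes agree; intercepts differ by slope * mean(density) as expected
  expect_equal(f_raw$theta[["k_density"]], f_ctr$theta[["k_density"]],
               tolerance = 1e-3)
})
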