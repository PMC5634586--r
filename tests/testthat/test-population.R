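test_that("parameter draws are deterministic in (seed, draw_index)", {
  spec <- population_spec(n_models = 20, seed = 7)
  expect_identical(sample_parameters(spec, 3), sample_parameters(spec, 3))
  expect_false(identical(sample_parameters(spec, 3),
                         sample_parameters(spec, 4)))
  expect_false(identical(sample_parameters(spec, 3),
                         sample_parameters(population_spec(20, seed = 8), 3)))
  # drawing must not disturb the global RNG stream
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(sample_parameters(spec, 1))
  expect_identical(runif(1), before)
  expect_error(sample_parameters(spec, 21), "draw_index")
})

test_that("draws respect the invariants and the degenerate limits", {
  spec <- population_spec(n_models = 200, seed = 5, cv = 0.3)
  for (i in c(1, 50, 200)) {
    p <- sample_parameters(spec, i)
    expect_s3_class(p, "easi_params")                 # validated on creation
    expect_true(p$max_decline >= p$normal_decline)
  }
  # zero dispersion: every draw is exactly the scenario-1 center
  spec0 <- population_spec(n_models = 5, seed = 5, cv = 0)
  center <- builtin_params("scenario", 1)
  for (i in 1:5) expect_equal(sample_parameters(spec0, i), center)
  # non-smoker populations have the exposure stage zeroed for every draw
  specn <- population_spec(n_models = 50, seed = 5, smoker = FALSE)
  for (i in c(1, 25, 50)) {
    p <- sample_parameters(specn, i)
    expect_identical(p$max_exposure, 0)
    expect_false(p$smoker_flag)
  }
  expect_error(population_spec(dispersion = data.frame(
    param = "fev1_at_20", center = 4, cv = 0.1, lower = 5, upper = 3)),
    "truncation")
})

test_that("an ensemble of one with zero dispersion equals the single run", {
  spec <- population_spec(n_models = 1, seed = 3, cv = 0)
  ens <- run_ensemble(spec)
  tr <- scenario_traj(1)
  on_grid <- tr[abs(tr$age - round(tr$age)) < 1e-9, ]
  expect_equal(ens$summary$mean_fev1_L, on_grid$fev1_L, tolerance = 1e-12)
  expect_identical(ens$summary$sd_fev1_L, rep(0, nrow(ens$summary)))
  expect_equal(ens$mean_decline_ml_yr,
               1000 * (traj_value(tr, 25, "fev1_L") -
                         traj_value(tr, 80, "fev1_L")) / 55,
               tolerance = 1e-12)
})

test_that("seeded ensembles are bitwise reproducible", {
  spec <- population_spec(n_models = 40, seed = 11)
  e1 <- run_ensemble(spec)
  e2 <- run_ensemble(spec)
  expect_identical(e1$summary, e2$summary)
  expect_identical(e1$decline_ml_yr, e2$decline_ml_yr)
  expect_identical(e1$fev1_at_age, e2$fev1_at_age)
  e3 <- run_ensemble(population_spec(n_models = 40, seed = 12))
  expect_false(identical(e1$summary, e3$summary))
})

test_that("ensemble dispersion is zero exactly when all CVs are zero", {
  z <- run_ensemble(population_spec(n_models = 10, seed = 2, cv = 0))
  expect_true(all(z$summary$sd_fev1_L == 0))
  d <- run_ensemble(population_spec(n_models = 10, seed = 2, cv = 0.15))
  expect_true(any(d$summary$sd_fev1_L > 0))
})

test_that("a degenerate non-smoking cohort declines at the normal rate", {
  ens <- run_ensemble(population_spec(n_models = 3, seed = 1, smoker = FALSE,
                                      cv = 0))
  # independent oracle: Euler product at the constant 30 ml/yr initial-slope
  # rate, F(80) = 4 * (1 - 0.2 * 30/4000)^((80-25)/0.2)
  f80 <- 4 * (1 - 0.2 * 30 / 4000)^(55 / 0.2)
  expect_equal(ens$mean_decline_ml_yr, 1000 * (4 - f80) / 55,
               tolerance = 1e-9)
  expect_true(all(ens$summary$sd_fev1_L == 0))
})

test_that("smoking shifts the cohort FEV1 distribution downward", {
  smoke <- run_ensemble(population_spec(n_models = 150, seed = 21))
  clean <- run_ensemble(population_spec(n_models = 150, seed = 21,
                                        smoker = FALSE))
  adult <- smoke$summary$age >= 25
  expect_true(all(clean$summary$mean_fev1_L[adult] >=
                    smoke$summary$mean_fev1_L[adult]))
  expect_gt(fraction_below_lln(smoke, 60), fraction_below_lln(clean, 60))
})

test_that("the LLN fraction reads off the stored FEV1 distribution", {
  # degenerate non-smokers sit on the reference: nobody below 80% of it
  clean0 <- run_ensemble(population_spec(n_models = 3, seed = 1,
                                         smoker = FALSE, cv = 0))
  expect_identical(fraction_below_lln(clean0, 60), 0)
  # degenerate susceptible smokers are all far below it by 60
  smoke0 <- run_ensemble(population_spec(n_models = 3, seed = 1, cv = 0))
  expect_identical(fraction_below_lln(smoke0, 60), 1)
  expect_lt(traj_value(scenario_traj(1), 60, "fev1_pct_ref"), 80)
  expect_error(fraction_below_lln(smoke0, 60.5), "grid")
  expect_length(ensemble_fev1(smoke0, 60), 3)
})

test_that("calibration recovers self-generated targets and is reproducible", {
  truth <- population_spec(n_models = 60, seed = 19, cv = 0.15)
  ens <- run_ensemble(truth)
  keep <- ens$summary$age %in% c(30, 50, 70)
  targets <- data.frame(age = ens$summary$age[keep],
                        mean_fev1_L = ens$summary$mean_fev1_L[keep],
                        sd_fev1_L = ens$summary$sd_fev1_L[keep])
  start <- population_spec(n_models = 60, seed = 19, cv = 0.40)
  cal <- calibrate_population(start, targets,
                              decline_target = ens$mean_decline_ml_yr,
                              budget = 30, step_sd = 0.3)
  expect_true(cal$improved)
  expect_lt(cal$loss, 0.1 * cal$initial_loss)
  expect_lt(abs(cal$spec$cv - 0.15), 0.08) # dispersion recovered
  # and the calibrated ensemble decline sits within Monte Carlo error
  recal <- run_ensemble(cal$spec)
  expect_lt(abs(recal$mean_decline_ml_yr - ens$mean_decline_ml_yr), 5)
  # deterministic given the seed
  cal2 <- calibrate_population(start, targets,
                               decline_target = ens$mean_decline_ml_yr,
                               budget = 30, step_sd = 0.3)
  expect_identical(cal$theta, cal2$theta)
  expect_identical(cal$trace, cal2$trace)
})

test_that("a search that cannot improve returns its input with a diagnostic", {
  truth <- population_spec(n_models = 30, seed = 4, cv = 0.15)
  ens <- run_ensemble(truth)
  targets <- data.frame(age = c(40, 60),
                        mean_fev1_L = ens$summary$mean_fev1_L[
                          ens$summary$age %in% c(40, 60)])
  cal <- calibrate_population(truth, targets, budget = 5)
  expect_identical(cal$initial_loss, 0)   # common random numbers: exact match
  expect_false(cal$improved)
  expect_match(cal$message, "without improvement")
  expect_identical(cal$spec$cv, truth$cv)
  expect_error(calibrate_population(truth, targets[0, ], budget = 2),
               "non-empty")
})
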