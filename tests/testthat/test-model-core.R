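test_that("activity target gates at the trigger and keeps a persistence floor", {
  p <- builtin_params("scenario", 1)
  expect_identical(activity_target(0, 0, p), 0)      # never smoked
  expect_identical(activity_target(0.3, 0, p), 0)    # at the trigger
  expect_gt(activity_target(1.5, 0, p), 0.9)
  # after quitting, activity is floored at persistence * peak
  p4 <- builtin_params("scenario", 4) # persistence 0.40
  expect_equal(activity_target(0, 0.9, p4), 0.36, tolerance = 1e-12)
  # the floor never lowers a supra-threshold response
  expect_equal(activity_target(1.5, 1, p4),
               activity_target(1.5, 0, p4), tolerance = 1e-12)
})

test_that("decline rate is exactly normal below the trigger, logistic above", {
  p <- builtin_params("scenario", 1) # normal 30, max 100, trigger 0.1, slope 2
  expect_identical(decline_rate(0, p), 30)
  expect_identical(decline_rate(0.1, p), 30)
  expect_equal(decline_rate(0.917, p), 30 + 70 / (1 + exp(-2 * (0.917 - 0.1))),
               tolerance = 1e-12)
  expect_equal(round(decline_rate(0.917, p), 1), 88.6)
  # saturation towards max_decline at steep slope
  steep <- easi_params(age_smoking_onset = 15, max_exposure = 1.5,
                       time_to_max_exposure = 5, severity_slope = 500)
  expect_equal(decline_rate(1, steep), 100, tolerance = 1e-6)
  A <- seq(0, 1, by = 0.01)
  expect_true(all(decline_rate(A, p) >= 30 & decline_rate(A, p) <= 100))
  expect_error(decline_rate(1.2, p), "\\[0, 1\\]")
})

test_that("reference trajectory holds its plateau then decays exponentially", {
  cc <- easi_constants()
  expect_identical(reference_fev1(20, cc), 4.0)
  expect_identical(reference_fev1(25, cc), 4.0)
  expect_equal(reference_fev1(80, cc), 4 * exp(-(30 / 4000) * 55),
               tolerance = 1e-12)
  expect_equal(round(reference_fev1(80, cc), 3), 2.648)
  expect_error(reference_fev1(95, cc), "window")
  expect_error(reference_fev1(5, cc), "window")
})

test_that("impact target is a shallow decreasing logistic of %ref", {
  p <- builtin_params("scenario", 1) # trigger 0.80, slope 2
  expect_equal(impact_target(0.80, p), 0.5)
  expect_equal(impact_target(0.45, p), 1 / (1 + exp(-0.7)), tolerance = 1e-12)
  expect_equal(round(impact_target(0.45, p), 3), 0.668)
  # a poor perceiver (trigger 0.50) feels less at the same lung function
  poor <- builtin_params("scenario", 6)
  expect_lt(impact_target(0.80, poor), impact_target(0.80, p))
  expect_error(impact_target(0, p), "> 0")
})

test_that("one Euler step leaves the dormant stages of a never-smoker alone", {
  p <- never_smoker_params()
  cc <- easi_constants()
  s <- easi_state(age = 15, E = 0, C = 0, A = 0, A_peak = 0, fev1 = 4, I = 0)
  s2 <- step_state(s, p, cc)
  expect_equal(s2$age, 15.2)
  expect_identical(s2$E, 0)
  expect_identical(s2$C, 0)
  expect_identical(s2$A, 0)
  expect_identical(s2$fev1, 4) # before the plateau end: no decline of any kind
  # impact relaxes towards its (nonzero) healthy-lung steady state
  expect_equal(s2$I, 0.2 * impact_target(1, p), tolerance = 1e-12)
})

test_that("activity relaxation matches its discrete closed form exactly", {
  p <- builtin_params("scenario", 1)
  cc <- easi_constants()
  # hold the system where exposure is flat at max: target is constant
  target <- activity_target(exposure_at(40, p), 0.2, p)
  s <- easi_state(age = 40, E = exposure_at(40, p), C = 10, A = 0.2,
                  A_peak = 0.2, fev1 = 3, I = 0.3)
  A <- numeric(51)
  A[1] <- s$A
  for (k in 1:50) {
    s <- step_state(s, p, cc)
    A[k + 1] <- s$A
  }
  n <- 0:50
  closed <- target + (0.2 - target) * (1 - cc$dt / cc$tau_activity)^n
  expect_equal(A, closed, tolerance = 1e-9)
  # after five relaxation times the state is within 1% of its target
  expect_lt(abs(A[26] - target), 0.01)
})

test_that("the integrator and the single-step operator agree step by step", {
  p <- builtin_params("scenario", 2) # quitter: exercises the hysteresis floor
  cc <- easi_constants()
  tr <- simulate_individual(p, cc)
  s <- easi_state(age = cc$sim_start_age, E = exposure_at(cc$sim_start_age, p),
                  C = 0, A = 0, A_peak = 0, fev1 = p$fev1_at_20, I = 0)
  got <- matrix(0, nrow(tr), 5)
  for (i in seq_len(nrow(tr))) {
    got[i, ] <- c(s$E, s$C, s$A, s$fev1, s$I)
    if (i < nrow(tr)) s <- step_state(s, p, cc)
  }
  # tolerance admits last-ulp drift from the accumulated vs gridded age
  want <- cbind(tr$exposure_packs_day, tr$pack_years, tr$activity,
                tr$fev1_L, tr$impact)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("trajectories satisfy the state invariants for all ten builtins", {
  all_params <- c(lapply(1:6, function(i) builtin_params("scenario", i)),
                  lapply(1:4, function(i) builtin_params("patient", i)))
  cc <- easi_constants()
  for (p in all_params) {
    tr <- simulate_individual(p, cc)
    expect_equal(nrow(tr), 401)
    expect_equal(diff(tr$age), rep(cc$dt, 400), tolerance = 1e-9)
    expect_true(all(tr$activity >= 0 & tr$activity <= 1))
    expect_true(all(tr$impact >= 0 & tr$impact <= 1))
    expect_true(all(tr$fev1_L > 0))
    expect_true(all(diff(tr$pack_years) >= 0))
    post <- tr$age >= cc$plateau_end_age
    expect_true(all(diff(tr$fev1_L[post]) <= 1e-12))
  }
})

test_that("downstream parameters cannot perturb upstream stages", {
  base <- scenario_traj(1)
  # impact parameters leave E, C, A and FEV1 bit-identical
  p_imp <- builtin_params("scenario", 1)
  p_imp$impact_trigger <- 0.5
  p_imp$impact_slope <- 7
  tr_imp <- simulate_individual(p_imp)
  for (col in c("exposure_packs_day", "pack_years", "activity", "fev1_L")) {
    expect_identical(tr_imp[[col]], base[[col]])
  }
  expect_false(identical(tr_imp$impact, base$impact))
  # severity parameters leave E, C and A bit-identical
  p_sev <- builtin_params("scenario", 1)
  p_sev$max_decline <- 60
  p_sev$severity_slope <- 5
  tr_sev <- simulate_individual(p_sev)
  for (col in c("exposure_packs_day", "pack_years", "activity")) {
    expect_identical(tr_sev[[col]], base[[col]])
  }
  expect_false(identical(tr_sev$fev1_L, base$fev1_L))
})

test_that("halving the Euler step moves FEV1 at 80 by at most 10 ml", {
  fine <- easi_constants(dt = 0.1)
  for (i in 1:6) {
    f02 <- traj_value(scenario_traj(i), 80, "fev1_L")
    f01 <- traj_value(scenario_traj(i, fine), 80, "fev1_L")
    expect_lt(abs(f02 - f01) * 1000, 10)
  }
})

test_that("a never-smoker with normal lungs tracks the reference everywhere", {
  tr <- simulate_individual(never_smoker_params())
  expect_true(all(abs(tr$fev1_pct_ref - 100) <= 0.1))
})

test_that("the model refuses to leave its validity domain", {
  cc <- easi_constants()
  p <- easi_params(age_smoking_onset = 15, max_exposure = 1.5,
                   time_to_max_exposure = 5, max_decline = 30000)
  s <- easi_state(age = 40, E = 1.5, C = 30, A = 1, A_peak = 1,
                  fev1 = 2, I = 0.5)
  expect_error(step_state(s, p, cc), "non-positive")
  expect_error(step_state(easi_state(age = 90, E = 0, fev1 = 4),
                          never_smoker_params(), cc), "window")
})
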