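# Stage equations and the fixed-step Euler integrator.
#
# Exposure is a closed-form product of two logistics in time; Activity and
# Impact relax towards logistic steady-state targets through first-order
# linear ODEs; Severity is the first-order linear decline law
# dF/dt = -(r(A)/F20) * F, so the ml/yr rates of the parameter table are
# initial-slope rates at F = fev1_at_20.

# Fully vectorized exposure kernel; recycles over ages or over parameter
# vectors. The onset / quitting logistics are parameterized by their 5%->95%
# span, centred mid-window.
exposure_core <- function(age, smoker, onset, ttm, quit_age, ttq, emax) {
  k <- 2 * log(19) # slope such that the logistic spans 0.05..0.95 over +/- 1/2
  l_on <- stats::plogis((k / ttm) * (age - (onset + ttm / 2)))
  l_off <- ifelse(is.na(quit_age), 1,
                  stats::plogis(-(k / ttq) * (age - (quit_age + ttq / 2))))
  val <- emax * l_on * ifelse(is.na(l_off), 1, l_off)
  ifelse(rep_len(smoker & emax > 0, length(val)), val, 0)
}

#' Smoking exposure at a given age
#'
#' Daily smoking dose E(t), modeled as the product of two logistic functions
#' of time: a rising one spanning 5% to 95% of `max_exposure` over
#' `[age_smoking_onset, age_smoking_onset + time_to_max_exposure]`, and for
#' quitters a mirrored falling one spanning
#' `[age_quitting, age_quitting + time_to_complete_quitting]`. Never-smokers
#' have E identically zero.
#'
#' @param age age(s) in years (vectorized).
#' @param p an [easi_params()] object.
#' @return exposure in packs/day.
#' @examples
#' exposure_at(60, builtin_params("scenario", 1)) # ~1.5 packs/day
#' @export
exposure_at <- function(age, p) {
  validate_params(p)
  if (any(!is.finite(age))) stop("exposure_at(): `age` must be finite",
                                 call. = FALSE)
  exposure_core(age, p$smoker_flag, p$age_smoking_onset,
                p$time_to_max_exposure, p$age_quitting,
                p$time_to_complete_quitting, p$max_exposure)
}

activity_target_core <- function(E, A_peak, trigger, slope, persistence) {
  d <- E - trigger
  g <- ifelse(d <= 0, 0, tanh(slope * d))
  floor <- ifelse(!is.na(persistence) & A_peak > 0, persistence * A_peak, 0)
  pmax(g, floor)
}

#' Steady-state inflammatory activity
#'
#' The activity target is the gated logistic activation of current exposure
#' (exactly zero at or below `activity_trigger`), floored -- once any activity
#' has ever been mounted -- at `persistence_after_quitting` times the running
#' peak activity. The floor implements hysteresis: after smoking cessation a
#' fraction of the maximal inflammatory response can persist indefinitely.
#'
#' @param E current exposure, packs/day.
#' @param A_peak running maximum of activity so far, fraction.
#' @param p an [easi_params()] object.
#' @return target activity, fraction in `[0, 1]`.
#' @export
activity_target <- function(E, A_peak, p) {
  validate_params(p)
  if (any(E < 0)) stop("activity_target(): `E` must be >= 0", call. = FALSE)
  activity_target_core(E, A_peak, p$activity_trigger, p$activity_slope,
                       p$persistence_after_quitting)
}

decline_rate_core <- function(A, trigger, slope, normal, maximal) {
  ifelse(A <= trigger, normal,
         normal + (maximal - normal) * stats::plogis(slope * (A - trigger)))
}

#' FEV1 decline rate as a function of disease activity
#'
#' Threshold dose-response of the Severity stage: at or below
#' `severity_trigger` the decline rate is exactly `normal_decline`; above the
#' threshold it follows the logistic
#' `normal + (max - normal) / (1 + exp(-slope (A - trigger)))`, saturating at
#' `max_decline`. The hard threshold keeps subclinical activity from causing
#' any excess decline, so a never-smoker declines exactly at the normal rate.
#'
#' @param A activity fraction in `[0, 1]`.
#' @param p an [easi_params()] object.
#' @return decline rate in ml/year (initial-slope convention).
#' @examples
#' decline_rate(0, builtin_params("scenario", 1))  # 30 ml/yr
#' @export
decline_rate <- function(A, p) {
  validate_params(p)
  if (any(A < 0 | A > 1)) stop("decline_rate(): `A` must be in [0, 1]",
                               call. = FALSE)
  decline_rate_core(A, p$severity_trigger, p$severity_slope,
                    p$normal_decline, p$max_decline)
}

#' Reference (normal-lung) FEV1 trajectory
#'
#' The internal normal trajectory against which "% ref" is computed: constant
#' at `reference_fev1_at_20` (4.0 L) until `plateau_end_age`, then declining
#' under the same first-order law as the individuals with zero disease
#' activity, i.e. exponentially with initial slope `reference_decline`
#' (30 ml/year): `F_ref(a) = F20 * exp(-(30 / 4000) * (a - 25))`.
#'
#' @param age age(s) in years, within the simulation window.
#' @param constants an [easi_constants()] object.
#' @return reference FEV1 in liters.
#' @examples
#' reference_fev1(20, easi_constants()) # 4.0
#' reference_fev1(80, easi_constants()) # ~2.648
#' @export
reference_fev1 <- function(age, constants = easi_constants()) {
  if (any(age < constants$sim_start_age | age > constants$sim_end_age)) {
    stop("reference_fev1(): `age` outside the simulation window [",
         constants$sim_start_age, ", ", constants$sim_end_age, "]",
         call. = FALSE)
  }
  R20 <- constants$reference_fev1_at_20
  rate <- constants$reference_decline / (1000 * R20) # fraction per year
  ifelse(age <= constants$plateau_end_age, R20,
         R20 * exp(-rate * (age - constants$plateau_end_age)))
}

impact_target_core <- function(pct_ref, trigger, slope) {
  stats::plogis(slope * (trigger - pct_ref))
}

#' Steady-state perceived impact
#'
#' Decreasing logistic of lung function on the fractional scale: impact is at
#' half-maximum when FEV1 equals `impact_trigger` times the age-matched
#' reference, and grows as lung function falls. Triggers above 1 encode
#' individuals who perceive symptoms while still within the normal range.
#'
#' @param fev1_pct_ref FEV1 as a fraction of the age-matched reference
#'   (0.80 for "80% ref"), must be positive.
#' @param p an [easi_params()] object.
#' @return target impact, fraction in `[0, 1]`.
#' @examples
#' impact_target(0.45, builtin_params("scenario", 1)) # ~0.668
#' @export
impact_target <- function(fev1_pct_ref, p) {
  validate_params(p)
  if (any(fev1_pct_ref <= 0)) {
    stop("impact_target(): `fev1_pct_ref` must be > 0", call. = FALSE)
  }
  impact_target_core(fev1_pct_ref, p$impact_trigger, p$impact_slope)
}

#' Construct a model state
#'
#' One point of the dynamical state: age, exposure E, cumulative pack-years C,
#' activity A with its running peak, FEV1 in liters, and impact I.
#'
#' @param age years.
#' @param E exposure, packs/day.
#' @param C cumulative pack-years.
#' @param A activity fraction.
#' @param A_peak running maximum of A.
#' @param fev1 FEV1, liters.
#' @param I impact fraction.
#' @return an object of class `easi_state`.
#' @export
easi_state <- function(age, E = 0, C = 0, A = 0, A_peak = 0, fev1, I = 0) {
  s <- list(age = age, E = E, C = C, A = A, A_peak = A_peak, fev1 = fev1, I = I)
  class(s) <- "easi_state"
  s
}

#' One explicit-Euler step of the cascade
#'
#' Advances the state by `dt`, strictly feed-forward: all stage targets are
#' evaluated at the current state (left endpoint). Exposure is re-evaluated in
#' closed form at the new age; pack-years accumulate by a left-endpoint sum;
#' Activity and Impact relax towards their logistic targets with time
#' constants `tau_activity` / `tau_impact` and are clamped to `[0, 1]`; FEV1
#' follows `F <- F * (1 - dt * r(A) / (1000 * fev1_at_20))` once past the
#' plateau, and is held constant before it.
#'
#' @param s an [easi_state()] object.
#' @param p an [easi_params()] object.
#' @param constants an [easi_constants()] object.
#' @return the state at `s$age + dt`.
#' @export
step_state <- function(s, p, constants = easi_constants()) {
  dt <- constants$dt
  if (s$age + dt > constants$sim_end_age + 1e-9) {
    stop("step_state(): step would leave the simulation window", call. = FALSE)
  }
  tA <- activity_target_core(s$E, s$A_peak, p$activity_trigger,
                             p$activity_slope, p$persistence_after_quitting)
  r <- decline_rate_core(s$A, p$severity_trigger, p$severity_slope,
                         p$normal_decline, p$max_decline)
  pct <- s$fev1 / reference_fev1(s$age, constants)
  tI <- impact_target_core(pct, p$impact_trigger, p$impact_slope)

  E_new <- exposure_core(s$age + dt, p$smoker_flag, p$age_smoking_onset,
                         p$time_to_max_exposure, p$age_quitting,
                         p$time_to_complete_quitting, p$max_exposure)
  C_new <- s$C + s$E * dt
  A_new <- clamp01(s$A + dt * (tA - s$A) / constants$tau_activity)
  F_new <- if (s$age >= constants$plateau_end_age - 1e-9) {
    s$fev1 * (1 - dt * r / (1000 * p$fev1_at_20))
  } else {
    s$fev1
  }
  if (F_new <= 0) {
    stop("step_state(): FEV1 reached a non-positive value at age ",
         format(s$age + dt), "; the model left its validity domain",
         call. = FALSE)
  }
  I_new <- clamp01(s$I + dt * (tI - s$I) / constants$tau_impact)
  easi_state(age = s$age + dt, E = E_new, C = C_new, A = A_new,
             A_peak = max(s$A_peak, A_new), fev1 = F_new, I = I_new)
}

clamp01 <- function(x) pmin(1, pmax(0, x))

# Vectorized integrator over a cohort: `P` is a list of parameter vectors of
# common length n (one element per model). Returns matrices n x n_ages.
# step_state() is the single-model reference semantics; this is the same
# update batched across models (kept in lockstep by tests).
integrate_cohort <- function(P, constants = easi_constants()) {
  dt <- constants$dt
  ages <- seq(constants$sim_start_age, constants$sim_end_age, by = dt)
  n_t <- length(ages)
  n <- length(P$max_exposure)
  inv_tau_a <- dt / constants$tau_activity
  inv_tau_i <- dt / constants$tau_impact
  ref <- reference_fev1(ages, constants)

  E <- C <- A <- Fv <- I <- matrix(0, nrow = n, ncol = n_t)
  A_peak <- numeric(n)
  E[, 1] <- exposure_core(ages[1], P$smoker_flag, P$age_smoking_onset,
                          P$time_to_max_exposure, P$age_quitting,
                          P$time_to_complete_quitting, P$max_exposure)
  Fv[, 1] <- P$fev1_at_20

  for (i in seq_len(n_t - 1L)) {
    a <- ages[i]
    tA <- activity_target_core(E[, i], A_peak, P$activity_trigger,
                               P$activity_slope, P$persistence_after_quitting)
    r <- decline_rate_core(A[, i], P$severity_trigger, P$severity_slope,
                           P$normal_decline, P$max_decline)
    tI <- impact_target_core(Fv[, i] / ref[i], P$impact_trigger, P$impact_slope)

    E[, i + 1L] <- exposure_core(a + dt, P$smoker_flag, P$age_smoking_onset,
                                 P$time_to_max_exposure, P$age_quitting,
                                 P$time_to_complete_quitting, P$max_exposure)
    C[, i + 1L] <- C[, i] + E[, i] * dt
    A[, i + 1L] <- clamp01(A[, i] + inv_tau_a * (tA - A[, i]))
    Fv[, i + 1L] <- if (a >= constants$plateau_end_age - 1e-9) {
      Fv[, i] * (1 - dt * r / (1000 * P$fev1_at_20))
    } else {
      Fv[, i]
    }
    if (any(Fv[, i + 1L] <= 0)) {
      bad <- which(Fv[, i + 1L] <= 0)[1L]
      stop("integrate_cohort(): FEV1 reached a non-positive value at age ",
           format(a + dt), " (model ", bad,
           "); the model left its validity domain", call. = FALSE)
    }
    I[, i + 1L] <- clamp01(I[, i] + inv_tau_i * (tI - I[, i]))
    A_peak <- pmax(A_peak, A[, i + 1L])
  }
  list(ages = ages, E = E, C = C, A = A, fev1 = Fv, I = I, ref = ref)
}

params_as_cohort <- function(plist) {
  P <- lapply(setNames(PARAM_FIELDS, PARAM_FIELDS),
              function(f) vapply(plist, function(p) {
                v <- p[[f]]
                if (is.logical(v)) as.numeric(v) else v
              }, numeric(1)))
  P$smoker_flag <- P$smoker_flag > 0
  P
}

#' Simulate one individual life-course trajectory
#'
#' Integrates the four-stage cascade from `sim_start_age` to `sim_end_age`
#' with the explicit Euler scheme. The individual starts with zero activity,
#' zero impact and `fev1_at_20` liters of lung function (held constant through
#' the growth/plateau phase up to `plateau_end_age`).
#'
#' @param p an [easi_params()] object.
#' @param constants an [easi_constants()] object.
#' @return an `easi_trajectory`: a data frame with one row per time step and
#'   columns `age`, `exposure_packs_day`, `pack_years`, `activity`, `fev1_L`,
#'   `fev1_pct_ref` (percent of the age-matched [reference_fev1()]) and
#'   `impact`, carrying `p` and `constants` as attributes.
#' @examples
#' tr <- simulate_individual(builtin_params("scenario", 1))
#' tr[tr$age == 80, ]
#' @export
simulate_individual <- function(p, constants = easi_constants()) {
  validate_params(p)
  stopifnot_constants(constants)
  res <- integrate_cohort(params_as_cohort(list(p)), constants)
  tr <- data.frame(
    age = res$ages,
    exposure_packs_day = res$E[1, ],
    pack_years = res$C[1, ],
    activity = res$A[1, ],
    fev1_L = res$fev1[1, ],
    fev1_pct_ref = 100 * res$fev1[1, ] / res$ref,
    impact = res$I[1, ]
  )
  attr(tr, "params") <- p
  attr(tr, "constants") <- constants
  class(tr) <- c("easi_trajectory", "data.frame")
  tr
}
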