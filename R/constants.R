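#' Model constants shared across individuals
#'
#' Numerical and reference settings of the simulator, as opposed to the
#' individual-specific inputs of [easi_params()].
#'
#' @param dt Euler time step, years. Default 0.2.
#' @param reference_fev1_at_20 FEV1 of the normal reference lung at age 20,
#'   liters (the "100% ref." anchor). Default 4.0.
#' @param reference_decline initial-slope decline rate of the reference lung,
#'   ml/year. Default 30.
#' @param plateau_end_age age at which the adult FEV1 plateau ends and decline
#'   begins, years. Default 25 (Fletcher-Peto convention).
#' @param sim_start_age,sim_end_age simulated age window, years.
#'   Defaults 10 and 90.
#' @param tau_activity,tau_impact relaxation times of the Activity and Impact
#'   first-order dynamics, years. Default 1 each, so Activity tracks exposure
#'   rapidly on the time scale of a life course.
#' @return an object of class `easi_constants`.
#' @export
easi_constants <- function(dt = 0.2,
                           reference_fev1_at_20 = 4.0,
                           reference_decline = 30,
                           plateau_end_age = 25,
                           sim_start_age = 10,
                           sim_end_age = 90,
                           tau_activity = 1,
                           tau_impact = 1) {
  c <- list(dt = as.numeric(dt),
            reference_fev1_at_20 = as.numeric(reference_fev1_at_20),
            reference_decline = as.numeric(reference_decline),
            plateau_end_age = as.numeric(plateau_end_age),
            sim_start_age = as.numeric(sim_start_age),
            sim_end_age = as.numeric(sim_end_age),
            tau_activity = as.numeric(tau_activity),
            tau_impact = as.numeric(tau_impact))
  stopifnot_constants(c)
  class(c) <- "easi_constants"
  c
}

stopifnot_constants <- function(c) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid constants: ", msg,
                                                 call. = FALSE)
  for (f in c("dt", "reference_fev1_at_20", "reference_decline",
              "plateau_end_age", "sim_start_age", "sim_end_age",
              "tau_activity", "tau_impact")) {
    chk(is.numeric(c[[f]]) && length(c[[f]]) == 1L && is.finite(c[[f]]),
        paste0(f, " must be a single finite numeric"))
  }
  chk(c$dt > 0, "dt must be > 0")
  chk(c$reference_fev1_at_20 > 0, "reference_fev1_at_20 must be > 0")
  chk(c$reference_decline >= 0, "reference_decline must be >= 0")
  chk(c$tau_activity > 0 && c$tau_impact > 0, "relaxation times must be > 0")
  chk(c$sim_start_age < 20 && 20 <= c$plateau_end_age &&
        c$plateau_end_age < c$sim_end_age,
      "need sim_start_age < 20 <= plateau_end_age < sim_end_age")
  invisible(c)
}

#' @export
print.easi_constants <- function(x, ...) {
  cat("<easi_constants>\n")
  for (f in names(unclass(x))) cat(sprintf("  %-22s %s\n", f, format(x[[f]])))
  invisible(x)
}
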