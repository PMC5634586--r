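# Shared helpers: trajectory sampling and cached simulations of the built-in
# parameterizations (cheap, but reused across many tests).

traj_value <- function(tr, age, col) tr[[col]][which.min(abs(tr$age - age))]

scenario_traj <- local({
  cache <- list()
  function(i, constants = easi_constants()) {
    key <- paste0("s", i, "-", constants$dt)
    if (is.null(cache[[key]])) {
      cache[[key]] <<- simulate_individual(builtin_params("scenario", i),
                                           constants)
    }
    cache[[key]]
  }
})

patient_traj <- local({
  cache <- list()
  function(i) {
    key <- paste0("p", i)
    if (is.null(cache[[key]])) {
      cache[[key]] <<- simulate_individual(builtin_params("patient", i))
    }
    cache[[key]]
  }
})

never_smoker_params <- function(fev1_at_20 = 4.0) {
  easi_params(smoker_flag = FALSE, max_exposure = 0, fev1_at_20 = fev1_at_20)
}
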