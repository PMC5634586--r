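#' Load and validate a run configuration
#'
#' A run configuration is a JSON object naming exactly one parameter source
#' (`"scenario"`: 1-6, `"patient"`: 1-4, or `"params"`: path to a parameter
#' JSON file), plus optional `"constants"` overrides (any field of
#' [easi_constants()]), an output path `"out"` and a `"verbose"` flag.
#' Unknown keys are rejected by name.
#'
#' @param path path to the JSON file.
#' @return an object of class `easi_run_config`: list with the resolved
#'   `params` ([easi_params()]), `constants` ([easi_constants()]), `out` and
#'   `verbose`.
#' @examples
#' cfg_file <- tempfile(fileext = ".json")
#' writeLines('{"scenario": 1}', cfg_file)
#' cfg <- load_config(cfg_file)
#' cfg$constants$dt
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  allowed <- c("scenario", "patient", "params", "constants", "out", "verbose")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sources <- intersect(c("scenario", "patient", "params"), names(cfg))
  if (length(sources) != 1L) {
    stop("config must name exactly one parameter source ",
         "(scenario, patient or params); found ", length(sources),
         call. = FALSE)
  }
  params <- switch(sources,
    scenario = builtin_params("scenario", cfg$scenario),
    patient = builtin_params("patient", cfg$patient),
    params = params_from_json(cfg$params)
  )
  const_args <- if (!is.null(cfg$constants)) as.list(cfg$constants) else list()
  unknown_c <- setdiff(names(const_args), names(unclass(easi_constants())))
  if (length(unknown_c)) {
    stop("unknown constants key(s): ", paste(unknown_c, collapse = ", "),
         call. = FALSE)
  }
  constants <- do.call(easi_constants, const_args)
  out <- list(params = params, constants = constants,
              out = if (!is.null(cfg$out)) as.character(cfg$out) else NULL,
              verbose = isTRUE(cfg$verbose))
  class(out) <- "easi_run_config"
  out
}
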