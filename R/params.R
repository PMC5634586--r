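PARAM_FIELDS <- c(
  "age_smoking_onset", "max_exposure", "time_to_max_exposure",
  "age_quitting", "time_to_complete_quitting",
  "activity_trigger", "activity_slope", "persistence_after_quitting",
  "normal_decline", "severity_trigger", "severity_slope", "max_decline",
  "fev1_at_20", "impact_trigger", "impact_slope", "smoker_flag"
)

#' Individual parameter set
#'
#' The 15 inputs defining one simulated individual, plus a smoker flag. Units
#' follow the model's parameter table: ages and durations in years, exposure in
#' packs/day, FEV1 decline rates in ml/year, FEV1 in liters; triggers and
#' persistence that are printed as percentages are stored as fractions
#' (e.g. an impact trigger of 80% reference FEV1 is 0.80; values above 1 are
#' legal for poor-lung-function triggers).
#'
#' Never-smokers (`smoker_flag = FALSE`) have exposure identically zero; their
#' exposure-stage parameters may be `NA`. Non-quitters are encoded with
#' `age_quitting = NA` (serialized as JSON `null`).
#'
#' @param age_smoking_onset age smoking starts, years (`NA` for never-smokers).
#' @param max_exposure maximal daily dose, packs/day.
#' @param time_to_max_exposure years from onset to maximal dose.
#' @param age_quitting age smoking stops, years; `NA` for non-quitters.
#' @param time_to_complete_quitting years from quit age to zero exposure;
#'   required for quitters.
#' @param activity_trigger exposure (packs/day) at which inflammatory
#'   activation begins.
#' @param activity_slope steepness of the activity activation.
#' @param persistence_after_quitting residual activity after exposure ceases,
#'   as a fraction of peak activity in `[0, 1]`; `NA` when not applicable.
#' @param normal_decline FEV1 decline rate with no disease activity, ml/year
#'   (initial-slope convention, see [simulate_individual()]).
#' @param severity_trigger activity fraction at which excess decline begins.
#' @param severity_slope steepness of the severity activation.
#' @param max_decline maximal FEV1 decline rate, ml/year.
#' @param fev1_at_20 FEV1 at age 20, liters.
#' @param impact_trigger fraction of reference FEV1 at which perceived impact
#'   reaches half-maximum (may exceed 1).
#' @param impact_slope steepness of the impact activation.
#' @param smoker_flag logical; `FALSE` forces exposure to zero at all ages.
#' @return an object of class `easi_params` (a validated named list).
#' @seealso [builtin_params()] for the canonical scenario and patient sets.
#' @examples
#' p <- builtin_params("scenario", 1)
#' p$max_exposure
#' @export
easi_params <- function(age_smoking_onset = NA_real_,
                        max_exposure = 0,
                        time_to_max_exposure = NA_real_,
                        age_quitting = NA_real_,
                        time_to_complete_quitting = NA_real_,
                        activity_trigger = 0.3,
                        activity_slope = 2,
                        persistence_after_quitting = NA_real_,
                        normal_decline = 30,
                        severity_trigger = 0.10,
                        severity_slope = 2,
                        max_decline = 100,
                        fev1_at_20 = 4.0,
                        impact_trigger = 0.80,
                        impact_slope = 2,
                        smoker_flag = TRUE) {
  p <- list(
    age_smoking_onset = as.numeric(age_smoking_onset),
    max_exposure = as.numeric(max_exposure),
    time_to_max_exposure = as.numeric(time_to_max_exposure),
    age_quitting = as.numeric(age_quitting),
    time_to_complete_quitting = as.numeric(time_to_complete_quitting),
    activity_trigger = as.numeric(activity_trigger),
    activity_slope = as.numeric(activity_slope),
    persistence_after_quitting = as.numeric(persistence_after_quitting),
    normal_decline = as.numeric(normal_decline),
    severity_trigger = as.numeric(severity_trigger),
    severity_slope = as.numeric(severity_slope),
    max_decline = as.numeric(max_decline),
    fev1_at_20 = as.numeric(fev1_at_20),
    impact_trigger = as.numeric(impact_trigger),
    impact_slope = as.numeric(impact_slope),
    smoker_flag = isTRUE(smoker_flag)
  )
  class(p) <- "easi_params"
  validate_params(p)
  p
}

#' Validate an individual parameter set
#'
#' Checks the structural invariants: non-negative exposure, positive slopes and
#' baseline FEV1, `max_decline >= normal_decline >= 0`, persistence in
#' `[0, 1]`, quit age after onset, and the presence of the quitting duration
#' for quitters.
#'
#' @param p an `easi_params` object (or list with the same fields).
#' @return `p`, invisibly; errors describe the violated invariant.
#' @export
validate_params <- function(p) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid parameter set: ", msg,
                                                 call. = FALSE)
  num1 <- function(x) is.numeric(x) && length(x) == 1L
  for (f in setdiff(PARAM_FIELDS, "smoker_flag")) {
    chk(num1(p[[f]]), paste0(f, " must be a single numeric"))
  }
  chk(is.logical(p$smoker_flag) && length(p$smoker_flag) == 1L,
      "smoker_flag must be a single logical")
  chk(!is.na(p$max_exposure) && p$max_exposure >= 0, "max_exposure must be >= 0")
  chk(!is.na(p$fev1_at_20) && p$fev1_at_20 > 0, "fev1_at_20 must be > 0")
  chk(!is.na(p$normal_decline) && p$normal_decline >= 0,
      "normal_decline must be >= 0")
  chk(!is.na(p$max_decline) && p$max_decline >= p$normal_decline,
      "max_decline must be >= normal_decline")
  for (f in c("activity_slope", "severity_slope", "impact_slope")) {
    chk(!is.na(p[[f]]) && p[[f]] > 0, paste0(f, " must be > 0"))
  }
  for (f in c("activity_trigger", "severity_trigger", "impact_trigger")) {
    chk(!is.na(p[[f]]) && p[[f]] > 0, paste0(f, " must be > 0"))
  }
  if (p$smoker_flag && p$max_exposure > 0) {
    chk(!is.na(p$age_smoking_onset), "smokers need age_smoking_onset")
    chk(!is.na(p$time_to_max_exposure) && p$time_to_max_exposure > 0,
        "time_to_max_exposure must be > 0 for smokers")
    if (!is.na(p$age_quitting)) {
      chk(p$age_quitting > p$age_smoking_onset,
          "age_quitting must be after age_smoking_onset")
      chk(!is.na(p$time_to_complete_quitting) &&
            p$time_to_complete_quitting > 0,
          "quitters need time_to_complete_quitting > 0")
      chk(!is.na(p$persistence_after_quitting) &&
            p$persistence_after_quitting >= 0 &&
            p$persistence_after_quitting <= 1,
          "quitters need persistence_after_quitting in [0, 1]")
    }
  }
  if (!is.na(p$persistence_after_quitting)) {
    chk(p$persistence_after_quitting >= 0 && p$persistence_after_quitting <= 1,
        "persistence_after_quitting must be in [0, 1]")
  }
  invisible(p)
}

#' @export
print.easi_params <- function(x, ...) {
  cat("<easi_params>",
      if (!x$smoker_flag) "never-smoker"
      else if (is.na(x$age_quitting)) "continuous smoker" else "quitter", "\n")
  for (f in PARAM_FIELDS) {
    cat(sprintf("  %-28s %s\n", f, format(x[[f]])))
  }
  invisible(x)
}

#' Serialize a parameter set to JSON
#'
#' Keys are the snake_case field names of [easi_params()]; `NA` fields (e.g.
#' `age_quitting` for a non-quitter) are written as JSON `null`.
#'
#' @param p an `easi_params` object.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return the JSON string (invisibly when written to `path`).
#' @export
params_to_json <- function(p, path = NULL) {
  validate_params(p)
  lst <- lapply(unclass(p)[PARAM_FIELDS], function(v) if (is.na(v)) NULL else v)
  js <- jsonlite::toJSON(lst, auto_unbox = TRUE, null = "null", digits = NA,
                         pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path, useBytes = TRUE)
  invisible(js)
}

#' Read a parameter set from JSON
#'
#' @param path file path, or a JSON string.
#' @return a validated `easi_params` object.
#' @export
params_from_json <- function(path) {
  lst <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  unknown <- setdiff(names(lst), PARAM_FIELDS)
  if (length(unknown)) {
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  args <- lapply(setNames(PARAM_FIELDS, PARAM_FIELDS), function(f) {
    v <- lst[[f]]
    if (is.null(v) || length(v) == 0L) {
      if (f == "smoker_flag") TRUE else NA_real_
    } else v
  })
  do.call(easi_params, args)
}
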