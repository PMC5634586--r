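# The ten canonical parameterizations: six clinical scenarios (susceptible
# continuous smoker; quitter at 45; quitter at 65; persistent inflammation
# despite quitting; abnormal lung development; poor perceiver) and four
# hypothetical patients who present with the same impact at age 50.
# Percent-valued entries are stored as fractions.

scenario_table <- function() {
  base <- list(age_smoking_onset = 15, max_exposure = 1.5,
               time_to_max_exposure = 5, age_quitting = NA_real_,
               time_to_complete_quitting = NA_real_,
               activity_trigger = 0.3, activity_slope = 2,
               persistence_after_quitting = NA_real_,
               normal_decline = 30, severity_trigger = 0.10,
               severity_slope = 2, max_decline = 100,
               fev1_at_20 = 4.0, impact_trigger = 0.80, impact_slope = 2,
               smoker_flag = TRUE)
  list(
    `1` = base,
    `2` = modifyList(base, list(age_quitting = 45,
                                time_to_complete_quitting = 1,
                                persistence_after_quitting = 0)),
    `3` = modifyList(base, list(age_quitting = 65,
                                time_to_complete_quitting = 1,
                                persistence_after_quitting = 0)),
    `4` = modifyList(base, list(age_quitting = 45,
                                time_to_complete_quitting = 1,
                                persistence_after_quitting = 0.40)),
    `5` = modifyList(base, list(fev1_at_20 = 3.0)),
    `6` = modifyList(base, list(impact_trigger = 0.50))
  )
}

patient_table <- function() {
  list(
    `1` = list(age_smoking_onset = 15, max_exposure = 3,
               time_to_max_exposure = 1, age_quitting = 40,
               time_to_complete_quitting = 1,
               activity_trigger = 0.3, activity_slope = 2,
               persistence_after_quitting = 0.25,
               normal_decline = 12, severity_trigger = 0.20,
               severity_slope = 2, max_decline = 75,
               fev1_at_20 = 3.0, impact_trigger = 0.90, impact_slope = 1,
               smoker_flag = TRUE),
    `2` = list(age_smoking_onset = 16, max_exposure = 2,
               time_to_max_exposure = 2.5, age_quitting = 45,
               time_to_complete_quitting = 1,
               activity_trigger = 0.1, activity_slope = 3.5,
               persistence_after_quitting = 0.20,
               normal_decline = 35, severity_trigger = 0.10,
               severity_slope = 2.5, max_decline = 90,
               fev1_at_20 = 4.0, impact_trigger = 0.85, impact_slope = 3,
               smoker_flag = TRUE),
    `3` = list(age_smoking_onset = 17, max_exposure = 1.5,
               time_to_max_exposure = 2, age_quitting = NA_real_,
               time_to_complete_quitting = NA_real_,
               activity_trigger = 0.1, activity_slope = 3.5,
               persistence_after_quitting = NA_real_,
               normal_decline = 20, severity_trigger = 0.30,
               severity_slope = 1, max_decline = 75,
               fev1_at_20 = 4.5, impact_trigger = 1.15, impact_slope = 2,
               smoker_flag = TRUE),
    # Never-smoker with low early-adult lung function; the activity trigger is
    # stored but inert (exposure is identically zero).
    `4` = list(age_smoking_onset = NA_real_, max_exposure = 0,
               time_to_max_exposure = NA_real_, age_quitting = NA_real_,
               time_to_complete_quitting = NA_real_,
               activity_trigger = 0.35, activity_slope = 2,
               persistence_after_quitting = NA_real_,
               normal_decline = 20, severity_trigger = 0.20,
               severity_slope = 1, max_decline = 60,
               fev1_at_20 = 2.8, impact_trigger = 0.85, impact_slope = 2,
               smoker_flag = FALSE)
  )
}

#' Built-in canonical parameter sets
#'
#' Returns one of the ten shipped parameterizations: clinical scenarios 1-6
#' (1 susceptible continuous smoker; 2 quitter at 45; 3 quitter at 65;
#' 4 persistent inflammation despite quitting; 5 abnormal lung development,
#' FEV1 3.0 L = 75% ref at 20; 6 poor perceiver, impact trigger 50% ref) or
#' patient profiles 1-4 (four individuals presenting with similar impact at
#' age 50; patient 4 is a never-smoker with low early-adult lung function).
#'
#' @param kind `"scenario"` or `"patient"`.
#' @param index scenario index in 1..6, or patient index in 1..4.
#' @return a validated [easi_params()] object.
#' @examples
#' builtin_params("scenario", 4)$persistence_after_quitting # 0.40
#' builtin_params("patient", 3)$impact_trigger              # 1.15
#' @export
builtin_params <- function(kind = c("scenario", "patient"), index) {
  kind <- match.arg(kind)
  tab <- if (kind == "scenario") scenario_table() else patient_table()
  key <- as.character(index)
  if (length(index) != 1L || !key %in% names(tab)) {
    stop("unknown ", kind, " index: ", paste(index, collapse = ","),
         " (valid: 1..", length(tab), ")", call. = FALSE)
  }
  do.call(easi_params, tab[[key]])
}
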