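TRAJECTORY_COLUMNS <- c("age", "exposure_packs_day", "pack_years", "activity",
                        "fev1_L", "fev1_pct_ref", "impact")

# Nearest grid row to a requested age; errors when outside the trajectory.
trajectory_row_at <- function(tr, age) {
  if (age < min(tr$age) - 1e-9 || age > max(tr$age) + 1e-9) {
    stop("age ", age, " outside the trajectory window [", min(tr$age), ", ",
         max(tr$age), "]", call. = FALSE)
  }
  which.min(abs(tr$age - age))
}

#' Decade summary ("heat-map") of a trajectory
#'
#' Samples the state at each decade age (nearest grid point): exposure as a
#' fraction of the individual's maximal exposure, activity, FEV1 as percent of
#' the age-matched reference, and impact. This is the tabular form of the
#' by-decade heat-map panel of the model display.
#'
#' @param tr an `easi_trajectory` from [simulate_individual()].
#' @param decades decade ages to sample; default `seq(20, 80, by = 10)`.
#' @return a data frame with columns `decade_age`, `exposure_frac`,
#'   `activity`, `fev1_pct_ref`, `impact`.
#' @examples
#' decade_heatmap(simulate_individual(builtin_params("scenario", 1)))
#' @export
decade_heatmap <- function(tr, decades = seq(20, 80, by = 10)) {
  stopifnot(inherits(tr, "easi_trajectory"))
  p <- attr(tr, "params")
  idx <- vapply(decades, function(d) trajectory_row_at(tr, d), integer(1))
  emax <- p$max_exposure
  data.frame(
    decade_age = decades,
    exposure_frac = if (emax > 0) tr$exposure_packs_day[idx] / emax
                    else rep(0, length(idx)),
    activity = tr$activity[idx],
    fev1_pct_ref = tr$fev1_pct_ref[idx],
    impact = tr$impact[idx]
  )
}

#' Compare several individuals at one age
#'
#' Simulates (or reuses) one trajectory per parameter set and samples a single
#' variable at the requested age, using the same nearest-grid-point rule as
#' [decade_heatmap()]. This is the cross-sectional view: individuals with very
#' different life courses lined up at the age at which they would present in
#' the clinic.
#'
#' @param params a named list of [easi_params()] objects (names label the rows),
#'   or a list of `easi_trajectory` objects.
#' @param age age in years at which to sample.
#' @param variable one of `"exposure_packs_day"`, `"activity"`,
#'   `"fev1_pct_ref"`, `"impact"` (the model short names `"E"`, `"A"`, `"I"`
#'   are also accepted).
#' @param constants an [easi_constants()] object (used when simulating).
#' @return a data frame with columns `id` and `value`.
#' @examples
#' pts <- lapply(1:4, function(i) builtin_params("patient", i))
#' names(pts) <- paste0("patient", 1:4)
#' compare_at(pts, age = 50, variable = "impact")
#' @export
compare_at <- function(params, age, variable = "fev1_pct_ref",
                       constants = easi_constants()) {
  variable <- switch(variable,
                     E = "exposure_packs_day", A = "activity", I = "impact",
                     variable)
  if (!variable %in% TRAJECTORY_COLUMNS) {
    stop("unknown variable: ", variable, call. = FALSE)
  }
  if (inherits(params, "easi_params") || inherits(params, "easi_trajectory")) {
    params <- list(params)
  }
  ids <- names(params)
  if (is.null(ids)) ids <- as.character(seq_along(params))
  values <- vapply(params, function(x) {
    tr <- if (inherits(x, "easi_trajectory")) x
          else simulate_individual(x, constants)
    tr[[variable]][trajectory_row_at(tr, age)]
  }, numeric(1))
  data.frame(id = ids, value = unname(values))
}

#' Write a trajectory to CSV
#'
#' Fixed 6-decimal format, UTF-8, LF line endings, header
#' `age,exposure_packs_day,pack_years,activity,fev1_L,fev1_pct_ref,impact`.
#' An empty trajectory yields a header-only file.
#'
#' @param tr an `easi_trajectory` (or data frame with the same columns).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(tr, path) {
  stopifnot(all(TRAJECTORY_COLUMNS %in% names(tr)))
  con <- file(path, open = "wb") # binary mode: LF endings on every platform
  on.exit(close(con))
  writeLines(paste(TRAJECTORY_COLUMNS, collapse = ","), con, sep = "\n",
             useBytes = TRUE)
  if (nrow(tr) > 0) {
    cells <- vapply(TRAJECTORY_COLUMNS,
                    function(col) formatC(tr[[col]], format = "f", digits = 6),
                    character(nrow(tr)))
    if (nrow(tr) == 1L) cells <- matrix(cells, nrow = 1L)
    writeLines(apply(cells, 1L, paste, collapse = ","), con, sep = "\n",
               useBytes = TRUE)
  }
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory()]
#'
#' @param path file path.
#' @return an `easi_trajectory` data frame (without parameter attributes).
#' @export
read_trajectory <- function(path) {
  tr <- utils::read.csv(path, colClasses = "numeric")
  if (!identical(names(tr), TRAJECTORY_COLUMNS)) {
    stop("not a trajectory CSV: unexpected columns", call. = FALSE)
  }
  class(tr) <- c("easi_trajectory", "data.frame")
  tr
}

#' @export
print.easi_trajectory <- function(x, ...) {
  cat("<easi_trajectory> ", nrow(x), " steps, age ",
      if (nrow(x)) paste0(min(x$age), "-", max(x$age)) else "(empty)", "\n",
      sep = "")
  if (nrow(x)) {
    decades <- seq(ceiling(min(x$age) / 10) * 10, max(x$age), by = 10)
    idx <- vapply(decades, function(d) which.min(abs(x$age - d)), integer(1))
    print.data.frame(as.data.frame(x)[idx, ], row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Plot the four stage trajectories of one individual
#'
#' Base-graphics convenience: exposure (normalized), activity, FEV1 %ref
#' (scaled to fractions) and impact against age.
#'
#' @param x an `easi_trajectory`.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.easi_trajectory <- function(x, ...) {
  emax <- max(x$exposure_packs_day, 1e-12)
  y <- cbind(x$exposure_packs_day / emax, x$activity, x$fev1_pct_ref / 100,
             x$impact)
  graphics::matplot(x$age, y, type = "l", lty = 1, lwd = 2,
                    col = c("blue", "red", "cyan3", "darkgreen"),
                    xlab = "age (years)", ylab = "fraction of maximum", ...)
  graphics::legend("topleft", bty = "n",
                   legend = c("exposure / max", "activity", "FEV1 %ref / 100",
                              "impact"),
                   col = c("blue", "red", "cyan3", "darkgreen"), lty = 1,
                   lwd = 2)
  invisible(x)
}
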