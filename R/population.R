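# Seeded Monte Carlo population layer: truncated-normal parameter dispersion
# around the susceptible-continuous-smoker (scenario 1) centers, ensemble
# simulation, and a random-search calibration loop against population FEV1
# targets.

# Parameters that receive dispersion, their scenario-1 centers and truncation
# bounds (bounds keep every draw inside the parameter-set invariants).
default_dispersion_table <- function(smoker = TRUE, cv = 0.15) {
  d <- data.frame(
    param = c("age_smoking_onset", "max_exposure", "time_to_max_exposure",
              "activity_trigger", "activity_slope",
              "normal_decline", "severity_trigger", "severity_slope",
              "max_decline", "fev1_at_20", "impact_trigger", "impact_slope"),
    center = c(15, 1.5, 5, 0.3, 2, 30, 0.10, 2, 100, 4.0, 0.80, 2),
    cv = cv,
    lower = c(10, 0.05, 0.5, 0.01, 0.1, 0, 0.01, 0.1, 10, 1, 0.05, 0.1),
    upper = c(40, 6, 20, 2, 20, 80, 0.90, 20, 300, 7, 2, 20),
    stringsAsFactors = FALSE
  )
  if (!smoker) {
    # Non-smoking population: exposure stage zeroed, no dispersion there.
    off <- d$param %in% c("age_smoking_onset", "max_exposure",
                          "time_to_max_exposure")
    d$center[off] <- 0
    d$cv[off] <- 0
  }
  d
}

#' Population sampling specification
#'
#' Defines a seeded Monte Carlo cohort: the number of models, the smoking
#' status, and per-parameter truncated-normal sampling distributions
#' (center, coefficient of variation, truncation bounds). Centers default to
#' the susceptible-continuous-smoker scenario values with a common CV of 0.15;
#' truncation bounds enforce the parameter-set invariants
#' (`max_decline` is additionally truncated below at each draw's
#' `normal_decline`). A non-smoking population zeroes the exposure-stage
#' parameters for every draw.
#'
#' @param n_models number of individuals, default 1000.
#' @param seed integer seed; every draw is a deterministic function of
#'   `(seed, draw_index)`.
#' @param smoker logical; `FALSE` gives a never-smoking population.
#' @param cv common coefficient of variation applied to all dispersed
#'   parameters. `0` gives a degenerate (all-identical) cohort.
#' @param dispersion optional replacement dispersion table (data frame with
#'   columns `param`, `center`, `cv`, `lower`, `upper`).
#' @return an object of class `easi_population_spec`.
#' @export
population_spec <- function(n_models = 1000, seed = 1L, smoker = TRUE,
                            cv = 0.15, dispersion = NULL) {
  if (n_models < 1) stop("n_models must be >= 1", call. = FALSE)
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  d <- if (is.null(dispersion)) default_dispersion_table(smoker, cv)
       else dispersion
  stopifnot(is.data.frame(d),
            all(c("param", "center", "cv", "lower", "upper") %in% names(d)))
  if (any(d$lower > d$upper)) {
    stop("impossible truncation bounds (lower > upper) for: ",
         paste(d$param[d$lower > d$upper], collapse = ", "), call. = FALSE)
  }
  spec <- list(n_models = as.integer(n_models), seed = as.integer(seed),
               smoker = isTRUE(smoker), cv = as.numeric(cv), dispersion = d)
  class(spec) <- "easi_population_spec"
  spec
}

#' @export
print.easi_population_spec <- function(x, ...) {
  cat("<easi_population_spec> n_models=", x$n_models, " seed=", x$seed,
      " smoker=", x$smoker, " cv=", format(x$cv), "\n", sep = "")
  print.data.frame(x$dispersion, row.names = FALSE, digits = 4)
  invisible(x)
}

# Deterministic positive sub-seed below 2^31 for (seed, index) pairs.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 2147483629 * 48271 + index * 9973) %%
               2147483629) + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Inverse-CDF truncated-normal draw from a uniform variate.
qtruncnorm <- function(u, center, sd, lower, upper) {
  if (sd <= 0) return(min(max(center, lower), upper))
  pa <- stats::pnorm(lower, center, sd)
  pb <- stats::pnorm(upper, center, sd)
  stats::qnorm(pa + u * (pb - pa), center, sd)
}

#' Draw one individual from a population specification
#'
#' Deterministic given `(spec$seed, draw_index)`: the same pair always yields
#' the identical parameter set, whether drawn alone or inside
#' [run_ensemble()]. Sampling is inverse-CDF truncated-normal per parameter;
#' `max_decline` is truncated below at the draw's `normal_decline` so every
#' draw satisfies the parameter invariants. The global RNG state is left
#' untouched.
#'
#' @param spec an [population_spec()] object.
#' @param draw_index index of the draw, in `1..spec$n_models`.
#' @return a validated [easi_params()] object.
#' @export
sample_parameters <- function(spec, draw_index) {
  stopifnot(inherits(spec, "easi_population_spec"))
  if (draw_index < 1 || draw_index > spec$n_models) {
    stop("draw_index must be in 1..n_models", call. = FALSE)
  }
  d <- spec$dispersion
  u <- with_seed(derive_seed(spec$seed, draw_index), runif(nrow(d)))
  vals <- numeric(nrow(d))
  names(vals) <- d$param
  for (i in seq_len(nrow(d))) {
    lo <- d$lower[i]
    if (d$param[i] == "max_decline") lo <- max(lo, vals[["normal_decline"]])
    vals[i] <- qtruncnorm(u[i], d$center[i], d$cv[i] * abs(d$center[i]),
                          lo, d$upper[i])
  }
  args <- as.list(vals)
  args$smoker_flag <- spec$smoker
  if (!spec$smoker) {
    args$max_exposure <- 0
    args$age_smoking_onset <- NA_real_
    args$time_to_max_exposure <- NA_real_
  }
  # scenario-1 centers are non-quitters: no quitting-stage dispersion
  args$age_quitting <- NA_real_
  args$time_to_complete_quitting <- NA_real_
  args$persistence_after_quitting <- NA_real_
  do.call(easi_params, args)
}

#' Simulate a seeded population ensemble
#'
#' Draws `spec$n_models` individuals with [sample_parameters()], integrates
#' all of them, and aggregates: per-age mean and SD of FEV1 (liters and
#' percent of reference), the fraction below the lower limit of normality
#' (LLN, a configurable fraction of the reference trajectory), and each
#' model's mean adult decline
#' `(FEV1(plateau_end_age) - FEV1(80)) / (80 - plateau_end_age)` in ml/year.
#' Identical spec and seed give bitwise-identical results.
#'
#' @param spec an [population_spec()] object.
#' @param constants an [easi_constants()] object.
#' @param lln_fraction LLN threshold as a fraction of [reference_fev1()],
#'   default 0.80.
#' @return an object of class `easi_ensemble` with elements `summary` (data
#'   frame at integer ages: `age`, `mean_fev1_L`, `sd_fev1_L`, `mean_pct_ref`,
#'   `sd_pct_ref`, `frac_below_lln`), `decline_ml_yr` (per-model vector),
#'   `mean_decline_ml_yr`, `fev1_at_age` (models x ages matrix), `ages`,
#'   `spec`, `constants`.
#' @examples
#' ens <- run_ensemble(population_spec(n_models = 50, seed = 1))
#' ens$mean_decline_ml_yr
#' @export
run_ensemble <- function(spec, constants = easi_constants(),
                         lln_fraction = 0.80) {
  stopifnot(inherits(spec, "easi_population_spec"))
  stopifnot_constants(constants)
  plist <- lapply(seq_len(spec$n_models), function(i) {
    tryCatch(sample_parameters(spec, i),
             error = function(e) stop("draw ", i, ": ", conditionMessage(e),
                                      call. = FALSE))
  })
  res <- tryCatch(integrate_cohort(params_as_cohort(plist), constants),
                  error = function(e) stop("ensemble simulation failed: ",
                                           conditionMessage(e), call. = FALSE))
  keep <- which(abs(res$ages - round(res$ages)) < 1e-9)
  ages <- round(res$ages[keep])
  Fm <- res$fev1[, keep, drop = FALSE]
  ref <- res$ref[keep]
  pct <- sweep(Fm, 2L, ref / 100, "/")
  lln <- lln_fraction * ref

  i_plateau <- which.min(abs(ages - constants$plateau_end_age))
  i_80 <- which.min(abs(ages - 80))
  span <- ages[i_80] - ages[i_plateau]
  decline <- 1000 * (Fm[, i_plateau] - Fm[, i_80]) / span

  col_sd <- function(m) { # SD of an ensemble of one is 0, not NA
    if (nrow(m) == 1L) rep(0, ncol(m)) else apply(m, 2L, stats::sd)
  }
  ens <- list(
    summary = data.frame(
      age = ages,
      mean_fev1_L = colMeans(Fm),
      sd_fev1_L = col_sd(Fm),
      mean_pct_ref = colMeans(pct),
      sd_pct_ref = col_sd(pct),
      frac_below_lln = colMeans(sweep(Fm, 2L, lln, "<"))
    ),
    decline_ml_yr = decline,
    mean_decline_ml_yr = mean(decline),
    fev1_at_age = Fm,
    ages = ages,
    lln_fraction = lln_fraction,
    spec = spec,
    constants = constants
  )
  class(ens) <- "easi_ensemble"
  ens
}

#' @export
print.easi_ensemble <- function(x, ...) {
  cat("<easi_ensemble> ", x$spec$n_models, " models (seed ", x$spec$seed,
      ", ", if (x$spec$smoker) "smokers" else "non-smokers", ")\n",
      "  mean adult decline: ", format(round(x$mean_decline_ml_yr, 1)),
      " ml/yr\n", sep = "")
  decades <- x$summary[x$summary$age %% 10 == 0, ]
  print.data.frame(decades, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Per-model FEV1 distribution at one age
#'
#' @param ens an `easi_ensemble` from [run_ensemble()].
#' @param age integer age within the stored grid.
#' @return numeric vector of FEV1 (liters), one per model.
#' @export
ensemble_fev1 <- function(ens, age) {
  stopifnot(inherits(ens, "easi_ensemble"))
  if (abs(age - round(age)) > 1e-9) {
    stop("age ", age, " not in the stored grid (integer ages only)",
         call. = FALSE)
  }
  i <- match(round(age), ens$ages)
  if (is.na(i)) stop("age ", age, " not in the stored grid", call. = FALSE)
  ens$fev1_at_age[, i]
}

#' Fraction of models below the lower limit of normality
#'
#' The LLN is a configurable fraction of the internal reference trajectory
#' (default 0.80), a stand-in for published reference-equation LLNs.
#'
#' @param ens an `easi_ensemble` from [run_ensemble()].
#' @param age integer age within the stored grid.
#' @param lln_fraction threshold as a fraction of [reference_fev1()].
#' @return fraction in `[0, 1]`.
#' @export
fraction_below_lln <- function(ens, age, lln_fraction = ens$lln_fraction) {
  fev1 <- ensemble_fev1(ens, age) # errors on ages outside the stored grid
  lln <- lln_fraction * reference_fev1(round(age), ens$constants)
  mean(fev1 < lln)
}

# Relative squared-error loss of an ensemble against mean/SD targets and an
# optional mean-decline target.
ensemble_loss <- function(ens, targets, decline_target = NULL) {
  m <- stats::approx(ens$summary$age, ens$summary$mean_fev1_L,
                     xout = targets$age)$y
  s <- stats::approx(ens$summary$age, ens$summary$sd_fev1_L,
                     xout = targets$age)$y
  if (any(is.na(m))) stop("target ages outside the simulated window",
                          call. = FALSE)
  loss <- sum(((m - targets$mean_fev1_L) / pmax(targets$mean_fev1_L, 1e-6))^2)
  if (!is.null(targets$sd_fev1_L)) {
    loss <- loss + sum(((s - targets$sd_fev1_L) /
                          pmax(targets$sd_fev1_L, 0.05))^2)
  }
  if (!is.null(decline_target)) {
    loss <- loss + ((ens$mean_decline_ml_yr - decline_target) /
                      decline_target)^2
  }
  loss
}

#' Calibrate population dispersion against FEV1 targets
#'
#' Seeded, derivative-free random search over the common coefficient of
#' variation (and optionally selected parameter centers), minimizing the
#' summed relative squared error between the ensemble mean/SD FEV1 curves and
#' the supplied targets, plus an optional mean-decline target. Candidate
#' ensembles reuse `spec$seed` (common random numbers), so the loss surface
#' is deterministic and the whole search is reproducible given the seed.
#'
#' @param spec starting [population_spec()].
#' @param targets data frame with columns `age`, `mean_fev1_L` and optionally
#'   `sd_fev1_L`.
#' @param decline_target optional target mean adult decline, ml/year.
#' @param vary character vector: `"cv"` and/or names of dispersed parameters
#'   whose centers to vary (e.g. `"max_decline"`).
#' @param budget number of candidate evaluations.
#' @param step_sd log-normal proposal SD of the multiplicative perturbations.
#' @param constants an [easi_constants()] object.
#' @return an object of class `easi_calibration`: list with the best `spec`,
#'   its `loss`, the `initial_loss`, an `improved` flag (when no candidate
#'   improved the starting spec is returned with a diagnostic `message`), and
#'   the search `trace`.
#' @export
calibrate_population <- function(spec, targets, decline_target = NULL,
                                 vary = "cv", budget = 100, step_sd = 0.4,
                                 constants = easi_constants()) {
  stopifnot(inherits(spec, "easi_population_spec"))
  if (is.null(targets) || nrow(targets) == 0L) {
    stop("calibrate_population(): `targets` must be non-empty", call. = FALSE)
  }
  stopifnot(all(c("age", "mean_fev1_L") %in% names(targets)))

  make_spec <- function(theta) {
    s <- spec
    if ("cv" %in% names(theta)) {
      s <- population_spec(spec$n_models, spec$seed, spec$smoker,
                           cv = unname(theta[["cv"]]))
    }
    for (nm in setdiff(names(theta), "cv")) {
      i <- match(nm, s$dispersion$param)
      if (is.na(i)) stop("unknown parameter to vary: ", nm, call. = FALSE)
      s$dispersion$center[i] <- unname(theta[[nm]])
    }
    s
  }
  theta0 <- vapply(vary, function(v) {
    if (v == "cv") spec$cv
    else spec$dispersion$center[match(v, spec$dispersion$param)]
  }, numeric(1))
  names(theta0) <- vary
  if (any(is.na(theta0))) stop("unknown parameter in `vary`", call. = FALSE)

  eval_loss <- function(theta) {
    ensemble_loss(run_ensemble(make_spec(theta), constants),
                  targets, decline_target)
  }
  best_theta <- theta0
  best_loss <- initial_loss <- eval_loss(theta0)
  trace <- data.frame(eval = 0L, loss = best_loss, accepted = TRUE)
  steps <- with_seed(derive_seed(spec$seed, 999983L),
                     matrix(rnorm(budget * length(theta0), 0, step_sd),
                            nrow = budget))
  for (k in seq_len(budget)) {
    cand <- best_theta * exp(steps[k, ])
    if ("cv" %in% names(cand)) cand[["cv"]] <- min(cand[["cv"]], 1)
    loss <- tryCatch(eval_loss(cand), error = function(e) Inf)
    acc <- loss < best_loss
    if (acc) {
      best_loss <- loss
      best_theta <- cand
    }
    trace <- rbind(trace, data.frame(eval = k, loss = loss, accepted = acc))
  }
  improved <- best_loss < initial_loss
  out <- list(
    spec = make_spec(best_theta),
    theta = best_theta,
    loss = best_loss,
    initial_loss = initial_loss,
    improved = improved,
    message = if (improved) "search improved on the starting specification"
              else "search budget exhausted without improvement; returning the input specification",
    trace = trace
  )
  class(out) <- "easi_calibration"
  out
}

#' @export
print.easi_calibration <- function(x, ...) {
  cat("<easi_calibration> loss ", format(x$initial_loss), " -> ",
      format(x$loss), " (", sum(x$trace$accepted[-1]), " accepted / ",
      nrow(x$trace) - 1L, " evaluated)\n  ", x$message, "\n", sep = "")
  print(x$theta)
  invisible(x)
}
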