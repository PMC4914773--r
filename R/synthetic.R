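# Synthetic quantitative-image-cytometry-style data: the acquisition design
# (snapshots every 2 min, 0-50 min, thousands of cells per well, negligible
# measurement noise) and a version-stamped synthetic ground truth used as the
# acceptance surface for the whole pipeline.
#
# The fixture numbers are the package's own synthetic choices: the study's
# inferred values are not public, so the values below were picked once to
# satisfy the stated phenomenology (a ppMEK/ppERK transient peaking within
# ~10 min that relaxes toward a sustained level, population CV ~0.3-0.6) and
# are NOT the study's estimates.

#' Default snapshot acquisition design
#'
#' Snapshots on t = 0, 2, ..., 50 min, 1,000 cells per time point
#' (configurable up to the ~1e4 seeding density), zero measurement noise.
#'
#' @param cells_per_time cells per time point (>= 1)
#' @param times acquisition grid (min)
#' @param measurement_cv multiplicative measurement-noise CV (default 0)
#' @param dose_label metadata label
#' @return object of class `acquisition_design`
#' @export
default_design <- function(cells_per_time = 1000L, times = default_times(),
                           measurement_cv = 0, dose_label = "NGF_synthetic") {
  stopifnot(cells_per_time >= 1)
  structure(list(times = times, cells_per_time = as.integer(cells_per_time),
                 measurement_cv = measurement_cv, dose_label = dose_label),
            class = "acquisition_design")
}

#' Synthetic reference parameter vector (single cell)
#'
#' Version-stamped synthetic ground truth for the distributive model; see the
#' note above — these are not inferred values from any experiment.
#'
#' @return named numeric parameter vector
#' @export
reference_parameters <- function() {
  c(a1 = 3, d1 = 1, c1 = 3, a2 = 3, d2 = 1, c2 = 3,
    a3 = 3, d3 = 1, c3 = 3, a4 = 3, d4 = 1, c4 = 3,
    k1 = 0.5, k2 = 0.5, k10 = 0.1, T_pulse = 4,
    E_tot = 1, P_tot = 0.3, M0 = 0.05, Epp0 = 0.05)
}

#' Synthetic reference hyperparameters per scenario
#'
#' `"extrinsic"`: population CVs on the five strongly contributing factors
#' (k1, k2, k10 and the two background-activity initial conditions M0, Epp0),
#' all other parameters fixed. `"driving_only"`: CVs only on k1 and k10.
#' `"intrinsic"`: all population variances zero and a small system size.
#'
#' @param scenario one of `"extrinsic"`, `"intrinsic"`, `"driving_only"`
#' @return `reference_fixture`: list with `name`, `version`, `scenario`,
#'   `theta`, `hyper`, `omega`, `intrinsic`
#' @export
reference_hyperparameters <- function(scenario = c("extrinsic", "intrinsic",
                                                   "driving_only")) {
  scenario <- match.arg(scenario)
  theta <- reference_parameters()
  cv <- setNames(rep(0, length(theta)), names(theta))
  omega <- Inf
  intrinsic <- FALSE
  if (scenario == "extrinsic") {
    cv[c("k1", "k2", "k10", "M0", "Epp0")] <- c(0.4, 0.3, 0.4, 0.5, 0.5)
  } else if (scenario == "driving_only") {
    cv[c("k1", "k10")] <- c(0.4, 0.4)
  } else {
    omega <- 50
    intrinsic <- TRUE
  }
  structure(list(name = paste0("synthetic-", scenario), version = "1.0.0",
                 scenario = scenario, theta = theta,
                 hyper = hyper_params(theta, cv = cv),
                 omega = omega, intrinsic = intrinsic),
            class = "reference_fixture")
}

#' Generate a synthetic snapshot dataset
#'
#' Fresh cohort of cells per time point (destructive sampling); per-cell
#' parameters drawn from the fixture population; deterministic dynamics for
#' extrinsic scenarios, SSA at the fixture system size for the intrinsic
#' scenario; optional multiplicative log-normal measurement noise.
#'
#' @param model an `erk_model`
#' @param fixture a `reference_fixture`
#' @param design an `acquisition_design`
#' @param seed integer RNG seed
#' @return a `snapshot_data`
#' @export
generate_qic_dataset <- function(model = build_distributive_model(),
                                 fixture = reference_hyperparameters("extrinsic"),
                                 design = default_design(), seed = 1L) {
  population_simulate(model, fixture$hyper, design$cells_per_time,
                      design$times, seed = seed,
                      intrinsic = fixture$intrinsic,
                      omega = if (is.finite(fixture$omega)) fixture$omega else NULL,
                      measurement_cv = design$measurement_cv,
                      dose_label = design$dose_label)
}
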