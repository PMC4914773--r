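# Glue between the likelihoods and the SMC sampler: standard fits used by the
# pipeline (intrinsic-noise model, extrinsic-noise model, average-data fit for
# mechanism selection), each returning weighted particles plus an evidence
# estimate.

.default_cv_prior <- list(family = "log-uniform", lower = 1e-3, upper = 10)

#' Fit the extrinsic-noise model to snapshot data
#'
#' Samples the posterior over population hyperparameters (natural-scale mean
#' and CV of each free parameter) under the UT/log-normal extrinsic
#' likelihood. Non-free parameters are fixed at `center` with zero variance.
#'
#' @param snapshot a `snapshot_data`
#' @param model an `erk_model`
#' @param center named baseline parameter vector (fixed values + prior centers)
#' @param free names of parameters whose population mean and CV are inferred
#' @param n_particles,ess_threshold,move_count,seed SMC settings
#' @param decades width of the log-uniform mean priors
#' @param verbose print tempering progress
#' @return `weighted_particles` fit; particle columns `mean_<p>` and `cv_<p>`
#' @export
fit_extrinsic <- function(snapshot, model, center, free,
                          n_particles = 256L, ess_threshold = 0.5,
                          move_count = 2L, seed = 1L, decades = 6,
                          verbose = FALSE) {
  stopifnot(all(free %in% model$param_names))
  specs <- list()
  for (p in free) {
    specs[[paste0("mean_", p)]] <- list(family = "log-uniform",
                                        lower = center[[p]] / 10^(decades / 2),
                                        upper = center[[p]] * 10^(decades / 2))
    specs[[paste0("cv_", p)]] <- .default_cv_prior
  }
  prior <- make_prior(specs)
  snap_split <- .snapshot_split(snapshot)
  ll <- function(v) {
    mean <- center
    cv <- setNames(rep(0, length(center)), names(center))
    mean[free] <- v[paste0("mean_", free)]
    cv[free] <- v[paste0("cv_", free)]
    if (mean[["Epp0"]] > mean[["E_tot"]]) return(-Inf)
    hyper <- hyper_params(mean, cv = cv)
    loglik_extrinsic(model, hyper, snap_split)
  }
  fit <- smc_sample(ll, prior, n_particles, ess_threshold, move_count, seed,
                    verbose = verbose)
  fit$model_id <- paste0(model$name, "/extrinsic")
  fit$free <- free
  fit$center <- center
  fit
}

#' Fit the intrinsic-noise model to snapshot data
#'
#' Samples the posterior over a common parameter vector shared by all cells
#' plus the system size Omega, under the Gaussian LNA likelihood. Intrinsic
#' variance on the intensity scale is unidentifiable without Omega, so Omega
#' is inferred with a wide log-uniform prior.
#'
#' @inheritParams fit_extrinsic
#' @param free names of model parameters inferred (others fixed at `center`)
#' @param omega_bounds log-uniform prior bounds for the system size
#' @return `weighted_particles` fit; particle columns the free parameters plus
#'   `omega`
#' @export
fit_intrinsic <- function(snapshot, model, center, free,
                          omega_bounds = c(1e-1, 1e5),
                          n_particles = 256L, ess_threshold = 0.5,
                          move_count = 2L, seed = 1L, decades = 6,
                          verbose = FALSE) {
  stopifnot(all(free %in% model$param_names))
  specs <- list()
  for (p in free) {
    specs[[p]] <- list(family = "log-uniform",
                       lower = center[[p]] / 10^(decades / 2),
                       upper = center[[p]] * 10^(decades / 2))
  }
  specs[["omega"]] <- list(family = "log-uniform",
                           lower = omega_bounds[1], upper = omega_bounds[2])
  prior <- make_prior(specs)
  snap_split <- .snapshot_split(snapshot)
  ll <- function(v) {
    theta <- center
    theta[free] <- v[free]
    if (theta[["Epp0"]] > theta[["E_tot"]]) return(-Inf)
    loglik_intrinsic(model, theta, v[["omega"]], snap_split)
  }
  fit <- smc_sample(ll, prior, n_particles, ess_threshold, move_count, seed,
                    verbose = verbose)
  fit$model_id <- paste0(model$name, "/intrinsic")
  fit$free <- free
  fit$center <- center
  fit
}

#' Fit a mechanism to average trajectories (Gaussian measurement error)
#'
#' Used for distributive-vs-processive model selection on population-average
#' data; the measurement variance v is inferred simultaneously with the
#' parameters.
#'
#' @inheritParams fit_intrinsic
#' @param avg_data data.frame with `time_min`, `ppMEK`, `ppERK`
#' @param v_bounds log-uniform prior bounds for the measurement variance
#' @return `weighted_particles` fit
#' @export
fit_average <- function(avg_data, model, center, free,
                        v_bounds = NULL,
                        n_particles = 256L, ess_threshold = 0.5,
                        move_count = 2L, seed = 1L, decades = 6,
                        verbose = FALSE) {
  stopifnot(all(free %in% model$param_names))
  if (is.null(v_bounds)) {
    scale2 <- mean(c(avg_data$ppMEK, avg_data$ppERK))^2
    v_bounds <- c(1e-6 * scale2, 1 * scale2)
  }
  specs <- list()
  for (p in free) {
    specs[[p]] <- list(family = "log-uniform",
                       lower = center[[p]] / 10^(decades / 2),
                       upper = center[[p]] * 10^(decades / 2))
  }
  specs[["v"]] <- list(family = "log-uniform",
                       lower = v_bounds[1], upper = v_bounds[2])
  prior <- make_prior(specs)
  ll <- function(v) {
    theta <- center
    theta[free] <- v[free]
    if (theta[["Epp0"]] > theta[["E_tot"]]) return(-Inf)
    loglik_average(model, theta, v[["v"]], avg_data)
  }
  fit <- smc_sample(ll, prior, n_particles, ess_threshold, move_count, seed,
                    verbose = verbose)
  fit$model_id <- paste0(model$name, "/average")
  fit$free <- free
  fit$center <- center
  fit
}
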