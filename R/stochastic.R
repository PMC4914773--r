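# Intrinsic-noise engines: exact stochastic simulation (the oracle) and the
# linear noise approximation (the workhorse behind the intrinsic likelihood).

#' Exact stochastic simulation (Gillespie SSA)
#'
#' Simulates one exact jump path of the reaction network in molecule counts.
#' Concentrations x map to counts n = round(Omega * x); bimolecular count
#' propensities carry the 1/Omega scaling and the zeroth-order input fires at
#' rate Omega * u(t). With the step input the pulse end is handled as an exact
#' event boundary; with the smooth input the input channel is thinned against
#' a piecewise-constant bound.
#'
#' @param model an `erk_model`
#' @param theta parameter vector
#' @param omega system size (molecules per concentration unit), > 0
#' @param times ascending sampling times (min)
#' @param seed integer RNG seed
#' @return a `jump_sample`: list with `times`, `counts` (time x species),
#'   `observables` (counts scale), `omega`, `seed`
#' @export
ssa_simulate <- function(model, theta, omega, times = default_times(), seed = 1L) {
  stopifnot(omega > 0)
  n0 <- round(omega * initial_state(model, theta))
  if (all(n0 == 0) && theta[["k1"]] == 0 && theta[["k10"]] == 0)
    warning("degenerate SSA run: all initial counts zero and no input")
  set.seed(seed)
  tgrid <- .grid_from_zero(times)
  counts <- cpp_ssa(model$stoich, model$reactants, .rate_vector(model, theta),
                    model$input_rxn, as.integer(model$input_form == "smooth"),
                    theta[["k1"]], theta[["k10"]], theta[["T_pulse"]], omega,
                    n0, tgrid$times)
  counts <- tgrid$strip(counts)
  colnames(counts) <- model$species
  structure(list(times = times, counts = counts,
                 observables = counts %*% t(model$obs_weights),
                 omega = omega, seed = seed),
            class = "jump_sample")
}

#' Replicated SSA observables
#'
#' Convenience wrapper running `n_rep` independent SSA paths and returning the
#' observable totals only, on the concentration scale (counts / Omega).
#'
#' @inheritParams ssa_simulate
#' @param n_rep number of independent replicates
#' @return array `n_rep x length(times) x 2` (ppMEK, ppERK), concentration scale
#' @export
ssa_replicates <- function(model, theta, omega, times = default_times(),
                           n_rep = 100L, seed = 1L) {
  stopifnot(omega > 0, n_rep >= 1)
  n0 <- round(omega * initial_state(model, theta))
  set.seed(seed)
  tgrid <- .grid_from_zero(times)
  cube <- cpp_ssa_obs_many(model$stoich, model$reactants,
                           .rate_vector(model, theta),
                           model$input_rxn, as.integer(model$input_form == "smooth"),
                           theta[["k1"]], theta[["k10"]], theta[["T_pulse"]], omega,
                           n0, tgrid$times, model$obs_weights, as.integer(n_rep))
  cube <- tgrid$strip_cube(cube)
  dimnames(cube) <- list(NULL, NULL, c("ppMEK", "ppERK"))
  cube / omega
}

#' Linear noise approximation moments
#'
#' Integrates the macroscopic rate equations jointly with the LNA covariance
#' equation dSigma/dt = J Sigma + Sigma J' + S diag(f) S' / Omega (full matrix
#' form, concentration scale, so variances shrink as 1/Omega). Observable
#' moments are the linear projection through the ppMEK/ppERK map.
#'
#' @inheritParams ssa_simulate
#' @param observables_only if `TRUE` (default) return moments of
#'   (ppMEK_total, ppERK_total); otherwise of all species
#' @param rtol,atol integration tolerances
#' @return a `moment_trajectory`: list with `times`, `mean` (time x k),
#'   `cov` (k x k x time), `omega`
#' @export
lna_moments <- function(model, theta, omega, times = default_times(),
                        observables_only = TRUE, rtol = 1e-8, atol = 1e-10) {
  stopifnot(omega > 0)
  tgrid <- .grid_from_zero(times)
  res <- cpp_lna(model$stoich, model$reactants, .rate_vector(model, theta),
                 model$input_rxn, as.integer(model$input_form == "smooth"),
                 theta[["k1"]], theta[["k10"]], theta[["T_pulse"]], omega,
                 initial_state(model, theta), tgrid$times, rtol, atol)
  if (!res$ok) {
    stop(structure(class = c("erk_solver_error", "error", "condition"),
                   list(message = "LNA integration failed", call = sys.call(),
                        theta = theta)))
  }
  mean <- tgrid$strip(res$mean)
  cov <- res$cov[, , if (tgrid$times[1] < times[1]) -1 else seq_along(times),
                 drop = FALSE]
  colnames(mean) <- model$species
  if (observables_only) {
    W <- model$obs_weights
    m2 <- mean %*% t(W)
    c2 <- array(0, c(2, 2, length(times)),
                dimnames = list(rownames(W), rownames(W), NULL))
    for (k in seq_along(times)) c2[, , k] <- W %*% cov[, , k] %*% t(W)
    mean <- m2
    cov <- c2
  } else {
    dimnames(cov) <- list(model$species, model$species, NULL)
  }
  structure(list(times = times, mean = mean, cov = cov, omega = omega),
            class = "moment_trajectory")
}

#' Write a moment trajectory to CSV
#'
#' Columns: time_min, mean per component, then the covariance flattened
#' row-major as cov_i_j.
#' @param mom a `moment_trajectory`
#' @param path output file
#' @export
write_moments_csv <- function(mom, path) {
  k <- ncol(mom$mean)
  covflat <- t(apply(mom$cov, 3, function(S) as.vector(t(S))))
  nm <- as.vector(t(outer(seq_len(k), seq_len(k),
                          function(i, j) paste0("cov_", i, "_", j))))
  df <- data.frame(time_min = mom$times, mom$mean, covflat, check.names = FALSE)
  colnames(df) <- c("time_min", paste0("mean_", colnames(mom$mean)), nm)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a jump sample to CSV
#' @param js a `jump_sample`
#' @param path output file
#' @export
write_jump_csv <- function(js, path) {
  df <- data.frame(time_min = js$times, js$counts, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
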