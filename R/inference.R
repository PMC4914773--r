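# The three likelihood functions of the framework:
#   - average-data Gaussian likelihood (deterministic ODE fit, used for
#     mechanism selection on population-average trajectories),
#   - intrinsic-noise likelihood (Gaussian with LNA means/variances),
#   - extrinsic-noise likelihood (log-normal with UT-propagated moments).
# Plus prior specifications and Bayes-factor model ranking.

# Cross-sectional snapshot indexed by time; computed once per fit and reused
# across likelihood evaluations.
.snapshot_split <- function(snapshot) {
  if (inherits(snapshot, "erk_snapshot_split")) return(snapshot)
  stopifnot(all(c("time_min", "ppMEK", "ppERK") %in% names(snapshot)))
  times <- sort(unique(snapshot$time_min))
  structure(list(times = times,
                 x = split(snapshot$ppMEK, factor(snapshot$time_min, levels = times)),
                 y = split(snapshot$ppERK, factor(snapshot$time_min, levels = times)),
                 all_positive = all(snapshot$ppMEK > 0) && all(snapshot$ppERK > 0)),
            class = "erk_snapshot_split")
}

#' Average-data Gaussian log-likelihood
#'
#' Independent Gaussian measurement error with constant variance v around the
#' deterministic ODE observables: sum over time points of the two normal
#' log-densities at (ppMEK_t, ppERK_t). When fitting, v is inferred
#' simultaneously with the model parameters.
#'
#' @param model an `erk_model`
#' @param theta parameter vector
#' @param v measurement variance, > 0
#' @param avg_data list/data.frame with `time_min`, `ppMEK`, `ppERK` (average
#'   trajectories on the model time grid)
#' @return log-likelihood (scalar); `-Inf` on solver failure
#' @export
loglik_average <- function(model, theta, v, avg_data) {
  stopifnot(v > 0)
  traj <- tryCatch(solve_ode(model, theta, avg_data$time_min,
                             rtol = 1e-7, atol = 1e-9),
                   erk_solver_error = function(e) NULL)
  if (is.null(traj)) return(-Inf)
  r <- c(avg_data$ppMEK - traj$observables[, "ppMEK"],
         avg_data$ppERK - traj$observables[, "ppERK"])
  sum(dnorm(r, 0, sqrt(v), log = TRUE))
}

#' Intrinsic-noise log-likelihood (LNA)
#'
#' Cross-sectional single-cell likelihood under pure intrinsic noise: every
#' cell shares the parameter vector theta and the observables are Gaussian
#' with the LNA marginal means and variances at each time; cells are
#' independent within and across time points (destructive sampling).
#'
#' @param model an `erk_model`
#' @param theta parameter vector
#' @param omega system size (> 0)
#' @param snapshot a `snapshot_data` data.frame
#' @param resolution_sd additive measurement-resolution SD (intensity units).
#'   At t = 0 the LNA covariance is exactly zero (deterministic initial
#'   condition), so without a floor any observed spread at t = 0 has zero
#'   likelihood. The same floor, on the same (natural) scale, is applied in
#'   [loglik_extrinsic()] so that model-evidence comparisons are not decided
#'   by floor asymmetries.
#' @return log-likelihood; `-Inf` if the LNA fails or yields negative
#'   variances beyond tolerance
#' @export
loglik_intrinsic <- function(model, theta, omega, snapshot,
                             resolution_sd = 1e-3) {
  d <- .snapshot_split(snapshot)
  mom <- tryCatch(lna_moments(model, theta, omega, d$times,
                              rtol = 1e-6, atol = 1e-8),
                  erk_solver_error = function(e) NULL)
  if (is.null(mom)) return(-Inf)
  vx <- pmax(mom$cov[1, 1, ], 0) + resolution_sd^2
  vy <- pmax(mom$cov[2, 2, ], 0) + resolution_sd^2
  if (any(!is.finite(vx)) || any(!is.finite(vy))) return(-Inf)
  ll <- 0
  for (k in seq_along(d$times)) {
    ll <- ll + sum(dnorm(d$x[[k]], mom$mean[k, 1], sqrt(vx[k]), log = TRUE)) +
      sum(dnorm(d$y[[k]], mom$mean[k, 2], sqrt(vy[k]), log = TRUE))
  }
  ll
}

#' Extrinsic-noise log-likelihood (UT + log-normal)
#'
#' Cross-sectional likelihood under pure extrinsic noise: observables are
#' log-normally distributed with natural-scale mean and variance propagated
#' from the parameter population by the unscented transform; the log-normal
#' density is evaluated through moment matching. A measurement-resolution
#' variance `resolution_sd^2` is added on the natural scale (mirroring
#' [loglik_intrinsic()]) so the degenerate var -> 0 limit stays finite and
#' the two likelihoods treat zero-spread data symmetrically; `var_floor` is
#' an additional numerical guard on the log-scale variance.
#'
#' @param model an `erk_model`
#' @param hyper a `hyper_params`
#' @param snapshot a `snapshot_data`; all intensities must be > 0 (log-normal
#'   support) or an error is raised
#' @param var_floor numerical floor for the log-scale variance (default 1e-12)
#' @param resolution_sd additive measurement-resolution SD, natural scale
#' @param moment_space `"log"` (default): parameterize the log-normal by
#'   UT moments of the log observables, exact for log-linear maps (notably at
#'   t = 0); `"natural"`: propagate natural-scale moments and convert via
#'   [moment_match_lognormal()]
#' @return log-likelihood; `-Inf` on propagation failure
#' @export
loglik_extrinsic <- function(model, hyper, snapshot, var_floor = 1e-12,
                             resolution_sd = 1e-3,
                             moment_space = c("log", "natural")) {
  moment_space <- match.arg(moment_space)
  if (!inherits(snapshot, "erk_snapshot_split") &&
      (any(snapshot$ppMEK <= 0) || any(snapshot$ppERK <= 0)))
    stop("extrinsic likelihood requires strictly positive intensities ",
         "(log-normal support); offending rows: ",
         paste(utils::head(which(snapshot$ppMEK <= 0 | snapshot$ppERK <= 0), 5),
               collapse = ", "))
  d <- .snapshot_split(snapshot)
  if (!d$all_positive)
    stop("extrinsic likelihood requires strictly positive intensities")
  mom <- tryCatch(ut_propagate(model, hyper, d$times, rtol = 1e-6, atol = 1e-8,
                               space = moment_space),
                  error = function(e) NULL)
  if (is.null(mom)) return(-Inf)
  mx <- mom$mean[, 1]; my <- mom$mean[, 2]
  vx <- pmax(mom$cov[1, 1, ], 0); vy <- pmax(mom$cov[2, 2, ], 0)
  if (any(!is.finite(c(mx, my, vx, vy)))) return(-Inf)
  if (moment_space == "log") {
    # convert log moments to natural moments, add the resolution variance,
    # and re-match; reduces to the raw log moments when resolution_sd = 0
    nx <- lognormal_moments(mx, vx)
    ny <- lognormal_moments(my, vy)
    if (any(!is.finite(c(nx$m, nx$v, ny$m, ny$v))) ||
        any(nx$m <= 0) || any(ny$m <= 0)) return(-Inf)
    px <- moment_match_lognormal(nx$m, nx$v + resolution_sd^2)
    py <- moment_match_lognormal(ny$m, ny$v + resolution_sd^2)
  } else {
    if (any(mx <= 0) || any(my <= 0)) return(-Inf)
    px <- moment_match_lognormal(mx, vx + resolution_sd^2)
    py <- moment_match_lognormal(my, vy + resolution_sd^2)
  }
  sx <- sqrt(pmax(px$s2_log, var_floor))
  sy <- sqrt(pmax(py$s2_log, var_floor))
  ll <- 0
  for (k in seq_along(d$times)) {
    ll <- ll +
      sum(dlnorm(d$x[[k]], px$mu_log[k], sx[k], log = TRUE)) +
      sum(dlnorm(d$y[[k]], py$mu_log[k], sy[k], log = TRUE))
  }
  ll
}

# ---- priors ---------------------------------------------------------------

#' Prior specification
#'
#' Independent per-parameter priors. Supported families: `"log-uniform"`
#' (uniform in log over [lower, upper]), `"log-normal"` (meanlog, sdlog) and
#' `"uniform"` (lower, upper). Rate-like parameters must use a
#' positive-support family.
#'
#' @param specs named list; each element is a list with `family` and its
#'   parameters (`lower`/`upper` or `meanlog`/`sdlog`)
#' @return object of class `erk_prior`
#' @export
make_prior <- function(specs) {
  for (nm in names(specs)) {
    s <- specs[[nm]]
    fam <- match.arg(s$family, c("log-uniform", "log-normal", "uniform"))
    specs[[nm]]$family <- fam
    if (fam %in% c("log-uniform", "uniform"))
      stopifnot(s$lower < s$upper, fam != "log-uniform" || s$lower > 0)
    else stopifnot(s$sdlog > 0)
  }
  structure(list(specs = specs), class = "erk_prior")
}

#' Default log-uniform prior spanning `decades` decades centered on a value
#' @param center strictly positive center(s), named
#' @param decades total width in log10 units (default 6)
#' @return an `erk_prior`
#' @export
prior_around <- function(center, decades = 6) {
  stopifnot(all(center > 0))
  half <- 10^(decades / 2)
  make_prior(setNames(lapply(names(center), function(p) {
    list(family = "log-uniform", lower = center[[p]] / half,
         upper = center[[p]] * half)
  }), names(center)))
}

prior_dim <- function(prior) length(prior$specs)

# sample on the natural scale
prior_sample <- function(prior, n) {
  out <- matrix(NA_real_, n, prior_dim(prior),
                dimnames = list(NULL, names(prior$specs)))
  for (nm in names(prior$specs)) {
    s <- prior$specs[[nm]]
    out[, nm] <- switch(s$family,
      "log-uniform" = exp(runif(n, log(s$lower), log(s$upper))),
      "log-normal" = rlnorm(n, s$meanlog, s$sdlog),
      "uniform" = runif(n, s$lower, s$upper))
  }
  out
}

# log-density on the SAMPLING scale used by the SMC (z = log theta for
# positive-support families, z = theta for the uniform family)
.prior_uses_log <- function(prior) {
  vapply(prior$specs, function(s) s$family != "uniform", logical(1))
}

prior_logdensity_z <- function(prior, z_mat) {
  ld <- numeric(nrow(z_mat))
  for (j in seq_along(prior$specs)) {
    s <- prior$specs[[j]]
    z <- z_mat[, j]
    ld <- ld + switch(s$family,
      "log-uniform" = ifelse(z >= log(s$lower) & z <= log(s$upper),
                             -log(log(s$upper) - log(s$lower)), -Inf),
      "log-normal" = dnorm(z, s$meanlog, s$sdlog, log = TRUE),
      "uniform" = ifelse(z >= s$lower & z <= s$upper,
                         -log(s$upper - s$lower), -Inf))
  }
  ld
}

#' Marginal prior CDF (for diagnostics and calibration tests)
#' @param prior an `erk_prior`
#' @param name parameter name
#' @param q natural-scale quantile values
#' @return CDF values
#' @export
prior_cdf <- function(prior, name, q) {
  s <- prior$specs[[name]]
  switch(s$family,
    "log-uniform" = pmin(1, pmax(0, (log(q) - log(s$lower)) /
                                   (log(s$upper) - log(s$lower)))),
    "log-normal" = plnorm(q, s$meanlog, s$sdlog),
    "uniform" = pmin(1, pmax(0, (q - s$lower) / (s$upper - s$lower))))
}

# ---- Bayes factor ---------------------------------------------------------

#' Bayes factor between two evidence results
#'
#' BF = exp(logZ_A - logZ_B). Evidence in favor of A is labelled
#' "very strong" when BF > 30; smaller values are graded on the conventional
#' scale.
#'
#' @param evA,evB `evidence_result` objects (or lists with `log_evidence`)
#' @return list with `bf`, `log_bf`, `label`
#' @export
bayes_factor <- function(evA, evB) {
  stopifnot(is.finite(evA$log_evidence), is.finite(evB$log_evidence))
  lbf <- evA$log_evidence - evB$log_evidence
  bf <- exp(lbf)
  label <- if (bf > 30) "very strong"
           else if (bf > 10) "strong"
           else if (bf > 3) "substantial"
           else if (bf >= 1) "weak"
           else "negative"
  list(bf = bf, log_bf = lbf, label = label)
}
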