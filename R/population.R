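# Extrinsic noise: cell-to-cell parameter variability. Parameters vary across
# the population following independent log-normal laws specified by their
# natural-scale means and variances; moments of the observables are propagated
# either by Monte Carlo over sampled cells or by the unscented transform.

#' Match natural-scale moments of a log-normal
#'
#' Given the natural-scale mean m and variance v of a log-normal variable,
#' returns the log-scale parameters: sigma2_log = log(1 + v/m^2),
#' mu_log = log(m) - sigma2_log/2. `v = 0` gives the degenerate point mass.
#'
#' @param m natural mean, > 0 (vectorized)
#' @param v natural variance, >= 0
#' @return list with `mu_log` and `s2_log`
#' @export
moment_match_lognormal <- function(m, v) {
  stopifnot(all(m > 0), all(v >= 0))
  s2 <- log1p(v / m^2)
  list(mu_log = log(m) - s2 / 2, s2_log = s2)
}

#' Natural-scale moments of a log-normal (inverse of [moment_match_lognormal()])
#' @param mu_log,s2_log log-scale mean and variance
#' @return list with `m` (mean) and `v` (variance)
#' @export
lognormal_moments <- function(mu_log, s2_log) {
  m <- exp(mu_log + s2_log / 2)
  list(m = m, v = m^2 * expm1(s2_log))
}

#' Population hyperparameters: per-parameter log-normal mean/variance
#'
#' @param mean named natural-scale population means (one per model parameter)
#' @param cv per-parameter coefficient of variation (sd/mean); variance is
#'   derived as `(cv*mean)^2`. Either `cv` or `var` must be given.
#' @param var per-parameter natural-scale variances (alternative to `cv`)
#' @param varies optional logical mask; defaults to `var > 0`
#' @return object of class `hyper_params` with fields `mean`, `var`, `varies`
#' @export
hyper_params <- function(mean, cv = NULL, var = NULL, varies = NULL) {
  stopifnot(!is.null(names(mean)), all(mean > 0))
  if (is.null(var)) {
    if (is.null(cv)) cv <- setNames(rep(0, length(mean)), names(mean))
    if (length(cv) == 1L) cv <- setNames(rep(cv, length(mean)), names(mean))
    cv <- cv[names(mean)]
    cv[is.na(cv)] <- 0
    var <- (cv * mean)^2
  } else {
    var <- var[names(mean)]
    var[is.na(var)] <- 0
  }
  stopifnot(all(var >= 0))
  if (is.null(varies)) varies <- var > 0
  varies <- setNames(as.logical(varies), names(mean))
  if (any(var > 0 & !varies)) stop("var > 0 requires varies = TRUE")
  structure(list(mean = mean, var = setNames(as.numeric(var), names(mean)),
                 varies = varies), class = "hyper_params")
}

#' Serialize hyperparameters to a JSON config block (round-trippable)
#' @param hyper a `hyper_params`
#' @param path optional file; if `NULL` the JSON string is returned
#' @export
hyper_to_json <- function(hyper, path = NULL) {
  cv <- ifelse(hyper$mean > 0, sqrt(hyper$var) / hyper$mean, 0)
  doc <- lapply(names(hyper$mean), function(p) {
    list(mean = hyper$mean[[p]], cv = cv[[p]], varies = hyper$varies[[p]])
  })
  names(doc) <- names(hyper$mean)
  js <- jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @rdname hyper_to_json
#' @export
hyper_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path)
  mean <- vapply(doc, function(d) d$mean, numeric(1))
  cv <- vapply(doc, function(d) d$cv, numeric(1))
  varies <- vapply(doc, function(d) isTRUE(d$varies), logical(1))
  hyper_params(mean, cv = cv, varies = varies | cv > 0)
}

#' @export
print.hyper_params <- function(x, ...) {
  cv <- ifelse(x$mean > 0, sqrt(x$var) / x$mean, 0)
  cat("<hyper_params>\n")
  print(data.frame(mean = x$mean, cv = round(cv, 4), varies = x$varies))
  invisible(x)
}

#' Draw per-cell parameter vectors from the population
#'
#' Each varying parameter is drawn independently log-normal with moments
#' matched to the hyperparameters; fixed parameters are copied from the mean
#' (no correlation between parameters).
#'
#' @param hyper a `hyper_params`
#' @param n_cells number of cells
#' @param seed integer RNG seed
#' @return matrix `n_cells x n_params` of class `cell_parameter_set`
#' @export
sample_cell_parameters <- function(hyper, n_cells, seed = 1L) {
  stopifnot(n_cells >= 1)
  set.seed(seed)
  nm <- names(hyper$mean)
  out <- matrix(rep(hyper$mean, each = n_cells), n_cells, length(nm),
                dimnames = list(NULL, nm))
  for (p in nm[hyper$varies & hyper$var > 0]) {
    mm <- moment_match_lognormal(hyper$mean[[p]], hyper$var[[p]])
    out[, p] <- rlnorm(n_cells, mm$mu_log, sqrt(mm$s2_log))
  }
  # guard the structural constraint Epp0 <= E_tot (resample offenders)
  if (all(c("Epp0", "E_tot") %in% nm)) {
    bad <- which(out[, "Epp0"] > out[, "E_tot"])
    guard <- 0L
    while (length(bad) && guard < 100L) {
      for (p in intersect(c("Epp0", "E_tot"), nm[hyper$varies & hyper$var > 0])) {
        mm <- moment_match_lognormal(hyper$mean[[p]], hyper$var[[p]])
        out[bad, p] <- rlnorm(length(bad), mm$mu_log, sqrt(mm$s2_log))
      }
      bad <- which(out[, "Epp0"] > out[, "E_tot"])
      guard <- guard + 1L
    }
    if (length(bad)) out[bad, "Epp0"] <- 0.99 * out[bad, "E_tot"]
  }
  structure(out, class = c("cell_parameter_set", "matrix", "array"), seed = seed)
}

# split a cells-x-params matrix into the pieces the C++ batch solvers take
.population_pieces <- function(model, theta_mat) {
  n <- nrow(theta_mat)
  rate_mat <- matrix(0, n, length(model$rate_names))
  for (j in seq_along(model$rate_names)) {
    rn <- model$rate_names[j]
    rate_mat[, j] <- if (rn == "input") NA_real_ else theta_mat[, rn]
  }
  x0 <- matrix(0, n, length(model$species),
               dimnames = list(NULL, model$species))
  x0[, "M"] <- theta_mat[, "M0"]
  x0[, "Epp"] <- theta_mat[, "Epp0"]
  x0[, "E"] <- theta_mat[, "E_tot"] - theta_mat[, "Epp0"]
  x0[, "P"] <- theta_mat[, "P_tot"]
  list(rate_mat = rate_mat, k1 = theta_mat[, "k1"], k10 = theta_mat[, "k10"],
       Tp = theta_mat[, "T_pulse"], x0 = x0)
}

# deterministic observables for every row of a cell-parameter matrix:
# returns cube cells x times x 2
.population_observables <- function(model, theta_mat, times,
                                    rtol = 1e-6, atol = 1e-8) {
  pp <- .population_pieces(model, theta_mat)
  tgrid <- .grid_from_zero(times)
  res <- cpp_solve_obs_many(model$stoich, model$reactants, pp$rate_mat,
                            model$input_rxn,
                            as.integer(model$input_form == "smooth"),
                            pp$k1, pp$k10, pp$Tp, pp$x0, tgrid$times,
                            model$obs_weights, rtol, atol)
  if (any(res$ok == 0)) warning(sum(res$ok == 0), " cells failed to integrate")
  obs <- tgrid$strip_cube(res$obs)
  dimnames(obs) <- list(NULL, NULL, c("ppMEK", "ppERK"))
  obs
}

#' Propagate population moments with the unscented transform
#'
#' Places 2d+1 scaled sigma points (alpha = 1, beta = 2, kappa = 0) in
#' log-parameter space, where the log-normal population is exactly Gaussian,
#' maps each through exp -> ODE solve -> observables, and returns the weighted
#' mean and variance of (ppMEK_total, ppERK_total) per time point.
#'
#' @param model an `erk_model`
#' @param hyper a `hyper_params`; d = number of varying parameters must be >= 1
#' @param times output times (min)
#' @param rtol,atol ODE tolerances
#' @param space `"natural"`: moments of the observables themselves;
#'   `"log"`: moments of their logarithms (exact whenever the map from log
#'   parameters to log observables is linear, e.g. at t = 0; preferred inside
#'   the log-normal extrinsic likelihood)
#' @return a `moment_trajectory` over the two observables; attribute
#'   `moment_space` records the space
#' @export
ut_propagate <- function(model, hyper, times = default_times(),
                         rtol = 1e-8, atol = 1e-10,
                         space = c("natural", "log")) {
  space <- match.arg(space)
  nm <- names(hyper$mean)
  vary <- nm[hyper$varies & hyper$var > 0]
  d <- length(vary)
  mu_log <- setNames(numeric(length(nm)), nm)
  sd_log <- setNames(numeric(length(nm)), nm)
  for (p in nm) {
    mm <- moment_match_lognormal(hyper$mean[[p]], hyper$var[[p]])
    mu_log[p] <- mm$mu_log
    sd_log[p] <- sqrt(mm$s2_log)
  }
  if (d == 0L) {
    traj <- solve_ode(model, hyper$mean, times, rtol, atol)
    mean <- if (space == "log") log(traj$observables) else traj$observables
    k <- ncol(mean)
    cov <- array(0, c(k, k, length(times)),
                 dimnames = list(colnames(mean), colnames(mean), NULL))
    return(structure(list(times = times, mean = mean, cov = cov,
                          omega = Inf), class = "moment_trajectory",
                     moment_space = space))
  }
  # sigma points: center + mu_log +- sqrt(d) * sd_log along each varying axis
  npt <- 2L * d + 1L
  sig <- matrix(rep(mu_log, each = npt), npt, length(nm),
                dimnames = list(NULL, nm))
  for (i in seq_len(d)) {
    p <- vary[i]
    sig[2L * i, p] <- mu_log[p] + sqrt(d) * sd_log[p]
    sig[2L * i + 1L, p] <- mu_log[p] - sqrt(d) * sd_log[p]
  }
  theta_mat <- exp(sig)
  if (any(theta_mat[, "Epp0"] > theta_mat[, "E_tot"]))
    stop("unscented transform: sigma point violates Epp0 <= E_tot ",
         "(population places substantial mass on invalid parameterizations)")
  obs <- .population_observables(model, theta_mat, times, rtol, atol)
  if (any(!is.finite(obs))) {
    bad <- which(apply(!is.finite(obs), 1, any))[1]
    stop("unscented transform: non-finite ODE output at sigma point ", bad)
  }
  if (space == "log") {
    if (any(obs <= 0))
      stop("unscented transform: non-positive observable; log-space moments undefined")
    obs <- log(obs)
  }
  # scaled-UT weights (alpha = 1, beta = 2, kappa = 0): mean weight 0 on the
  # center point, 1/(2d) elsewhere; covariance center weight 2
  wm <- c(0, rep(1 / (2 * d), 2 * d))
  wc <- c(2, rep(1 / (2 * d), 2 * d))
  mean <- apply(obs, c(2, 3), function(col) sum(wm * col))
  k <- dim(obs)[3]
  cov <- array(0, c(k, k, length(times)),
               dimnames = list(dimnames(obs)[[3]], dimnames(obs)[[3]], NULL))
  for (t in seq_along(times)) {
    Y <- obs[, t, ]           # npt x k
    dev <- sweep(Y, 2, mean[t, ])
    cov[, , t] <- t(dev) %*% (wc * dev)
  }
  structure(list(times = times, mean = mean, cov = cov, omega = Inf),
            class = "moment_trajectory", moment_space = space)
}

#' Simulate a heterogeneous cell population (snapshot data)
#'
#' Draws a fresh cohort of cells at every time point (destructive,
#' cross-sectional sampling: no cell is observed twice), simulates each cell
#' deterministically or by SSA, and records the two observables. Optional
#' multiplicative log-normal measurement noise.
#'
#' @param model an `erk_model`
#' @param hyper a `hyper_params`
#' @param n_per_time cells per time point
#' @param times snapshot times (min)
#' @param seed integer RNG seed
#' @param intrinsic `FALSE` for deterministic per-cell dynamics, `TRUE` for SSA
#' @param omega system size, required when `intrinsic = TRUE`
#' @param measurement_cv multiplicative log-normal measurement-error CV
#'   (default 0: experimental noise is negligible)
#' @param dose_label metadata label attached to the snapshot
#' @return a `snapshot_data`: data.frame with columns time_min, cell_id,
#'   ppMEK, ppERK, dose_label (plus attributes seed/mode)
#' @export
population_simulate <- function(model, hyper, n_per_time,
                                times = default_times(), seed = 1L,
                                intrinsic = FALSE, omega = NULL,
                                measurement_cv = 0, dose_label = "synthetic") {
  stopifnot(n_per_time >= 1)
  if (intrinsic && is.null(omega)) stop("omega required when intrinsic = TRUE")
  set.seed(seed)
  rows <- vector("list", length(times))
  cell0 <- 0L
  for (ti in seq_along(times)) {
    tt <- times[ti]
    seeds <- sample.int(.Machine$integer.max - 1L, 2L)
    cohort_seed <- seeds[1]
    theta_mat <- sample_cell_parameters(hyper, n_per_time, seed = cohort_seed)
    if (!intrinsic) {
      obs <- .population_observables(model, theta_mat, c(0, tt)[if (tt > 0) 1:2 else 1],
                                     rtol = 1e-6, atol = 1e-8)
      take <- dim(obs)[2]
      x <- obs[, take, "ppMEK"]
      y <- obs[, take, "ppERK"]
    } else {
      pp <- .population_pieces(model, theta_mat)
      set.seed(seeds[2])
      cube <- cpp_ssa_obs_population(model$stoich, model$reactants, pp$rate_mat,
                                     model$input_rxn,
                                     as.integer(model$input_form == "smooth"),
                                     pp$k1, pp$k10, pp$Tp, omega,
                                     round(omega * pp$x0),
                                     c(0, tt)[if (tt > 0) 1:2 else 1],
                                     model$obs_weights)
      take <- dim(cube)[2]
      x <- cube[, take, 1] / omega
      y <- cube[, take, 2] / omega
    }
    if (measurement_cv > 0) {
      mm <- moment_match_lognormal(1, measurement_cv^2)
      x <- x * rlnorm(n_per_time, mm$mu_log, sqrt(mm$s2_log))
      y <- y * rlnorm(n_per_time, mm$mu_log, sqrt(mm$s2_log))
    }
    rows[[ti]] <- data.frame(time_min = tt,
                             cell_id = cell0 + seq_len(n_per_time),
                             ppMEK = x, ppERK = y, dose_label = dose_label)
    cell0 <- cell0 + n_per_time
  }
  snap <- do.call(rbind, rows)
  attr(snap, "seed") <- seed
  attr(snap, "mode") <- if (intrinsic) sprintf("intrinsic(omega=%g)", omega) else "extrinsic"
  class(snap) <- c("snapshot_data", "data.frame")
  snap
}

#' Total variance: intrinsic + extrinsic (law of total variance)
#'
#' Draws `n_outer` parameter sets from the population; for each, computes the
#' LNA mean and variance of the observables; returns, per time point, the
#' decomposition Var_total = E[Var_intrinsic | theta] + Var[E_intrinsic |
#' theta].
#'
#' @inheritParams population_simulate
#' @param omega system size for the intrinsic (LNA) component
#' @param n_outer number of parameter draws (>= 2)
#' @return list with per-time matrices (`times` x 2 observables): `total`,
#'   `mean_intrinsic_var`, `var_of_means`
#' @export
total_variance <- function(model, hyper, omega, times = default_times(),
                           n_outer = 200L, seed = 1L) {
  stopifnot(n_outer >= 2)
  theta_mat <- sample_cell_parameters(hyper, n_outer, seed = seed)
  means <- array(NA_real_, c(n_outer, length(times), 2))
  vars <- array(NA_real_, c(n_outer, length(times), 2))
  for (i in seq_len(n_outer)) {
    mom <- lna_moments(model, theta_mat[i, ], omega, times,
                       rtol = 1e-6, atol = 1e-8)
    means[i, , ] <- mom$mean
    vars[i, , 1] <- mom$cov[1, 1, ]
    vars[i, , 2] <- mom$cov[2, 2, ]
  }
  miv <- apply(vars, c(2, 3), mean)
  vom <- apply(means, c(2, 3), function(z) stats::var(z) * (length(z) - 1) / length(z))
  dimnames(miv) <- dimnames(vom) <- list(NULL, c("ppMEK", "ppERK"))
  list(times = times, total = miv + vom,
       mean_intrinsic_var = miv, var_of_means = vom)
}
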