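# Source attribution of cell-to-cell variability: variance decomposition by
# parameter group, posterior CV ranking of contributors, and the lambda scan
# quantifying how output heterogeneity tracks input (k1, k10) heterogeneity.

#' Named parameter groups for variance decomposition
#'
#' upstream = {k1, k2, k10}; initial_conditions = {E_tot, P_tot, M0, Epp0};
#' reaction_rates = the binding/unbinding/catalysis cycle rates;
#' driving = {k1, k10}; all = every parameter. T_pulse is kept fixed
#' (non-varying) by default and can be added to the upstream group.
#'
#' @param model an `erk_model`
#' @param t_pulse_upstream include T_pulse in the upstream group
#' @return named list of character vectors
#' @export
group_masks <- function(model = build_distributive_model(),
                        t_pulse_upstream = FALSE) {
  nm <- model$param_names
  rates <- grep("^[adc][0-9]$", nm, value = TRUE)
  upstream <- c("k1", "k2", "k10")
  if (t_pulse_upstream) upstream <- c(upstream, "T_pulse")
  list(upstream = upstream,
       initial_conditions = c("E_tot", "P_tot", "M0", "Epp0"),
       reaction_rates = rates,
       driving = c("k1", "k10"),
       all = nm)
}

.restrict_hyper <- function(hyper, keep) {
  var <- hyper$var
  var[setdiff(names(var), keep)] <- 0
  hyper_params(hyper$mean, var = var)
}

# per-time observable variances for a hyperparameter set, by UT or Monte Carlo
.engine_variance <- function(model, hyper, times, engine = c("ut", "mc"),
                             n = 10000L, seed = 1L) {
  engine <- match.arg(engine)
  if (!any(hyper$var > 0)) {
    z <- matrix(0, length(times), 2, dimnames = list(NULL, c("ppMEK", "ppERK")))
    traj <- solve_ode(model, hyper$mean, times)
    return(list(mean = traj$observables, var = z))
  }
  if (engine == "ut") {
    mom <- ut_propagate(model, hyper, times)
    v <- cbind(ppMEK = mom$cov[1, 1, ], ppERK = mom$cov[2, 2, ])
    return(list(mean = mom$mean, var = pmax(v, 0)))
  }
  theta_mat <- sample_cell_parameters(hyper, n, seed = seed)
  obs <- .population_observables(model, theta_mat, times)
  list(mean = apply(obs, c(2, 3), mean), var = apply(obs, c(2, 3), var),
       obs = obs)
}

#' Predicted observable variances when only one parameter group varies
#'
#' Copies the hyperparameters, zeroes the population variances outside the
#' requested group, and propagates the restricted population.
#'
#' @param model an `erk_model`
#' @param hyper full `hyper_params`
#' @param group group name from [group_masks()] or a character vector of
#'   parameter names
#' @param times output times (min)
#' @param engine `"ut"` (deterministic sigma points) or `"mc"` (sampling)
#' @param n Monte Carlo population size (engine "mc")
#' @param seed RNG seed (engine "mc")
#' @return data.frame time_min, var_ppMEK, var_ppERK
#' @export
variance_by_group <- function(model, hyper, group, times = default_times(),
                              engine = c("ut", "mc"), n = 10000L, seed = 1L) {
  masks <- group_masks(model)
  keep <- if (is.character(group) && length(group) == 1L && group %in% names(masks))
    masks[[group]] else as.character(group)
  stopifnot(length(keep) >= 1, all(keep %in% model$param_names))
  res <- .engine_variance(model, .restrict_hyper(hyper, keep), times,
                          engine, n, seed)
  data.frame(time_min = times, var_ppMEK = res$var[, "ppMEK"],
             var_ppERK = res$var[, "ppERK"])
}

#' Rank extrinsic-noise contributors by posterior coefficient of variation
#'
#' For each inferred parameter, summarizes the posterior of its population CV
#' (median and 5-95% credible interval) and flags parameters whose lower
#' credible bound exceeds `threshold` as significant contributors; ranked by
#' the lower bound.
#'
#' @param fit a `weighted_particles` from [fit_extrinsic()] (columns
#'   `cv_<p>`), or a particle matrix with such columns plus a `weights` vector
#' @param weights optional weights when `fit` is a bare matrix
#' @param threshold significance threshold on the lower 5% CV bound
#' @return data.frame (parameter, cv_median, cv_lo, cv_hi, significant),
#'   ordered by decreasing cv_lo
#' @export
rank_contributors <- function(fit, weights = NULL, threshold = 0.05) {
  if (is.matrix(fit)) {
    particles <- fit
    if (is.null(weights)) weights <- rep(1 / nrow(fit), nrow(fit))
  } else {
    particles <- fit$particles
    weights <- fit$weights
  }
  cv_cols <- grep("^cv_", colnames(particles), value = TRUE)
  stopifnot(length(cv_cols) >= 1)
  out <- do.call(rbind, lapply(cv_cols, function(cc) {
    q <- .weighted_quantile(particles[, cc], weights, c(0.05, 0.5, 0.95))
    data.frame(parameter = sub("^cv_", "", cc),
               cv_lo = q[1], cv_median = q[2], cv_hi = q[3])
  }))
  out$significant <- out$cv_lo > threshold
  out <- out[order(-out$cv_lo), ]
  rownames(out) <- NULL
  out
}

#' Input-variability (lambda) scan
#'
#' For each pair of input SDs (sigma_k1, sigma_k10) computes the per-time SD
#' s(sigma_k1, sigma_k10, t) of the output (ppERK_total) across the
#' population, and the ratio lambda = s / s(sigma*, sigma*, t), where
#' sigma*_k1 = mu_k1 and sigma*_k10 = mu_k10 are the maximal (reference)
#' input SDs. In `"driving"` mode all parameters other than k1, k10 are fixed
#' at their means; in `"full"` mode the remaining extrinsic variances are
#' retained.
#'
#' @param model an `erk_model`
#' @param hyper full `hyper_params` (means set the reference SDs)
#' @param sigma_k1,sigma_k10 grids of input SDs, in (0, mu]
#' @param times output times (min)
#' @param mode `"driving"` or `"full"`
#' @param engine `"ut"` or `"mc"`
#' @param n,seed Monte Carlo settings (common random numbers across the grid)
#' @return `lambda_scan` object: arrays `lambda` and `s`
#'   (sigma_k1 x sigma_k10 x time), the grids, mode, and the reference SDs
#' @export
lambda_scan <- function(model, hyper, sigma_k1, sigma_k10,
                        times = default_times(), mode = c("driving", "full"),
                        engine = c("ut", "mc"), n = 10000L, seed = 1L) {
  mode <- match.arg(mode)
  engine <- match.arg(engine)
  mu1 <- hyper$mean[["k1"]]
  mu10 <- hyper$mean[["k10"]]
  if (mu1 <= 0 || mu10 <= 0) stop("reference SDs are zero: mu_k1/mu_k10 must be > 0")
  stopifnot(all(sigma_k1 > 0), all(sigma_k1 <= mu1 + 1e-12),
            all(sigma_k10 > 0), all(sigma_k10 <= mu10 + 1e-12))
  base_var <- if (mode == "driving")
    setNames(rep(0, length(hyper$mean)), names(hyper$mean)) else hyper$var
  sd_at <- function(s1, s10) {
    v <- base_var
    v[["k1"]] <- s1^2
    v[["k10"]] <- s10^2
    h <- hyper_params(hyper$mean, var = v)
    res <- .engine_variance(model, h, times, engine, n, seed)
    sqrt(pmax(res$var[, "ppERK"], 0))
  }
  s_ref <- sd_at(mu1, mu10)
  if (any(s_ref == 0))
    warning("reference output SD is zero at some times; lambda undefined there")
  s <- array(NA_real_, c(length(sigma_k1), length(sigma_k10), length(times)))
  for (i in seq_along(sigma_k1)) for (j in seq_along(sigma_k10))
    s[i, j, ] <- sd_at(sigma_k1[i], sigma_k10[j])
  lambda <- sweep(s, 3, s_ref, "/")
  structure(list(sigma_k1 = sigma_k1, sigma_k10 = sigma_k10, times = times,
                 s = s, lambda = lambda, s_ref = s_ref, mode = mode,
                 engine = engine,
                 sigma_star = c(k1 = mu1, k10 = mu10)),
            class = "lambda_scan")
}

#' Tidy a lambda scan for export/plotting
#' @param scan a `lambda_scan`
#' @return data.frame (time_min, sigma_k1, sigma_k10, s, lambda)
#' @export
lambda_scan_table <- function(scan) {
  g <- expand.grid(i = seq_along(scan$sigma_k1), j = seq_along(scan$sigma_k10),
                   k = seq_along(scan$times))
  data.frame(time_min = scan$times[g$k],
             sigma_k1 = scan$sigma_k1[g$i],
             sigma_k10 = scan$sigma_k10[g$j],
             s = scan$s[cbind(g$i, g$j, g$k)],
             lambda = scan$lambda[cbind(g$i, g$j, g$k)])
}
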