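# Likelihood-tempered sequential Monte Carlo sampler with adaptive
# temperature schedule, systematic resampling, and adaptive Gaussian
# random-walk Metropolis moves in the (log-transformed) sampling space.
# The sum of the log incremental normalizing constants estimates the log
# model evidence.

.ess <- function(w) 1 / sum(w^2)

.systematic_resample <- function(w, n) {
  u <- (runif(1) + 0:(n - 1)) / n
  cum <- cumsum(w)
  findInterval(u, cum, left.open = TRUE) + 1L
}

# bisect for the largest temperature increment delta such that the effective
# sample size of the reweighted cloud stays at ess_target
.next_delta <- function(W, ll, gamma, ess_target) {
  reweight <- function(delta) {
    a <- delta * ll
    a[W == 0] <- -Inf
    m <- max(a[is.finite(a)], -Inf)
    if (!is.finite(m)) return(NULL)
    w <- W * exp(a - m)
    s <- sum(w)
    if (s == 0 || !is.finite(s)) return(NULL)
    w / s
  }
  hi <- 1 - gamma
  w <- reweight(hi)
  if (!is.null(w) && .ess(w) >= ess_target) return(hi)
  lo <- 0
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    w <- reweight(mid)
    if (!is.null(w) && .ess(w) >= ess_target) lo <- mid else hi <- mid
  }
  max(lo, 1e-10 * (1 - gamma))
}

#' Sequential Monte Carlo sampler with model-evidence estimate
#'
#' Samples from posterior ~ prior(theta) * L(theta) by tempering the
#' likelihood, p_gamma ~ prior * L^gamma, with the temperature increment
#' chosen adaptively by bisection so that the effective sample size of the
#' reweighted particle cloud equals `ess_threshold * n_particles`. After each
#' reweighting the cloud is resampled systematically and diversified with
#' `move_count` adaptive Gaussian random-walk Metropolis steps (proposal
#' covariance 2.38^2/d times the current cloud covariance, in log space for
#' positive-support priors). The log evidence is the accumulated log of the
#' incremental weight sums. Fully deterministic given `seed`.
#'
#' @param loglik function(named numeric vector) -> log-likelihood
#' @param prior an `erk_prior`
#' @param n_particles number of particles (>= 16)
#' @param ess_threshold relative ESS target in (0, 1)
#' @param move_count Metropolis moves per tempering step
#' @param seed integer RNG seed
#' @param verbose print schedule progress
#' @return list with `particles` (natural scale, one row per particle),
#'   `weights`, `log_evidence`, `mc_error`, `schedule` (gammas),
#'   `acceptance`, `seed`; classes `weighted_particles` and `evidence_result`
#' @export
smc_sample <- function(loglik, prior, n_particles = 1000L,
                       ess_threshold = 0.5, move_count = 2L, seed = 1L,
                       verbose = FALSE) {
  stopifnot(n_particles >= 16, ess_threshold > 0, ess_threshold < 1)
  set.seed(seed)
  n <- as.integer(n_particles)
  d <- prior_dim(prior)
  use_log <- .prior_uses_log(prior)
  to_z <- function(theta_mat) {
    z <- theta_mat
    z[, use_log] <- log(theta_mat[, use_log, drop = FALSE])
    z
  }
  to_theta <- function(z_mat) {
    th <- z_mat
    th[, use_log] <- exp(z_mat[, use_log, drop = FALSE])
    th
  }
  eval_ll <- function(z_mat) {
    th <- to_theta(z_mat)
    vapply(seq_len(nrow(th)), function(i) {
      v <- loglik(th[i, ])
      if (!is.finite(v)) -Inf else v
    }, numeric(1))
  }

  z <- to_z(prior_sample(prior, n))
  ll <- eval_ll(z)
  if (all(ll == -Inf))
    stop("SMC initialization failed: likelihood is -Inf for every prior draw ",
         "(prior/model mismatch)")
  W <- rep(1 / n, n)
  gamma <- 0
  prop_scale <- 1.0  # adapted toward ~23% RWM acceptance
  schedule <- numeric(0)
  increments <- numeric(0)
  inc_boot_var <- numeric(0)
  acceptance <- numeric(0)
  ess_target <- ess_threshold * n

  while (gamma < 1) {
    delta <- .next_delta(W, ll, gamma, ess_target)
    a <- delta * ll
    m <- max(a[W > 0 & is.finite(a)])
    wu <- W * exp(a - m)
    inc <- m + log(sum(wu))               # log sum_i W_i L_i^delta
    W <- wu / sum(wu)
    gamma <- min(1, gamma + delta)
    schedule <- c(schedule, gamma)
    increments <- c(increments, inc)
    # delta-method variance of the log increment under multinomial bootstrap
    inc_boot_var <- c(inc_boot_var, max(0, (sum(wu^2) / sum(wu)^2) - 1 / n))

    if (.ess(W) < n - 1e-9) {             # skip when weights stayed uniform
      idx <- .systematic_resample(W, n)
      z <- z[idx, , drop = FALSE]
      ll <- ll[idx]
      W <- rep(1 / n, n)
      # adaptive RWM targeting p_gamma
      C <- stats::cov(z)
      C <- C + diag(1e-10 + 1e-6 * mean(diag(C)), d)
      L <- chol(2.38^2 / d * C)
      lp <- prior_logdensity_z(prior, z)
      acc <- 0L
      for (mv in seq_len(move_count)) {
        zprop <- z + prop_scale * (matrix(rnorm(n * d), n, d) %*% L)
        lpprop <- prior_logdensity_z(prior, zprop)
        ok <- which(is.finite(lpprop))
        llprop <- rep(-Inf, n)
        if (length(ok)) llprop[ok] <- eval_ll(zprop[ok, , drop = FALSE])
        logr <- gamma * (llprop - ll) + lpprop - lp
        u <- runif(n)
        take <- which(log(u) < logr)
        if (length(take)) {
          z[take, ] <- zprop[take, , drop = FALSE]
          ll[take] <- llprop[take]
          lp[take] <- lpprop[take]
          acc <- acc + length(take)
        }
        rate <- length(take) / n
        prop_scale <- max(0.05, min(10, prop_scale * exp(rate - 0.234)))
      }
      acceptance <- c(acceptance, acc / (n * move_count))
    } else {
      acceptance <- c(acceptance, NA_real_)
    }
    if (verbose)
      message(sprintf("gamma = %.5f, log-evidence so far = %.3f",
                      gamma, sum(increments)))
  }

  particles <- to_theta(z)
  colnames(particles) <- names(prior$specs)
  structure(list(
    particles = particles,
    weights = W,
    log_evidence = sum(increments),
    mc_error = sqrt(sum(inc_boot_var)),
    schedule = schedule,
    increments = increments,
    acceptance = acceptance,
    seed = seed
  ), class = c("weighted_particles", "evidence_result"))
}

#' @export
print.weighted_particles <- function(x, ...) {
  cat(sprintf("<SMC fit: %d particles, %d temperature steps, log-evidence %.3f (mc error %.3f)>\n",
              nrow(x$particles), length(x$schedule), x$log_evidence, x$mc_error))
  invisible(x)
}

#' Weighted posterior quantiles of SMC particles
#' @param fit a `weighted_particles`
#' @param probs quantile levels
#' @return matrix parameters x probs
#' @export
posterior_quantiles <- function(fit, probs = c(0.05, 0.5, 0.95)) {
  out <- sapply(colnames(fit$particles), function(p) {
    .weighted_quantile(fit$particles[, p], fit$weights, probs)
  })
  t(out)
}

.weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]
  cw <- cumsum(w[o]) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

#' Maximum-weight particle ("inferred parameter vector")
#' @param fit a `weighted_particles`
#' @return named numeric vector
#' @export
inferred_parameters <- function(fit) {
  fit$particles[which.max(fit$weights), ]
}
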