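# Independent oracles kept deliberately naive: a fixed-step RK4 integrator in
# pure R (dual route for the package's adaptive C++ solver) and loop-based
# likelihood evaluations.

# mass-action drift assembled directly from the model description
oracle_drift <- function(model, theta, t, x) {
  f <- numeric(ncol(model$stoich))
  for (j in seq_along(f)) {
    rn <- model$rate_names[j]
    if (rn == "input") {
      f[j] <- upstream_input(t, theta[["k1"]], theta[["k10"]],
                             theta[["T_pulse"]], model$input_form)
    } else {
      f[j] <- theta[[rn]] * prod(x[model$reactants[[j]]])
    }
  }
  as.numeric(model$stoich %*% f)
}

# fixed-step classical RK4, stepping exactly onto the pulse boundary
oracle_rk4 <- function(model, theta, times, h = 0.001) {
  x <- initial_state(model, theta)
  out <- matrix(NA_real_, length(times), length(x),
                dimnames = list(NULL, names(x)))
  out[1, ] <- x
  t <- times[1]
  breaks <- sort(unique(c(times, theta[["T_pulse"]])))
  breaks <- breaks[breaks > t]
  for (b in breaks) {
    nstep <- max(1L, ceiling((b - t) / h))
    hh <- (b - t) / nstep
    for (s in seq_len(nstep)) {
      k1 <- oracle_drift(model, theta, t, x)
      k2 <- oracle_drift(model, theta, t + hh / 2, x + hh / 2 * k1)
      k3 <- oracle_drift(model, theta, t + hh / 2, x + hh / 2 * k2)
      k4 <- oracle_drift(model, theta, t + hh, x + hh * k3)
      x <- x + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + hh
    }
    t <- b
    k <- which(times == b)
    if (length(k)) out[k, ] <- x
  }
  list(times = times, states = out,
       observables = out %*% t(model$obs_weights))
}

# naive per-point Gaussian likelihood for average data
oracle_loglik_average <- function(model, theta, v, avg_data) {
  traj <- solve_ode(model, theta, avg_data$time_min, rtol = 1e-7, atol = 1e-9)
  ll <- 0
  for (k in seq_along(avg_data$time_min)) {
    ll <- ll + dnorm(avg_data$ppMEK[k], traj$observables[k, "ppMEK"], sqrt(v), log = TRUE)
    ll <- ll + dnorm(avg_data$ppERK[k], traj$observables[k, "ppERK"], sqrt(v), log = TRUE)
  }
  ll
}

# naive double-loop intrinsic likelihood (same solver settings and
# resolution floor as the vectorized implementation)
oracle_loglik_intrinsic <- function(model, theta, omega, snapshot,
                                    resolution_sd = 1e-3) {
  times <- sort(unique(snapshot$time_min))
  mom <- lna_moments(model, theta, omega, times, rtol = 1e-6, atol = 1e-8)
  ll <- 0
  for (k in seq_along(times)) {
    rows <- snapshot[snapshot$time_min == times[k], ]
    vx <- mom$cov[1, 1, k] + resolution_sd^2
    vy <- mom$cov[2, 2, k] + resolution_sd^2
    for (i in seq_len(nrow(rows))) {
      ll <- ll + dnorm(rows$ppMEK[i], mom$mean[k, 1], sqrt(vx), log = TRUE)
      ll <- ll + dnorm(rows$ppERK[i], mom$mean[k, 2], sqrt(vy), log = TRUE)
    }
  }
  ll
}

# log-normal density with mean m / variance v via explicit change of variables
# from the matched normal (independent of dlnorm)
oracle_dlognormal <- function(x, m, v) {
  s2 <- log(1 + v / m^2)
  mu <- log(m) - s2 / 2
  exp(-(log(x) - mu)^2 / (2 * s2)) / (x * sqrt(2 * pi * s2))
}

# closed-form marginal likelihood for the conjugate SMC toy:
# z = log(theta) ~ N(m0, s0^2), observation x | z ~ N(z, s^2)
oracle_toy_evidence <- function(x, m0, s0, s) {
  dnorm(x, m0, sqrt(s0^2 + s^2), log = TRUE)
}
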