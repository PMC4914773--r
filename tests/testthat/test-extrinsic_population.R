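# Log-normal parameter populations, unscented-transform propagation, and the
# law-of-total-variance decomposition.

test_that("log-normal moment matching is exact and invertible", {
  expect_equal(moment_match_lognormal(1, 0), list(mu_log = 0, s2_log = 0))
  # closed form: mu_log = 0, s2_log = 1 gives mean e^(1/2), var (e-1)e
  mm <- moment_match_lognormal(exp(0.5), (exp(1) - 1) * exp(1))
  expect_equal(mm$mu_log, 0, tolerance = 1e-12)
  expect_equal(mm$s2_log, 1, tolerance = 1e-12)
  # numerical verification against the density integral
  f <- function(x) x * dlnorm(x, mm$mu_log, sqrt(mm$s2_log))
  expect_equal(integrate(f, 0, Inf, rel.tol = 1e-10)$value, exp(0.5),
               tolerance = 1e-7)
  set.seed(1)
  for (i in 1:100) {
    m <- runif(1, 1e-3, 1e3)
    v <- runif(1, 0, m^2 * 4)
    mm <- moment_match_lognormal(m, v)
    back <- lognormal_moments(mm$mu_log, mm$s2_log)
    expect_equal(back$m, m, tolerance = 1e-12)
    expect_equal(back$v, v, tolerance = 1e-10)
  }
  expect_error(moment_match_lognormal(-1, 1))
})

test_that("hyper_params derives variances from CVs and validates the mask", {
  th <- reference_parameters()
  cv <- setNames(rep(0, 20), names(th)); cv["k1"] <- 0.3
  h <- hyper_params(th, cv = cv)
  expect_equal(h$var[["k1"]], (0.3 * th[["k1"]])^2)
  expect_true(h$varies[["k1"]])
  expect_false(any(h$varies[names(th) != "k1"]))
  expect_error(hyper_params(th, var = h$var,
                            varies = setNames(rep(FALSE, 20), names(th))))
})

test_that("population sampling matches the stated moments and independence", {
  th <- reference_parameters()
  h0 <- hyper_params(th)                      # all variances zero
  cells <- sample_cell_parameters(h0, 50, seed = 1)
  expect_true(all(apply(cells, 2, function(col) all(col == col[1]))))

  cv <- setNames(rep(0, 20), names(th))
  cv[c("k1", "k2", "k10", "E_tot")] <- c(0.4, 0.3, 0.5, 0.2)
  h <- hyper_params(th, cv = cv)
  cells <- sample_cell_parameters(h, 1e5, seed = 7)
  for (p in c("k1", "k2", "k10", "E_tot")) {
    se <- sd(cells[, p]) / sqrt(1e5)
    expect_lt(abs(mean(cells[, p]) - th[[p]]), 3 * se)
    # log of each marginal is Gaussian: skewness of log ~ 0
    lg <- log(cells[, p])
    expect_lt(abs(mean((lg - mean(lg))^3) / sd(lg)^3), 0.05)
  }
  r <- cor(cells[, c("k1", "k2", "k10", "E_tot")])
  expect_lt(max(abs(r[upper.tri(r)])), 0.02)
  expect_identical(sample_cell_parameters(h, 100, seed = 5),
                   sample_cell_parameters(h, 100, seed = 5))
})

test_that("UT reduces to the deterministic solution when variances vanish", {
  m <- build_distributive_model()
  th <- reference_parameters()
  h0 <- hyper_params(th)
  mom <- ut_propagate(m, h0)
  tr <- solve_ode(m, th)
  expect_equal(mom$mean, tr$observables, tolerance = 1e-8)
  expect_true(all(mom$cov == 0))
})

test_that("UT reproduces log-normal marginal moments through the identity map", {
  # ppERK at t = 0 equals Epp0 exactly, so varying only Epp0 makes the map
  # an identity on that parameter; at CV = 2% the sigma-point truncation
  # error (~sigma_log^4) is far below the 1e-6 tolerance
  m <- build_distributive_model()
  th <- reference_parameters()
  cv <- setNames(rep(0, 20), names(th)); cv["Epp0"] <- 0.02
  h <- hyper_params(th, cv = cv)
  mom <- ut_propagate(m, h, times = c(0, 2))
  expect_equal(unname(mom$mean[1, "ppERK"]), th[["Epp0"]], tolerance = 1e-6)
  expect_equal(mom$cov[2, 2, 1], (0.02 * th[["Epp0"]])^2, tolerance = 1e-6)
  # log-space flavor: exact log moments at t = 0
  mml <- moment_match_lognormal(th[["Epp0"]], (0.02 * th[["Epp0"]])^2)
  moml <- ut_propagate(m, h, times = c(0, 2), space = "log")
  expect_equal(unname(moml$mean[1, "ppERK"]), mml$mu_log, tolerance = 1e-9)
  expect_equal(moml$cov[2, 2, 1], mml$s2_log, tolerance = 1e-9)
})

test_that("UT variance agrees with a Monte Carlo population at CV = 5%", {
  m <- build_distributive_model()
  th <- reference_parameters()
  cv <- setNames(rep(0, 20), names(th))
  cv[c("k1", "k2", "k10", "M0", "Epp0")] <- 0.05
  h <- hyper_params(th, cv = cv)
  mom <- ut_propagate(m, h)
  cells <- sample_cell_parameters(h, 2e4, seed = 3)
  obs <- erknoise:::.population_observables(m, cells, default_times())
  v_mc <- apply(obs[, , "ppERK"], 2, var)
  expect_true(all(abs(mom$cov[2, 2, -1] / v_mc[-1] - 1) < 0.1))
})

test_that("population_simulate honors determinism and the degenerate limit", {
  m <- build_distributive_model()
  th <- reference_parameters()
  h0 <- hyper_params(th)
  snap <- population_simulate(m, h0, n_per_time = 3, times = c(0, 10, 20), seed = 1)
  tr <- solve_ode(m, th, c(0, 10, 20))
  for (k in 1:3) {
    rows <- snap[snap$time_min == c(0, 10, 20)[k], ]
    expect_equal(rows$ppMEK, rep(unname(tr$observables[k, "ppMEK"]), 3),
                 tolerance = 1e-5)
    expect_equal(rows$ppERK, rep(unname(tr$observables[k, "ppERK"]), 3),
                 tolerance = 1e-5)
  }
  h <- reference_hyperparameters("extrinsic")$hyper
  a <- population_simulate(m, h, 20, c(0, 10), seed = 42)
  b <- population_simulate(m, h, 20, c(0, 10), seed = 42)
  c <- population_simulate(m, h, 20, c(0, 10), seed = 43)
  expect_identical(a$ppERK, b$ppERK)
  expect_false(identical(a$ppERK, c$ppERK))
})

test_that("per-time population variance cross-validates the UT engine", {
  m <- build_distributive_model()
  th <- reference_parameters()
  cv <- setNames(rep(0, 20), names(th)); cv["k1"] <- 0.05
  h <- hyper_params(th, cv = cv)
  times <- c(0, 6, 20, 40)
  snap <- population_simulate(m, h, n_per_time = 10000, times = times, seed = 8)
  mom <- ut_propagate(m, h, times)
  for (k in 2:4) {
    v_emp <- var(snap$ppERK[snap$time_min == times[k]])
    expect_lt(abs(mom$cov[2, 2, k] / v_emp - 1), 0.15)
  }
})

test_that("total variance decomposes by the law of total variance", {
  m <- build_distributive_model()
  th <- reference_parameters()
  h0 <- hyper_params(th)
  times <- c(0, 10, 30)
  tv0 <- total_variance(m, h0, omega = 100, times = times, n_outer = 3, seed = 1)
  mom <- lna_moments(m, th, omega = 100, times = times)
  expect_equal(unname(tv0$total[, "ppERK"]), mom$cov[2, 2, ], tolerance = 1e-5)
  expect_true(all(tv0$var_of_means < 1e-12))

  h <- reference_hyperparameters("extrinsic")$hyper
  tv <- total_variance(m, h, omega = 100, times = times, n_outer = 150, seed = 2)
  expect_true(all(tv$mean_intrinsic_var >= 0))
  expect_true(all(tv$var_of_means >= 0))
  expect_equal(tv$total, tv$mean_intrinsic_var + tv$var_of_means)
  # intrinsic term scales away as 1/Omega: at huge Omega the total reduces to
  # the extrinsic-only variance of the same parameter draws
  tvbig <- total_variance(m, h, omega = 1e8, times = times, n_outer = 150, seed = 2)
  cells <- sample_cell_parameters(h, 150, seed = 2)
  obs <- erknoise:::.population_observables(m, cells, times)
  vext <- apply(obs[, , "ppERK"], 2, function(z) var(z) * (length(z) - 1) / length(z))
  expect_true(all(abs(tvbig$total[-1, "ppERK"] / vext[-1] - 1) < 0.05))
  expect_true(all(tv$total >= tv$var_of_means - 1e-12))
  expect_true(all(tv$total >= tv$mean_intrinsic_var - 1e-12))
})

test_that("hyperparameter config block round-trips through JSON", {
  h <- reference_hyperparameters("extrinsic")$hyper
  f <- tempfile(fileext = ".json")
  hyper_to_json(h, f)
  back <- hyper_from_json(f)
  expect_equal(back$mean, h$mean)
  expect_equal(back$var, h$var, tolerance = 1e-12)
  expect_equal(back$varies, h$varies)
  unlink(f)
})
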