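# The three likelihood functions against naive-loop and density oracles, the
# prior machinery, and Bayes-factor labelling.

test_that("average-data likelihood has the exact zero-residual value", {
  m <- build_distributive_model()
  th <- reference_parameters()
  tr <- solve_ode(m, th)
  avg <- data.frame(time_min = tr$times, ppMEK = tr$observables[, 1],
                    ppERK = tr$observables[, 2])
  # 26 time points x 2 observables, each contributing -0.5*log(2*pi) at v = 1
  expect_equal(loglik_average(m, th, 1, avg), -26 * log(2 * pi),
               tolerance = 1e-6)
})

test_that("average-data likelihood is the Gaussian quadratic form in residuals", {
  m <- build_distributive_model()
  th <- reference_parameters()
  tr <- solve_ode(m, th)
  set.seed(3)
  r <- rnorm(26, 0, 0.05)
  avg1 <- data.frame(time_min = tr$times, ppMEK = tr$observables[, 1] + r,
                     ppERK = tr$observables[, 2])
  avg2 <- avg1; avg2$ppMEK <- tr$observables[, 1] + 2 * r
  v <- 0.3
  drop <- loglik_average(m, th, v, avg1) - loglik_average(m, th, v, avg2)
  expect_equal(drop, 3 * sum(r^2) / (2 * v), tolerance = 1e-6)
  # naive per-point oracle
  expect_equal(loglik_average(m, th, v, avg1),
               oracle_loglik_average(m, th, v, avg1), tolerance = 1e-10)
})

test_that("intrinsic likelihood matches formula and naive double loop", {
  m <- build_distributive_model()
  th <- reference_parameters()
  mom <- lna_moments(m, th, omega = 100, times = c(0, 10),
                     rtol = 1e-6, atol = 1e-8)
  # single cell at the LNA mean: contribution is -0.5*log(2*pi*v) per obs,
  # with v carrying the additive measurement-resolution floor
  snap1 <- data.frame(time_min = 10, cell_id = 1,
                      ppMEK = mom$mean[2, 1], ppERK = mom$mean[2, 2])
  ll <- loglik_intrinsic(m, th, 100, snap1)
  expect_equal(ll, -0.5 * log(2 * pi * (mom$cov[1, 1, 2] + 1e-6)) -
                 0.5 * log(2 * pi * (mom$cov[2, 2, 2] + 1e-6)),
               tolerance = 1e-8)

  set.seed(11)
  snap <- data.frame(time_min = rep(c(4, 10, 30), each = 5), cell_id = 1:15,
                     ppMEK = abs(rnorm(15, 0.5, 0.1)),
                     ppERK = abs(rnorm(15, 0.4, 0.1)))
  expect_equal(loglik_intrinsic(m, th, 80, snap),
               oracle_loglik_intrinsic(m, th, 80, snap), tolerance = 1e-10)
  # exchangeability within a time point
  perm <- snap[order(-snap$cell_id), ]
  expect_equal(loglik_intrinsic(m, th, 80, perm),
               loglik_intrinsic(m, th, 80, snap), tolerance = 1e-12)
})

test_that("extrinsic log-normal density agrees with a change-of-variables oracle", {
  x <- c(0.3, 1.7, 0.02)
  m0 <- 0.8; v0 <- 0.1
  expect_equal(dlnorm(x, moment_match_lognormal(m0, v0)$mu_log,
                      sqrt(moment_match_lognormal(m0, v0)$s2_log)),
               oracle_dlognormal(x, m0, v0), tolerance = 1e-10)
})

test_that("extrinsic likelihood handles support, floors, and near-mode behavior", {
  m <- build_distributive_model()
  fx <- reference_hyperparameters("extrinsic")
  snap <- population_simulate(m, fx$hyper, 40, times = c(0, 10, 30), seed = 21)
  ll0 <- loglik_extrinsic(m, fx$hyper, snap)
  expect_true(is.finite(ll0))
  # moving the E_tot population mean far from truth degrades the likelihood
  worse <- fx$hyper
  worse$mean[["E_tot"]] <- 5 * worse$mean[["E_tot"]]
  expect_lt(loglik_extrinsic(m, worse, snap), ll0)
  # degenerate population on identical cells stays finite via the floor
  th <- reference_parameters()
  h0 <- hyper_params(th, cv = setNames(c(1e-9, rep(0, 19)), names(th)),
                     varies = c(TRUE, rep(FALSE, 19)))
  snap0 <- population_simulate(m, hyper_params(th), 3, times = c(10), seed = 1)
  expect_true(is.finite(loglik_extrinsic(m, h0, snap0)))
  # non-positive observations violate the log-normal support
  bad <- snap; bad$ppMEK[1] <- -1
  expect_error(loglik_extrinsic(m, fx$hyper, bad), "positive")
})

test_that("priors sample, evaluate, and report CDFs consistently", {
  pr <- make_prior(list(
    a = list(family = "log-uniform", lower = 0.01, upper = 100),
    b = list(family = "log-normal", meanlog = 1, sdlog = 0.5),
    c = list(family = "uniform", lower = -2, upper = 3)))
  set.seed(4)
  s <- prior_sample(pr, 5000)
  expect_true(all(s[, "a"] >= 0.01 & s[, "a"] <= 100))
  expect_true(all(s[, "c"] >= -2 & s[, "c"] <= 3))
  ks <- ks.test(s[, "a"], function(q) prior_cdf(pr, "a", q))
  expect_gt(ks$p.value, 0.01)
  # z-space density: log-uniform is flat in log
  z <- cbind(log(s[, "a"]), log(s[, "b"]), s[, "c"])
  ld <- prior_logdensity_z <- erknoise:::prior_logdensity_z(pr, z)
  expect_true(all(is.finite(ld)))
  expect_error(make_prior(list(a = list(family = "log-uniform",
                                        lower = -1, upper = 1))))
})

test_that("Bayes factor labelling follows the conventional scale", {
  ev <- function(l) list(log_evidence = l)
  expect_equal(bayes_factor(ev(2), ev(2))$bf, 1)
  expect_false(bayes_factor(ev(2), ev(2))$label == "very strong")
  # boundary at 30 is open: just above crosses into "very strong"
  expect_equal(bayes_factor(ev(log(30) + 1e-9), ev(0))$label, "very strong")
  expect_false(bayes_factor(ev(log(30) - 1e-9), ev(0))$label == "very strong")
  ab <- bayes_factor(ev(3), ev(1))
  ba <- bayes_factor(ev(1), ev(3))
  expect_equal(ab$bf * ba$bf, 1, tolerance = 1e-12)
})
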