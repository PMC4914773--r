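# Variance decomposition by parameter group, contributor ranking, and the
# lambda input-variability scan.

test_that("group masks partition the parameter set as documented", {
  g <- group_masks()
  expect_setequal(g$upstream, c("k1", "k2", "k10"))
  expect_setequal(g$initial_conditions, c("E_tot", "P_tot", "M0", "Epp0"))
  expect_length(g$reaction_rates, 12)
  expect_setequal(g$driving, c("k1", "k10"))
  expect_length(g$all, 20)
  expect_true("T_pulse" %in% group_masks(t_pulse_upstream = TRUE)$upstream)
})

test_that("variance_by_group: identity mask equals the full extrinsic variance", {
  m <- build_distributive_model()
  h <- reference_hyperparameters("extrinsic")$hyper
  times <- c(0, 10, 30)
  va <- variance_by_group(m, h, "all", times)
  mom <- ut_propagate(m, h, times)
  expect_equal(va$var_ppERK, unname(mom$cov[2, 2, ]), tolerance = 1e-8)
})

test_that("singleton groups are near-additive in the small-variance regime", {
  m <- build_distributive_model()
  th <- reference_parameters()
  vary <- c("k1", "k2", "k10", "M0", "Epp0")
  cv <- setNames(rep(0, 20), names(th)); cv[vary] <- 0.02
  h <- hyper_params(th, cv = cv)
  times <- c(10, 30, 50)
  vfull <- variance_by_group(m, h, "all", times)$var_ppERK
  vsum <- Reduce(`+`, lapply(vary, function(p)
    variance_by_group(m, h, p, times)$var_ppERK))
  expect_true(all(abs(vsum / vfull - 1) < 0.2))
  # any subgroup contributes at most the full variance (5% slack)
  for (g in c("upstream", "initial_conditions", "driving")) {
    vg <- variance_by_group(m, h, g, times)$var_ppERK
    expect_true(all(vg <= vfull * 1.05))
  }
})

test_that("contributor ranking summarizes posterior CVs correctly", {
  set.seed(2)
  n <- 400
  particles <- cbind(
    cv_k1 = rlnorm(n, log(0.4), 0.05),
    cv_k2 = rlnorm(n, log(0.3), 0.05),
    cv_a1 = rep(1e-8, n),                  # non-contributor: CV pinned at ~0
    mean_k1 = rlnorm(n, log(0.5), 0.05))
  rk <- rank_contributors(particles)
  expect_equal(rk$parameter[1:2], c("k1", "k2"))
  expect_false(rk$significant[rk$parameter == "a1"])
  expect_true(all(rk$significant[rk$parameter %in% c("k1", "k2")]))
  # invariant to particle order
  rk2 <- rank_contributors(particles[sample(n), ])
  expect_equal(rk2$parameter, rk$parameter)
  expect_equal(rk2$cv_median, rk$cv_median, tolerance = 1e-12)
})

test_that("lambda is 1 at the reference SDs and vanishes in the driving-only limit", {
  m <- build_distributive_model()
  h <- reference_hyperparameters("extrinsic")$hyper
  mu1 <- h$mean[["k1"]]; mu10 <- h$mean[["k10"]]
  times <- c(2, 10, 30, 50)
  scan <- lambda_scan(m, h, sigma_k1 = c(mu1 / 100, mu1 / 2, mu1),
                      sigma_k10 = c(mu10 / 100, mu10 / 2, mu10),
                      times = times, mode = "driving", engine = "ut")
  expect_equal(scan$lambda[3, 3, ], rep(1, 4), tolerance = 1e-10)
  # with no other variance source, tiny input SDs give tiny lambda
  expect_true(all(scan$lambda[1, 1, ] < 0.05))
  # monotone non-decreasing in each input SD (0.01 slack for the UT
  # engine's truncation wiggles where lambda is flat in one SD)
  for (k in seq_along(times)) {
    expect_true(all(diff(scan$lambda[, 1, k]) > -0.01))
    expect_true(all(diff(scan$lambda[1, , k]) > -0.01))
  }
})

test_that("full-extrinsic lambda plateaus above zero and matches Monte Carlo", {
  m <- build_distributive_model()
  h <- reference_hyperparameters("extrinsic")$hyper
  mu1 <- h$mean[["k1"]]; mu10 <- h$mean[["k10"]]
  times <- c(10, 30, 50)
  scan <- lambda_scan(m, h, sigma_k1 = c(mu1 / 20, mu1),
                      sigma_k10 = c(mu10 / 20, mu10),
                      times = times, mode = "full", engine = "ut")
  expect_true(all(scan$lambda[1, 1, ] > 0.1))
  expect_true(all(scan$lambda <= 1 + 0.01))  # UT truncation slack
  mcscan <- lambda_scan(m, h, sigma_k1 = c(mu1 / 20, mu1),
                        sigma_k10 = c(mu10 / 20, mu10),
                        times = times, mode = "full", engine = "mc",
                        n = 8000, seed = 6)
  expect_true(all(abs(mcscan$lambda[1, 1, ] - scan$lambda[1, 1, ]) /
                    scan$lambda[1, 1, ] < 0.1))
  # tidy export covers the full grid
  tab <- lambda_scan_table(scan)
  expect_equal(nrow(tab), 2 * 2 * 3)
  expect_true(all(c("time_min", "sigma_k1", "sigma_k10", "s", "lambda") %in%
                    names(tab)))
})

test_that("early lambda responds to pulse-height SD, late lambda to background SD", {
  # fixture mirror of the early/late input-sensitivity regimes: before the
  # pulse end output SD tracks sigma_k1; at late times it tracks sigma_k10
  m <- build_distributive_model()
  h <- reference_hyperparameters("driving_only")$hyper
  mu1 <- h$mean[["k1"]]; mu10 <- h$mean[["k10"]]
  scan <- lambda_scan(m, h, sigma_k1 = c(mu1 / 10, mu1),
                      sigma_k10 = c(mu10 / 10, mu10),
                      times = c(2, 50), mode = "driving", engine = "ut")
  d_k1_early <- scan$lambda[2, 1, 1] - scan$lambda[1, 1, 1]
  d_k10_early <- scan$lambda[1, 2, 1] - scan$lambda[1, 1, 1]
  d_k1_late <- scan$lambda[2, 1, 2] - scan$lambda[1, 1, 2]
  d_k10_late <- scan$lambda[1, 2, 2] - scan$lambda[1, 1, 2]
  expect_gt(d_k1_early, d_k10_early)
  expect_gt(d_k10_late, d_k1_late)
})

test_that("driving-only population reproduces the full-extrinsic MEK-ERK correlation", {
  m <- build_distributive_model()
  full <- population_simulate(m, reference_hyperparameters("extrinsic")$hyper,
                              2000, times = c(10, 30, 50), seed = 14)
  drv <- population_simulate(m, reference_hyperparameters("driving_only")$hyper,
                             2000, times = c(10, 30, 50), seed = 15)
  for (tt in c(10, 30, 50)) {
    cf <- cor(full$ppMEK[full$time_min == tt], full$ppERK[full$time_min == tt])
    cd <- cor(drv$ppMEK[drv$time_min == tt], drv$ppERK[drv$time_min == tt])
    expect_lt(abs(cf - cd), 0.15)
  }
})
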