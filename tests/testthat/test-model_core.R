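test_that("distributive model has the documented structure", {
  m <- build_distributive_model()
  expect_s3_class(m, "erk_model")
  expect_length(m$species, 9)
  expect_equal(ncol(m$stoich), 14)
  # 12 mass-action cycle rate parameters + 4 upstream + 4 initial conditions
  cycle <- grep("^[adc][0-9]$", m$param_names, value = TRUE)
  expect_length(cycle, 12)
  expect_length(m$param_names, 20)
  expect_setequal(setdiff(m$param_names, cycle),
                  c("k1", "k2", "k10", "T_pulse", "E_tot", "P_tot", "M0", "Epp0"))
  # structural conservation: ERK and phosphatase moieties have zero net
  # stoichiometry in every reaction column
  expect_true(all(colSums(m$stoich[m$erk_moiety, ]) == 0))
  expect_true(all(colSums(m$stoich[m$ptase_moiety, ]) == 0))
})

test_that("processive model is a reduced mechanism with the same conservation laws", {
  p <- build_processive_model()
  d <- build_distributive_model()
  expect_lt(ncol(p$stoich), ncol(d$stoich))
  expect_lt(length(p$param_names), length(d$param_names))
  expect_true(all(colSums(p$stoich[p$erk_moiety, ]) == 0))
  expect_true(all(colSums(p$stoich[p$ptase_moiety, ]) == 0))
})

test_that("upstream input is a pulse followed by background", {
  expect_equal(upstream_input(0, 5, 1, 4), 5)
  expect_equal(upstream_input(10, 5, 1, 4), 1)
  # half-open convention: the pulse end belongs to the background branch
  expect_equal(upstream_input(4, 5, 1, 4), 1)
  expect_error(upstream_input(-1, 5, 1, 4))
  # smooth variant relaxes from k1 to k10
  expect_equal(upstream_input(0, 5, 1, 4, form = "smooth"), 5)
  expect_equal(upstream_input(1e3, 5, 1, 4, form = "smooth"), 1, tolerance = 1e-6)
})

test_that("initial state encodes background activity and rejects Epp0 > E_tot", {
  m <- build_distributive_model()
  th <- reference_parameters()
  th[c("M0", "Epp0", "E_tot", "P_tot")] <- c(0, 0, 100, 10)
  x0 <- initial_state(m, th)
  expect_equal(unname(x0[c("E", "P")]), c(100, 10))
  expect_true(all(x0[setdiff(names(x0), c("E", "P"))] == 0))
  th["Epp0"] <- th["E_tot"]
  expect_equal(unname(initial_state(m, th)["E"]), 0)
  expect_equal(sum(initial_state(m, th)[m$erk_moiety]), unname(th["E_tot"]))
  th["Epp0"] <- th["E_tot"] + 1
  expect_error(initial_state(m, th), "Epp0")
})

test_that("erk_params validates positivity and completeness", {
  th <- reference_parameters()
  expect_s3_class(erk_params(th), "erk_params")
  bad <- th; bad["a1"] <- -1
  expect_error(erk_params(bad), "positive")
  expect_error(erk_params(th[-1]), "missing")
})

test_that("decoupled MEK subsystem matches the scalar linear-ODE closed form", {
  m <- build_distributive_model()
  th <- reference_parameters()
  th[c("a1", "a2", "a3", "a4")] <- 1e-14   # decouple the cycle
  th["M0"] <- 0
  th["k10"] <- th["k1"] <- 1
  th["k2"] <- 0.1
  times <- seq(0, 60, by = 5)
  tr <- solve_ode(m, th, times, rtol = 1e-10, atol = 1e-12)
  expect_equal(tr$states[, "M"], (1 / 0.1) * (1 - exp(-0.1 * times)),
               tolerance = 1e-8)
  expect_equal(unname(tr$states[nrow(tr$states), "M"]), 10, tolerance = 1e-2)
})

test_that("no upstream input and M0 = 0 gives identically zero ppMEK", {
  m <- build_distributive_model()
  th <- reference_parameters()
  th["M0"] <- 0
  th[c("k1", "k10")] <- 1e-300   # structurally zero source
  tr <- solve_ode(m, th)
  expect_true(all(abs(tr$observables[, "ppMEK"]) < 1e-12))
})

test_that("adaptive solver matches an independent fixed-step RK4 oracle", {
  m <- build_distributive_model()
  th <- reference_parameters()
  times <- seq(0, 50, by = 10)
  tr <- solve_ode(m, th, times, rtol = 1e-10, atol = 1e-12)
  orc <- oracle_rk4(m, th, times, h = 0.002)
  rel <- abs(tr$observables - orc$observables) /
    pmax(abs(orc$observables), 1e-8)
  expect_lt(max(rel[-1, ]), 1e-5)
})

test_that("conservation and nonnegativity hold along trajectories", {
  m <- build_distributive_model()
  set.seed(42)
  for (rep in 1:5) {
    th <- reference_parameters() * exp(rnorm(20, 0, 0.3))
    th["T_pulse"] <- 4
    th["Epp0"] <- min(th[["Epp0"]], th[["E_tot"]])
    tr <- solve_ode(m, th, rtol = 1e-8, atol = 1e-10)
    erk <- rowSums(tr$states[, m$erk_moiety])
    pt <- rowSums(tr$states[, m$ptase_moiety])
    expect_lt(max(abs(erk - erk[1])), 10 * 1e-10 + 1e-9)
    expect_lt(max(abs(pt - pt[1])), 10 * 1e-10 + 1e-9)
    expect_true(all(tr$states > -1e-9))
  }
})

test_that("observable map sums free and complex-bound phosphorylated forms", {
  m <- build_distributive_model()
  x <- setNames(numeric(9), m$species)
  expect_equal(unname(observables(x, m)), c(0, 0))
  x[c("M", "C1", "C2")] <- c(1, 2, 3)
  expect_equal(unname(observables(x, m)["ppMEK"]), 6)
  x[] <- 0; x[c("Epp", "C3")] <- c(4, 1)
  expect_equal(unname(observables(x, m)["ppERK"]), 5)
})

test_that("model JSON export round-trips", {
  m <- build_distributive_model()
  js <- model_to_json(m)
  m2 <- model_from_json(js)
  expect_equal(m2$stoich, m$stoich)
  expect_equal(m2$param_names, m$param_names)
  expect_equal(m2$reactants, m$reactants)
  expect_equal(m2$obs_weights, m$obs_weights)
  tr <- solve_ode(m2, reference_parameters())
  expect_equal(tr$observables,
               solve_ode(m, reference_parameters())$observables)
})

test_that("trajectory CSV writer produces the documented columns", {
  m <- build_distributive_model()
  tr <- solve_ode(m, reference_parameters(), times = c(0, 10, 20))
  f <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f)
  df <- read.csv(f)
  expect_equal(names(df), c("time_min", m$species, "ppMEK_total", "ppERK_total"))
  expect_equal(df$time_min, c(0, 10, 20))
  unlink(f)
})
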