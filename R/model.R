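#' @useDynLib erknoise, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif setNames var sd median quantile cor dnorm
#'   dlnorm plnorm qlnorm ks.test rlnorm
#' @keywords internal
"_PACKAGE"

# Species order used throughout: free active MEK (M), unphosphorylated ERK (E),
# mono-phospho ERK (Ep), doubly phosphorylated ERK (Epp), free phosphatase (P),
# and the four enzyme-substrate complexes C1 = M.E, C2 = M.Ep, C3 = P.Epp,
# C4 = P.Ep.

.DISTRIBUTIVE_SPECIES <- c("M", "E", "Ep", "Epp", "P", "C1", "C2", "C3", "C4")
.PROCESSIVE_SPECIES <- c("M", "E", "Epp", "P", "C1", "C3")

.PARAM_NAMES_DISTRIBUTIVE <- c(
  "a1", "d1", "c1", "a2", "d2", "c2", "a3", "d3", "c3", "a4", "d4", "c4",
  "k1", "k2", "k10", "T_pulse", "E_tot", "P_tot", "M0", "Epp0"
)
.PARAM_NAMES_PROCESSIVE <- c(
  "a1", "d1", "c1", "a3", "d3", "c3",
  "k1", "k2", "k10", "T_pulse", "E_tot", "P_tot", "M0", "Epp0"
)

#' Construct the distributive dual-phosphorylation MEK-ERK model
#'
#' Active MEK (M) is produced by a time-dependent upstream input u(t) and
#' degraded at rate k2. ERK is phosphorylated in two distributive steps by M
#' (E -> Ep -> Epp, each step a bind/unbind/catalyze triplet with rates
#' a_i, d_i, c_i) and dephosphorylated in two distributive steps by the
#' cognate phosphatase P (Epp -> Ep -> E). This gives 9 species, 14 reactions
#' and 20 free parameters: 12 cycle rates, 4 upstream parameters
#' (k1, k2, k10, T_pulse) and 4 initial-condition parameters
#' (E_tot, P_tot, M0, Epp0).
#'
#' @param input upstream input shape: `"step"` (piecewise constant: k1 during
#'   the pulse, k10 afterwards) or `"smooth"` (exponential relaxation from k1
#'   to k10 on timescale T_pulse).
#' @return an object of class `erk_model`
#' @export
build_distributive_model <- function(input = c("step", "smooth")) {
  input <- match.arg(input)
  sp <- .DISTRIBUTIVE_SPECIES
  rxn <- list(
    # list(reactants, products, rate_name)
    list(character(0), "M", "input"),
    list("M", character(0), "k2"),
    list(c("M", "E"), "C1", "a1"),
    list("C1", c("M", "E"), "d1"),
    list("C1", c("M", "Ep"), "c1"),
    list(c("M", "Ep"), "C2", "a2"),
    list("C2", c("M", "Ep"), "d2"),
    list("C2", c("M", "Epp"), "c2"),
    list(c("P", "Epp"), "C3", "a3"),
    list("C3", c("P", "Epp"), "d3"),
    list("C3", c("P", "Ep"), "c3"),
    list(c("P", "Ep"), "C4", "a4"),
    list("C4", c("P", "Ep"), "d4"),
    list("C4", c("P", "E"), "c4")
  )
  .assemble_model("distributive", sp, rxn, .PARAM_NAMES_DISTRIBUTIVE, input,
                  erk_moiety = c("E", "Ep", "Epp", "C1", "C2", "C3", "C4"),
                  ptase_moiety = c("P", "C3", "C4"),
                  obs = list(ppMEK = c("M", "C1", "C2"), ppERK = c("Epp", "C3")))
}

#' Construct the processive alternative mechanism
#'
#' Alternative mechanism for Bayesian model comparison: a single kinase
#' binding event yields double phosphorylation (M + E <-> C1 -> M + Epp) and a
#' single phosphatase binding yields full dephosphorylation
#' (P + Epp <-> C3 -> P + E). 6 species, 8 reactions, 14 free parameters.
#'
#' @inheritParams build_distributive_model
#' @return an object of class `erk_model`
#' @export
build_processive_model <- function(input = c("step", "smooth")) {
  input <- match.arg(input)
  sp <- .PROCESSIVE_SPECIES
  rxn <- list(
    list(character(0), "M", "input"),
    list("M", character(0), "k2"),
    list(c("M", "E"), "C1", "a1"),
    list("C1", c("M", "E"), "d1"),
    list("C1", c("M", "Epp"), "c1"),
    list(c("P", "Epp"), "C3", "a3"),
    list("C3", c("P", "Epp"), "d3"),
    list("C3", c("P", "E"), "c3")
  )
  .assemble_model("processive", sp, rxn, .PARAM_NAMES_PROCESSIVE, input,
                  erk_moiety = c("E", "Epp", "C1", "C3"),
                  ptase_moiety = c("P", "C3"),
                  obs = list(ppMEK = c("M", "C1"), ppERK = c("Epp", "C3")))
}

.assemble_model <- function(name, species, rxn, param_names, input,
                            erk_moiety, ptase_moiety, obs) {
  ns <- length(species)
  nr <- length(rxn)
  S <- matrix(0L, ns, nr, dimnames = list(species, NULL))
  reactants <- vector("list", nr)
  rate_names <- character(nr)
  for (j in seq_len(nr)) {
    for (r in rxn[[j]][[1]]) S[r, j] <- S[r, j] - 1L
    for (p in rxn[[j]][[2]]) S[p, j] <- S[p, j] + 1L
    reactants[[j]] <- match(rxn[[j]][[1]], species)
    rate_names[j] <- rxn[[j]][[3]]
  }
  W <- matrix(0, 2, ns, dimnames = list(c("ppMEK", "ppERK"), species))
  W["ppMEK", obs$ppMEK] <- 1
  W["ppERK", obs$ppERK] <- 1
  structure(list(
    name = name,
    species = species,
    stoich = S,
    reactants = reactants,
    rate_names = rate_names,
    input_rxn = which(rate_names == "input"),
    input_form = input,
    param_names = param_names,
    erk_moiety = erk_moiety,
    ptase_moiety = ptase_moiety,
    obs_weights = W
  ), class = "erk_model")
}

#' @export
print.erk_model <- function(x, ...) {
  cat(sprintf("<erk_model: %s mechanism, %d species, %d reactions, %d free parameters, %s input>\n",
              x$name, length(x$species), ncol(x$stoich),
              length(x$param_names), x$input_form))
  invisible(x)
}

#' Number and names of free model parameters
#' @param model an `erk_model`
#' @return character vector of parameter names
#' @export
param_names <- function(model) model$param_names

#' Time-dependent upstream input u(t)
#'
#' Summarizes the stimulus and all reactions upstream of MEK as a zeroth-order
#' activation rate: the pulse intensity k1 during the initial transient of
#' duration T_pulse, then the sustained background intensity k10. The smooth
#' form relaxes exponentially from k1 to k10 with timescale T_pulse.
#'
#' @param t time (min), non-negative (vectorized)
#' @param k1 pulse intensity (conc/min)
#' @param k10 background intensity (conc/min)
#' @param T_pulse pulse duration / relaxation timescale (min), > 0
#' @param form `"step"` or `"smooth"`
#' @return input rate(s), conc/min
#' @export
upstream_input <- function(t, k1, k10, T_pulse, form = c("step", "smooth")) {
  form <- match.arg(form)
  stopifnot(all(t >= 0), k1 >= 0, k10 >= 0, T_pulse > 0)
  if (form == "step") ifelse(t < T_pulse, k1, k10)
  else k10 + (k1 - k10) * exp(-t / T_pulse)
}

#' Construct and validate a single-cell parameter vector
#'
#' @param ... named parameter values, or a single named numeric vector; must
#'   cover exactly the model's free parameters (see [param_names()]).
#' @param model the `erk_model` the vector parameterizes (default distributive)
#' @return named numeric vector of class `erk_params`
#' @export
erk_params <- function(..., model = build_distributive_model()) {
  args <- list(...)
  if (length(args) == 1L && is.numeric(args[[1]]) && !is.null(names(args[[1]]))) {
    theta <- args[[1]]
  } else {
    theta <- unlist(args)
  }
  nm <- model$param_names
  missing <- setdiff(nm, names(theta))
  if (length(missing)) stop("missing parameters: ", paste(missing, collapse = ", "))
  theta <- theta[nm]
  validate_params(theta, model)
  structure(theta, class = "erk_params")
}

validate_params <- function(theta, model) {
  nm <- model$param_names
  nonneg <- c("M0", "Epp0")
  pos <- setdiff(nm, nonneg)
  if (any(!is.finite(theta))) stop("non-finite parameter value")
  if (any(theta[pos] <= 0)) stop("parameters must be strictly positive: ",
                                 paste(pos[theta[pos] <= 0], collapse = ", "))
  if (any(theta[nonneg] < 0)) stop("M0 and Epp0 must be >= 0")
  if (theta[["Epp0"]] > theta[["E_tot"]])
    stop("invalid parameterization: Epp0 exceeds E_tot")
  invisible(theta)
}

#' Initial state implied by a parameter vector
#'
#' Background activity at stimulus onset: M(0) = M0, Epp(0) = Epp0,
#' E(0) = E_tot - Epp0, P(0) = P_tot; Ep and all complexes start at zero.
#'
#' @param model an `erk_model`
#' @param theta parameter vector (named, covering the model's parameters)
#' @return named state vector (concentrations)
#' @export
initial_state <- function(model, theta) {
  if (theta[["Epp0"]] > theta[["E_tot"]])
    stop("invalid parameterization: Epp0 exceeds E_tot")
  x0 <- setNames(numeric(length(model$species)), model$species)
  x0["M"] <- theta[["M0"]]
  x0["Epp"] <- theta[["Epp0"]]
  x0["E"] <- theta[["E_tot"]] - theta[["Epp0"]]
  x0["P"] <- theta[["P_tot"]]
  x0
}

# per-reaction rate constants from the parameter vector (input slot gets NA)
.rate_vector <- function(model, theta) {
  k <- numeric(length(model$rate_names))
  for (j in seq_along(k)) {
    rn <- model$rate_names[j]
    k[j] <- if (rn == "input") NA_real_ else theta[[rn]]
  }
  k
}

# The integrators treat the first grid entry as the initial time, but model
# state is defined at stimulus onset (t = 0): always solve from 0 and strip
# the helper row when the caller's grid starts later.
.grid_from_zero <- function(times) {
  if (times[1] > 0) {
    list(times = c(0, times), strip = function(m) m[-1, , drop = FALSE],
         strip_cube = function(a) a[, -1, , drop = FALSE])
  } else {
    list(times = times, strip = identity, strip_cube = identity)
  }
}

#' Default observation time grid
#'
#' Snapshots every 2 minutes from stimulus onset to 50 min, mirroring the
#' acquisition design of the quantitative-image-cytometry experiment.
#' @return numeric vector of times (min)
#' @export
default_times <- function() seq(0, 50, by = 2)

#' Solve the macroscopic rate equations
#'
#' Deterministic mass-action dynamics of one cell, integrated with an
#' adaptive Dormand-Prince RK45 scheme that treats the end of the input pulse
#' as an exact event boundary.
#'
#' @param model an `erk_model`
#' @param theta parameter vector
#' @param times ascending output times starting at 0 (min)
#' @param rtol,atol relative/absolute integration tolerances
#' @return an `erk_trajectory`: list with `times`, `states` (time x species)
#'   and `observables` (time x c(ppMEK, ppERK))
#' @export
solve_ode <- function(model, theta, times = default_times(),
                      rtol = 1e-8, atol = 1e-10) {
  stopifnot(all(diff(times) > 0), times[1] >= 0, rtol > 0, atol > 0)
  tgrid <- .grid_from_zero(times)
  res <- cpp_solve_ode(model$stoich, model$reactants, .rate_vector(model, theta),
                       model$input_rxn, as.integer(model$input_form == "smooth"),
                       theta[["k1"]], theta[["k10"]], theta[["T_pulse"]],
                       initial_state(model, theta), tgrid$times, rtol, atol)
  if (!res$ok) {
    stop(structure(class = c("erk_solver_error", "error", "condition"),
                   list(message = "ODE integration failed", call = sys.call(),
                        theta = theta)))
  }
  states <- tgrid$strip(res$states)
  colnames(states) <- model$species
  obs <- states %*% t(model$obs_weights)
  structure(list(times = times, states = states, observables = obs),
            class = "erk_trajectory")
}

#' Observable map: total phosphorylated MEK and ERK
#'
#' ppMEK_total = M + C1 + C2 and ppERK_total = Epp + C3 (sums of free and
#' complex-bound phosphorylated forms), matching what the phospho-specific
#' antibodies measure.
#'
#' @param state a state vector or a time-by-species matrix
#' @param model an `erk_model`
#' @return named vector (or matrix) with ppMEK and ppERK totals
#' @export
observables <- function(state, model = build_distributive_model()) {
  W <- model$obs_weights
  if (is.matrix(state)) {
    out <- state[, colnames(W), drop = FALSE] %*% t(W)
    return(out)
  }
  drop(W[, names(state), drop = FALSE] %*% state)
}

#' Write a trajectory to CSV
#' @param traj an `erk_trajectory`
#' @param path output file
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- data.frame(time_min = traj$times, traj$states, traj$observables,
                   check.names = FALSE)
  colnames(df)[(ncol(df) - 1):ncol(df)] <- c("ppMEK_total", "ppERK_total")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a model description to JSON (round-trippable)
#' @param model an `erk_model`
#' @param path optional file; if `NULL`, the JSON string is returned
#' @export
model_to_json <- function(model, path = NULL) {
  doc <- list(
    name = model$name,
    species = model$species,
    stoich = unclass(model$stoich),
    reactants = lapply(model$reactants, as.integer),
    rate_names = model$rate_names,
    input_form = model$input_form,
    param_names = model$param_names,
    erk_moiety = model$erk_moiety,
    ptase_moiety = model$ptase_moiety,
    obs_weights = unclass(model$obs_weights)
  )
  js <- jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Import a model description from JSON
#' @param path file or JSON string produced by [model_to_json()]
#' @return an `erk_model`
#' @export
model_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  S <- doc$stoich
  dimnames(S) <- list(doc$species, NULL)
  W <- doc$obs_weights
  dimnames(W) <- list(c("ppMEK", "ppERK"), doc$species)
  structure(list(
    name = doc$name, species = doc$species, stoich = S,
    reactants = lapply(seq_len(ncol(S)), function(j) as.integer(doc$reactants[[j]])),
    rate_names = doc$rate_names,
    input_rxn = which(doc$rate_names == "input"),
    input_form = doc$input_form,
    param_names = doc$param_names,
    erk_moiety = doc$erk_moiety,
    ptase_moiety = doc$ptase_moiety,
    obs_weights = W
  ), class = "erk_model")
}
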