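# Readers/writers and the end-to-end pipeline gluing the stages together:
# snapshot CSV I/O, a JSON run configuration, and run_pipeline() executing
# fit -> evidence comparison -> contributor ranking -> variance decomposition
# -> mutual-information and lambda analyses.

#' Read snapshot data from CSV
#'
#' Requires columns time_min, cell_id, ppMEK, ppERK; extra columns are
#' preserved. Non-positive intensities and non-numeric cells are reported
#' with their row numbers.
#'
#' @param path CSV file
#' @param require_positive reject non-positive intensities (default TRUE,
#'   matching the log-normal observation model)
#' @return a `snapshot_data`
#' @export
read_snapshot_csv <- function(path, require_positive = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("time_min", "cell_id", "ppMEK", "ppERK")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("missing required column(s): ",
                            paste(missing, collapse = ", "))
  for (cc in c("time_min", "ppMEK", "ppERK")) {
    v <- df[[cc]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      if (any(is.na(vn) & !is.na(v)))
        stop("non-numeric value in column '", cc, "' at row(s): ",
             paste(utils::head(which(is.na(vn) & !is.na(v)), 5), collapse = ", "))
      df[[cc]] <- vn
    }
  }
  if (require_positive) {
    bad <- which(df$ppMEK <= 0 | df$ppERK <= 0)
    if (length(bad)) stop("non-positive intensities at row(s): ",
                          paste(utils::head(bad, 10), collapse = ", "))
  }
  class(df) <- c("snapshot_data", "data.frame")
  df
}

#' Write snapshot data to CSV
#' @param snapshot a `snapshot_data`
#' @param path output file
#' @export
write_snapshot_csv <- function(snapshot, path) {
  utils::write.csv(as.data.frame(snapshot), path, row.names = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' Flat key-value configuration driving [run_pipeline()]; serialized as JSON.
#' Reduced settings keep a desk run in minutes; increase `cells_per_time` and
#' `n_particles` for production-quality posteriors.
#'
#' @param ... overrides of the default fields
#' @return list of class `run_config`
#' @export
default_run_config <- function(...) {
  cfg <- list(
    model = "distributive",
    input_form = "step",
    scenario = "extrinsic",
    data_path = NULL,
    cells_per_time = 200L,
    times = default_times(),
    free_extrinsic = c("k1", "k2", "k10", "M0", "Epp0"),
    free_intrinsic = c("k1", "k2", "k10", "M0", "Epp0"),
    n_particles = 128L,
    ess_threshold = 0.5,
    move_count = 2L,
    seed = 1L,
    mi_times = c(10, 20, 40),
    lambda_fractions = c(0.25, 0.5, 1),
    out_dir = NULL
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  for (nm in names(over)) cfg[nm] <- list(over[[nm]])  # preserves NULLs
  class(cfg) <- "run_config"
  cfg
}

#' Write / read a run configuration (JSON)
#' @param config a `run_config`
#' @param path file
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(default_run_config, cfg)
}

#' Run the full variability-dissection pipeline
#'
#' Executes the analysis workflow on a snapshot dataset: (1) load or generate
#' the data, (2) fit the intrinsic- and extrinsic-noise models by SMC, (3)
#' compare model evidences (Bayes factor), (4) rank extrinsic contributors by
#' posterior CV, (5) decompose the predicted variance by parameter group, (6)
#' compute mutual-information series and a lambda input-variability scan.
#' Deterministic given (config, seed). If `config$out_dir` is set, per-stage
#' CSVs and a JSON report are written there.
#'
#' @param config a `run_config`
#' @param verbose print stage progress
#' @return list report (also serialized to JSON when out_dir is set)
#' @export
run_pipeline <- function(config = default_run_config(), verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (!config$model %in% c("distributive", "processive"))
    stop("unknown model: ", config$model)
  model <- if (config$model == "distributive")
    build_distributive_model(config$input_form)
  else build_processive_model(config$input_form)
  say <- function(...) if (verbose) message(...)

  stage <- "data"
  report <- list(config = unclass(config), stages = character(0))
  out <- function(name) file.path(config$out_dir, name)
  result <- tryCatch({
    if (!is.null(config$data_path)) {
      snap <- read_snapshot_csv(config$data_path)
    } else {
      fixture <- reference_hyperparameters(config$scenario)
      design <- default_design(config$cells_per_time, config$times)
      snap <- generate_qic_dataset(model, fixture, design, seed = config$seed)
    }
    report$stages <- c(report$stages, stage)
    say("data: ", nrow(snap), " cells")

    stage <- "summary"
    stats <- summary_stats(snap)
    report$stages <- c(report$stages, stage)

    stage <- "fit"
    center <- reference_parameters()[model$param_names]
    fit_ex <- fit_extrinsic(snap, model, center, config$free_extrinsic,
                            n_particles = config$n_particles,
                            ess_threshold = config$ess_threshold,
                            move_count = config$move_count,
                            seed = config$seed, verbose = verbose)
    fit_in <- fit_intrinsic(snap, model, center, config$free_intrinsic,
                            n_particles = config$n_particles,
                            ess_threshold = config$ess_threshold,
                            move_count = config$move_count,
                            seed = config$seed + 1L, verbose = verbose)
    report$stages <- c(report$stages, stage)
    say(sprintf("log-evidence: extrinsic %.2f, intrinsic %.2f",
                fit_ex$log_evidence, fit_in$log_evidence))

    stage <- "evidence"
    bf <- bayes_factor(fit_ex, fit_in)
    report$stages <- c(report$stages, stage)

    stage <- "contributors"
    contributors <- rank_contributors(fit_ex)
    report$stages <- c(report$stages, stage)

    stage <- "decomposition"
    map <- posterior_quantiles(fit_ex, c(0.05, 0.5, 0.95))
    mean_hat <- setNames(map[paste0("mean_", fit_ex$free), 2], fit_ex$free)
    cv_hat <- setNames(map[paste0("cv_", fit_ex$free), 2], fit_ex$free)
    center_hat <- center
    center_hat[fit_ex$free] <- mean_hat
    cv_full <- setNames(rep(0, length(center_hat)), names(center_hat))
    cv_full[fit_ex$free] <- cv_hat
    hyper_hat <- hyper_params(center_hat, cv = cv_full)
    decomposition <- lapply(c("upstream", "initial_conditions",
                              "reaction_rates", "driving", "all"),
                            function(g) variance_by_group(model, hyper_hat, g,
                                                          config$times))
    names(decomposition) <- c("upstream", "initial_conditions",
                              "reaction_rates", "driving", "all")
    report$stages <- c(report$stages, stage)

    stage <- "information"
    mi <- mi_series(snap)
    s1 <- sqrt(hyper_hat$var[["k1"]])
    s10 <- sqrt(hyper_hat$var[["k10"]])
    fr <- config$lambda_fractions
    scan <- if (s1 > 0 && s10 > 0)
      lambda_scan(model, hyper_hat,
                  sigma_k1 = pmin(fr * hyper_hat$mean[["k1"]], hyper_hat$mean[["k1"]]),
                  sigma_k10 = pmin(fr * hyper_hat$mean[["k10"]], hyper_hat$mean[["k10"]]),
                  times = config$mi_times, mode = "full", engine = "ut")
    else NULL
    report$stages <- c(report$stages, stage)

    list(snapshot = snap, summary = stats, fit_extrinsic = fit_ex,
         fit_intrinsic = fit_in, bayes_factor = bf,
         contributors = contributors, decomposition = decomposition,
         mi = mi, lambda = scan)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e))
  })

  report$log_evidence_extrinsic <- result$fit_extrinsic$log_evidence
  report$log_evidence_intrinsic <- result$fit_intrinsic$log_evidence
  report$bayes_factor <- result$bayes_factor
  report$winning_model <- if (result$bayes_factor$log_bf > 0) "extrinsic" else "intrinsic"
  report$contributors <- result$contributors
  report$seed <- config$seed

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_snapshot_csv(result$snapshot, out("snapshot.csv"))
    utils::write.csv(result$summary, out("summary_stats.csv"), row.names = FALSE)
    utils::write.csv(result$contributors, out("contributors.csv"), row.names = FALSE)
    utils::write.csv(result$mi, out("mutual_information.csv"), row.names = FALSE)
    for (g in names(result$decomposition))
      utils::write.csv(result$decomposition[[g]],
                       out(paste0("variance_", g, ".csv")), row.names = FALSE)
    if (!is.null(result$lambda))
      utils::write.csv(lambda_scan_table(result$lambda),
                       out("lambda_scan.csv"), row.names = FALSE)
    schema <- list(
      snapshot.csv = list(time_min = "minutes since stimulus",
                          cell_id = "unique cell index (never reused)",
                          ppMEK = "total phospho-MEK, intensity a.u.",
                          ppERK = "total phospho-ERK, intensity a.u.",
                          dose_label = "stimulus label"),
      summary_stats.csv = list(mean = "intensity a.u.",
                               variance = "intensity a.u. squared",
                               cv = "dimensionless", fano = "intensity a.u."),
      mutual_information.csv = list(mi = "nats"),
      variance_groups = list(var_ppMEK = "intensity a.u. squared",
                             var_ppERK = "intensity a.u. squared"),
      lambda_scan.csv = list(s = "SD of ppERK, intensity a.u.",
                             lambda = "dimensionless ratio in [0, 1]"))
    jsonlite::write_json(schema, out("schema.json"), auto_unbox = TRUE,
                         pretty = TRUE)
    jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
  }
  result$report <- report
  invisible(result)
}
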