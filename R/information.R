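# Descriptive snapshot statistics (variance, CV, Fano time courses) and the
# kernel-density plug-in estimator of the mutual information between ppMEK
# and ppERK.

#' Per-time summary statistics of a snapshot
#'
#' Sample mean, unbiased variance, coefficient of variation (SD/mean) and
#' Fano factor (variance/mean) per time point and observable. Time points
#' with fewer than two cells, or zero mean, are flagged and their undefined
#' statistics set to NA.
#'
#' @param snapshot a `snapshot_data`
#' @return data.frame (time_min, observable, n, mean, variance, cv, fano,
#'   flagged)
#' @export
summary_stats <- function(snapshot) {
  d <- .snapshot_split(snapshot)
  one <- function(v, tt, obs) {
    n <- length(v)
    if (n < 2) {
      return(data.frame(time_min = tt, observable = obs, n = n,
                        mean = if (n) mean(v) else NA_real_, variance = NA_real_,
                        cv = NA_real_, fano = NA_real_, flagged = TRUE))
    }
    m <- mean(v)
    va <- var(v)
    bad <- m == 0
    data.frame(time_min = tt, observable = obs, n = n, mean = m, variance = va,
               cv = if (bad) NA_real_ else sqrt(va) / m,
               fano = if (bad) NA_real_ else va / m,
               flagged = bad)
  }
  out <- do.call(rbind, c(
    lapply(seq_along(d$times), function(k) one(d$x[[k]], d$times[k], "ppMEK")),
    lapply(seq_along(d$times), function(k) one(d$y[[k]], d$times[k], "ppERK"))))
  rownames(out) <- NULL
  out
}

#' Normal-reference KDE bandwidth
#'
#' The kernel SD per marginal is 1.06 * sigma * N^(-1/5) with sigma the
#' sample SD and N the sample size (Silverman-type normal-reference rule).
#' A literal reading in which the rule sets the kernel *variance* is
#' available via `literal_variance = TRUE`.
#'
#' @param samples numeric vector (N >= 2, positive SD), or alternatively pass
#'   `sigma` and `n` directly to evaluate the rule
#' @param sigma,n optional explicit SD and count (bypass `samples`)
#' @param literal_variance if TRUE return sqrt(1.06 * sigma * N^(-1/5))
#'   (the rule read as a variance)
#' @return bandwidth (kernel SD)
#' @export
kde_bandwidth <- function(samples = NULL, sigma = NULL, n = NULL,
                          literal_variance = FALSE) {
  if (is.null(sigma)) {
    stopifnot(length(samples) >= 2)
    sigma <- sd(samples)
    n <- length(samples)
  }
  if (sigma <= 0) stop("zero-variance sample: bandwidth undefined")
  h <- 1.06 * sigma * n^(-1 / 5)
  if (literal_variance) sqrt(h) else h
}

#' Mutual information between two observables (KDE plug-in estimator)
#'
#' Plug-in estimate I = (1/N) sum_i log[ f_xy(x_i, y_i) / (f_x(x_i) f_y(y_i)) ]
#' with product-Gaussian-kernel density estimates evaluated at the sample
#' points; marginal bandwidths from [kde_bandwidth()]. The raw value is
#' returned (it can be slightly negative for independent data).
#'
#' @param x,y paired samples (N >= 10)
#' @param unit `"nats"` (natural log) or `"bits"`
#' @param log_transform apply log() to both samples first (requires positive
#'   data)
#' @return mutual information estimate
#' @export
mutual_information <- function(x, y, unit = c("nats", "bits"),
                               log_transform = FALSE) {
  unit <- match.arg(unit)
  if (length(x) != length(y)) stop("x and y must have equal length")
  stopifnot(length(x) >= 10)
  if (log_transform) {
    stopifnot(all(x > 0), all(y > 0))
    x <- log(x)
    y <- log(y)
  }
  mi <- cpp_mi_kde(x, y, kde_bandwidth(x), kde_bandwidth(y))
  if (unit == "bits") mi / log(2) else mi
}

#' Per-time mutual information between ppMEK and ppERK
#'
#' @param snapshot a `snapshot_data`
#' @inheritParams mutual_information
#' @return data.frame (time_min, n, mi, unit)
#' @export
mi_series <- function(snapshot, unit = c("nats", "bits"),
                      log_transform = FALSE) {
  unit <- match.arg(unit)
  d <- .snapshot_split(snapshot)
  out <- do.call(rbind, lapply(seq_along(d$times), function(k) {
    x <- d$x[[k]]
    y <- d$y[[k]]
    mi <- if (length(x) >= 10 && sd(x) > 0 && sd(y) > 0)
      mutual_information(x, y, unit, log_transform) else NA_real_
    data.frame(time_min = d$times[k], n = length(x), mi = mi, unit = unit)
  }))
  rownames(out) <- NULL
  out
}
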