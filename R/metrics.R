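#' Per-pixel lifetime map from a readout
#'
#' Accumulates one decay histogram per pixel over the exposure and fits
#' each with the chosen estimator. Pixels that recorded no photon are
#' missing (`NA`), as are pixels whose fit did not converge.
#'
#' @param readout a `spad_readout` from [readout_exposure()].
#' @param method estimator passed to [fit_lifetime()].
#' @param ... further arguments to [fit_lifetime()] (e.g.
#'   `window_correction`).
#' @return an object of class `lifetime_map`: list with `tau` (matrix, ns),
#'   `n_counts` (matrix of per-pixel photon counts), `method`,
#'   `exposure_s` and the configuration.
#' @export
build_lifetime_map <- function(readout, method = c("mle", "cmm", "lsm"), ...) {
  stopifnot(inherits(readout, "spad_readout"))
  method <- match.arg(method)
  cfg <- readout$config
  counts <- pixel_code_counts(readout)
  nc <- colSums(counts)
  tau <- rep(NA_real_, length(nc))
  for (k in which(nc > 0)) {
    hist <- decay_histogram(counts[, k], h = cfg_h_ns(cfg),
                            m_used = cfg$tdc_code_max,
                            window = cfg$laser_period_T)
    fit <- fit_lifetime(hist, method, ...)
    if (fit$converged) tau[k] <- fit$tau
  }
  structure(list(tau = matrix(tau, cfg$n_rows, cfg$n_cols),
                 n_counts = matrix(nc, cfg$n_rows, cfg$n_cols),
                 method = method,
                 exposure_s = readout$n_pulses / (cfg$laser_rate * 1e6),
                 config = cfg),
            class = "lifetime_map")
}

#' @export
print.lifetime_map <- function(x, ...) {
  cat(sprintf(
    "lifetime_map (%s): %d x %d pixels, exposure %.4g s, %d missing\n",
    toupper(x$method), nrow(x$tau), ncol(x$tau), x$exposure_s,
    sum(is.na(x$tau))))
  if (any(!is.na(x$tau)))
    cat(sprintf("  tau: mean %.3f ns, sd %.3f ns\n",
                mean(x$tau, na.rm = TRUE), sd(as.vector(x$tau), na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.lifetime_map <- function(x, ...) {
  graphics::image(t(x$tau)[, nrow(x$tau):1, drop = FALSE],
                  main = sprintf("%s lifetime map [ns]", toupper(x$method)),
                  axes = FALSE, ...)
  invisible(x)
}

#' Accuracy metrics of a lifetime map
#'
#' Compares an estimated lifetime map with the ground truth and reports the
#' average offset `delta_tau = mean(tau_hat - tau_true)`, the spread
#' `sigma_tau = sd(tau_hat)` across pixels, the average relative error
#' `|delta_tau| / tau_true * 100` (meaningful for uniform-truth
#' experiments) and the imaging figure of merit
#' \deqn{FoM = \tau / \sqrt{\sigma_\tau^2 + \Delta\tau^2}}
#' which rewards estimators that are simultaneously precise and unbiased.
#'
#' @param map a [build_lifetime_map()] result.
#' @param truth a [decay_map()] with the true lifetimes.
#' @return an object of class `metrics_report` with fields `mean_tau`,
#'   `delta_tau`, `sigma_tau` (ns), `avg_error_percent`, `fom`, `method`,
#'   `exposure_s` and `n_pixels`.
#' @export
compute_metrics <- function(map, truth) {
  stopifnot(inherits(map, "lifetime_map"), inherits(truth, "decay_map"))
  if (!all(dim(map$tau) == dim(truth$tau)))
    stop("map and truth shapes differ", call. = FALSE)
  ok <- !is.na(map$tau)
  if (!any(ok)) stop("lifetime map has no estimated pixels", call. = FALSE)
  est <- map$tau[ok]
  tru <- truth$tau[ok]
  delta <- mean(est - tru)
  sigma <- sd(est)
  tau_ref <- mean(tru)
  structure(list(mean_tau = mean(est), delta_tau = delta, sigma_tau = sigma,
                 avg_error_percent = abs(delta) / tau_ref * 100,
                 fom = tau_ref / sqrt(sigma^2 + delta^2),
                 method = map$method, exposure_s = map$exposure_s,
                 n_pixels = sum(ok)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report (%s, %.4g s exposure, %d pixels)\n",
              toupper(x$method), x$exposure_s, x$n_pixels))
  cat(sprintf("  mean tau  = %.4f ns\n", x$mean_tau))
  cat(sprintf("  delta tau = %+.4f ns (avg error %.3f%%)\n",
              x$delta_tau, x$avg_error_percent))
  cat(sprintf("  sigma tau = %.4f ns\n", x$sigma_tau))
  cat(sprintf("  FoM       = %.1f\n", x$fom))
  invisible(x)
}

#' Uniform-intensity, uniform-lifetime experiment
#'
#' Full pipeline at a spatially uniform true lifetime and detection
#' probability: generate photon arrivals, run the event-driven readout,
#' build one lifetime map per estimator and score each against the truth.
#' This is the worst case for pile-up, since every pixel competes for the
#' shared readout at the maximal uniform rate.
#'
#' @param tau true lifetime, ns.
#' @param n_cycles number of laser periods to simulate.
#' @param config a [sensor_config()].
#' @param methods estimators to apply.
#' @param seed integer seed.
#' @param ... further arguments to [fit_lifetime()].
#' @return named list of [compute_metrics()] reports, one per method, with
#'   the maps attached as attribute `"maps"`.
#' @export
run_uniform_experiment <- function(tau, n_cycles, config = sensor_config(),
                                   methods = c("mle", "cmm", "lsm"),
                                   seed = NULL, ...) {
  truth <- decay_map(tau, config)
  stream <- generate_photon_arrivals(config, truth, n_cycles, seed = seed)
  if (config$bg_rate > 0)
    stream <- add_background_events(stream, config,
                                    seed = if (is.null(seed)) NULL else seed + 1L)
  ro <- readout_exposure(stream, config)
  maps <- lapply(methods, function(m) build_lifetime_map(ro, m, ...))
  names(maps) <- methods
  reports <- lapply(maps, compute_metrics, truth = truth)
  attr(reports, "maps") <- maps
  attr(reports, "losses") <- ro$losses
  reports
}

#' Pixel-interaction experiment
#'
#' Area-array mode stress test: pixel (1, 1) observes lifetime `tau_11`
#' while every other pixel observes `tau_array`. Short neighbour lifetimes
#' concentrate the sub-array's photons right after excitation, so they
#' preferentially occupy the OR-tree and the shared TDCs and distort the
#' histogram of the target pixel. Reports the relative deviation of the
#' (1, 1) estimate per method.
#'
#' @param tau_11 true lifetime of pixel (1, 1), ns.
#' @param tau_array true lifetime of all other pixels, ns.
#' @param n_cycles number of laser periods.
#' @param config a [sensor_config()].
#' @param methods estimators to apply.
#' @param seed integer seed.
#' @param ... further arguments to [fit_lifetime()].
#' @return `data.frame` with columns `method`, `tau_hat`,
#'   `deviation_percent` (relative to `tau_11`).
#' @export
run_interaction_experiment <- function(tau_11, tau_array, n_cycles,
                                       config = sensor_config(),
                                       methods = c("mle", "cmm", "lsm"),
                                       seed = NULL, ...) {
  if (tau_11 <= 0 || tau_array <= 0) stop("lifetimes must be positive")
  grid <- matrix(tau_array, config$n_rows, config$n_cols)
  grid[1, 1] <- tau_11
  truth <- decay_map(grid, config)
  stream <- generate_photon_arrivals(config, truth, n_cycles, seed = seed)
  ro <- readout_exposure(stream, config)
  hist <- histogram_from_readout(ro, pixel = c(1, 1))
  res <- lapply(methods, function(m) {
    fit <- fit_lifetime(hist, m, ...)
    data.frame(method = m, tau_hat = fit$tau,
               deviation_percent = abs(fit$tau - tau_11) / tau_11 * 100)
  })
  do.call(rbind, res)
}

#' Frame-rate arithmetic of the sensor
#'
#' Photon budget bookkeeping: with laser rate `R` (MHz) and per-pixel
#' detection probability `p0`, a pixel collects `R * 1e6 * p0` photons per
#' second, so gathering `photons_per_pixel` photons takes
#' `photons_per_pixel / (R * 1e6 * p0)` seconds and the sensor can produce
#' one lifetime map per such exposure. With the defaults (10 MHz, 1%,
#' 1000 photons) the exposure is 10 ms, i.e. 100 maps per second.
#'
#' @param config a [sensor_config()].
#' @param photons_per_pixel photons required per pixel for one map.
#' @return list with `photons_per_pixel_per_s`, `exposure_s`, `maps_per_s`
#'   and `n_cycles` (laser periods per exposure).
#' @export
imaging_rate <- function(config = sensor_config(), photons_per_pixel = 1000) {
  rate <- config$laser_rate * 1e6 * config$photon_rate_P0
  exposure <- photons_per_pixel / rate
  list(photons_per_pixel_per_s = rate, exposure_s = exposure,
       maps_per_s = 1 / exposure,
       n_cycles = exposure * config$laser_rate * 1e6)
}
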