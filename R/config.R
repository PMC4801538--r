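#' Sensor and experiment configuration
#'
#' Builds the full set of constants describing the sensor and the acquisition:
#' array geometry, laser timing, TDC quantization, OR-tree dead time and
#' per-pixel photon rate. Defaults describe a 16x16 SPAD array organised as
#' four 8x8 sub-arrays, each sharing 4 TDCs behind an OR-tree, driven by a
#' 10 MHz pulsed laser (100 ns measurement window), with a 10-bit TDC of
#' 97.6 ps LSB whose output code is limited to 950, a 360 ps OR-tree pulse
#' width (dead time) and a 1% per-pixel per-pulse detection probability.
#'
#' @param n_rows,n_cols sensor resolution in pixels; must be divisible by
#'   `subarray_size`.
#' @param subarray_size side of the square sub-array sharing one readout
#'   chain (OR-tree + TDC bank).
#' @param n_tdc_per_subarray number of TDCs shared by one sub-array; at most
#'   this many events per sub-array are time-stamped per laser pulse.
#' @param laser_period_T laser period / measurement window, ns.
#' @param laser_rate laser repetition rate, MHz; must equal
#'   `1000 / laser_period_T`.
#' @param tdc_lsb_h TDC least significant bit (time bin width), ps.
#' @param tdc_bins_M nominal number of TDC bins (2^10 for a 10-bit TDC).
#' @param tdc_code_max first invalid TDC code; events quantizing to a code
#'   `>= tdc_code_max` are discarded (the quantized range is
#'   `tdc_code_max * tdc_lsb_h`, about 92.7 ns with the defaults).
#' @param dead_time_tp OR-tree pulse width t_p, ps: two events on the same
#'   sub-array closer than this merge and only the first survives.
#' @param encoder_hold_time position-encoder hold time, ps; two recorded
#'   events closer than this corrupt the position code and invalidate the
#'   whole sub-array frame. 0 (default) disables the mechanism.
#' @param photon_rate_P0 probability that a pixel detects a signal photon in
#'   one laser period.
#' @param bg_rate probability of a uniform background/dark count per pixel
#'   per laser period.
#' @param dead_time_mode `"paralyzable"` (merged pulses keep extending the
#'   OR-tree output, the default) or `"nonparalyzable"` (dead time restarts
#'   only on accepted events).
#' @param seed optional integer seed recorded with the configuration.
#'
#' @return an object of class `sensor_config` (a validated named list).
#' @examples
#' cfg <- sensor_config()
#' cfg$dead_time_tp
#' @export
sensor_config <- function(n_rows = 16L,
                          n_cols = 16L,
                          subarray_size = 8L,
                          n_tdc_per_subarray = 4L,
                          laser_period_T = 100,
                          laser_rate = 10,
                          tdc_lsb_h = 97.6,
                          tdc_bins_M = 1024L,
                          tdc_code_max = 950L,
                          dead_time_tp = 360,
                          encoder_hold_time = 0,
                          photon_rate_P0 = 0.01,
                          bg_rate = 0,
                          dead_time_mode = c("paralyzable", "nonparalyzable"),
                          seed = NULL) {
  dead_time_mode <- match.arg(dead_time_mode)
  cfg <- list(
    n_rows = as.integer(n_rows),
    n_cols = as.integer(n_cols),
    subarray_size = as.integer(subarray_size),
    n_tdc_per_subarray = as.integer(n_tdc_per_subarray),
    laser_period_T = as.numeric(laser_period_T),
    laser_rate = as.numeric(laser_rate),
    tdc_lsb_h = as.numeric(tdc_lsb_h),
    tdc_bins_M = as.integer(tdc_bins_M),
    tdc_code_max = as.integer(tdc_code_max),
    dead_time_tp = as.numeric(dead_time_tp),
    encoder_hold_time = as.numeric(encoder_hold_time),
    photon_rate_P0 = as.numeric(photon_rate_P0),
    bg_rate = as.numeric(bg_rate),
    dead_time_mode = dead_time_mode,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  class(cfg) <- "sensor_config"
  validate_sensor_config(cfg)
}

validate_sensor_config <- function(cfg) {
  stopifnot(inherits(cfg, "sensor_config"))
  err <- function(...) stop("invalid sensor_config: ", sprintf(...), call. = FALSE)
  with(cfg, {
    if (n_rows < 1L || n_cols < 1L) err("array dimensions must be positive")
    if (subarray_size < 1L) err("subarray_size must be positive")
    if (n_rows %% subarray_size != 0L || n_cols %% subarray_size != 0L)
      err("n_rows and n_cols must be divisible by subarray_size")
    if (n_tdc_per_subarray < 1L) err("need at least one TDC per sub-array")
    if (laser_period_T <= 0 || tdc_lsb_h <= 0) err("times must be positive")
    if (abs(laser_period_T - 1000 / laser_rate) > 1e-6 * laser_period_T)
      err("laser_period_T [ns] must equal 1000 / laser_rate [MHz]")
    if (tdc_code_max < 1L || tdc_code_max > tdc_bins_M)
      err("tdc_code_max must lie in 1..tdc_bins_M")
    if (tdc_code_max * tdc_lsb_h / 1000 > laser_period_T + 1e-9)
      err("quantized range tdc_code_max * h exceeds the laser period")
    if (dead_time_tp < 0 || encoder_hold_time < 0)
      err("dead_time_tp and encoder_hold_time must be non-negative")
    if (photon_rate_P0 < 0 || photon_rate_P0 > 1)
      err("photon_rate_P0 must lie in [0, 1]")
    if (bg_rate < 0 || bg_rate > 1) err("bg_rate must lie in [0, 1]")
  })
  cfg
}

# internal: derived quantities in consistent units (ns)
cfg_h_ns <- function(cfg) cfg$tdc_lsb_h / 1000
cfg_tp_ns <- function(cfg) cfg$dead_time_tp / 1000
cfg_hold_ns <- function(cfg) cfg$encoder_hold_time / 1000
cfg_n_subarrays <- function(cfg) {
  (cfg$n_rows %/% cfg$subarray_size) * (cfg$n_cols %/% cfg$subarray_size)
}

#' @export
print.sensor_config <- function(x, ...) {
  cat("SPAD sensor configuration\n")
  cat(sprintf("  array: %d x %d (sub-arrays of %d x %d, %d TDCs each)\n",
              x$n_rows, x$n_cols, x$subarray_size, x$subarray_size,
              x$n_tdc_per_subarray))
  cat(sprintf("  laser: %.4g MHz (window %.4g ns)\n", x$laser_rate, x$laser_period_T))
  cat(sprintf("  TDC: h = %.4g ps, %d bins, codes limited to %d (range %.4g ns)\n",
              x$tdc_lsb_h, x$tdc_bins_M, x$tdc_code_max,
              x$tdc_code_max * x$tdc_lsb_h / 1000))
  cat(sprintf("  dead time t_p = %.4g ps (%s), encoder hold = %.4g ps\n",
              x$dead_time_tp, x$dead_time_mode, x$encoder_hold_time))
  cat(sprintf("  photon rate P0 = %.4g per pixel per pulse, background = %.4g\n",
              x$photon_rate_P0, x$bg_rate))
  invisible(x)
}

#' Read / write a sensor configuration as JSON
#'
#' `load_config()` reads a JSON file whose keys are a subset of the
#' [sensor_config()] arguments; absent keys take the defaults, unknown keys
#' are an error. `save_config()` writes the complete validated
#' configuration, so a load/save/load round trip is the identity.
#'
#' @param path file path.
#' @return `load_config()` returns a `sensor_config`; `save_config()`
#'   returns `path` invisibly.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  vals <- if (nzchar(trimws(txt))) jsonlite::fromJSON(txt, simplifyVector = TRUE) else list()
  if (!is.list(vals)) stop("config must be a JSON object", call. = FALSE)
  known <- names(formals(sensor_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  do.call(sensor_config, vals)
}

#' @rdname load_config
#' @param cfg a `sensor_config`.
#' @export
save_config <- function(cfg, path) {
  validate_sensor_config(cfg)
  out <- unclass(cfg)
  out$seed <- cfg$seed  # NULL seeds are dropped by toJSON, which is fine
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
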