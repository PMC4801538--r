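#' OR-tree dead-time filter
#'
#' Applies the sub-array OR-tree pulse-merging rule to the events of one
#' sub-array within one laser period. Pixel pulses have a finite width `tp`;
#' when two events are strictly closer than `tp` the pulses merge at the
#' OR-tree output and only the first is processed further. In
#' `"paralyzable"` mode every event (accepted or merged) re-extends the OR
#' output, so the reference is the immediately preceding event; in
#' `"nonparalyzable"` mode the reference is the last accepted event. Events
#' exactly `tp` apart are both accepted. Simultaneous arrivals are ordered
#' by `(row, col)`.
#'
#' @param events `data.frame` with at least columns `t`, `row`, `col`,
#'   sorted by `t` ascending (an unsorted input is an error, not silently
#'   reordered).
#' @param tp dead time in ns.
#' @param mode `"paralyzable"` or `"nonparalyzable"`.
#' @return the accepted subset of `events`.
#' @examples
#' ev <- data.frame(t = c(0, 0.2, 0.5, 1), row = 1:4, col = 1)
#' apply_dead_time(ev, tp = 0.36, mode = "paralyzable")$t     # 0, 1
#' apply_dead_time(ev, tp = 0.36, mode = "nonparalyzable")$t  # 0, 0.5, 1
#' @export
apply_dead_time <- function(events, tp, mode = c("paralyzable", "nonparalyzable")) {
  mode <- match.arg(mode)
  if (nrow(events) == 0L) return(events)
  if (is.unsorted(events$t)) stop("events must be sorted by t", call. = FALSE)
  o <- order(events$t, events$row, events$col)  # stable tie-break
  events <- events[o, , drop = FALSE]
  keep <- dead_time_keep(events$t, rep(1L, nrow(events)), tp,
                         mode == "paralyzable")
  events[keep, , drop = FALSE]
}

#' TDC allocation
#'
#' A sub-array shares `n_tdc` time-to-digital converters; within one laser
#' period only the first `n_tdc` surviving events (in arrival order) obtain
#' a converter, the rest are lost to TDC exhaustion.
#'
#' @param events `data.frame` sorted by `t`.
#' @param n_tdc number of TDCs available.
#' @return the first `min(n_tdc, nrow(events))` rows.
#' @export
allocate_tdcs <- function(events, n_tdc) {
  if (is.unsorted(events$t)) stop("events must be sorted by t", call. = FALSE)
  head(events, n_tdc)
}

#' TDC time quantization
#'
#' Quantizes continuous arrival times into TDC codes of width `h` (the TDC
#' LSB): `code = floor(t / h)` with half-open bins `[code*h, (code+1)*h)`.
#' Codes at or beyond `tdc_code_max` fall outside the converter's quantized
#' range and the event is discarded (`NA`), not saturated into the last
#' bin.
#'
#' @param t arrival times in ns, all in `[0, T)`.
#' @param config a [sensor_config()].
#' @return integer codes in `0..tdc_code_max - 1`, `NA` for discarded
#'   events.
#' @examples
#' quantize_time(c(0, 95), sensor_config())  # 0, NA (floor(95000/97.6) = 973)
#' @export
quantize_time <- function(t, config) {
  validate_sensor_config(config)
  if (any(t < 0)) stop("negative arrival time", call. = FALSE)
  if (any(t >= config$laser_period_T))
    stop("arrival time outside the measurement window", call. = FALSE)
  code <- as.integer(floor(t / cfg_h_ns(config)))
  code[code >= config$tdc_code_max] <- NA_integer_
  code
}

#' Position encoding and frame validation
#'
#' Emits the 3-bit row/column addresses of the kept events of one sub-array
#' in one laser period and applies the frame-validity rule: the frame is
#' valid only when the column, row and time lists have equal lengths and no
#' code equals the invalid encoder code (`subarray_size`, the "1000"
#' pattern for an 8-wide sub-array). If the encoder hold time is positive
#' and two kept events are closer than it, the encoder cannot latch the
#' earlier event's address: its code becomes the invalid code and the whole
#' sub-array frame is abandoned.
#'
#' @param events kept events of one sub-array/pulse: `data.frame` with
#'   `t`, `row`, `col` (absolute pixel coordinates) and optionally `code`.
#' @param config a [sensor_config()].
#' @param subarray_origin integer `c(row0, col0)`, the 0-based origin of the
#'   sub-array; defaults to the sub-array containing the first event.
#' @return a `frame_record`: list with `time_codes`, `row_codes`,
#'   `col_codes` and `valid`.
#' @export
encode_positions_and_validate <- function(events, config,
                                          subarray_origin = NULL) {
  validate_sensor_config(config)
  s <- config$subarray_size
  inv <- s  # "1000" for s = 8: one bit beyond the 3-bit address range
  if (nrow(events) == 0L)
    return(structure(list(time_codes = integer(), row_codes = integer(),
                          col_codes = integer(), valid = TRUE),
                     class = "frame_record"))
  if (is.null(subarray_origin))
    subarray_origin <- c(((events$row[1] - 1L) %/% s) * s,
                         ((events$col[1] - 1L) %/% s) * s)
  r <- events$row - 1L - subarray_origin[1]
  c <- events$col - 1L - subarray_origin[2]
  if (any(r < 0L | r >= s | c < 0L | c >= s))
    stop("event outside the sub-array", call. = FALSE)
  codes <- if (!is.null(events$code)) events$code else
    quantize_time(events$t, config)
  hold <- cfg_hold_ns(config)
  valid <- TRUE
  if (hold > 0 && nrow(events) > 1L) {
    clash <- diff(events$t) < hold
    if (any(clash)) {
      r[which(clash)] <- inv
      c[which(clash)] <- inv
      valid <- FALSE
    }
  }
  if (anyNA(codes)) valid <- FALSE  # time entry missing: list lengths differ
  structure(list(time_codes = codes, row_codes = as.integer(r),
                 col_codes = as.integer(c), valid = valid),
            class = "frame_record")
}

# sub-array index (1-based, row-major over sub-array grid) of each pixel
subarray_of <- function(row, col, config) {
  s <- config$subarray_size
  nsc <- config$n_cols %/% s
  ((row - 1L) %/% s) * nsc + ((col - 1L) %/% s) + 1L
}

#' Run the full event-driven readout over an exposure
#'
#' Applies the complete readout chain of the sensor to a raw photon stream,
#' per sub-array and laser period: OR-tree dead-time merging
#' ([apply_dead_time()]), allocation of the shared TDCs
#' ([allocate_tdcs()]), 10-bit time quantization with limited code range
#' ([quantize_time()]) and position encoding with frame validation
#' ([encode_positions_and_validate()]). Sub-arrays are independent. Every
#' generated event is either recorded or attributed to exactly one loss
#' category: dead-time merging, TDC exhaustion, invalid frames (encoder
#' hold-time violations) or TDC code overflow.
#'
#' @param stream a `photon_events` stream.
#' @param config a [sensor_config()].
#' @return an object of class `spad_readout`: list with `events` (recorded
#'   detections with columns `pulse`, `row`, `col`, `subarray`, `t`,
#'   `code`, `is_background`), `losses` (named counts: `merged`,
#'   `tdc_exhausted`, `invalid_frame`, `code_overflow`), `n_generated`,
#'   `n_pulses` and the configuration.
#' @examples
#' cfg <- sensor_config()
#' ev <- generate_photon_arrivals(cfg, decay_map(10.5, cfg), 500, seed = 1)
#' ro <- readout_exposure(ev, cfg)
#' ro$losses
#' @export
readout_exposure <- function(stream, config) {
  stopifnot(inherits(stream, "photon_events"))
  validate_sensor_config(config)
  n_sub <- cfg_n_subarrays(config)
  df <- as.data.frame(stream)
  n_gen <- nrow(df)
  losses <- c(merged = 0L, tdc_exhausted = 0L, invalid_frame = 0L,
              code_overflow = 0L)
  if (n_gen == 0L)
    return(structure(list(events = cbind(df, subarray = integer(),
                                         code = integer()),
                          losses = losses, n_generated = 0L,
                          n_pulses = attr(stream, "n_pulses"),
                          config = config),
                     class = "spad_readout"))

  df$subarray <- subarray_of(df$row, df$col, config)
  gid_num <- (as.numeric(df$pulse) - 1) * n_sub + df$subarray
  if (max(gid_num) >= .Machine$integer.max)
    stop("exposure too large for group indexing", call. = FALSE)
  gid <- as.integer(gid_num)
  o <- order(gid, df$t, df$row, df$col)
  df <- df[o, , drop = FALSE]
  gid <- gid[o]

  # (a) OR-tree merging
  keep <- dead_time_keep(df$t, gid, cfg_tp_ns(config),
                         config$dead_time_mode == "paralyzable")
  losses["merged"] <- sum(!keep)
  df <- df[keep, , drop = FALSE]; gid <- gid[keep]

  # (b) TDC exhaustion: first n_tdc arrivals per sub-array per pulse
  rk <- run_rank(gid)
  keep <- rk <= config$n_tdc_per_subarray
  losses["tdc_exhausted"] <- sum(!keep)
  df <- df[keep, , drop = FALSE]; gid <- gid[keep]

  # (d) encoder hold-time violations abandon the whole sub-array frame
  hold <- cfg_hold_ns(config)
  if (hold > 0 && nrow(df) > 1L) {
    same_grp <- c(FALSE, gid[-1] == gid[-length(gid)])
    clash <- same_grp & c(FALSE, diff(df$t) < hold)
    bad_grp <- unique(gid[clash])
    keep <- !(gid %in% bad_grp)
    losses["invalid_frame"] <- sum(!keep)
    df <- df[keep, , drop = FALSE]
  }

  # (c) quantization and code-range overflow
  df$code <- as.integer(floor(df$t / cfg_h_ns(config)))
  over <- df$code >= config$tdc_code_max
  losses["code_overflow"] <- sum(over)
  df <- df[!over, , drop = FALSE]

  rownames(df) <- NULL
  structure(list(events = df, losses = losses, n_generated = n_gen,
                 n_pulses = attr(stream, "n_pulses"), config = config),
            class = "spad_readout")
}

#' @export
print.spad_readout <- function(x, ...) {
  cat(sprintf("spad_readout: %d pulses, %d generated -> %d recorded events\n",
              x$n_pulses, x$n_generated, nrow(x$events)))
  cat("  losses:", paste(names(x$losses), x$losses, sep = " = ",
                         collapse = ", "), "\n")
  invisible(x)
}

#' Export recorded frames to CSV
#'
#' One line per recorded event with its sub-array-local 3-bit position
#' codes: `pulse_index, subarray_id, time_code, row_code, col_code, valid`.
#' Only valid frames carry events after [readout_exposure()], so `valid` is
#' `TRUE` throughout.
#' @param readout a `spad_readout`.
#' @param path file path.
#' @export
write_frame_records <- function(readout, path) {
  stopifnot(inherits(readout, "spad_readout"))
  s <- readout$config$subarray_size
  ev <- readout$events
  out <- data.frame(pulse_index = ev$pulse, subarray_id = ev$subarray,
                    time_code = ev$code,
                    row_code = (ev$row - 1L) %% s,
                    col_code = (ev$col - 1L) %% s,
                    valid = TRUE)
  write.csv(out, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Export a readout loss report to JSON
#' @param readout a `spad_readout`.
#' @param path file path.
#' @export
write_loss_report <- function(readout, path) {
  stopifnot(inherits(readout, "spad_readout"))
  jsonlite::write_json(c(as.list(readout$losses),
                         list(n_generated = readout$n_generated,
                              n_recorded = nrow(readout$events))),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
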