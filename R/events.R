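# evaluate code with a private RNG state so callers' streams are untouched
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# inverse-CDF draw from an exponential truncated and renormalized to [0, T)
rtexp <- function(n, tau, T) {
  -tau * log1p(-runif(n) * (1 - exp(-T / tau)))
}

new_photon_events <- function(df, config, n_pulses, decay = NULL) {
  o <- order(df$pulse, df$t, df$row, df$col)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("photon_events", "data.frame"),
            config = config, n_pulses = as.integer(n_pulses), decay = decay)
}

#' Simulate raw photon arrivals
#'
#' Draws the photon detections of every pixel over `n_pulses` laser periods,
#' before any readout loss. In each period a pixel fires at most once (the
#' SPAD is re-armed only by the global reset): a detection occurs with
#' probability `p0[i, j]` and its arrival time is drawn from the
#' single-exponential decay density `(1/tau) exp(-t/tau)` truncated and
#' renormalized to the measurement window `[0, T)`. Photons whose nominal
#' arrival falls beyond the window are treated as never detected, not
#' wrapped into the next period.
#'
#' @param config a [sensor_config()].
#' @param decay a [decay_map()] with matching shape.
#' @param n_pulses number of laser periods to simulate.
#' @param seed integer seed; equal seeds and inputs give identical streams.
#' @return an event stream: a `data.frame` of class `photon_events` with
#'   columns `pulse`, `row`, `col` (1-based), `t` (ns in `[0, T)`) and
#'   `is_background`, sorted by pulse then arrival time, carrying the
#'   configuration and pulse count as attributes.
#' @examples
#' cfg <- sensor_config()
#' ev <- generate_photon_arrivals(cfg, decay_map(10.5, cfg), 100, seed = 1)
#' @export
generate_photon_arrivals <- function(config, decay, n_pulses, seed = NULL) {
  validate_sensor_config(config)
  stopifnot(inherits(decay, "decay_map"))
  if (!all(dim(decay$tau) == c(config$n_rows, config$n_cols)))
    stop("decay map shape does not match the sensor", call. = FALSE)
  n_pulses <- as.integer(n_pulses)
  if (n_pulses < 1L) stop("n_pulses must be >= 1", call. = FALSE)
  T <- config$laser_period_T

  with_seed(seed, {
    parts <- vector("list", config$n_rows * config$n_cols)
    k <- 0L
    for (col in seq_len(config$n_cols)) {
      for (row in seq_len(config$n_rows)) {
        k <- k + 1L
        p0 <- decay$p0[row, col]
        if (p0 <= 0) next
        n_ev <- rbinom(1L, n_pulses, p0)
        if (n_ev == 0L) next
        pulses <- sort(sample.int(n_pulses, n_ev))
        parts[[k]] <- data.frame(
          pulse = pulses, row = row, col = col,
          t = rtexp(n_ev, decay$tau[row, col], T),
          is_background = FALSE
        )
      }
    }
    parts <- parts[!vapply(parts, is.null, logical(1))]
    df <- if (length(parts) > 0) do.call(rbind, parts) else
      data.frame(pulse = integer(), row = integer(), col = integer(),
                 t = numeric(), is_background = logical())
    new_photon_events(df, config, n_pulses, decay)
  })
}

#' Add uniform background / dark-count events
#'
#' Superimposes uncorrelated background and dark-count (DCR) detections:
#' per pixel and laser period an extra event occurs with probability
#' `config$bg_rate`, uniformly distributed over the window. Because a pixel
#' can fire only once per period, a background arrival colliding with a
#' signal arrival in the same period survives only if it is earlier (the
#' SPAD fires on whichever photon comes first).
#'
#' @param stream a `photon_events` stream from [generate_photon_arrivals()].
#' @param config a [sensor_config()] with the `bg_rate` to apply.
#' @param seed integer seed.
#' @return the augmented `photon_events` stream; background rows have
#'   `is_background = TRUE`.
#' @export
add_background_events <- function(stream, config, seed = NULL) {
  stopifnot(inherits(stream, "photon_events"))
  validate_sensor_config(config)
  if (config$bg_rate <= 0) return(stream)
  n_pulses <- attr(stream, "n_pulses")
  T <- config$laser_period_T

  with_seed(seed, {
    parts <- list()
    k <- 0L
    for (col in seq_len(config$n_cols)) {
      for (row in seq_len(config$n_rows)) {
        n_ev <- rbinom(1L, n_pulses, config$bg_rate)
        if (n_ev == 0L) next
        k <- k + 1L
        parts[[k]] <- data.frame(
          pulse = sort(sample.int(n_pulses, n_ev)), row = row, col = col,
          t = runif(n_ev, 0, T), is_background = TRUE
        )
      }
    }
    if (length(parts) == 0L) return(stream)
    bg <- do.call(rbind, parts)

    # resolve signal/background collisions on the same (pixel, pulse):
    # the earlier arrival wins, the later one is never detected
    key <- function(d) ((d$row - 1) * config$n_cols + (d$col - 1)) *
      (n_pulses + 1) + d$pulse
    sig <- as.data.frame(stream)
    ks <- key(sig); kb <- key(bg)
    clash <- kb %in% ks
    if (any(clash)) {
      ts_min <- tapply(sig$t, ks, min)
      keep_bg <- !clash | bg$t < as.numeric(ts_min[as.character(kb)])
      keep_bg[is.na(keep_bg)] <- TRUE
      drop_sig_key <- kb[clash][bg$t[clash] < as.numeric(ts_min[as.character(kb[clash])])]
      sig <- sig[!(ks %in% drop_sig_key), , drop = FALSE]
      bg <- bg[keep_bg, , drop = FALSE]
    }
    new_photon_events(rbind(sig, bg), config, n_pulses, attr(stream, "decay"))
  })
}

#' Write an event stream to CSV
#'
#' Columns `pulse_index,row,col,t_ns,is_background`, one line per detected
#' photon, LF endings.
#' @param stream a `photon_events` stream.
#' @param path file path.
#' @export
write_event_stream <- function(stream, path) {
  stopifnot(inherits(stream, "photon_events"))
  df <- data.frame(pulse_index = stream$pulse, row = stream$row,
                   col = stream$col, t_ns = stream$t,
                   is_background = stream$is_background)
  write.csv(df, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}
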