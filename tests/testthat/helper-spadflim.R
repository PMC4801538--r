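# shared fixtures and independent oracles, all built in code

# cheap config factory with overrides
test_config <- function(...) {
  args <- list(...)
  do.call(sensor_config, args)
}

# single 8x8 sub-array sensor (isolates OR-tree behaviour)
subarray_config <- function(...) {
  test_config(n_rows = 8L, n_cols = 8L, ...)
}

# per-event loop oracle for the OR-tree dead-time rule (kept deliberately
# naive; the package uses a compiled kernel)
brute_dead_time <- function(t, tp, mode) {
  n <- length(t)
  keep <- logical(n)
  if (n == 0L) return(keep)
  keep[1] <- TRUE
  ref <- prev <- t[1]
  for (i in seq_len(n)[-1]) {
    r <- if (mode == "paralyzable") prev else ref
    if (t[i] - r < tp) keep[i] <- FALSE else {
      keep[i] <- TRUE
      ref <- t[i]
    }
    prev <- t[i]
  }
  keep
}

# binned truncated-exponential probabilities via stats::pexp (independent
# of the package's expm1-based arithmetic)
oracle_bin_probs <- function(tau, h, m) {
  edges <- (0:m) * h
  p <- diff(pexp(edges, rate = 1 / tau))
  p / pexp(m * h, rate = 1 / tau)
}

# closed-form mean of an exponential truncated to [0, W)
oracle_trunc_mean <- function(tau, W) {
  tau - W * exp(-W / tau) / (1 - exp(-W / tau))
}

# multinomial draw of a clean (no readout) decay histogram
draw_histogram <- function(tau, n_counts, config = sensor_config()) {
  h <- config$tdc_lsb_h / 1000
  m <- config$tdc_code_max
  p <- oracle_bin_probs(tau, h, m)
  counts <- numeric(config$tdc_bins_M)
  counts[seq_len(m)] <- as.numeric(rmultinom(1, n_counts, p))
  decay_histogram(counts, h = h, m_used = m, window = config$laser_period_T)
}
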