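test_that("raw center-of-mass follows the printed first-moment formula", {
  # all counts in the first bin: (1 + 1/2) h under the hardware convention
  one <- decay_histogram(c(10, 0, 0, 0), h = 0.1)
  fit <- fit_lifetime(one, "cmm", window_correction = FALSE)
  expect_equal(coef(fit), c(tau = 1.5 * 0.1))
  # bin-center convention
  fit2 <- fit_lifetime(one, "cmm", window_correction = FALSE, cmm_offset = -0.5)
  expect_equal(unname(coef(fit2)), 0.5 * 0.1)
})

test_that("center-of-mass equals an independent weighted mean to machine precision", {
  withr::local_seed(8)
  hist <- draw_histogram(9, 5000)
  fit <- fit_lifetime(hist, "cmm", window_correction = FALSE)
  # independent code path: explicit loop over occupied bins
  num <- 0; den <- 0
  for (j in seq_len(hist$m_used)) {
    num <- num + j * hist$counts[j]
    den <- den + hist$counts[j]
  }
  expect_equal(unname(coef(fit)), (num / den + 0.5) * hist$h,
               tolerance = 1e-15)
})

test_that("raw center-of-mass matches a mean-of-samples oracle and shows truncation bias", {
  cfg <- sensor_config()
  h <- cfg$tdc_lsb_h / 1000
  m <- cfg$tdc_code_max
  W <- m * h
  # expected counts of the discretized decay as the histogram
  expe <- round(1e6 * oracle_bin_probs(10.5, h, m))
  counts <- numeric(cfg$tdc_bins_M); counts[seq_len(m)] <- expe
  hist <- decay_histogram(counts, h, m_used = m, window = 100)
  tau_raw <- unname(coef(fit_lifetime(hist, "cmm", window_correction = FALSE)))

  # sampling oracle: quantized draws from the truncated exponential
  withr::local_seed(9)
  u <- runif(1e6)
  t <- -10.5 * log(1 - u * (1 - exp(-W / 10.5)))
  j <- floor(t / h) + 1
  oracle <- (mean(j) + 0.5) * h
  expect_equal(tau_raw, oracle, tolerance = 3 * sd(j) * h / sqrt(1e6) / oracle)
  # the bin-center moment reproduces the truncated-exponential mean, which
  # sits below the true lifetime: the documented window truncation bias
  tau_center <- unname(coef(fit_lifetime(hist, "cmm", window_correction = FALSE,
                                         cmm_offset = -0.5)))
  expect_lt(tau_center, 10.5)
  expect_equal(tau_center, oracle_trunc_mean(10.5, W), tolerance = 1e-3)
})

test_that("window-corrected center-of-mass inverts the truncation bias", {
  cfg <- sensor_config()
  h <- cfg$tdc_lsb_h / 1000
  m <- cfg$tdc_code_max
  for (tau in c(5, 10.5, 15, 20)) {
    expe <- round(1e7 * oracle_bin_probs(tau, h, m))
    counts <- numeric(cfg$tdc_bins_M); counts[seq_len(m)] <- expe
    hist <- decay_histogram(counts, h, m_used = m, window = 100)
    fit <- fit_lifetime(hist, "cmm")
    expect_true(fit$converged)
    # half-bin discretization residue is the only error left
    expect_equal(unname(coef(fit)), tau, tolerance = 2e-3)
  }
})

test_that("MLE solves its score equation and matches a grid-search likelihood oracle", {
  # self-consistency: noiseless expected counts return the generating tau
  cfg <- sensor_config()
  h <- cfg$tdc_lsb_h / 1000
  for (tau in c(2, 10.5, 25)) {
    expe <- round(1e7 * oracle_bin_probs(tau, h, cfg$tdc_code_max))
    counts <- numeric(cfg$tdc_bins_M)
    counts[seq_len(cfg$tdc_code_max)] <- expe
    hist <- decay_histogram(counts, h, m_used = cfg$tdc_code_max, window = 100)
    fit <- fit_lifetime(hist, "mle")
    expect_true(fit$converged)
    expect_equal(unname(coef(fit)), tau, tolerance = 1e-4)
  }

  # randomized histograms against brute-force likelihood maximization
  withr::local_seed(33)
  m <- 300L; hh <- 0.0976
  for (i in 1:20) {
    tau_true <- runif(1, 2, 18)
    p <- oracle_bin_probs(tau_true, hh, m)
    counts <- as.numeric(rmultinom(1, 3000, p))
    hist <- decay_histogram(counts, hh, window = m * hh)
    fit <- fit_lifetime(hist, "mle")
    expect_true(fit$converged)
    grid <- seq(max(0.5, tau_true - 4), tau_true + 4, by = 0.005)
    ll <- vapply(grid, function(tt) {
      q <- oracle_bin_probs(tt, hh, m)
      sum(counts[counts > 0] * log(q[counts > 0]))
    }, numeric(1))
    expect_lt(abs(unname(coef(fit)) - grid[which.max(ll)]), 0.005 + 1e-9)
  }
})

test_that("the MLE left side is strictly monotone over the bracket", {
  # monotone over the region where a root can fall; at the extremes the
  # curve saturates (towards 1 below ~h/20, towards (M + 1) / 2 above
  # ~100 T) and floating point flattens it there
  taus <- exp(seq(log(5e-3), log(500), length.out = 200))
  lhs <- spadflim:::mle_lhs(taus, 0.0976, 950)
  expect_true(all(diff(lhs) > 0))
  expect_gt(lhs[1], 1 - 1e-9)
  expect_lt(lhs[200], (950 + 1) / 2)
})

test_that("least squares recovers the truth on noiseless and random histograms", {
  cfg <- sensor_config()
  h <- cfg$tdc_lsb_h / 1000
  m <- cfg$tdc_code_max
  for (tau in c(5, 10.5)) {
    expe <- round(1e7 * oracle_bin_probs(tau, h, m))
    counts <- numeric(cfg$tdc_bins_M); counts[seq_len(m)] <- expe
    hist <- decay_histogram(counts, h, m_used = m, window = 100)
    for (rb in c(1, 20)) {
      fit <- fit_lifetime(hist, "lsm", rebin_min = rb)
      expect_true(fit$converged)
      expect_equal(unname(coef(fit)), tau, tolerance = 1e-3)
    }
  }

  # solver output equals a brute-force fine-grid chi-square scan
  withr::local_seed(55)
  mm <- 200L; hh <- 0.0976
  for (i in 1:20) {
    tau_true <- runif(1, 2, 12)
    counts <- as.numeric(rmultinom(1, 4000, oracle_bin_probs(tau_true, hh, mm)))
    hist <- decay_histogram(counts, hh, window = mm * hh)
    fit <- fit_lifetime(hist, "lsm", rebin_min = 1)
    grid <- seq(max(0.5, tau_true - 3), tau_true + 6, by = 0.002)
    chi <- vapply(grid, function(tt) {
      e <- 4000 * oracle_bin_probs(tt, hh, mm)
      sum((counts - e)^2 / pmax(e, 1e-12))
    }, numeric(1))
    expect_lt(abs(unname(coef(fit)) - grid[which.min(chi)]), 0.002 + 1e-9)
  }
})

test_that("the literal weighted normal equation solves cleanly on ideal data", {
  cfg <- sensor_config()
  h <- cfg$tdc_lsb_h / 1000
  m <- cfg$tdc_code_max
  expe <- round(1e7 * oracle_bin_probs(8, h, m))
  counts <- numeric(cfg$tdc_bins_M); counts[seq_len(m)] <- expe
  hist <- decay_histogram(counts, h, m_used = m, window = 100)
  fit <- fit_lifetime(hist, "lsm", lsm_variant = "root")
  expect_true(fit$converged)
  # the squared-count weighting is biased, but must sit near the truth
  expect_equal(unname(coef(fit)), 8, tolerance = 0.05)
})

test_that("degenerate and non-bracketable inputs are flagged, not clamped", {
  expect_error(fit_lifetime(decay_histogram(numeric(10), h = 1), "mle"),
               "empty")
  # single occupied bin: chi-square mode cannot determine a lifetime
  one <- decay_histogram(c(0, 50, 0, 0), h = 1)
  expect_false(fit_lifetime(one, "lsm")$converged)
  # a rising histogram pushes the moment beyond the attainable range
  rising <- decay_histogram(c(0, 0, 0, 100), h = 1)
  fit <- fit_lifetime(rising, "mle")
  expect_false(fit$converged)
  expect_true(is.na(coef(fit)))
})

test_that("all three estimators are consistent on an unconstrained readout", {
  # no dead time, one TDC per pixel, full code range: pure TCSPC statistics
  cfg <- test_config(dead_time_tp = 0, n_tdc_per_subarray = 64L,
                     tdc_bins_M = 1024L, tdc_code_max = 1024L)
  dm <- decay_map(10.5, cfg)
  ev <- generate_photon_arrivals(cfg, dm, 3e4, seed = 77)
  ro <- readout_exposure(ev, cfg)
  hist <- histogram_from_readout(ro)
  n <- hist$n_counts
  se <- 10.5 / sqrt(n)
  for (method in c("mle", "cmm", "lsm")) {
    fit <- fit_lifetime(hist, method)
    expect_true(fit$converged)
    expect_lt(abs(coef(fit) - 10.5), 4 * se)
  }
})

test_that("raw center-of-mass degrades faster than MLE for long lifetimes", {
  cfg <- sensor_config()
  h <- cfg$tdc_lsb_h / 1000
  m <- cfg$tdc_code_max
  withr::local_seed(91)
  for (tau in c(16, 18, 20)) {
    counts <- numeric(cfg$tdc_bins_M)
    counts[seq_len(m)] <- as.numeric(rmultinom(1, 2e5, oracle_bin_probs(tau, h, m)))
    hist <- decay_histogram(counts, h, m_used = m, window = 100)
    bias_cmm <- abs(coef(fit_lifetime(hist, "cmm", window_correction = FALSE)) - tau)
    bias_mle <- abs(coef(fit_lifetime(hist, "mle")) - tau)
    expect_gt(bias_cmm, bias_mle)
  }
})

test_that("fit methods expose a coherent model object", {
  withr::local_seed(14)
  hist <- draw_histogram(10.5, 20000)
  fit <- fit_lifetime(hist, "mle")
  expect_s3_class(fit, "lifetime_fit")
  expect_output(print(fit), "MLE")
  s <- summary(fit)
  expect_output(print(s), "Lifetime")

  e <- predict(fit, "counts")
  expect_length(e, hist$m_used)
  expect_equal(sum(e), fit$n_used, tolerance = 1e-9)
  d <- predict(fit, "density")
  expect_equal(sum(d) * hist$h, 1, tolerance = 1e-9)

  r <- residuals(fit)
  expect_length(r, hist$m_used)
  expect_lt(abs(mean(r)), 0.2)  # centred Pearson residuals on a true model

  sims <- simulate(fit, nsim = 3, seed = 2)
  expect_length(sims, 3)
  expect_true(all(vapply(sims, function(s) s$n_counts, numeric(1)) ==
                  fit$n_used))
  # simulated histograms refit close to the generating estimate
  refit <- fit_lifetime(sims[[1]], "mle")
  expect_lt(abs(coef(refit) - coef(fit)), 5 * 10.5 / sqrt(fit$n_used))

  expect_equal(attr(logLik(fit), "df"), 1L)
})
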