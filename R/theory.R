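#' Expected per-pixel detection density under pile-up (MSP mode)
#'
#' Closed-form expected number of photons one pixel records per laser
#' period and unit time when all `N^2` pixels of a sub-array observe the
#' same single-exponential decay (mini silicon photomultiplier mode) and
#' the OR-tree imposes a paralyzable dead time `tp`. With `mu` the expected
#' number of photons the sub-array detects per period,
#' \deqn{c(t) = \frac{\mu}{N^2\tau} e^{-t/\tau} \times
#'   \begin{cases} \exp(-\mu(1 - e^{-t/\tau})) & t < t_p \\
#'   \exp(-\mu e^{-t/\tau}(e^{t_p/\tau} - 1)) & t \ge t_p \end{cases}}
#' The prefactor `mu / N^2` is the per-pixel detection probability, so with
#' `tp = 0` the density integrates to the photons one pixel detects per
#' period. The second factor is the probability that no photon arrived on
#' the sub-array within the preceding dead-time window, i.e. that the
#' OR-tree output was low when this photon arrived; it equals 1 when
#' `tp = 0`, and the relative count deficit it causes is largest right
#' after excitation.
#'
#' @param t time since excitation, ns (vectorized, `t >= 0`).
#' @param mu expected photons per sub-array per period (`N^2 * P0`).
#' @param tau fluorescence lifetime, ns.
#' @param tp dead time, ns.
#' @param N sub-array side (the sub-array has `N^2` pixels).
#' @return density per pixel per period, 1/ns.
#' @export
expected_density_msp <- function(t, mu, tau, tp, N = 8) {
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  e <- exp(-t / tau)
  mod <- ifelse(t < tp,
                exp(-mu * (1 - e)),
                exp(-mu * e * (exp(tp / tau) - 1)))
  mu * e / (N^2 * tau) * mod
}

#' Per-pixel detection density without pile-up
#'
#' Probability density that pixel `(i, j)` detects a photon at time `t`:
#' `p0 / tau * exp(-t / tau)`. Integrates to `p0` over `[0, Inf)`.
#'
#' @param t time, ns (vectorized).
#' @param p0 per-period detection probability of the pixel.
#' @param tau lifetime, ns.
#' @export
pixel_detection_density <- function(t, p0, tau) {
  p0 / tau * exp(-t / tau)
}

#' Probability that a pixel does not fire within the preceding dead-time
#' window
#'
#' The complement of the probability that pixel `(i, j)` fires during
#' `(t - tp, t]`, the interval in which its pulse would still hold the
#' OR-tree output high at time `t`:
#' \deqn{P'(t; t_p) = \begin{cases}
#'   1 - p_0 (1 - e^{-t_p/\tau}) & t < t_p \\
#'   1 - p_0 (e^{-(t - t_p)/\tau} - e^{-t/\tau}) & t \ge t_p
#'   \end{cases}}
#' (For `t < tp` the window is clipped at the excitation instant; the
#' printed branch keeps the full-window value, an upper bound on the firing
#' probability that both branches share at `t = tp`.) Lies in
#' `[1 - p0, 1]`; equals 1 everywhere when `tp = 0`.
#'
#' @param t time, ns (vectorized).
#' @param p0 per-period detection probability.
#' @param tau lifetime, ns.
#' @param tp dead time, ns.
#' @export
pixel_miss_probability <- function(t, p0, tau, tp) {
  ifelse(t < tp,
         1 - p0 * (1 - exp(-tp / tau)),
         1 - p0 * (exp(-(t - tp) / tau) - exp(-t / tau)))
}

#' Detection density of one pixel modulated by its sub-array neighbours
#'
#' In area-array mode each pixel observes its own lifetime; the probability
#' that a target pixel's photon at time `t` is recorded is its own
#' detection density times the probability that no other pixel of the
#' sub-array fired within the preceding dead-time window:
#' `prod over others of pixel_miss_probability * pixel_detection_density`.
#' For a 1x1 grid (no neighbours) it reduces exactly to
#' [pixel_detection_density()].
#'
#' @param t time, ns (vectorized).
#' @param tau_grid,p0_grid matrices of per-pixel lifetimes (ns) and rates.
#' @param target `c(row, col)` of the target pixel (1-based).
#' @param tp dead time, ns.
#' @export
modulated_detection_density <- function(t, tau_grid, p0_grid, target, tp) {
  tau_grid <- as.matrix(tau_grid); p0_grid <- as.matrix(p0_grid)
  stopifnot(all(dim(tau_grid) == dim(p0_grid)))
  if (target[1] < 1 || target[1] > nrow(tau_grid) ||
      target[2] < 1 || target[2] > ncol(tau_grid))
    stop("target pixel outside the grid", call. = FALSE)
  dens <- pixel_detection_density(t, p0_grid[target[1], target[2]],
                                  tau_grid[target[1], target[2]])
  for (i in seq_len(nrow(tau_grid))) {
    for (j in seq_len(ncol(tau_grid))) {
      if (i == target[1] && j == target[2]) next
      dens <- dens * pixel_miss_probability(t, p0_grid[i, j], tau_grid[i, j], tp)
    }
  }
  dens
}

#' Pile-up counts-error curve
#'
#' Relative deviation of the pile-up-modulated detection density from the
#' ideal (unmodulated) exponential on a time grid:
#' `(modulated - ideal) / ideal`. In MSP mode the modulated density is
#' [expected_density_msp()]; in array mode it is
#' [modulated_detection_density()] for a target pixel. The error is largest
#' close to the excitation, where the arrival rate — and hence the chance
#' of OR-tree merging — is highest, and decays later in the window.
#'
#' @param t time grid, ns.
#' @param tau lifetime of the (target) pixel, ns.
#' @param tp dead time, ns.
#' @param mu expected photons per sub-array per period (MSP mode).
#' @param tau_grid,p0_grid,target optional array-mode inputs (see
#'   [modulated_detection_density()]); when supplied they override `mu`.
#' @return `data.frame` with columns `t`, `error` (signed) and `abs_error`.
#' @export
counts_error_curve <- function(t, tau, tp, mu = NULL, tau_grid = NULL,
                               p0_grid = NULL, target = c(1, 1), N = 8) {
  if (!is.null(tau_grid)) {
    p0 <- p0_grid[target[1], target[2]]
    ideal <- pixel_detection_density(t, p0, tau)
    modded <- modulated_detection_density(t, tau_grid, p0_grid, target, tp)
    err <- (modded - ideal) / ideal
  } else if (mu > 0) {
    ideal <- mu * exp(-t / tau) / (N^2 * tau)
    modded <- expected_density_msp(t, mu, tau, tp, N)
    err <- (modded - ideal) / ideal
  } else {
    err <- rep(0, length(t))  # no photons, no pile-up
  }
  data.frame(t = t, error = err, abs_error = abs(err))
}
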