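---
title: "Simulating an event-driven SPAD FLIM sensor: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating an event-driven SPAD FLIM sensor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spadflim)
```

## The measurement being simulated

Time-correlated single photon counting (TCSPC) fluorescence lifetime
imaging (FLIM) measures, per image pixel, the decay constant $\tau$ of a
fluorophore's emission. A pulsed laser excites the sample; single-photon
avalanche diodes (SPADs) detect individual emitted photons; a
time-to-digital converter (TDC) stamps each photon's arrival time relative
to the laser pulse; and the per-pixel histogram of arrival times,
accumulated over many laser periods, is fit with a single-exponential decay
$f(t) = A e^{-t/\tau}$.

`spadflim` simulates a compact 16×16 SPAD imager that economizes hardware
by *event-driven* readout: each 8×8 sub-array shares only 4 TDCs behind an
OR-tree that merges all 64 pixel outputs onto one wire, plus row/column
encoders for the position. Because a pixel detects a photon in only ~1% of
laser periods, four shared converters normally suffice — but the sharing
creates a specific, structured distortion (pile-up) that this package
models three ways: by Monte Carlo simulation of the full detection chain,
by closed-form expected-count densities, and through the bias it induces in
three lifetime estimators.

## The sensor model and its parameters

`sensor_config()` carries the constants. Defaults describe the simulated
design and are the conditions for every canned experiment:

| parameter | default | meaning |
|---|---|---|
| `n_rows`, `n_cols` | 16 | array resolution, tiled into 8×8 sub-arrays |
| `n_tdc_per_subarray` | 4 | shared converters; at most 4 events per sub-array per period are time-stamped |
| `laser_rate` | 10 MHz | so the measurement window `laser_period_T` is 100 ns |
| `tdc_lsb_h` | 97.6 ps | TDC bin width (10-bit converter, 1024 nominal bins) |
| `tdc_code_max` | 950 | codes ≥ 950 are outside the converter's range; such events are *discarded*, not saturated, since saturation would pile spurious counts into the last bin. The usable window is 950 × 97.6 ps ≈ 92.7 ns |
| `dead_time_tp` | 360 ps | OR-tree pulse width: two events on one sub-array closer than this merge, only the first survives |
| `photon_rate_P0` | 0.01 | per-pixel per-period detection probability (the classic TCSPC ~1% pile-up guard) |
| `bg_rate` | 0 | uniform background/dark-count probability per pixel per period |
| `encoder_hold_time` | 0 | position-encoder hold time; the published description never quantifies it, so the mechanism ships disabled with a sensitivity switch |
| `dead_time_mode` | paralyzable | see below |

Two points deserve justification:

**Dead-time mode.** The OR-tree merges *pulses*: a pixel pulse arriving
while the OR output is still high extends it. That is paralyzable behaviour
— the reference for the "closer than $t_p$" test is the immediately
preceding event whether or not it was itself recorded — and it is also the
behaviour the closed-form density assumes (its survival factor is the
probability of *no arrival at all* in the preceding $t_p$ window). A
nonparalyzable variant (dead time restarts only on accepted events) is
provided because the hardware description admits either reading at the
margins; the default follows the theory.

**Reverse START-STOP.** The hardware TDC runs from the photon to the next
laser sync to save power, storing what amounts to $T - t$. Since the
histogram is identical up to index reversal, the simulator records forward
codes `floor(t / h)` directly.

## Monte Carlo generation

`generate_photon_arrivals()` draws, per pixel: a binomial number of
detections over the exposure, the periods in which they occur (sampled
without replacement — a SPAD re-arms only at the global reset, so at most
one event per pixel per period), and arrival times from the exponential
truncated and renormalized to $[0, T)$. Photons nominally arriving after
$T$ are treated as never detected rather than wrapped into the next period,
matching a theory defined on a single window. All randomness flows from one
explicit seed; equal seeds give byte-identical streams. (Sampling is
vectorized per pixel rather than per pulse; determinism, not stream
layout, is the contract.)

The generator emulates: Bernoulli detection, single-exponential decay,
window truncation, uniform background/DCR (`add_background_events()`, with
earlier-arrival-wins collision resolution). It does **not** emulate SPAD
device physics (afterpulsing, crosstalk, detection-efficiency spectra),
multi-exponential decays, instrument response functions, or TDC
nonlinearity — so passing tests demonstrate the readout-induced biases and
estimator properties, not detector artifacts of real hardware.

## The readout chain and the pile-up theory

`readout_exposure()` applies, per sub-array and laser period: dead-time
merging → TDC allocation (first 4 arrivals) → quantization with code-range
discard → position encoding with frame validation. Every generated photon
is either recorded or attributed to exactly one loss category, an
accounting identity the tests verify event-by-event against a brute-force
per-pulse loop.

The matching closed forms: `expected_density_msp()` gives the expected
per-pixel detection density when all pixels observe one lifetime,

$$c(t) = \frac{\mu}{N^2 \tau} e^{-t/\tau} \times
  \begin{cases} \exp(-\mu(1 - e^{-t/\tau})) & t < t_p\\
  \exp(-\mu e^{-t/\tau}(e^{t_p/\tau} - 1)) & t \ge t_p\end{cases}$$

with $\mu = N^2 P_0$ the expected photons per sub-array per period. One
typographic ambiguity in the source material had to be resolved: the
prefactor. We use $\mu/(N^2\tau)$, under which the density integrates (at
$t_p = 0$) to exactly $P_0$ photons per pixel per period; the Monte Carlo
confirms this normalization to within counting error, bin by bin. A second
typo (a sign in the per-pixel miss probability's decaying exponential) is
corrected the only way that keeps probabilities in $[0,1]$ and the two
branches continuous at $t = t_p$. For $t < t_p$ the printed miss
probability keeps the full-window value rather than clipping the window at
the excitation instant; the functions implement the printed form and the
documentation marks the region as approximate.

In area-array mode (`modulated_detection_density()`), a pixel's recorded
density is its own exponential times the product over its 63 neighbours of
their miss probabilities. Fast neighbours crowd the dead-time window right
after excitation and are exhausted late, so a long-lifetime pixel among
short-lifetime ones loses early counts disproportionately — the interaction
bias the estimators inherit.

## The estimators

`fit_lifetime()` is the model-fitting core; it returns a classed object
with `print`, `summary`, `coef`, `predict`, `residuals`, `simulate`,
`logLik` and `plot` methods.

**MLE.** For the binned, window-truncated exponential the score equation
equates the model's expected mean bin index — strictly increasing in
$\tau$, which we assert numerically over the bracket — with the observed
one. Solved by `uniroot` on $[h/100,\,100T]$ at $10^{-9}$ tolerance;
failure to bracket is reported as non-convergence, never clamped. $M$ is
the number of *usable* bins (950, the code limit), not the nominal 1024,
since bins past the code limit can hold no data.

**CMM.** The center-of-mass method is the hardware-friendly first moment:
$\tau_{\mathrm{CMM}} = (\sum_j j N_j / N_c + \tfrac12)h$ in its raw
printed form (a bin-center $-\tfrac12$ convention is available). On a
finite window the raw moment cannot exceed $W/2$ and underestimates long
lifetimes badly (−4.5% at 20 ns on a 92.7 ns window). The standard
software calibration inverts the truncated-exponential mean
$\bar t = \tau - W/(e^{W/\tau} - 1)$; `window_correction = TRUE` (default)
applies it, which is what keeps the center-of-mass error below 1% across
the 5–20 ns resolvability range.

**LSM.** Minimizes Pearson's chi-square $\sum_j (N_j - e_j)^2/e_j$ with
$e_j$ the expected binned-exponential counts, by bounded golden-section
search. Pearson's statistic is only valid when cells hold enough counts; on
a 950-bin histogram with $10^3$–$10^4$ photons, most cells are nearly
empty, and the raw per-bin statistic acquires a large upward bias (we
measured +9% at $10^4$ photons and +0.7% at $2\times10^5$ on clean
synthetic multinomials — note the second figure matches the residual bias
published for this estimator at full statistics, which is why reproduction
runs use the raw form). The default therefore merges consecutive bins until
each cell holds at least 20 observed counts (`rebin_min = 20`), calibrated
on that synthetic study: the rebinned estimator is nearly unbiased at every
count level. The grouping uses observed counts, keeping the objective
continuous in $\tau$. A literal closed-form weighted normal equation (bin
weights $N_j^2 e^{jh/\tau}$, with the printed interval symbol read as the
bin width — the only reading under which the true $\tau$ is an exact root
on noiseless data) is available as `lsm_variant = "root"`.

## Imaging metrics and canned experiments

`build_lifetime_map()` fits every pixel; `compute_metrics()` reports the
average offset $\Delta\tau$, the across-pixel spread $\sigma_\tau$, the
average relative error, and the imaging figure of merit
$\mathrm{FoM} = \tau/\sqrt{\sigma_\tau^2 + \Delta\tau^2}$. The spread is
computed across pixels within one map — the natural choice for
uniform-intensity experiments, where all pixels are exchangeable — and the
average error as $|\overline{\hat\tau} - \tau|/\tau \times 100$.

Frame-rate arithmetic (`imaging_rate()`): at 10 MHz and 1% detection a
pixel collects $10^5$ photons/s, so the ~1000 photons per pixel a lifetime
map needs take 10 ms — 100 maps per second.

```{r example, eval = FALSE}
cfg <- sensor_config()
rep <- run_uniform_experiment(10.5, 1e5, cfg, seed = 42)
rep$cmm
```

## Problem sizes, seeds and numerical choices

The canned accuracy experiments run at $10^6$ laser cycles (about
$2.6\times10^6$ generated photons, ~$10^4$ per pixel), a size chosen so a
full experiment completes in well under a minute on one core while keeping
the Monte Carlo standard error of a mean-lifetime estimate near 6 ps. The
published reference simulations used $2\times10^7$ cycles; quantities that
depend on photon count per histogram (notably the raw least-squares bias)
therefore differ at scale, and the documentation of each experiment says
which. The 10 ms-exposure spread experiment uses ten independent $10^5$
cycle exposures and averages the across-pixel standard deviation.

Ties in arrival time (probability zero under continuous times, but
possible after user construction) break lexicographically by (row,
column), for deterministic testability. Group indexing of the vectorized
readout guards against integer overflow; exposures are otherwise limited
only by memory (~50 bytes per generated photon).

## Known limitations

* Single-exponential decays only; no IRF convolution, no phasor analysis,
  no multi-exponential unmixing.
* The position-encoder hold time is unspecified upstream and defaults to
  disabled; enabling it is a sensitivity analysis, not a calibrated model.
* The background correction is a uniform-floor subtraction
  (`subtract_uniform_background()`); the elaborate dark-count calibration
  used by hardware center-of-mass engines is out of scope.
* Circuit-level effects (quenching-delay spread across process corners,
  TDC differential nonlinearity, oscillator jitter) are not modelled. The
  published per-pixel spread at 10 ms exposure (~410 ps) exceeds the
  statistical floor $\tau/\sqrt{N_c} \approx 330$ ps that an ideal chain
  reaches; our simulator, which models the readout but not circuit jitter,
  reproduces the floor, not the published figure.
* Phantom geometry is synthetic (a centered rectangle); only summary
  statistics and fluorophore/background contrast are meaningful.
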