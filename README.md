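# spadflim

Desk-scale simulation of an event-driven SPAD image sensor for
fluorescence lifetime imaging (FLIM), with the matching analytic pile-up
model and three lifetime estimators.

## What problem this addresses, and for whom

Time-correlated single photon counting (TCSPC) builds, per pixel, a
histogram of photon arrival times after each laser pulse and fits it with
a single-exponential decay `f(t) = A exp(-t/τ)` to image the fluorescence
lifetime `τ`. Compact SPAD imagers cut cost and data rate by *event-driven
readout*: in the simulated 16×16 sensor, each 8×8 sub-array shares just
4 time-to-digital converters (TDCs) behind an OR-tree that merges all 64
pixel pulses onto one line. The price is a structured distortion —
pile-up: pulses closer than the OR-tree dead time `t_p = 360 ps` merge
(only the first survives), at most 4 events per sub-array are time-stamped
per laser period, and the 10-bit TDC (97.6 ps bins) only quantizes codes
below 950 (~92.7 ns of the 100 ns window).

The package is for sensor designers and FLIM methodologists who want to
quantify, before building hardware, how that readout chain biases lifetime
estimates: it simulates the full detection chain photon by photon,
provides the closed-form expected-count densities the chain should follow,
and fits lifetimes three ways.

## The models at the core

**Pile-up density (all pixels observing one lifetime).** With
`μ = N²·P0` expected photons per sub-array per period, the expected
per-pixel detection density under a paralyzable OR-tree dead time is

    c(t) = μ/(N²τ) · exp(-t/τ) · { exp(-μ(1 - e^(-t/τ)))          t < t_p
                                 { exp(-μ e^(-t/τ)(e^(t_p/τ)-1))  t ≥ t_p

In area-array mode a pixel's density is further multiplied by each
neighbour's probability of *not* firing within the preceding dead-time
window — fast neighbours suppress a slow pixel's early counts.

**Estimators**, via `fit_lifetime()` (a classed model object with
`coef`/`predict`/`residuals`/`simulate`/`plot` methods):

* **MLE** — solves the binned truncated-exponential score equation
  `1 + (e^(h/τ)-1)⁻¹ - M(e^(Mh/τ)-1)⁻¹ = Σⱼ j Nⱼ/Nc` by bracketed root
  finding.
* **CMM** (center of mass) — the hardware-friendly first moment
  `τ = (Σⱼ j Nⱼ/Nc + ½)h`, plus the standard finite-window calibration
  that inverts the truncated-exponential mean (default on).
* **LSM** — minimizes Pearson's chi-square `Σ (Nⱼ-eⱼ)²/eⱼ` against the
  binned exponential, with validity rebinning (≥ 20 counts per cell) by
  default and the raw per-bin statistic as an option.

`run_uniform_experiment()` / `run_interaction_experiment()` wrap the whole
pipeline and score lifetime maps with the imaging figure of merit
`FoM = τ/√(σ_τ² + Δτ²)`.

## Worked example

```r
library(spadflim)
cfg <- sensor_config()   # the simulated sensor's constants
cfg
#> SPAD sensor configuration
#>   array: 16 x 16 (sub-arrays of 8 x 8, 4 TDCs each)
#>   laser: 10 MHz (window 100 ns)
#>   TDC: h = 97.6 ps, 1024 bins, codes limited to 950 (range 92.72 ns)
#>   dead time t_p = 360 ps (paralyzable), encoder hold = 0 ps
#>   photon rate P0 = 0.01 per pixel per pulse, background = 0

# 10 ms exposure (100k laser cycles) of a uniform 10.5 ns fluorophore
ev <- generate_photon_arrivals(cfg, decay_map(10.5, cfg), 1e5, seed = 42)
ro <- readout_exposure(ev, cfg)
ro
#> spad_readout: 100000 pulses, 256393 generated -> 253413 recorded events
#>   losses: merged = 2803, tdc_exhausted = 162, invalid_frame = 0, code_overflow = 15
```

Of ~256k generated photons, ~1.1% merged in the OR-tree, 162 lost the race
for a TDC, and 15 arrived past the quantized range. Fitting the aggregate
histogram:

```r
fit <- fit_lifetime(histogram_from_readout(ro), "mle")
fit
#> Fluorescence lifetime fit (MLE)
#>   tau = 10.5218 ns  (from 253413 photons)
```

The +22 ps offset from the true 10.5 ns is the pile-up bias: merging
removes early photons preferentially, flattening the apparent decay. The
full per-pixel experiment scores each estimator:

```r
rep <- run_uniform_experiment(10.5, 1e5, cfg, seed = 42)
rep$cmm
#> metrics_report (CMM, 0.01 s exposure, 256 pixels)
#>   mean tau  = 10.5221 ns
#>   delta tau = +0.0221 ns (avg error 0.210%)
#>   sigma tau = 0.3186 ns
#>   FoM       = 32.9
```

At ~1000 photons per pixel the across-pixel spread (319 ps) sits at the
statistical floor `τ/√Nc`; longer exposures shrink it as `1/√Nc`.

A thin command-line front end over the same functions ships in
`inst/cli/spadflim` (`simulate`, `estimate`, `theory`, `experiment`,
`fixtures` subcommands).

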