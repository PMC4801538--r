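#' Generate example input files
#'
#' Writes ready-to-use fixture files: ground-truth decay-map CSV grids
#' (uniform or phantom), or a sample TCSPC histogram CSV produced by a
#' short fixed-seed simulation, plus a provenance note. All fixtures are
#' synthetic and regenerating with the same seed reproduces them
#' byte-identically.
#'
#' @param kind `"uniform"`, `"phantom1"`, `"phantom2"` or `"histogram"`.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed for the histogram simulation.
#' @param config a [sensor_config()].
#' @param tau_ns lifetime for `kind = "uniform"` and the histogram run, ns.
#' @return invisibly, the paths written.
#' @export
generate_fixtures <- function(kind = c("uniform", "phantom1", "phantom2",
                                       "histogram"),
                              out_dir, seed = 1L, config = sensor_config(),
                              tau_ns = 10.5) {
  kind <- match.arg(kind)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  if (kind %in% c("uniform", "phantom1", "phantom2")) {
    map <- if (kind == "uniform") lifetime_phantom("uniform", config, tau_ns)
           else lifetime_phantom(kind, config)
    p <- file.path(out_dir, paste0(kind, "_decay_map.csv"))
    write_decay_map(map, p)
    paths <- p
  } else {
    stream <- generate_photon_arrivals(config, decay_map(tau_ns, config),
                                       n_pulses = 20000L, seed = seed)
    ro <- readout_exposure(stream, config)
    hist <- histogram_from_readout(ro)
    p <- file.path(out_dir, sprintf("histogram_tau%.3gns_seed%d.csv",
                                    tau_ns, seed))
    write_histogram(hist, p)
    paths <- p
  }
  note <- file.path(out_dir, "README_fixtures.txt")
  writeLines(c("Synthetic fixtures generated by spadflim::generate_fixtures().",
               sprintf("kind = %s, seed = %d, tau = %g ns", kind, seed, tau_ns),
               "Decay maps: headerless CSV grids of lifetimes in ns.",
               "Histograms: CSV with columns bin_index (1-based), count."),
             note)
  invisible(c(paths, note))
}
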