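#' TCSPC decay histogram
#'
#' Binned photon arrival-time counts: `counts[j]` is the number of photons
#' recorded in time bin `j` (1-based; TDC code `c` maps to bin `j = c + 1`),
#' each bin `h` ns wide. Only the first `m_used` bins can carry data (the
#' TDC code limit); the nominal number of bins may be larger (1024 for a
#' 10-bit TDC with codes limited to 950).
#'
#' @param counts non-negative integer vector of per-bin counts.
#' @param h bin width, ns.
#' @param m_used number of usable bins (defaults to `length(counts)`);
#'   estimators sum over bins `1..m_used`.
#' @param window measurement window (laser period), ns; defaults to
#'   `length(counts) * h`.
#' @return an object of class `decay_histogram`.
#' @examples
#' hist <- decay_histogram(c(5, 3, 2, 0), h = 1)
#' hist$n_counts
#' @export
decay_histogram <- function(counts, h, m_used = length(counts),
                            window = length(counts) * h) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (h <= 0) stop("bin width must be positive", call. = FALSE)
  if (m_used < 1 || m_used > length(counts))
    stop("m_used must lie in 1..length(counts)", call. = FALSE)
  if (any(counts[seq_along(counts) > m_used] > 0))
    stop("counts beyond m_used bins must be zero", call. = FALSE)
  structure(list(counts = counts, h = h, m_used = as.integer(m_used),
                 window = window, n_counts = sum(counts)),
            class = "decay_histogram")
}

#' @export
print.decay_histogram <- function(x, ...) {
  cat(sprintf("decay_histogram: %d bins of %.4g ns (%d usable), %g counts\n",
              length(x$counts), x$h, x$m_used, x$n_counts))
  invisible(x)
}

# internal: M x n_pixels matrix of per-pixel code histograms (col-major
# pixel index (col-1)*n_rows + row, matching R matrix linear indexing)
pixel_code_counts <- function(readout) {
  cfg <- readout$config
  M <- cfg$tdc_bins_M
  npx <- cfg$n_rows * cfg$n_cols
  ev <- readout$events
  px <- (ev$col - 1L) * cfg$n_rows + ev$row
  idx <- (px - 1L) * M + ev$code + 1L
  matrix(tabulate(idx, nbins = as.numeric(M) * npx), nrow = M)
}

#' Accumulate a decay histogram from recorded events
#'
#' Standard TCSPC accumulation: counts of TDC time codes over the exposure,
#' for one pixel or aggregated over a set of pixels. Only recorded (valid)
#' events contribute; invalid frames were already discarded by
#' [readout_exposure()].
#'
#' @param readout a `spad_readout` from [readout_exposure()].
#' @param pixel `NULL` for the whole array, `c(row, col)` for one pixel, or
#'   a logical matrix selecting pixels.
#' @return a [decay_histogram()] with `tdc_bins_M` bins of width `h` and
#'   `m_used = tdc_code_max`.
#' @export
histogram_from_readout <- function(readout, pixel = NULL) {
  stopifnot(inherits(readout, "spad_readout"))
  cfg <- readout$config
  ev <- readout$events
  if (!is.null(pixel)) {
    if (is.matrix(pixel)) {
      keep <- pixel[cbind(ev$row, ev$col)]
    } else {
      if (pixel[1] < 1 || pixel[1] > cfg$n_rows ||
          pixel[2] < 1 || pixel[2] > cfg$n_cols)
        stop("pixel outside the array", call. = FALSE)
      keep <- ev$row == pixel[1] & ev$col == pixel[2]
    }
    ev <- ev[keep, , drop = FALSE]
  }
  counts <- tabulate(ev$code + 1L, nbins = cfg$tdc_bins_M)
  decay_histogram(counts, h = cfg_h_ns(cfg), m_used = cfg$tdc_code_max,
                  window = cfg$laser_period_T)
}

#' Subtract a uniform background floor from a histogram
#'
#' Simple uniform-background model for background light and dark counts:
#' subtracts `bg_level` counts from every usable bin, clipping at zero, and
#' recomputes the total. (A uniform floor is exact for background that is
#' uncorrelated with the laser, which arrives uniformly over the window.)
#'
#' @param hist a [decay_histogram()].
#' @param bg_level expected background counts per bin (non-negative).
#' @return the corrected [decay_histogram()].
#' @export
subtract_uniform_background <- function(hist, bg_level) {
  stopifnot(inherits(hist, "decay_histogram"))
  if (bg_level < 0) stop("bg_level must be non-negative", call. = FALSE)
  counts <- pmax(hist$counts - bg_level, 0)
  counts <- round(counts)
  decay_histogram(counts, h = hist$h, m_used = hist$m_used,
                  window = hist$window)
}

#' Read / write a decay histogram as CSV
#'
#' Two columns: `bin_index` (1-based) and `count`.
#'
#' @param path file path.
#' @param h bin width in ns.
#' @param m_used,window see [decay_histogram()].
#' @export
read_histogram <- function(path, h, m_used = NULL, window = NULL) {
  df <- read.csv(path)
  if (!all(c("bin_index", "count") %in% names(df)))
    stop("histogram CSV needs columns bin_index, count", call. = FALSE)
  M <- max(df$bin_index)
  counts <- numeric(M)
  counts[df$bin_index] <- df$count
  decay_histogram(counts, h = h,
                  m_used = if (is.null(m_used)) M else m_used,
                  window = if (is.null(window)) M * h else window)
}

#' @rdname read_histogram
#' @param hist a [decay_histogram()].
#' @export
write_histogram <- function(hist, path) {
  stopifnot(inherits(hist, "decay_histogram"))
  df <- data.frame(bin_index = seq_along(hist$counts), count = hist$counts)
  write.csv(df, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}
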