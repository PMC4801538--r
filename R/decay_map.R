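#' Per-pixel true-lifetime map
#'
#' A decay map holds the ground truth of a simulated FLIM acquisition: one
#' fluorescence lifetime (ns) per pixel and, optionally, one per-pixel
#' detection probability. It is the input to [generate_photon_arrivals()]
#' and the reference for [compute_metrics()].
#'
#' @param tau numeric matrix of lifetimes in ns (all positive), or a single
#'   value recycled to the sensor shape.
#' @param config a [sensor_config()]; fixes the expected matrix shape.
#' @param p0 per-pixel detection probability; a single value or a matrix of
#'   the same shape as `tau`. Defaults to `config$photon_rate_P0`.
#' @return an object of class `decay_map` with elements `tau` and `p0`.
#' @examples
#' dm <- decay_map(10.5, sensor_config())
#' @export
decay_map <- function(tau, config, p0 = NULL) {
  validate_sensor_config(config)
  if (length(tau) == 1L)
    tau <- matrix(as.numeric(tau), config$n_rows, config$n_cols)
  tau <- as.matrix(tau)
  if (!all(dim(tau) == c(config$n_rows, config$n_cols)))
    stop("tau grid shape must be (n_rows, n_cols)", call. = FALSE)
  if (any(!is.finite(tau)) || any(tau <= 0))
    stop("all lifetimes must be positive and finite", call. = FALSE)
  if (is.null(p0)) p0 <- config$photon_rate_P0
  if (length(p0) == 1L) p0 <- matrix(as.numeric(p0), config$n_rows, config$n_cols)
  p0 <- as.matrix(p0)
  if (!all(dim(p0) == dim(tau)))
    stop("p0 grid shape must match tau", call. = FALSE)
  if (any(p0 < 0) || any(p0 > 1))
    stop("p0 must lie in [0, 1]", call. = FALSE)
  structure(list(tau = tau, p0 = p0), class = "decay_map")
}

#' @export
print.decay_map <- function(x, ...) {
  cat(sprintf("decay_map: %d x %d pixels, lifetimes %.3g-%.3g ns, p0 %.3g-%.3g\n",
              nrow(x$tau), ncol(x$tau), min(x$tau), max(x$tau),
              min(x$p0), max(x$p0)))
  invisible(x)
}

#' Built-in lifetime phantoms
#'
#' Toy ground-truth pictures for end-to-end runs: a centered rectangular
#' "fluorophore" region on a uniform background. `"phantom1"` places a 14 ns
#' fluorophore on a 4 ns background, `"phantom2"` a 10.5 ns fluorophore on
#' the same background, and `"uniform"` fills the whole array with `tau_ns`.
#' The exact published pictures these phantoms stand in for are not
#' available, so the rectangle geometry (half the array side, centered) is a
#' synthetic choice; only summary statistics and fluorophore/background
#' contrast are meaningful, not pixel shapes.
#'
#' @param kind `"uniform"`, `"phantom1"` or `"phantom2"`.
#' @param config a [sensor_config()].
#' @param tau_ns lifetime for `kind = "uniform"`, ns.
#' @return a [decay_map()].
#' @export
lifetime_phantom <- function(kind = c("uniform", "phantom1", "phantom2"),
                             config = sensor_config(), tau_ns = 10.5) {
  kind <- match.arg(kind)
  if (kind == "uniform") return(decay_map(tau_ns, config))
  bg <- 4
  fg <- if (kind == "phantom1") 14 else 10.5
  tau <- matrix(bg, config$n_rows, config$n_cols)
  hr <- max(1L, config$n_rows %/% 4L); hc <- max(1L, config$n_cols %/% 4L)
  rows <- (hr + 1L):(config$n_rows - hr)
  cols <- (hc + 1L):(config$n_cols - hc)
  tau[rows, cols] <- fg
  decay_map(tau, config)
}

#' Read / write a decay map as a CSV grid
#'
#' The on-disk format is a headerless grid of `n_rows` lines with `n_cols`
#' comma-separated lifetimes in ns ('.' decimal separator, LF endings).
#'
#' @param path file path.
#' @param config a [sensor_config()] used to validate the shape.
#' @export
read_decay_map <- function(path, config) {
  m <- as.matrix(read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  decay_map(m, config)
}

#' @rdname read_decay_map
#' @param map a [decay_map()].
#' @export
write_decay_map <- function(map, path) {
  stopifnot(inherits(map, "decay_map"))
  write.table(map$tau, path, sep = ",", row.names = FALSE, col.names = FALSE,
              eol = "\n")
  invisible(path)
}
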