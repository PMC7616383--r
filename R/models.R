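#' Velocity model on a regular 2D grid
#'
#' The model parameters of the inversion: a rectangular grid of acoustic
#' sound speeds. The grid uses a (z, x) row/column convention; the physical
#' coordinate of grid cell `(1, 1)` (R indexing) is `origin`, and cell
#' `(i, j)` sits at `origin + (i - 1, j - 1) * dx`. The grid covers the
#' half-open physical extent `[origin, origin + n * dx)`.
#'
#' @param c Matrix of sound speeds (m/s), all positive and finite.
#' @param dx Grid spacing (m), identical in both dimensions.
#' @param origin Physical `(z, x)` coordinate (m) of grid cell `(1, 1)`.
#' @return An object of class `velocity_model` with fields `c`, `dx`, `nz`,
#'   `nx`, `origin`.
#' @examples
#' m <- velocity_model(matrix(1500, 40, 40), dx = 1e-3)
#' @export
velocity_model <- function(c, dx, origin = c(0, 0)) {
  c <- as.matrix(c)
  if (!is.numeric(c) || !all(is.finite(c))) stop("sound speeds must be finite numbers")
  if (any(c <= 0)) stop("sound speeds must be positive")
  if (!is.numeric(dx) || length(dx) != 1L || !is.finite(dx) || dx <= 0)
    stop("dx must be a positive scalar")
  structure(list(c = unname(c), dx = as.numeric(dx), nz = nrow(c), nx = ncol(c),
                 origin = as.numeric(origin)),
            class = "velocity_model")
}

#' @export
print.velocity_model <- function(x, ...) {
  cat(sprintf("<velocity_model> %d x %d grid, dx = %g m, c in [%g, %g] m/s\n",
              x$nz, x$nx, x$dx, min(x$c), max(x$c)))
  invisible(x)
}

#' Mass density model on a regular 2D grid
#'
#' Used only when generating observed data with the variable-density solver
#' (the inversion itself assumes homogeneous density). Same grid convention
#' as [velocity_model()]. Units follow the conventional phantom description
#' (g/cm^3-scaled values such as 1010 for water); only relative spatial
#' variation of density enters the wave equation, so the absolute unit
#' cancels.
#'
#' @param rho Matrix of densities, all positive and finite.
#' @param dx Grid spacing (m).
#' @param origin Physical coordinate of grid cell `(1, 1)`.
#' @return An object of class `density_model`.
#' @export
density_model <- function(rho, dx, origin = c(0, 0)) {
  rho <- as.matrix(rho)
  if (!is.numeric(rho) || !all(is.finite(rho))) stop("densities must be finite numbers")
  if (any(rho <= 0)) stop("densities must be positive")
  if (!is.numeric(dx) || length(dx) != 1L || dx <= 0) stop("dx must be a positive scalar")
  structure(list(rho = unname(rho), dx = as.numeric(dx), nz = nrow(rho),
                 nx = ncol(rho), origin = as.numeric(origin)),
            class = "density_model")
}

#' @export
print.density_model <- function(x, ...) {
  cat(sprintf("<density_model> %d x %d grid, rho in [%g, %g]\n",
              x$nz, x$nx, min(x$rho), max(x$rho)))
  invisible(x)
}

#' Source wavelet
#'
#' A sampled pressure time series injected at the source position. The
#' solver time step is taken from the wavelet, so the wavelet must be
#' sampled at the time step the simulation will use.
#'
#' @param samples Numeric vector of pressure samples (arbitrary units).
#' @param dt Time step (s).
#' @param centre_frequency Centre frequency (Hz), metadata used for
#'   dispersion diagnostics.
#' @return An object of class `wavelet`.
#' @export
wavelet <- function(samples, dt, centre_frequency = NA_real_) {
  if (!is.numeric(samples) || !all(is.finite(samples)))
    stop("wavelet samples must be finite")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) stop("dt must be a positive scalar")
  structure(list(samples = as.numeric(samples), dt = as.numeric(dt),
                 centre_frequency = as.numeric(centre_frequency)),
            class = "wavelet")
}

#' Ricker wavelet
#'
#' Standard band-limited source signature: the negative second derivative of
#' a Gaussian, `(1 - 2 (pi f0 (t - t0))^2) exp(-(pi f0 (t - t0))^2)`,
#' delayed by `t0` so the signal starts near zero.
#'
#' @param f0 Centre frequency (Hz).
#' @param dt Sampling interval (s).
#' @param t0 Delay (s); default `1.5 / f0`.
#' @param duration Total duration (s); default `2 * t0`.
#' @return A [wavelet()] object.
#' @examples
#' w <- ricker_wavelet(370e3, dt = 0.25e-6)
#' @export
ricker_wavelet <- function(f0, dt, t0 = 1.5 / f0, duration = 2 * t0) {
  if (!is.numeric(f0) || f0 <= 0) stop("f0 must be positive")
  t <- seq(0, duration, by = dt)
  a <- (pi * f0 * (t - t0))^2
  wavelet((1 - 2 * a) * exp(-a), dt = dt, centre_frequency = f0)
}

#' @export
print.wavelet <- function(x, ...) {
  cat(sprintf("<wavelet> %d samples, dt = %g s, f0 = %g Hz\n",
              length(x$samples), x$dt, x$centre_frequency))
  invisible(x)
}

#' Shot gather
#'
#' The time-by-receiver matrix of pressure traces recorded for one source
#' excitation.
#'
#' @param traces `nt x n_receivers` matrix of pressure samples.
#' @param dt Time step (s).
#' @param source_index Which source (1-based) produced the gather.
#' @param meta Optional named list of provenance metadata.
#' @return An object of class `shot_gather`.
#' @export
shot_gather <- function(traces, dt, source_index = 1L, meta = list()) {
  traces <- as.matrix(traces)
  if (!all(is.finite(traces))) stop("gather traces must be finite")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) stop("dt must be a positive scalar")
  structure(list(traces = unname(traces), dt = as.numeric(dt),
                 source_index = as.integer(source_index), meta = meta),
            class = "shot_gather")
}

#' @export
print.shot_gather <- function(x, ...) {
  cat(sprintf("<shot_gather> source %d: %d time samples x %d receivers, dt = %g s\n",
              x$source_index, nrow(x$traces), ncol(x$traces), x$dt))
  invisible(x)
}
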