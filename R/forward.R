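# Wave-propagation counter: every call into a propagation kernel increments
# it, so tests can assert which operations do (and do not) run simulations.
.sim_env <- new.env(parent = emptyenv())
.sim_env$count <- 0L

#' Number of wave simulations run so far
#'
#' Incremented once per forward or adjoint propagation. Used to verify the
#' no-cost claim for the standard-deviation update, which must never trigger
#' a simulation.
#' @return Integer count.
#' @export
sim_count <- function() .sim_env$count

#' Reset the wave-simulation counter
#' @return Invisibly, the previous count.
#' @export
reset_sim_count <- function() {
  old <- .sim_env$count
  .sim_env$count <- 0L
  invisible(old)
}

bump_sim <- function() .sim_env$count <- .sim_env$count + 1L

#' Absorbing sponge specification
#'
#' The model grid is extended on all four sides by `width` cells carrying a
#' friction term: the solver integrates `u_tt = c^2 lap(u) - 2 g u_t` with
#' damping rate `g = strength * (depth/width)^2 * c_max / dx` (zero in the
#' imaging region, quadratic ramp into the sponge). Absorption is defined
#' per unit time, so it is independent of the time step; a wave crossing
#' the full sponge once is attenuated by about
#' `exp(-strength * width / 3)` in amplitude. The sponge lies entirely
#' outside the user grid, so gradients are reported on the imaging region
#' only.
#'
#' @param width Sponge width in cells (default 40).
#' @param strength Damping rate coefficient (default 0.3; dimensionless per
#'   cell-crossing time).
#' @param c_ref Reference speed (m/s) fixing the damping rate scale. A fixed
#'   constant rather than the model maximum, so the sponge operator does not
#'   change when the model does (keeps the misfit gradient exactly
#'   model-independent through the boundary).
#' @return An object of class `sponge_spec`.
#' @export
sponge_spec <- function(width = 40L, strength = 0.3, c_ref = 1500) {
  if (width < 0) stop("width must be >= 0")
  structure(list(width = as.integer(width), strength = strength,
                 c_ref = c_ref),
            class = "sponge_spec")
}

# gamma * dt on the padded grid; returns the two diagonal update factors
# A = 1/(1 + g dt) and AB = (1 - g dt)/(1 + g dt) of the damped leapfrog.
build_damp <- function(nz, nx, sponge, nu) {
  W <- sponge$width
  nzp <- nz + 2L * W; nxp <- nx + 2L * W
  if (W == 0) {
    one <- matrix(1, nzp, nxp)
    return(list(A = one, AB = one))
  }
  dep <- function(i, n) pmax(W - (i - 1), i - (n - W), 0)
  dz <- dep(seq_len(nzp), nzp)
  dxv <- dep(seq_len(nxp), nxp)
  d <- outer(dz, dxv, pmax)
  gd <- sponge$strength * (d / W)^2 * nu
  list(A = 1 / (1 + gd), AB = (1 - gd) / (1 + gd))
}

pad_edge <- function(m, W) {
  if (W == 0) return(m)
  m <- m[c(rep(1, W), seq_len(nrow(m)), rep(nrow(m), W)), , drop = FALSE]
  m[, c(rep(1, W), seq_len(ncol(m)), rep(ncol(m), W)), drop = FALSE]
}

#' Courant stability limit of the solver stencil
#'
#' The maximum stable Courant number `c_max * dt / dx` of the explicit
#' scheme (2nd-order in time, 10th-order in space, 2D), from the spectral
#' radius of the discrete Laplacian at the Nyquist wavenumber.
#' @return Scalar limit (about 0.541).
#' @export
courant_limit <- function() courant_limit_cpp()

#' Check time-step stability and dispersion
#'
#' Computes the Courant number `nu = c_max * dt / dx` and compares it with
#' the stencil's stability limit; optionally checks the number of grid
#' points per minimum wavelength at the source centre frequency.
#'
#' @param model A [velocity_model()].
#' @param dt Proposed time step (s), must be positive.
#' @param f0 Optional source centre frequency (Hz) for the dispersion check.
#' @param ppw_threshold Minimum acceptable points per wavelength (default 4,
#'   a conventional figure for a 10th-order stencil).
#' @param c_max Optional override of the maximum speed (e.g. the upper clip
#'   bound when models will be sampled stochastically).
#' @return A list of class `stability_report`: `courant`, `limit`, `stable`,
#'   `ppw`, `dispersion_warning`.
#' @examples
#' m <- velocity_model(matrix(1540, 20, 20), dx = 0.5e-3)
#' check_stability(m, dt = 0.06e-6)
#' @export
check_stability <- function(model, dt, f0 = NULL, ppw_threshold = 4,
                            c_max = NULL) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) stop("dt must be positive")
  cmax <- if (is.null(c_max)) max(model$c) else c_max
  nu <- cmax * dt / model$dx
  lim <- courant_limit()
  ppw <- if (is.null(f0)) NA_real_ else min(model$c) / (f0 * model$dx)
  structure(list(courant = nu, limit = lim, stable = nu <= lim, ppw = ppw,
                 dispersion_warning = !is.na(ppw) && ppw < ppw_threshold),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> Courant %.4f (limit %.4f): %s", x$courant,
              x$limit, if (x$stable) "stable" else "UNSTABLE"))
  if (!is.na(x$ppw))
    cat(sprintf("; %.1f points/wavelength%s", x$ppw,
                if (x$dispersion_warning) " (dispersion warning)" else ""))
  cat("\n")
  invisible(x)
}

#' 10th-order Laplacian
#'
#' Centred 10th-order finite-difference approximation of the 2D Laplacian,
#' the spatial operator of the wave solver. Cells outside the grid are
#' treated as zero (the padding convention of the solver, whose sponge
#' drives the field to zero at the padded boundary).
#'
#' @param field Numeric matrix, at least 11 points in each dimension.
#' @param dx Grid spacing (m).
#' @return Matrix of the same shape.
#' @export
laplacian <- function(field, dx) {
  field <- as.matrix(field)
  if (nrow(field) < 11 || ncol(field) < 11)
    stop("field must be at least 11 points in each dimension")
  laplacian_cpp(field, dx)
}

# Internal: assemble padded grids and stencils shared by forward/adjoint.
solver_setup <- function(model, geometry, wavelet, source_index, nt,
                         sponge, scheme, density = NULL) {
  W <- sponge$width
  c_pad <- pad_edge(model$c, W)
  damp <- build_damp(model$nz, model$nx, sponge,
                     nu = sponge$c_ref * wavelet$dt / model$dx)
  src <- map_positions(geometry$sources[source_index, , drop = FALSE], model,
                       W, scheme)
  rec <- map_positions(geometry$receivers, model, W, scheme)
  amp <- matrix(0, nt, length(source_index))
  nw <- min(length(wavelet$samples), nt)
  amp[seq_len(nw), ] <- wavelet$samples[seq_len(nw)]
  gl <- NULL
  if (!is.null(density)) {
    if (!identical(dim(density$rho), dim(model$c)))
      stop("density grid must be conformal with the velocity grid")
    lr <- log(pad_edge(density$rho, W))
    gl <- list(glz = first_deriv(lr, model$dx, 1),
               glx = first_deriv(lr, model$dx, 2))
  }
  list(c2 = c_pad^2, damp = damp, src = src, rec = rec, amp = amp, gl = gl,
       W = W, n_rec = nrow(geometry$receivers))
}

# 10th-order centred first derivative along dimension 1 (z) or 2 (x), with
# edge replication outside the grid (so a constant field has an exactly
# zero derivative everywhere); used to precompute grad(ln rho).
first_deriv <- function(m, dx, dim) {
  co <- c(5 / 6, -5 / 21, 5 / 84, -5 / 504, 1 / 1260)
  out <- matrix(0, nrow(m), ncol(m))
  shift <- function(m, k, dim) {
    n <- if (dim == 1) nrow(m) else ncol(m)
    idx <- pmin(pmax(seq_len(n) + k, 1), n)
    if (dim == 1) m[idx, , drop = FALSE] else m[, idx, drop = FALSE]
  }
  for (k in 1:5) out <- out + co[k] * (shift(m, k, dim) - shift(m, -k, dim))
  out / dx
}

default_nt <- function(model, geometry, wavelet) {
  d <- 0
  for (i in seq_len(nrow(geometry$sources)))
    d <- max(d, sqrt(colSums((t(geometry$receivers) - geometry$sources[i, ])^2)))
  diag_len <- sqrt((model$nz * model$dx)^2 + (model$nx * model$dx)^2)
  tmax <- 1.3 * max(d, diag_len / 2) / min(model$c) +
    2 * length(wavelet$samples) * wavelet$dt
  as.integer(ceiling(tmax / wavelet$dt))
}

#' Simulate one shot (constant density)
#'
#' Explicit finite-difference time stepping of the acoustic wave equation
#' `c^-2 u_tt - lap(u) = s` with an absorbing sponge boundary, injecting
#' the wavelet at one source and recording traces at every receiver.
#'
#' @param model A [velocity_model()].
#' @param geometry An [acquisition_geometry()].
#' @param wavelet A [wavelet()]; its `dt` is the solver time step.
#' @param source_index Which source fires (1-based).
#' @param record_wavefield If `TRUE`, also return the full forward
#'   wavefield history (needed by the imaging condition).
#' @param nt Number of time samples; default sized from the geometry.
#' @param sponge A [sponge_spec()].
#' @param scheme Source/receiver gridding: `"nearest"` (default) or
#'   `"bilinear"`.
#' @param enforce_stability If `TRUE` (default), error when
#'   [check_stability()] fails rather than attempting the run.
#' @return A [shot_gather()], with the wavefield store attached as attribute
#'   `"wavefield"` when requested.
#' @export
simulate_shot <- function(model, geometry, wavelet, source_index = 1L,
                          record_wavefield = FALSE, nt = NULL,
                          sponge = sponge_spec(), scheme = "nearest",
                          enforce_stability = TRUE) {
  propagate(model, geometry, wavelet, source_index, record_wavefield, nt,
            sponge, scheme, enforce_stability, density = NULL)
}

#' Simulate one shot with variable density
#'
#' Solves the variable-density acoustic wave equation in pressure form,
#' `rho c^2 div(rho^-1 grad p)`, expanded as
#' `c^2 lap(p) - c^2 grad(ln rho) . grad(p)` so that with uniform density it
#' reduces exactly to [simulate_shot()]. Used to generate observed data
#' whose physics deliberately mismatches the (constant-density) inversion.
#'
#' @inheritParams simulate_shot
#' @param density A [density_model()] conformal with `model`.
#' @return A [shot_gather()].
#' @export
simulate_shot_variable_density <- function(model, density, geometry, wavelet,
                                           source_index = 1L, nt = NULL,
                                           sponge = sponge_spec(),
                                           scheme = "nearest",
                                           enforce_stability = TRUE) {
  propagate(model, geometry, wavelet, source_index, FALSE, nt, sponge,
            scheme, enforce_stability, density = density)
}

propagate <- function(model, geometry, wavelet, source_index, record_wavefield,
                      nt, sponge, scheme, enforce_stability, density) {
  if (is.null(nt)) nt <- default_nt(model, geometry, wavelet)
  nt <- as.integer(nt)
  rep_ <- check_stability(model, wavelet$dt)
  if (enforce_stability && !rep_$stable)
    stop(sprintf("time step unstable: Courant %.3f exceeds limit %.3f",
                 rep_$courant, rep_$limit))
  st <- solver_setup(model, geometry, wavelet, source_index, nt, sponge,
                     scheme, density)
  bump_sim()
  out <- fd_forward_cpp(st$c2, if (is.null(st$gl)) NULL else st$gl$glz,
                        if (is.null(st$gl)) NULL else st$gl$glx,
                        model$dx, wavelet$dt, nt,
                        st$src$cell, st$src$grp, st$src$w, st$amp,
                        st$rec$cell, st$rec$grp, st$rec$w, st$n_rec,
                        st$damp$A, st$damp$AB, isTRUE(record_wavefield))
  if (!out$ok)
    stop(sprintf("instability detected at time step %d (field overflowed)",
                 out$bad_step))
  g <- shot_gather(out$traces, wavelet$dt, source_index,
                   meta = list(nt = nt, sponge_width = st$W))
  if (isTRUE(record_wavefield)) {
    attr(g, "wavefield") <- wavefield_store(out$wavefield, wavelet$dt,
                                            model$dx, st, nt)
  }
  g
}

wavefield_store <- function(arr, dt, dx, setup, nt, every = 1L) {
  structure(list(u = arr, dt = dt, dx = dx, nt = nt, every = as.integer(every),
                 c2 = setup$c2, damp = setup$damp, src = setup$src,
                 amp = setup$amp, W = setup$W),
            class = "wavefield_store")
}

#' @export
print.wavefield_store <- function(x, ...) {
  d <- dim(x$u)
  cat(sprintf("<wavefield_store> %d x %d padded grid, %d snapshots (every %d)\n",
              d[1], d[2], d[3], x$every))
  invisible(x)
}

#' Zero-phase low-pass filter a gather
#'
#' Trace-wise zero-phase Butterworth low-pass (order 4, applied forward and
#' backward), the multiscale-inversion device used to keep observed and
#' predicted data in phase: both sides of the residual are filtered with the
#' identical operator.
#'
#' @param gather A [shot_gather()] (or plain matrix with attribute-free
#'   traces and a `dt` argument).
#' @param cutoff Cut-off frequency (Hz), `0 < cutoff < Nyquist`.
#' @param order Butterworth order (default 4).
#' @return The filtered gather (same class as input).
#' @export
lowpass_filter <- function(gather, cutoff, order = 4) {
  is_g <- inherits(gather, "shot_gather")
  tr <- if (is_g) gather$traces else as.matrix(gather)
  dt <- if (is_g) gather$dt else attr(gather, "dt")
  if (is.null(dt)) stop("dt unavailable")
  nyq <- 1 / (2 * dt)
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff >= nyq)
    stop("cutoff must satisfy 0 < cutoff < Nyquist")
  bf <- signal::butter(order, cutoff / nyq, type = "low")
  out <- apply(tr, 2, function(x) signal::filtfilt(bf, x))
  out <- matrix(out, nrow = nrow(tr))
  if (is_g) {
    gather$traces <- out
    gather$meta$lowpass_cutoff <- cutoff
    gather
  } else out
}

filter_traces <- function(traces, dt, cutoff, order = 4) {
  if (is.null(cutoff)) return(traces)
  nyq <- 1 / (2 * dt)
  bf <- signal::butter(order, cutoff / nyq, type = "low")
  matrix(apply(traces, 2, function(x) signal::filtfilt(bf, x)),
         nrow = nrow(traces))
}
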