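#' Back-propagate a data residual
#'
#' Injects the residual `d - L(m)` time-reversed at the receiver stencils
#' and propagates it with the exact discrete transpose of the forward
#' time-stepping operator, returning the adjoint wavefield history aligned
#' to forward time. The returned store also carries the adjoint-mapped
#' source series (the transpose of the wavelet-to-traces map evaluated on
#' the residual), which the dot-product test uses.
#'
#' @param model A [velocity_model()].
#' @param geometry An [acquisition_geometry()].
#' @param residual `nt x n_receivers` matrix of residual traces
#'   (observed minus predicted, after identical filtering), or a
#'   [shot_gather()] holding them.
#' @param dt Time step (s); taken from the residual gather if one is given.
#' @param source_index Source of the shot (for the adjoint-source
#'   extraction stencil).
#' @param sponge,scheme As in [simulate_shot()] (must match the forward run).
#' @return A `wavefield_store` for the adjoint field with element `adjsrc`
#'   attached as an attribute.
#' @export
backpropagate_adjoint <- function(model, geometry, residual, dt = NULL,
                                  source_index = 1L, sponge = sponge_spec(),
                                  scheme = "nearest") {
  if (inherits(residual, "shot_gather")) {
    dt <- residual$dt
    residual <- residual$traces
  }
  if (is.null(dt)) stop("dt must be supplied with a plain residual matrix")
  residual <- as.matrix(residual)
  if (ncol(residual) != nrow(geometry$receivers))
    stop("residual does not conform to the geometry")
  nt <- nrow(residual)
  wv <- wavelet(numeric(2), dt)  # placeholder; only stencils are needed
  st <- solver_setup(model, geometry, wv, source_index, nt, sponge, scheme)
  bump_sim()
  out <- fd_adjoint_cpp(st$c2, model$dx, dt, nt, residual,
                        st$rec$cell, st$rec$grp, st$rec$w,
                        st$src$cell, st$src$grp, st$src$w,
                        length(source_index), st$damp$A, st$damp$AB, TRUE)
  if (!out$ok)
    stop(sprintf("instability detected at adjoint time step %d", out$bad_step))
  ws <- wavefield_store(out$wavefield, dt, model$dx, st, nt)
  attr(ws, "adjsrc") <- out$adjsrc
  ws
}

#' Zero-lag imaging condition
#'
#' Correlates the forward and adjoint wavefield histories into the per-pixel
#' misfit gradient with respect to sound speed. The correlation is the exact
#' discrete gradient of the data misfit for the solver's time-stepping
#' scheme: `delta_m = -2 c dt^2 G sum_n w[n+1] * (lap(u[n]) + s[n])`, where
#' `G` is the sponge taper and `s` the source injection. Through the wave
#' equation itself this is the familiar zero-lag correlation of the adjoint
#' field with the (scaled) second time derivative of the forward field. The
#' absorbing margin lies outside the user grid and is excluded from the
#' returned image.
#'
#' @param forward Forward `wavefield_store` from
#'   `simulate_shot(..., record_wavefield = TRUE)`.
#' @param adjoint Adjoint `wavefield_store` from [backpropagate_adjoint()].
#' @param model The [velocity_model()] both fields were propagated in.
#' @return A `gradient_image`: matrix `delta_m` of the model grid shape
#'   (m/s misfit-gradient units) with class attribute.
#' @export
imaging_condition <- function(forward, adjoint, model) {
  if (!identical(dim(forward$u)[1:2], dim(adjoint$u)[1:2]))
    stop("wavefield stores are on different grids")
  if (forward$nt != adjoint$nt || forward$dt != adjoint$dt)
    stop("wavefield stores are misaligned in time")
  if (forward$every != 1L || adjoint$every != 1L)
    stop("imaging condition requires undecimated stores (every = 1)")
  out <- grad_correlate_cpp(forward$u, adjoint$u, forward$c2, forward$damp$A,
                            forward$dx, forward$dt, forward$nt,
                            forward$src$cell, forward$src$grp, forward$src$w,
                            forward$amp)
  W <- forward$W
  ii <- (W + 1):(W + model$nz); jj <- (W + 1):(W + model$nx)
  inner <- out$grad[ii, jj, drop = FALSE]
  structure(inner, class = c("gradient_image", "matrix", "array"),
            illum = out$illum[ii, jj, drop = FALSE])
}

#' Adjoint-state gradient and misfit for one shot
#'
#' Runs the forward solve, low-pass filters observed and predicted data
#' identically, forms the residual, back-propagates it, and applies the
#' imaging condition. The misfit is `Gamma = 0.5 * ||r_f||^2` over the
#' filtered residual; to keep the gradient exact for that objective the
#' adjoint source is the filter re-applied to the filtered residual (the
#' zero-phase filter is symmetric, hence self-transpose up to edge effects).
#'
#' @param model A [velocity_model()] (the current model iterate).
#' @param geometry An [acquisition_geometry()].
#' @param wavelet The source [wavelet()].
#' @param observed A [shot_gather()] of observed data for this source.
#' @param cutoff Low-pass cut-off (Hz) applied to both sides, or `NULL` for
#'   no filtering.
#' @param sponge,scheme,enforce_stability As in [simulate_shot()].
#' @return List with `gradient` (a `gradient_image`) and `misfit` (scalar).
#' @export
shot_gradient <- function(model, geometry, wavelet, observed, cutoff = NULL,
                          sponge = sponge_spec(), scheme = "nearest",
                          enforce_stability = TRUE) {
  if (!inherits(observed, "shot_gather")) stop("observed must be a shot_gather")
  nt <- nrow(observed$traces)
  pred <- simulate_shot(model, geometry, wavelet, observed$source_index,
                        record_wavefield = TRUE, nt = nt, sponge = sponge,
                        scheme = scheme, enforce_stability = enforce_stability)
  fwd <- attr(pred, "wavefield")
  dobs <- filter_traces(observed$traces, observed$dt, cutoff)
  dprd <- filter_traces(pred$traces, observed$dt, cutoff)
  rf <- dobs - dprd
  misfit <- 0.5 * sum(rf^2)
  adj_src <- if (is.null(cutoff)) rf else filter_traces(rf, observed$dt, cutoff)
  adj <- backpropagate_adjoint(model, geometry, adj_src, dt = observed$dt,
                               source_index = observed$source_index,
                               sponge = sponge, scheme = scheme)
  list(gradient = imaging_condition(fwd, adj, model), misfit = misfit)
}

#' Data misfit for one shot
#'
#' `Gamma = 0.5 * ||filter(d) - filter(L(m))||^2`, the objective whose
#' gradient [shot_gradient()] computes. Used by finite-difference gradient
#' checks.
#' @inheritParams shot_gradient
#' @return Scalar misfit.
#' @export
shot_misfit <- function(model, geometry, wavelet, observed, cutoff = NULL,
                        sponge = sponge_spec(), scheme = "nearest",
                        enforce_stability = TRUE) {
  nt <- nrow(observed$traces)
  pred <- simulate_shot(model, geometry, wavelet, observed$source_index,
                        record_wavefield = FALSE, nt = nt, sponge = sponge,
                        scheme = scheme, enforce_stability = enforce_stability)
  rf <- filter_traces(observed$traces, observed$dt, cutoff) -
    filter_traces(pred$traces, observed$dt, cutoff)
  0.5 * sum(rf^2)
}
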