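# Shared fixtures. Desk-scale runs are expensive (tens of seconds), so they
# are computed once per session and reused across test files.
.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- force(expr)
  .run_cache[[key]]
}

desk_cfg <- function() desk_config()

desk_obs <- function(condition = "matched", seed = 1L) {
  cached(paste0("obs_", condition, "_", seed),
         experiment_observed(desk_cfg(), condition, seed = seed))
}

desk_matched <- function(seed = 1L) {
  cached(paste0("matched_", seed),
         run_experiment("progressive_decoding", seed = seed,
                        config = desk_cfg(), observed = desk_obs()))
}

# Small-grid transmission setup used by the gradient-oracle and adjoint
# tests: 40 x 40 cells at 1 mm, smooth fast anomaly, 2 sources, 4 receivers.
small_problem <- function() {
  cached("small_problem", {
    nz <- 40; nx <- 40; dx <- 1e-3
    zz <- matrix(seq_len(nz), nz, nx)
    xx <- matrix(seq_len(nx), nz, nx, byrow = TRUE)
    bump <- 40 * exp(-((zz - 20)^2 + (xx - 22)^2) / 30)
    m_true <- velocity_model(matrix(1500, nz, nx) + bump, dx)
    m0 <- velocity_model(matrix(1500, nz, nx), dx)
    geom <- acquisition_geometry(
      sources = rbind(c(8e-3, 8e-3), c(32e-3, 10e-3)),
      receivers = rbind(c(8e-3, 32e-3), c(32e-3, 30e-3),
                        c(20e-3, 34e-3), c(10e-3, 30e-3)))
    wv <- ricker_wavelet(150e3, dt = 0.25e-6)
    sp <- sponge_spec(20)
    nt <- 250L
    obs <- lapply(1:2, function(s)
      simulate_shot(m_true, geom, wv, s, nt = nt, sponge = sp))
    list(m_true = m_true, m0 = m0, geom = geom, wv = wv, sp = sp, nt = nt,
         obs = obs, dx = dx)
  })
}

# Tiny inversion problem for loop-level tests (seconds, not minutes).
tiny_inversion <- function(iterations = 12L, deterministic = FALSE,
                           sigma0 = 2, seed = 7L) {
  p <- small_problem()
  init <- init_from_prior(prior_spec(1500, sigma0^2), c(40, 40))
  cfg <- inversion_config(iterations = iterations, batch_size = 1L,
                          cutoff = NULL, step_frac = 0.01,
                          deterministic = deterministic, sponge = p$sp,
                          store_trajectory = TRUE)
  run_inversion(p$obs, init, p$geom, p$wv, cfg, dx = p$dx, seed = seed)
}
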