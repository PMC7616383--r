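test_that("stability report computes the Courant number and flags bad time steps", {
  m <- velocity_model(matrix(1540, 20, 20), dx = 0.5e-3)
  r <- check_stability(m, dt = 0.06e-6)
  expect_equal(r$courant, 1540 * 0.06e-6 / 0.5e-3, tolerance = 1e-12)
  expect_equal(r$courant, 0.1848, tolerance = 1e-3)
  expect_true(r$stable)
  expect_error(check_stability(m, dt = 0), "positive")
  r2 <- check_stability(m, dt = 1e-6)  # nu = 3.08, far beyond the limit
  expect_false(r2$stable)
  # dispersion warning from points per wavelength
  r3 <- check_stability(m, dt = 0.06e-6, f0 = 1.4e6)
  expect_true(r3$dispersion_warning)
})

test_that("runs just below the stability bound stay bounded; above it they diverge", {
  c0 <- 1500
  dx <- 1e-3
  m <- velocity_model(matrix(c0, 40, 40), dx)
  geom <- acquisition_geometry(rbind(c(20e-3, 15e-3)), rbind(c(20e-3, 25e-3)))
  lim <- courant_limit()
  run_max <- function(fac) {
    dt <- fac * lim * dx / c0
    wv <- ricker_wavelet(100e3, dt)
    g <- simulate_shot(m, geom, wv, nt = 400L, sponge = sponge_spec(0L),
                       enforce_stability = FALSE)
    max(abs(g$traces))
  }
  expect_lt(run_max(0.99), 1)          # bounded wave amplitude
  expect_error(run_max(1.05), "instability")
})

test_that("laplacian reproduces polynomials and plane-wave eigenvalues", {
  dx <- 1e-3
  n <- 30
  interior <- 8:(n - 8)
  # constant field -> zero in the interior
  L0 <- laplacian(matrix(3.7, n, n), dx)
  expect_equal(max(abs(L0[interior, interior])), 0, tolerance = 1e-9)
  # quadratic along x -> constant second derivative 2
  x <- matrix(((seq_len(n)) - 1) * dx, n, n, byrow = TRUE)
  Lq <- laplacian(x^2, dx)
  expect_equal(Lq[interior, interior], matrix(2, length(interior),
                                              length(interior)),
               tolerance = 1e-8)
  # plane wave at 10 points per wavelength: eigenvalue ~ -k^2
  k <- 2 * pi / (10 * dx)
  s <- sin(k * x)
  Ls <- laplacian(s, dx)
  err <- Ls[interior, interior] + k^2 * s[interior, interior]
  expect_lt(max(abs(err)), 1e-5 * k^2)
  expect_error(laplacian(matrix(0, 5, 5), dx), "11 points")
})

test_that("homogeneous first arrival matches distance over speed", {
  m <- velocity_model(matrix(1500, 60, 60), dx = 1e-3)
  wv <- ricker_wavelet(370e3, dt = 0.25e-6)
  geom <- acquisition_geometry(rbind(c(15e-3, 15e-3)), rbind(c(15e-3, 45e-3)))
  g <- simulate_shot(m, geom, wv, nt = 300L, sponge = sponge_spec(30))
  # matched-filter pick: lag of peak cross-correlation with the wavelet
  tr <- g$traces[, 1]
  n <- length(tr)
  xc <- vapply(0:(n - length(wv$samples)), function(l)
    sum(tr[l + seq_along(wv$samples)] * wv$samples), 0)
  t_pick <- (which.max(xc) - 1) * wv$dt
  expect_lt(abs(t_pick - 0.030 / 1500), 1 / 370e3)
})

test_that("the solver is linear in the source and zero wavelets give zero gathers", {
  p <- small_problem()
  g0 <- simulate_shot(p$m_true, p$geom, wavelet(numeric(10), p$wv$dt),
                      nt = 100L, sponge = p$sp)
  expect_identical(max(abs(g0$traces)), 0)
  g1 <- simulate_shot(p$m_true, p$geom, p$wv, 1, nt = p$nt, sponge = p$sp)
  wv2 <- wavelet(2.5 * p$wv$samples, p$wv$dt, p$wv$centre_frequency)
  g2 <- simulate_shot(p$m_true, p$geom, wv2, 1, nt = p$nt, sponge = p$sp)
  expect_equal(g2$traces, 2.5 * g1$traces, tolerance = 1e-12)
})

test_that("source-receiver reciprocity holds on a heterogeneous model", {
  p <- small_problem()
  a <- c(8e-3, 8e-3); b <- c(30e-3, 32e-3)
  g_ab <- simulate_shot(p$m_true,
                        acquisition_geometry(rbind(a), rbind(b)),
                        p$wv, nt = p$nt, sponge = p$sp)
  g_ba <- simulate_shot(p$m_true,
                        acquisition_geometry(rbind(b), rbind(a)),
                        p$wv, nt = p$nt, sponge = p$sp)
  expect_equal(g_ab$traces, g_ba$traces, tolerance = 1e-9)
})

test_that("field energy decays after the wave leaves a homogeneous grid", {
  m <- velocity_model(matrix(1500, 60, 60), dx = 1e-3)
  wv <- ricker_wavelet(200e3, dt = 0.25e-6)
  geom <- acquisition_geometry(rbind(c(30e-3, 30e-3)), rbind(c(30e-3, 40e-3)))
  g <- simulate_shot(m, geom, wv, nt = 400L, record_wavefield = TRUE,
                     sponge = sponge_spec(40))
  en <- apply(attr(g, "wavefield")$u^2, 3, sum)
  expect_lt(en[400] / max(en), 0.05)
})

test_that("variable-density solver coincides with the constant-density one for uniform density", {
  p <- small_problem()
  rho <- density_model(matrix(1010, 40, 40), p$dx)
  g_vd <- simulate_shot_variable_density(p$m_true, rho, p$geom, p$wv, 1,
                                         nt = p$nt, sponge = p$sp)
  g_cd <- simulate_shot(p$m_true, p$geom, p$wv, 1, nt = p$nt, sponge = p$sp)
  expect_lt(max(abs(g_vd$traces - g_cd$traces)), 1e-6 * max(abs(g_cd$traces)))
  # zero wavelet -> zero gather through the variable-density path too
  g0 <- simulate_shot_variable_density(p$m_true, rho, p$geom,
                                       wavelet(numeric(5), p$wv$dt), 1,
                                       nt = 80L, sponge = p$sp)
  expect_identical(max(abs(g0$traces)), 0)
})

test_that("a density contrast increases back-scattered energy", {
  dx <- 0.5e-3; n <- 100
  m <- velocity_model(matrix(1500, n, n), dx)
  ctr <- c(24.75e-3, 24.75e-3)
  rho_u <- density_model(matrix(1010, n, n), dx)
  sp2 <- phantom_spec(c(n, n), dx, background_density = 1010,
                      inclusions = list(circle_inclusion(ctr, 12e-3, 1500,
                                                         1220)))
  rho_c <- make_phantom(sp2)$density
  geom <- acquisition_geometry(rbind(c(24.75e-3, 4e-3)),
                               rbind(c(20e-3, 4e-3)))
  wv <- ricker_wavelet(370e3, 0.05e-6)
  nt <- 700L
  g_u <- simulate_shot_variable_density(m, rho_u, geom, wv, 1, nt = nt,
                                        sponge = sponge_spec(40))
  g_c <- simulate_shot_variable_density(m, rho_c, geom, wv, 1, nt = nt,
                                        sponge = sponge_spec(40))
  # window after the direct wave: reflection from the impedance contrast
  win <- 350:700
  expect_gt(sum(g_c$traces[win, 1]^2), 2 * sum(g_u$traces[win, 1]^2))
})

test_that("low-pass filtering preserves the passband, kills the stopband, and is near-idempotent", {
  dt <- 1e-6
  t <- (0:1999) * dt
  mk <- function(f) shot_gather(cbind(sin(2 * pi * f * t)), dt)
  mid <- 500:1500
  rms <- function(g) sqrt(mean(g$traces[mid, 1]^2))
  pass <- lowpass_filter(mk(100e3), 200e3)
  expect_equal(rms(pass) / rms(mk(100e3)), 1, tolerance = 0.02)
  stopb <- lowpass_filter(mk(400e3), 200e3)
  expect_lt(rms(stopb) / rms(mk(400e3)), 0.05)
  once <- lowpass_filter(mk(100e3), 400e3)
  twice <- lowpass_filter(once, 400e3)
  expect_equal(twice$traces[mid, ], once$traces[mid, ], tolerance = 0.02)
  expect_error(lowpass_filter(mk(100e3), 600e3), "Nyquist")
})

test_that("gather and model I/O round-trip bit-exactly", {
  p <- small_problem()
  g <- p$obs[[1]]
  td <- tempfile("io")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  write_gather(g, file.path(td, "g1"))
  g2 <- read_gather(file.path(td, "g1"))
  expect_identical(g2$traces, g$traces)
  expect_identical(g2$dt, g$dt)
  expect_identical(g2$source_index, g$source_index)
  write_model(p$m_true, file.path(td, "m"))
  m2 <- read_model(file.path(td, "m"))
  expect_identical(m2$c, p$m_true$c)
  expect_identical(m2$dx, p$m_true$dx)
})

test_that("model constructors validate their invariants", {
  expect_error(velocity_model(matrix(-1, 5, 5), 1e-3), "positive")
  expect_error(velocity_model(matrix(1500, 5, 5), 0), "positive")
  expect_error(density_model(matrix(0, 5, 5), 1e-3), "positive")
  expect_error(wavelet(c(1, NA), 1e-6), "finite")
  expect_error(shot_gather(matrix(Inf, 2, 2), 1e-6), "finite")
})
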