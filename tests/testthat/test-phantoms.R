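test_that("circle rasterisation matches its analytic area within a perimeter band", {
  sp <- phantom_spec(c(200, 200), 0.5e-3,
                     inclusions = list(circle_inclusion(c(50e-3, 50e-3),
                                                        50e-3, 1540, 1010)))
  ph <- make_phantom(sp)
  count <- sum(ph$velocity$c == 1540)
  r_px <- 25e-3 / 0.5e-3
  expect_lt(abs(count - pi * r_px^2), 2 * pi * r_px)
  # halving dx quadruples the pixel count within perimeter tolerance
  sp2 <- phantom_spec(c(400, 400), 0.25e-3,
                      inclusions = list(circle_inclusion(c(50e-3, 50e-3),
                                                         50e-3, 1540, 1010)))
  count2 <- sum(make_phantom(sp2)$velocity$c == 1540)
  expect_lt(abs(count2 - 4 * count), 4 * pi * (2 * r_px))
})

test_that("phantoms honour their speeds, densities, and bounds", {
  sp <- phantom_spec(c(100, 100), 0.5e-3, background_density = 1010,
                     inclusions = list(circle_inclusion(c(25e-3, 25e-3),
                                                        20e-3, 1540, 1220)))
  ph <- make_phantom(sp)
  expect_setequal(unique(c(ph$density$rho)), c(1010, 1220))
  expect_setequal(unique(c(ph$velocity$c)), c(1500, 1540))
  # no inclusions -> uniform grids
  ph0 <- make_phantom(phantom_spec(c(20, 20), 1e-3))
  expect_true(all(ph0$velocity$c == 1500))
  expect_true(all(ph0$density$rho == 1010))
  expect_error(make_phantom(
    phantom_spec(c(50, 50), 0.5e-3,
                 inclusions = list(circle_inclusion(c(24e-3, 24e-3), 60e-3)))),
    "outside")
})

test_that("circular arrays place co-located elements exactly on the circle", {
  g4 <- circular_array(4, diameter = 20e-3, centre = c(0, 0))
  expect_equal(g4$sources,
               rbind(c(0, 10e-3), c(10e-3, 0), c(0, -10e-3), c(-10e-3, 0)),
               tolerance = 1e-12)
  expect_identical(g4$sources, g4$receivers)
  g510 <- circular_array(510, diameter = 50e-3, centre = c(1, 1))
  expect_identical(nrow(g510$sources), 510L)
  rad <- sqrt(rowSums((g510$sources - rep(1, 2)[col(g510$sources)])^2))
  expect_equal(rad, rep(25e-3, 510), tolerance = 1e-12)
  ang <- sort(atan2(g510$sources[, 1] - 1, g510$sources[, 2] - 1))
  gaps <- diff(ang)
  expect_equal(max(gaps), 2 * pi / 510, tolerance = 1e-9)
  expect_equal(min(gaps), 2 * pi / 510, tolerance = 1e-9)
})

test_that("rotating-transducer schedules exclude colliding stations", {
  rt <- rotating_transducer_geometry(16, elements_per_transducer = 24,
                                     exclusion = 2)
  expect_identical(rt$receivers_per_source, 11)
  expect_identical(rt$n_sources, 384)
  expect_true(all(table(rt$schedule$source_station) == 11))
  rt0 <- rotating_transducer_geometry(8, exclusion = 0)
  expect_identical(rt0$receivers_per_source, 7)
  expect_error(rotating_transducer_geometry(5, exclusion = 2), "exceed")
})

test_that("geometry corruption displaces exactly the specified sources", {
  g <- circular_array(16, 40e-3, c(25e-3, 25e-3))
  same <- corrupt_geometry(g, corruption_spec(fraction = 0), seed = 1)
  expect_identical(same$sources, g$sources)
  expect_length(same$meta$corrupted, 0)
  all_c <- corrupt_geometry(g, corruption_spec(fraction = 1, offset = 2e-3),
                            seed = 1)
  shifts <- sqrt(rowSums((all_c$sources - g$sources)^2))
  expect_equal(shifts, rep(2e-3, 16), tolerance = 1e-12)
  expect_identical(all_c$receivers, g$receivers)  # receivers untouched
  part <- corrupt_geometry(g, corruption_spec(fraction = 0.25), seed = 3)
  expect_length(part$meta$corrupted, 4)
  moved <- which(sqrt(rowSums((part$sources - g$sources)^2)) > 1e-12)
  expect_identical(moved, part$meta$corrupted)
  # same seed reproduces the draw
  part2 <- corrupt_geometry(g, corruption_spec(fraction = 0.25), seed = 3)
  expect_identical(part2$sources, part$sources)
})

test_that("corrupted observed data differ only on corrupted shots", {
  p <- small_problem()
  sp <- phantom_spec(c(40, 40), 1e-3, background_speed = 1500,
                     inclusions = list(circle_inclusion(c(20e-3, 20e-3),
                                                        10e-3, 1540, 1010)))
  geom <- circular_array(4, 30e-3, c(19.5e-3, 19.5e-3))
  wv <- ricker_wavelet(150e3, 0.25e-6)
  clean <- generate_observed(sp, geom, wv, nt = 250L, fine_factor = 1L,
                             grid_shift = 0, sponge = p$sp,
                             scheme = "nearest")
  bad_geom <- corrupt_geometry(geom, corruption_spec(fraction = 0.25,
                                                     offset = 2e-3), seed = 2)
  corr <- generate_observed(sp, bad_geom, wv, nt = 250L, fine_factor = 1L,
                            grid_shift = 0, sponge = p$sp,
                            scheme = "nearest")
  bad <- bad_geom$meta$corrupted
  for (s in 1:4) {
    if (s %in% bad) expect_gt(max(abs(corr[[s]]$traces - clean[[s]]$traces)), 0)
    else expect_identical(corr[[s]]$traces, clean[[s]]$traces)
  }
})

test_that("inverting matched data from the true model starts at near-zero misfit", {
  cfg <- desk_cfg()
  obs <- desk_obs()
  ph <- make_phantom(svifwi:::exp_phantom_spec(cfg))
  sg <- shot_gradient(ph$velocity, svifwi:::exp_geometry(cfg),
                      svifwi:::exp_wavelet(cfg), obs[[1]],
                      cutoff = cfg$cutoff, sponge = cfg$sponge,
                      scheme = cfg$scheme)
  # residual energy at the generating model is a tiny fraction of the
  # misfit at the prior model
  m0 <- velocity_model(matrix(cfg$prior_mu, cfg$grid, cfg$grid), cfg$dx)
  mis0 <- shot_misfit(m0, svifwi:::exp_geometry(cfg),
                      svifwi:::exp_wavelet(cfg), obs[[1]],
                      cutoff = cfg$cutoff, sponge = cfg$sponge,
                      scheme = cfg$scheme)
  expect_lt(sg$misfit, 0.01 * mis0)
})
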