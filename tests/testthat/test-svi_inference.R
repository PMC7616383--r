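test_that("prior initialisation broadcasts mean and standard deviation", {
  vp <- init_from_prior(prior_spec(1480, 4), c(10, 12))
  expect_identical(dim(vp$mu), c(10L, 12L))
  expect_true(all(vp$mu == 1480))
  expect_true(all(vp$sigma == 2))
  # zero prior variance degenerates to a point mass
  vp0 <- init_from_prior(prior_spec(1480, 0), c(5, 5))
  expect_true(all(vp0$sigma == 0))
  d <- sample_model(vp0)
  expect_equal(d$model_sample, vp0$mu)
  # grid-valued prior round-trips unchanged
  mg <- matrix(1450 + runif(25), 5, 5)
  vg <- matrix(runif(25), 5, 5)
  vp2 <- init_from_prior(prior_spec(mg, vg), c(5, 5))
  expect_equal(vp2$mu, mg)
  expect_equal(vp2$sigma, sqrt(vg))
  expect_error(prior_spec(1480, -1), "non-negative")
})

test_that("reparameterised sampling is mu + sigma * epsilon with clipping", {
  vp <- variational_params(matrix(1480, 4, 4), matrix(2, 4, 4))
  eps <- matrix(0, 4, 4)
  eps[2, 3] <- 1
  d <- sample_model(vp, epsilon = eps)
  expect_equal(d$model_sample[2, 3], 1482)
  expect_equal(d$model_sample[1, 1], 1480)
  expect_equal(d$model_sample - vp$mu, vp$sigma * d$epsilon)
  # clipping to the physical band
  vph <- variational_params(matrix(1790, 2, 2), matrix(20, 2, 2))
  dh <- sample_model(vph, clip = c(1300, 1800), epsilon = matrix(2, 2, 2))
  expect_true(all(dh$model_sample <= 1800))
  expect_identical(dh$n_clipped, 4L)
})

test_that("sample moments converge to the variational parameters", {
  vp <- variational_params(matrix(1480, 5, 5), matrix(2, 5, 5))
  set.seed(99)
  draws <- replicate(1e4, sample_model(vp, clip = NULL)$model_sample[3, 3])
  expect_lt(abs(mean(draws) - 1480), 3 * 2 / sqrt(1e4))
  expect_lt(abs(sd(draws) - 2), 3 * 2 / sqrt(2e4))
})

test_that("mean and sigma updates are the stated elementwise arithmetic", {
  vp <- variational_params(matrix(1480, 2, 2), matrix(0, 2, 2))
  g <- structure(matrix(c(0.5, 0.5, 0, 0), 2, 2),
                 class = c("gradient_image", "matrix", "array"))
  up <- update_mean(vp, g, step = 2)
  expect_equal(up$mu, matrix(c(1479, 1479, 1480, 1480), 2, 2))
  expect_equal(up$sigma, vp$sigma)  # untouched
  draw <- list(epsilon = matrix(c(1, -1, 0, 0), 2, 2))
  us <- update_sigma(vp, g, draw, step = 1)
  expect_equal(us$sigma, matrix(c(-0.5, 0.5, 0, 0), 2, 2))
  expect_equal(variance_image(us), matrix(c(0.25, 0.25, 0, 0), 2, 2))
  # zero epsilon / zero gradient leave parameters unchanged
  expect_equal(update_sigma(vp, g, list(epsilon = matrix(0, 2, 2)), 1)$sigma,
               vp$sigma)
  g0 <- structure(matrix(0, 2, 2), class = c("gradient_image", "matrix",
                                             "array"))
  expect_equal(update_mean(vp, g0, 5)$mu, vp$mu)
  # successive mean updates commute with one update of the summed gradients
  two <- update_mean(update_mean(vp, g, 1), g0, 1)
  one <- update_mean(vp, structure(unclass(g) + unclass(g0),
                                   class = class(g)), 1)
  expect_equal(two$mu, one$mu)
})

test_that("variance image is the square of signed sigma, sign-invariant", {
  vp <- variational_params(matrix(0, 3, 3),
                           matrix(c(-2, 2, 0, 1, -1, 3, -3, 0.5, 0), 3, 3))
  v <- variance_image(vp)
  expect_true(all(v >= 0))
  expect_equal(v[1, 1], 4)
  vp2 <- vp
  vp2$sigma <- -vp2$sigma
  expect_equal(variance_image(vp2), v)
})

test_that("a fixed seed reproduces the inversion report bit-for-bit", {
  r1 <- tiny_inversion(iterations = 4L, seed = 42L)
  r2 <- tiny_inversion(iterations = 4L, seed = 42L)
  expect_identical(r1$mu, r2$mu)
  expect_identical(r1$sigma, r2$sigma)
  expect_identical(r1$misfit, r2$misfit)
  expect_identical(r1$mean_variance, r2$mean_variance)
  r3 <- tiny_inversion(iterations = 4L, seed = 43L)
  expect_false(identical(r3$mu, r1$mu))
})

test_that("the loop cycles sources round-robin and logs per-iteration traces", {
  r <- tiny_inversion(iterations = 5L)
  expect_identical(unlist(r$batch), c(1L, 2L, 1L, 2L, 1L))
  expect_length(r$misfit, 5L)
  expect_length(r$mean_variance, 5L)
  expect_true(all(is.finite(r$misfit)))
})

test_that("an interrupted run resumes from its checkpoint to the identical result", {
  p <- small_problem()
  ckpt <- tempfile(fileext = ".rds")
  on.exit(unlink(ckpt))
  mk_cfg <- function(iters, ck = NULL)
    inversion_config(iterations = iters, batch_size = 1L, cutoff = NULL,
                     step_frac = 0.01, sponge = p$sp,
                     store_trajectory = TRUE, checkpoint = ck)
  init <- init_from_prior(prior_spec(1500, 4), c(40, 40))
  full <- run_inversion(p$obs, init, p$geom, p$wv, mk_cfg(6L),
                        dx = p$dx, seed = 31L)
  # "interrupted" after 3 iterations, then resumed for the remaining 3
  invisible(run_inversion(p$obs, init, p$geom, p$wv, mk_cfg(3L, ckpt),
                          dx = p$dx, seed = 31L))
  resumed <- run_inversion(p$obs, init, p$geom, p$wv, mk_cfg(6L, ckpt),
                           dx = p$dx, seed = 31L)
  expect_identical(resumed$mu, full$mu)
  expect_identical(resumed$sigma, full$sigma)
  expect_identical(resumed$misfit, full$misfit)
  expect_identical(resumed$mean_variance, full$mean_variance)
})
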