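test_that("ssim is 1 on identical images, symmetric, and <= 0 on contrast inversion", {
  set.seed(1)
  a <- matrix(rnorm(900), 30, 30)
  b <- matrix(rnorm(900), 30, 30)
  expect_identical(ssim(a, a), 1)
  expect_equal(ssim(a, b, data_range = 4), ssim(b, a, data_range = 4),
               tolerance = 1e-12)
  # contrast inversion of a pattern with (near) zero-mean windows: the
  # luminance term is ~1 and the negated structure term drives SSIM <= 0
  ij <- outer(1:30, 1:30, function(i, j) sin(pi * i / 2) * cos(pi * j / 2))
  expect_lte(ssim(ij, -ij, data_range = diff(range(ij))), 0)
  expect_error(ssim(a, matrix(0, 5, 5)), "mismatch")
})

test_that("ssim agrees with the frozen independent reference implementation", {
  # expected values computed once with scikit-image's structural_similarity
  # (uniform 7x7 window, sample covariance, data_range = ref max - min)
  # on these seeded fixtures
  set.seed(20260922)
  a <- matrix(rnorm(900), 30, 30)
  b <- a + 0.5 * matrix(rnorm(900), 30, 30)
  c2 <- matrix(runif(900, 0, 10), 30, 30)
  expect_equal(ssim(a, b), 0.7383319558, tolerance = 1e-6)
  expect_equal(ssim(a, c2), 0.0001055685, tolerance = 1e-6)
})

test_that("variance trends summarise monotone and rise-fall traces correctly", {
  dec <- seq(10, 1, length.out = 20)
  td <- variance_trend(dec)
  expect_identical(td$peak_iteration, 1L)
  expect_lt(td$tail_slope, 0)
  inc <- seq(1, 10, length.out = 20)
  ti <- variance_trend(inc)
  expect_identical(ti$final_peak_ratio, 1)
  expect_gt(ti$tail_slope, 0)
  rf <- c(seq(1, 8, length.out = 7), seq(7.5, 3, length.out = 13))
  expect_identical(variance_trend(rf)$peak_iteration, 7L)
})

test_that("failure flag fires on rising elevated traces and stays quiet otherwise", {
  expect_false(flag_failure(rep(5, 20))$flag)           # constant
  expect_false(flag_failure(seq(20, 2, length.out = 30))$flag)  # converging
  rising <- seq(2, 30, length.out = 30)
  expect_true(flag_failure(rising)$flag)
  # against a matched reference
  expect_true(flag_failure(rising, reference = 3)$flag)
  expect_error(flag_failure(c(1, 2, 3)), "at least 10")
})

test_that("artefact masks find hot blocks, ignore uniform images, and are scale-invariant", {
  u <- matrix(1, 50, 50)
  expect_identical(sum(artefact_mask(u)), 0L)
  set.seed(2)
  v <- matrix(rexp(2500), 50, 50)
  v[11:20, 31:40] <- v[11:20, 31:40] + 10 * median(v)
  mk <- artefact_mask(v)
  expect_gt(sum(mk), 0)
  expect_true(all(which(mk, arr.ind = TRUE)[, 1] %in% 11:20))
  expect_true(all(which(mk, arr.ind = TRUE)[, 2] %in% 31:40))
  expect_identical(artefact_mask(1e6 * v), mk)
  expect_error(artefact_mask(matrix(NA_real_, 50, 50)), "finite")
})

test_that("qc report assembles ssim, trend, flag and mask", {
  m <- desk_matched()
  cfg <- desk_cfg()
  truth <- make_phantom(svifwi:::exp_phantom_spec(cfg))$velocity$c
  qc <- qc_report(m$report, reference_image = truth)
  expect_true(is.finite(qc$ssim) && qc$ssim >= -1 && qc$ssim <= 1)
  # similarity to the truth beats similarity to its contrast inversion
  expect_gt(qc$ssim, ssim(m$report$mu, 2 * mean(truth) - truth))
  expect_false(qc$failure$flag)
  expect_identical(length(qc$mean_variance_trace), m$report$iterations)
})

test_that("grayscale PNG export writes a normalised image of the right shape", {
  f <- tempfile(fileext = ".png")
  on.exit(unlink(f))
  v <- matrix(seq(0, 100, length.out = 600), 20, 30)
  write_image_png(v, f)
  img <- png::readPNG(f)
  expect_identical(dim(img)[1:2], c(20L, 30L))
  expect_equal(min(img), 0)
  expect_equal(max(img), 1)
})
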