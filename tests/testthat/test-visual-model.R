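# Vision-model primitives: Delta-S contrasts against closed forms, cone-catch
# conversion, acuity blur geometry, and the behaviour of the RNL filter.

test_that("luminance Delta-S matches its closed form", {
  expect_equal(delta_s_lum(0.4, 0.4), 0)
  expect_equal(delta_s_lum(exp(1) * 0.2, 0.2, weber_lum = 0.1), 10,
               tolerance = 1e-12)
  expect_equal(delta_s_lum(0.70, 0.25, 0.1), abs(log(0.70) - log(0.25)) / 0.1,
               tolerance = 1e-12)
  # symmetry and joint-scale invariance on random catches
  set.seed(11)
  qa <- runif(50, 0.01, 1); qb <- runif(50, 0.01, 1)
  expect_equal(delta_s_lum(qa, qb), delta_s_lum(qb, qa))
  expect_equal(delta_s_lum(3 * qa, 3 * qb), delta_s_lum(qa, qb),
               tolerance = 1e-12)
  expect_error(delta_s_lum(0, 1), "positive")
})

test_that("chromatic Delta-S matches an independent scalar evaluation", {
  v <- viewer_model()
  expect_equal(delta_s_chromatic(c(.2, .3, .4), c(.2, .3, .4), v), 0)
  # a pure luminance shift has zero chromatic contrast
  expect_equal(delta_s_chromatic(2.5 * c(.2, .3, .4), c(.2, .3, .4), v), 0,
               tolerance = 1e-12)
  # brute-force oracle: literal formula evaluation for Df = (0.1, 0, 0)
  el <- 0.05; em <- 0.07071; es <- 0.1657
  df <- c(0.1, 0, 0)
  num <- es^2 * (df[1] - df[2])^2 + em^2 * (df[1] - df[3])^2 +
    el^2 * (df[2] - df[3])^2
  den <- (el * em)^2 + (el * es)^2 + (em * es)^2
  qb <- c(.2, .3, .4)
  expect_equal(delta_s_chromatic(qb * exp(df), qb, v), sqrt(num / den),
               tolerance = 1e-9)
  # symmetric and nonnegative over random catch pairs
  set.seed(12)
  for (i in 1:20) {
    qa <- runif(3, .05, 1); qb <- runif(3, .05, 1)
    d1 <- delta_s_chromatic(qa, qb, v); d2 <- delta_s_chromatic(qb, qa, v)
    expect_equal(d1, d2, tolerance = 1e-12)
    expect_gte(d1, 0)
  }
  expect_error(delta_s_chromatic(c(0, 1, 1), c(1, 1, 1), v), "positive")
})

test_that("cone-catch conversion maps grey levels and clamps zeros", {
  cc <- to_cone_catch(matrix(0.37, 2, 2))
  expect_equal(cc$lum, matrix(0.37, 2, 2))          # (v + v) / 2
  rgb <- array(0.6, dim = c(3, 3, 3))
  cc2 <- to_cone_catch(rgb)
  expect_equal(cc2$lw, cc2$sw)
  expect_equal(cc2$lum, cc2$lw)
  cc0 <- to_cone_catch(matrix(0, 2, 2))
  expect_true(all(cc0$lw == 1 / 65536))             # log-safety floor
  srgb <- to_cone_catch(matrix(0.5, 1, 1), gamma_mode = "srgb")
  expect_equal(srgb$lum[1, 1], 0.5^2.2, tolerance = 1e-12)
  expect_error(to_cone_catch(matrix(-0.1, 1, 1)), "negative")
})

test_that("acuity blur geometry follows the viewing model", {
  v <- viewer_model()   # 72 cpd, 1300 mm
  fp <- 1300 * tan(0.01389 * pi / 180) * 11.8
  expect_equal(acuity_sigma_px(v, 11.8, sigma_per_footprint = 1), fp,
               tolerance = 1e-3)
  expect_equal(acuity_sigma_px(v, 11.8, sigma_per_footprint = 0.5), fp / 2,
               tolerance = 1e-3)
  expect_equal(round(fp, 2), 3.72, tolerance = 0.01)
  # sigma scales inversely with acuity at fixed distance
  v10 <- viewer_model(acuity_cpd = 10)
  expect_equal(acuity_sigma_px(v10, 11.8) / acuity_sigma_px(v, 11.8), 7.2,
               tolerance = 1e-6)
  # uniform raster unchanged; mean preserved on structured input
  u <- matrix(0.4, 32, 32)
  expect_equal(acuity_blur(u, v, 11.8), u, tolerance = 1e-12)
  set.seed(5)
  x <- matrix(runif(64 * 64, 0.2, 0.8), 64)
  expect_equal(mean(acuity_blur(x, v, 11.8)), mean(x), tolerance = 1e-6)
  # sub-pixel blur is skipped with a notice
  expect_message(acuity_blur(x, v, px_per_mm = 0.05), "below pixel scale")
})

test_that("RNL filter preserves suprathreshold steps and removes noise", {
  v <- viewer_model()
  u <- matrix(0.5, 16, 16)
  expect_equal(rnl_filter(u, rnl_params(), v), u, tolerance = 1e-12)

  # two-level step, Delta-S ~ 10: side means unchanged, no mixing across
  step <- cbind(matrix(0.25, 64, 32), matrix(0.68, 64, 32))
  out <- rnl_filter(step, rnl_params(), v)
  expect_equal(mean(out[, 1:32]), 0.25, tolerance = 1e-6)
  expect_equal(mean(out[, 33:64]), 0.68, tolerance = 1e-6)
  expect_true(all(abs(out[, 1:32] - 0.25) < 1e-9))
  expect_true(all(abs(out[, 33:64] - 0.68) < 1e-9))

  # sub-threshold noise: variance strictly reduced, range bounds kept
  set.seed(21)
  noisy <- matrix(0.5 * exp(rnorm(64 * 64, 0, 0.02)), 64)
  fo <- rnl_filter(noisy, rnl_params(), v)
  expect_lt(var(as.vector(fo)), var(as.vector(noisy)))
  expect_gte(min(fo), min(noisy) - 1e-12)
  expect_lte(max(fo), max(noisy) + 1e-12)

  # deterministic
  expect_identical(rnl_filter(noisy, rnl_params(), v),
                   rnl_filter(noisy, rnl_params(), v))
})

test_that("RNL filter reconstructs a blurred suprathreshold edge", {
  v <- viewer_model()
  step <- cbind(matrix(0.25, 64, 48), matrix(0.70, 64, 48))
  blurred <- acuity_blur(step, v, 11.8)   # sigma ~ 3.7 px
  out <- rnl_filter(blurred, rnl_params(), v)
  # flank-to-flank contrast across the edge approaches the original step
  lo <- mean(out[, 44]); hi <- mean(out[, 53])
  expect_gt(log(hi / lo), 0.8 * log(0.70 / 0.25))
  # plateaus away from the edge (and from the circular wrap) untouched
  expect_equal(mean(out[, 25:35]), 0.25, tolerance = 5e-3)
  expect_equal(mean(out[, 61:71]), 0.70, tolerance = 5e-3)
})

test_that("colour path keeps chromatic boundaries unmixed", {
  v <- viewer_model()
  # equal luminance, strongly different shortwave channel
  lw <- cbind(matrix(0.3, 32, 16), matrix(0.5, 32, 16))
  mw <- cbind(matrix(0.5, 32, 16), matrix(0.3, 32, 16))
  sw <- cbind(matrix(0.1, 32, 16), matrix(0.9, 32, 16))
  cc <- structure(list(lw = lw, mw = mw, sw = sw, lum = (lw + mw) / 2),
                  class = "cone_catch")
  out <- rnl_filter(cc, rnl_params(), v)
  expect_true(all(abs(out$sw[, 1:16] - 0.1) < 1e-9))
  expect_true(all(abs(out$sw[, 17:32] - 0.9) < 1e-9))
})
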