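# Mean luminance comparison: region means as exact mixtures, the transition
# optimum, and the analytic coverage fraction.

test_that("appendage-region mean is exactly affine in pixel coverage", {
  for (n in c(0L, 16L, 48L)) {
    sp <- small_spec(appendage_count = n)
    img <- render_object_scene(sp)
    side <- nrow(img)
    rs <- mlc_regions(disc_mask(side, 60), disc_mask(side, 80))
    m <- region_means(img, rs)
    alpha <- mean(img[rs$appendage_region] == 0.70)
    expect_equal(m$mean_appendage, alpha * 0.70 + (1 - alpha) * 0.25,
                 tolerance = 1e-12)
    expect_equal(m$mean_object, 0.70)
    expect_equal(m$mean_background, 0.25)
    if (n == 0L) expect_false(m$is_intermediate)
    else expect_true(m$is_intermediate)
  }
})

test_that("half coverage reaches the transition optimum exactly", {
  side <- 200
  outline <- disc_mask(side, 40); feather <- disc_mask(side, 60)
  rs <- mlc_regions(outline, feather)
  img <- matrix(0.25, side, side)
  img[outline] <- 0.70
  # cover the right angular half of the annulus
  right <- col(img) > (side + 1) / 2
  img[rs$appendage_region & right] <- 0.70
  alpha <- mean(img[rs$appendage_region] == 0.70)
  m <- region_means(img, rs)
  expect_equal(m$midpoint, (0.70 + 0.25) / 2)
  expect_equal(m$transition_score, abs(alpha - 0.5) * (0.70 - 0.25),
               tolerance = 1e-12)
  expect_lt(m$transition_score, 0.005)          # alpha ~ 0.5 by construction
  # swapping the object/background labels leaves the score unchanged
  swapped <- region_means(0.95 - img, rs)       # invert the two grey levels
  expect_equal(swapped$transition_score, m$transition_score, tolerance = 1e-9)
  expect_error(region_means(img, structure(list(object_region = outline & FALSE,
                                                appendage_region = rs$appendage_region,
                                                background_region = rs$background_region),
                                           class = "roi_set")), "empty")
})

test_that("analytic coverage follows the line-area law", {
  annulus_area <- pi * (588^2 - 470^2)
  expect_equal(coverage_fraction(scenario_spec(appendage_count = 256)),
               256 * 4 * 118 / annulus_area, tolerance = 1e-12)
  expect_equal(coverage_fraction(scenario_spec(appendage_count = "full")), 1)
  # transparency halves the effective coverage; doubling the count restores it
  c_half <- coverage_fraction(scenario_spec(appendage_count = 100,
                                            transparency = 0.5))
  expect_equal(c_half,
               0.5 * coverage_fraction(scenario_spec(appendage_count = 100)),
               tolerance = 1e-12)
  expect_equal(coverage_fraction(scenario_spec(appendage_count = 200,
                                               transparency = 0.5)),
               coverage_fraction(scenario_spec(appendage_count = 100)),
               tolerance = 1e-12)
  # length heterogeneity reduces the covered area proportionally
  c3 <- coverage_fraction(scenario_spec(appendage_count = 100,
                                        length_profile = list(c(0.5, 1),
                                                              c(0.5, 0.5))))
  expect_equal(c3, 0.75 * coverage_fraction(scenario_spec(appendage_count = 100)),
               tolerance = 1e-12)
})

test_that("half coverage is reached between 256 and 512 appendages", {
  count_at_half <- 0.5 * pi * (588^2 - 470^2) / (4 * 118)
  expect_gt(count_at_half, 256)
  expect_lt(count_at_half, 512)
  expect_equal(ceiling(count_at_half), 416)
  # and the analytic law inverts consistently
  expect_equal(coverage_fraction(scenario_spec(appendage_count = 416)), 0.5,
               tolerance = 0.01)
})

test_that("rendered wedge coverage exceeds the nominal line area as documented", {
  sp <- small_spec(appendage_count = 24)
  img <- render_object_scene(sp)
  co <- fringecam:::scene_coords(nrow(img))
  rendered <- mean(img[co$r > 60 & co$r <= 80] == 0.70)
  widen <- (60 + 80) / (2 * 60)                # (r_in + r_out) / (2 r_in)
  expect_equal(rendered, widen * coverage_fraction(sp), tolerance = 0.05)
})
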