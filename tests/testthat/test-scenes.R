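# Procedural scene rendering: geometry, compositing, scenario grids and
# determinism.

test_that("zero-appendage scene is two-tone with correct disc geometry", {
  sp <- scenario_spec(appendage_count = 0)
  img <- render_object_scene(sp)
  expect_setequal(unique(as.vector(img)), c(0.25, 0.70))
  side <- nrow(img)
  expect_equal(side, 2 * (470 + 118 + 200))
  # disc area within 1% of pi r^2; all object pixels within the radius
  co <- fringecam:::scene_coords(side)
  obj <- img == 0.70
  expect_equal(sum(obj), pi * 470^2, tolerance = 0.01)
  expect_lte(max(co$r[obj]), 470)
  # printed circumference consistent with the radius
  expect_equal(2 * pi * 470, 2950, tolerance = 0.005)
})

test_that("full-circle appendages fill the annulus completely", {
  sp <- scenario_spec(appendage_count = "full")
  expect_equal(resolve_appendage_count(sp), floor(2950 / 4))
  img <- render_object_scene(sp)
  co <- fringecam:::scene_coords(nrow(img))
  ann <- co$r > 470 & co$r <= 588
  expect_true(all(img[ann] == 0.70))
  # thicker appendages pack fewer
  expect_equal(resolve_appendage_count(scenario_spec(appendage_count = "full",
                                                     appendage_thickness_px = 8)),
               floor(2950 / 8))
})

# count contiguous covered arcs around a circular ring (merging the wrap)
count_arcs <- function(covered) {
  start <- which(!covered)[1]
  if (is.na(start)) return(1L)
  rot <- c(covered[start:length(covered)], covered[seq_len(start - 1)])
  sum(rle(rot)$values)
}

test_that("appendages are equally spaced radial wedges", {
  sp <- scenario_spec(appendage_count = 32)
  img <- render_object_scene(sp)
  co <- fringecam:::scene_coords(nrow(img))
  # sample a ring inside the appendage zone and count covered arcs
  ring <- which(co$r > 520 & co$r <= 522)
  ang <- sort(atan2(co$y[ring], co$x[ring]) %% (2 * pi))
  covered <- img[ring][order(atan2(co$y[ring], co$x[ring]) %% (2 * pi))] == 0.70
  expect_equal(count_arcs(covered), 32)         # 32 arcs = 11.25 deg spacing
  # wedge width: covered arc fraction = count * thickness / (2 pi r_in)
  expect_equal(mean(covered), 32 * 4 / 2950, tolerance = 0.05)
})

test_that("alpha compositing of transparent appendages is exact", {
  sp <- scenario_spec(appendage_count = 64, transparency = 0.5)
  img <- render_object_scene(sp)
  vals <- sort(unique(as.vector(img)))
  expect_equal(vals, c(0.25, 0.5 * 0.70 + 0.5 * 0.25, 0.70), tolerance = 1e-12)
  # uniform-background histogram support is exactly the predicted three levels
  sp2 <- scenario_spec(appendage_count = 128, transparency = 0.25)
  expect_length(unique(as.vector(render_object_scene(sp2))), 3)
})

test_that("length profiles interleave deterministically around the circle", {
  sp <- scenario_spec(appendage_count = 64,
                      length_profile = list(c(0.5, 1), c(0.5, 0.5)))
  img <- render_object_scene(sp)
  co <- fringecam:::scene_coords(nrow(img))
  # beyond the short-appendage tip radius only every other appendage remains
  ring <- which(co$r > 560 & co$r <= 562)
  covered <- img[ring][order(atan2(co$y[ring], co$x[ring]) %% (2 * pi))] == 0.70
  expect_equal(count_arcs(covered), 32)
  ring2 <- which(co$r > 500 & co$r <= 502)
  covered2 <- img[ring2][order(atan2(co$y[ring2], co$x[ring2]) %% (2 * pi))] == 0.70
  expect_equal(count_arcs(covered2), 64)
})

test_that("chessboard backgrounds tile with the stated period", {
  bg <- render_background("chessboard", side = 800, level_a = 0.25,
                          level_b = 0.70, square_px = 346)
  expect_equal(bg[1, 1], 0.25)
  expect_equal(bg[1, 1 + 346], 0.70)
  expect_equal(bg[1, 1 + 692], bg[1, 1])        # period 692 px
  expect_equal(bg[1 + 346, 1 + 346], bg[1, 1])
  u <- render_background("uniform", side = 64, level_a = 0.4)
  expect_equal(var(as.vector(u)), 0)
  # small squares have proportionally more boundaries per unit length
  expect_equal(346 / 86, 4.02, tolerance = 0.01)
})

test_that("scenario grids enumerate the factorial design", {
  basic <- scenario_grid("basic")
  expect_length(basic, 7)
  counts <- vapply(basic, function(s) as.character(s$appendage_count), "")
  expect_equal(counts, c("0", "32", "64", "128", "256", "512", "full"))
  th <- scenario_grid("thickness")
  expect_length(th, 14)
  expect_setequal(unique(vapply(th, `[[`, numeric(1), "appendage_thickness_px")),
                  c(8, 12))
  ac <- scenario_grid("acuity")
  expect_setequal(unique(vapply(ac, `[[`, numeric(1), "acuity_cpd")), c(30, 10))
  bgf <- scenario_grid("background")
  expect_setequal(unique(vapply(bgf, `[[`, numeric(1), "square_px")), c(346, 86))
  expect_error(scenario_grid("unknown"))
  cfg <- grid_as_config(th)
  expect_equal(nrow(cfg), 14)
  expect_true(all(c("scenario_id", "appendage_count", "thickness_px") %in%
                    names(cfg)))
})

test_that("rendering is deterministic and coverage grows with count", {
  sp <- small_spec(appendage_count = 16)
  expect_identical(render_object_scene(sp), render_object_scene(sp))
  cov <- vapply(c(0, 8, 16, 32), function(n) {
    img <- render_object_scene(small_spec(appendage_count = n))
    co <- fringecam:::scene_coords(nrow(img))
    mean(img[co$r > 60 & co$r <= 80] == 0.70)
  }, numeric(1))
  expect_true(all(diff(cov) > 0))
})

test_that("invalid scenarios are rejected", {
  expect_error(scenario_spec(transparency = 1.2))
  expect_error(scenario_spec(object_level = 0.4, background_level = 0.4),
               "differ")
  expect_error(scenario_spec(background = "chessboard"), "square_px")
  expect_error(scenario_spec(length_profile = list(c(0.7, 1), c(0.7, 0.5))),
               "sum")
  expect_error(render_object_scene(scenario_spec(appendage_count = 2000),
                                   strict_capacity = TRUE), "capacity")
})
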