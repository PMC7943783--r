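# Local Edge Intensity Analysis: orientation slices against closed forms and
# a brute-force post-processing oracle.

test_that("uniform luminance yields all-zero slices", {
  lum <- matrix(0.5, 16, 16)
  roi <- matrix(TRUE, 16, 16)
  st <- leia_stack(lum, roi)
  for (s in st$slices) expect_true(all(s == 0))
})

test_that("a vertical two-level step registers only in the horizontal slice", {
  a <- 0.7; b <- 0.25; w <- 0.1
  lum <- cbind(matrix(a, 20, 10), matrix(b, 20, 10))
  roi <- matrix(TRUE, 20, 20)
  st <- leia_stack(lum, roi, weber_lum = w)
  expected <- abs(log(a / b)) / w
  # the two columns straddling the boundary see the full contrast
  expect_equal(st$slices$horizontal[10, 10], expected, tolerance = 1e-12)
  expect_equal(st$slices$horizontal[10, 11], expected, tolerance = 1e-12)
  expect_true(all(st$slices$horizontal[, c(1:8, 13:20)] == 0))
  expect_true(all(st$slices$vertical == 0))
  # border pixels lacking neighbours are zero
  expect_true(all(st$slices$horizontal[, c(1, 20)] == 0))
  # diagonal slices carry the same contrast at the boundary
  expect_equal(st$slices$diagonal_ne[10, 10], expected, tolerance = 1e-12)
})

test_that("a diagonal step separates the two diagonal orientations", {
  n <- 24
  lum <- outer(1:n, 1:n, function(i, j) ifelse(j > i, 0.7, 0.25))
  st <- leia_stack(lum, matrix(TRUE, n, n))
  # the perpendicular diagonal sees the full contrast, the parallel one none
  expect_equal(max(st$slices$diagonal_ne), log(0.7 / 0.25) / 0.1,
               tolerance = 1e-12)
  expect_equal(max(st$slices$diagonal_se), 0)
  # horizontal and vertical both straddle the oblique edge
  expect_gt(max(st$slices$horizontal), 0)
  expect_gt(max(st$slices$vertical), 0)
  # mirrored positions along the edge get equal collapsed maxima
  pp <- postprocess_stack(st)
  expect_equal(pp$collapsed[10, 12], pp$collapsed[12, 14], tolerance = 1e-12)
})

test_that("post-processing follows the log/discard/clamp/parallel-max rules", {
  # one pixel whose four ln Delta-S values are 0.5, 1.2, 0.3, 0
  mk <- function(v) matrix(v, 1, 1)
  st <- structure(list(slices = list(h = mk(exp(0.5)), v = mk(exp(1.2)),
                                     d1 = mk(exp(0.3)), d2 = mk(0)),
                       roi_mask = mk(TRUE)), class = "edge_stack")
  expect_equal(postprocess_stack(st)$collapsed[1, 1], 1.2, tolerance = 1e-12)
  # all sub-JND contrasts clamp to zero
  st2 <- structure(list(slices = list(h = mk(0.5), v = mk(0.9), d1 = mk(0.2),
                                      d2 = mk(0.99)),
                        roi_mask = mk(TRUE)), class = "edge_stack")
  expect_equal(postprocess_stack(st2)$collapsed[1, 1], 0)
  # all-zero positions leave the analysis set
  st3 <- structure(list(slices = list(h = mk(0), v = mk(0), d1 = mk(0),
                                      d2 = mk(0)),
                        roi_mask = mk(TRUE)), class = "edge_stack")
  expect_length(postprocess_stack(st3)$analysis_values, 0)
})

test_that("collapsed map equals a brute-force per-pixel oracle", {
  set.seed(33)
  n <- 32
  slices <- replicate(4, matrix(rexp(n * n), n, n), simplify = FALSE)
  for (s in seq_along(slices)) slices[[s]][sample(n * n, 100)] <- 0
  roi <- matrix(runif(n * n) > 0.2, n, n)
  st <- structure(list(slices = slices, roi_mask = roi), class = "edge_stack")
  pp <- postprocess_stack(st)
  # independent per-pixel loop
  oracle <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (!roi[i, j]) next
    post <- vapply(slices, function(s) {
      if (s[i, j] > 0) max(log(s[i, j]), 0) else 0
    }, numeric(1))
    oracle[i, j] <- max(post)
  }
  expect_equal(pp$collapsed, oracle, tolerance = 1e-12)
  # analysis set: in-ROI positions with at least one nonzero slice
  nz <- Reduce(`|`, lapply(slices, function(s) s > 0))
  expect_equal(sum(pp$analysis_mask), sum(roi & nz))
  expect_equal(attr(pp$analysis_values, "n_roi"), sum(roi))
})

test_that("collapsed map is permutation-invariant and monotone in slices", {
  set.seed(34)
  slices <- replicate(4, matrix(rexp(64), 8, 8), simplify = FALSE)
  roi <- matrix(TRUE, 8, 8)
  st <- structure(list(slices = slices, roi_mask = roi), class = "edge_stack")
  stp <- structure(list(slices = slices[c(3, 1, 4, 2)], roi_mask = roi),
                   class = "edge_stack")
  expect_equal(postprocess_stack(st)$collapsed, postprocess_stack(stp)$collapsed)
  # pointwise increase of one slice never decreases the collapsed map
  slices2 <- slices; slices2[[2]] <- slices2[[2]] * 1.5
  st2 <- structure(list(slices = slices2, roi_mask = roi), class = "edge_stack")
  expect_true(all(postprocess_stack(st2)$collapsed -
                    postprocess_stack(st)$collapsed >= -1e-12))
})

test_that("degenerate inputs are rejected", {
  expect_error(leia_stack(matrix(1, 4, 4), matrix(FALSE, 4, 4)), "empty")
  lum <- matrix(1, 4, 4); lum[2, 2] <- 0
  expect_error(leia_stack(lum, matrix(TRUE, 4, 4)), "positive")
})
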