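# Local Edge Intensity Analysis: per-pixel, per-orientation luminance Delta-S
# maps and the post-processing that collapses the four orientation slices into
# one edge-intensity value per pixel.

#' Local Edge Intensity Analysis stack
#'
#' For every pixel inside the region of interest and each of four
#' orientations (horizontal, vertical and the two diagonals), measures the
#' luminance Delta-S between the two pixels straddling the focal position at
#' offset `offset_px` along that orientation. Border pixels lacking a
#' neighbour, and all positions outside the ROI, are set to exactly 0 (the
#' zero value is the out-of-analysis marker used downstream).
#'
#' @param lum strictly positive luminance matrix (observer space, i.e. after
#'   acuity blur and RNL filtering).
#' @param roi logical region-of-interest mask.
#' @param weber_lum luminance Weber fraction (default 0.1).
#' @param offset_px neighbour offset in px (default 1, the finest local
#'   scale).
#' @return an object of class `edge_stack`: list with `slices` (named list of
#'   four Delta-S matrices) and `roi_mask`.
#' @export
leia_stack <- function(lum, roi, weber_lum = 0.1, offset_px = 1L) {
  roi <- roi > 0
  if (!any(roi)) stop("empty region of interest")
  if (any(lum[roi] <= 0)) stop("luminance must be strictly positive inside the ROI")
  nr <- nrow(lum); nc <- ncol(lum)
  o <- as.integer(offset_px)
  L <- log(pmax(lum, .Machine$double.xmin))
  shift_diff <- function(di, dj) {
    # |L(i+di, j+dj) - L(i-di, j-dj)| / w at valid interior positions
    out <- matrix(0, nr, nc)
    ri <- (1 + abs(di)):(nr - abs(di)); cj <- (1 + abs(dj)):(nc - abs(dj))
    out[ri, cj] <- abs(L[ri + di, cj + dj, drop = FALSE] -
                       L[ri - di, cj - dj, drop = FALSE]) / weber_lum
    out[!roi] <- 0
    out
  }
  slices <- list(horizontal = shift_diff(0L, o),
                 vertical   = shift_diff(o, 0L),
                 diagonal_ne = shift_diff(-o, o),
                 diagonal_se = shift_diff(o, o))
  structure(list(slices = slices, roi_mask = roi, weber_lum = weber_lum,
                 offset_px = o),
            class = "edge_stack")
}

#' Collapse an edge stack into per-pixel edge intensities
#'
#' Post-processing pipeline: (1) natural-log transform each Delta-S slice;
#' (2) discard exact zeros, the out-of-analysis marker (positions where all
#' four raw slices are exactly 0 leave the analysis set); (3) clamp negative
#' log values -- artefacts of edge-free areas -- to 0; (4) take the parallel
#' maximum of the four slices at each position.
#'
#' @param stack an [leia_stack()] result.
#' @return the stack with added elements `collapsed` (matrix of per-pixel
#'   maxima, 0 outside the ROI), `analysis_mask` (logical: retained in-ROI
#'   positions) and `analysis_values` (collapsed values at retained
#'   positions).
#' @export
postprocess_stack <- function(stack) {
  stopifnot(inherits(stack, "edge_stack"))
  post <- lapply(stack$slices, function(s) {
    out <- matrix(0, nrow(s), ncol(s))
    pos <- s > 0
    out[pos] <- pmax(log(s[pos]), 0)
    out
  })
  collapsed <- Reduce(pmax, post)
  collapsed[!stack$roi_mask] <- 0
  nonzero <- Reduce(`|`, lapply(stack$slices, function(s) s > 0))
  analysis_mask <- stack$roi_mask & nonzero
  stack$post_slices <- post
  stack$collapsed <- collapsed
  stack$analysis_mask <- analysis_mask
  vals <- collapsed[analysis_mask]
  attr(vals, "n_roi") <- sum(stack$roi_mask)
  stack$analysis_values <- vals
  stack
}

#' Edge-intensity analysis set of an image
#'
#' Convenience wrapper: [leia_stack()] followed by [postprocess_stack()],
#' returning the retained collapsed values.
#'
#' @inheritParams leia_stack
#' @return numeric vector of collapsed log edge intensities.
#' @export
leia_analysis_values <- function(lum, roi, weber_lum = 0.1, offset_px = 1L) {
  postprocess_stack(leia_stack(lum, roi, weber_lum, offset_px))$analysis_values
}
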