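# Regions of interest: the contour band straddling the appendage zone, the
# enlarged rectangular ROI, the three luminance-comparison regions, and
# shadow exclusion. Masks are logical matrices; morphology uses disc
# structuring elements (radial pads, matching the annular geometry).

#' Filled disc mask
#' @param side canvas side in px.
#' @param radius disc radius in px.
#' @return logical `side x side` matrix (pixel centres within `radius`).
#' @export
disc_mask <- function(side, radius) {
  co <- scene_coords(side)
  co$r <= radius
}

#' Filled ellipse mask
#' @param side canvas side in px.
#' @param a,b semi-axes in px (x and y).
#' @param cx,cy centre (defaults to the canvas centre).
#' @return logical matrix.
#' @export
ellipse_mask <- function(side, a, b, cx = (side + 1) / 2, cy = (side + 1) / 2) {
  xs <- matrix(rep(seq_len(side) - cx, each = side), nrow = side)
  ys <- matrix(rep(seq_len(side) - cy, times = side), nrow = side)
  (xs / a)^2 + (ys / b)^2 <= 1
}

disc_brush <- function(pad) EBImage::makeBrush(2L * as.integer(pad) + 1L, "disc")

#' Contour-band region of interest
#'
#' The band runs from the object outline extended `pad_px` towards the object
#' inside to the feather boundary extended `pad_px` towards the outside:
#' `dilate(feather_boundary, pad) \ erode(outline, pad)`. For the
#' proof-of-principle circle (radius 470, feather boundary 588, pad 30) this
#' is the annulus r in \[440, 618\] -- a 178 px wide band.
#'
#' @param outline logical mask of the filled subject region (up to the
#'   outline).
#' @param feather_boundary logical mask of the filled region up to the
#'   appendage/feather tips; must contain `outline`.
#' @param pad_px radial padding in px (default 30).
#' @return logical band mask.
#' @export
contour_band <- function(outline, feather_boundary, pad_px = 30) {
  if (any(outline & !feather_boundary))
    stop("outline mask must lie within the feather-boundary footprint")
  outline <- outline > 0; feather_boundary <- feather_boundary > 0
  if (pad_px == 0) return(feather_boundary & !outline)
  k <- disc_brush(pad_px)
  grown <- EBImage::imageData(EBImage::dilate(feather_boundary * 1, k)) > 0.5
  core <- EBImage::imageData(EBImage::erode(outline * 1, k)) > 0.5
  if (!any(core)) stop("erosion by pad_px emptied the object region")
  grown & !core
}

#' Square region of interest around the object
#'
#' @param side canvas side in px.
#' @param side_px ROI side in px (default 1500).
#' @param cx,cy ROI centre (defaults to the canvas centre).
#' @return logical mask.
#' @export
rect_roi <- function(side, side_px = 1500, cx = (side + 1) / 2,
                     cy = (side + 1) / 2) {
  half <- side_px / 2
  cols <- seq_len(side); rows <- seq_len(side)
  cok <- abs(cols - cx) <= half - 0.5 + 1e-9
  rok <- abs(rows - cy) <= half - 0.5 + 1e-9
  if (sum(cok) < side_px || sum(rok) < side_px)
    stop("rectangle ROI of side ", side_px, " px does not fit the canvas")
  outer(rok, cok, `&`)
}

#' Object / appendage / background regions for the luminance comparison
#'
#' Partitions the canvas: the object region (inside the outline), the
#' appendage region (feather boundary minus outline), and the background
#' (outside the feather boundary).
#'
#' @inheritParams contour_band
#' @return an object of class `roi_set`: list of logical masks
#'   `object_region`, `appendage_region`, `background_region`.
#' @export
mlc_regions <- function(outline, feather_boundary) {
  if (any(outline & !feather_boundary))
    stop("outline mask must lie within the feather-boundary footprint")
  outline <- outline > 0; feather_boundary <- feather_boundary > 0
  structure(list(object_region = outline,
                 appendage_region = feather_boundary & !outline,
                 background_region = !feather_boundary),
            class = "roi_set")
}

#' Remove shadowed pixels from an analysis band
#'
#' @param band logical band mask.
#' @param shadow logical shadow mask (same dimensions).
#' @return list with `mask` (band minus shadow) and `retained_fraction`.
#' @export
apply_shadow_exclusion <- function(band, shadow) {
  stopifnot(identical(dim(band), dim(shadow)))
  band <- band > 0; shadow <- shadow > 0
  kept <- band & !shadow
  frac <- sum(kept) / sum(band)
  if (frac == 0) stop("shadow exclusion removed the entire analysis band")
  list(mask = kept, retained_fraction = frac)
}
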