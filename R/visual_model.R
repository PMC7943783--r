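# Receptor-noise-limited (RNL) achromatic vision model: observer parameters,
# cone-catch conversion, spatial-acuity blurring, Delta-S contrast metrics and
# the iterative edge-preserving RNL filter.

#' Observer model for receptor-noise-limited vision
#'
#' Bundles the receptor noise (Weber fractions) and spatial acuity of a
#' simulated observer. Defaults follow the human achromatic setting used
#' throughout the package: Weber fractions 0.05 (longwave), 0.07071
#' (mediumwave), 0.1657 (shortwave), 0.1 (luminance), acuity 72 cycles per
#' degree viewed from 1300 mm.
#'
#' @param acuity_cpd spatial acuity in cycles per degree. 72 approximates
#'   human foveal vision; 30 a corvid and 10 a canid predator.
#' @param viewing_distance_mm distance between observer and scene, mm.
#' @param weber_lw,weber_mw,weber_sw,weber_lum Weber fractions of the long-,
#'   medium-, shortwave and luminance channels.
#' @param mra_deg minimum resolvable angle in degrees; defaults to
#'   `1/acuity_cpd`.
#' @return an object of class `viewer_model`.
#' @export
viewer_model <- function(acuity_cpd = 72, viewing_distance_mm = 1300,
                         weber_lw = 0.05, weber_mw = 0.07071,
                         weber_sw = 0.1657, weber_lum = 0.1,
                         mra_deg = 1 / acuity_cpd) {
  stopifnot(acuity_cpd > 0, viewing_distance_mm > 0,
            weber_lw > 0, weber_mw > 0, weber_sw > 0, weber_lum > 0)
  if (abs(mra_deg * acuity_cpd - 1) > 1e-4)
    stop("mra_deg must equal 1/acuity_cpd (within 1e-4)")
  structure(list(acuity_cpd = acuity_cpd,
                 viewing_distance_mm = viewing_distance_mm,
                 weber_lw = weber_lw, weber_mw = weber_mw,
                 weber_sw = weber_sw, weber_lum = weber_lum,
                 mra_deg = mra_deg),
            class = "viewer_model")
}

#' Parameters of the edge-preserving RNL filter
#'
#' @param iterations number of smoothing passes (default 5).
#' @param radius_px neighbourhood radius in pixels (default 5).
#' @param falloff_px width of the linear spatial-weight falloff at the rim of
#'   the neighbourhood (default 3).
#' @param threshold_delta_s Delta-S discrimination threshold gating the
#'   smoothing; neighbours at or above it contribute nothing. Default 1.0,
#'   the conventional just-noticeable difference.
#' @param min_cluster_frac minority-cluster criterion of [rnl_filter()]: a
#'   focal pixel whose own sub-threshold cluster carries less than this
#'   fraction of the kernel weight is snapped to the dominant local cluster.
#' @return an object of class `rnl_params`.
#' @export
rnl_params <- function(iterations = 5, radius_px = 5, falloff_px = 3,
                       threshold_delta_s = 1.0, min_cluster_frac = 0.45) {
  stopifnot(iterations >= 0, radius_px >= falloff_px, falloff_px >= 0,
            threshold_delta_s > 0, min_cluster_frac >= 0, min_cluster_frac <= 1)
  structure(list(iterations = as.integer(iterations), radius_px = radius_px,
                 falloff_px = falloff_px, threshold_delta_s = threshold_delta_s,
                 min_cluster_frac = min_cluster_frac),
            class = "rnl_params")
}

# floor used to keep cone catches strictly positive (Delta-S takes logs)
CATCH_FLOOR <- 1 / 65536

#' Convert an image to linear cone catches
#'
#' Produces a cone-catch image: long-, medium- and shortwave channels plus a
#' luminance channel defined as the mean of the long and medium channel (the
#' standard achromatic proxy for human vision). Synthetic scenes are already
#' linear (`gamma_mode = "linear"`); photographs stored with a display
#' nonlinearity are linearised with an inverse 2.2-exponent
#' (`gamma_mode = "srgb"`). Zeros are clamped to a floor of 1/65536 so that
#' the logarithms inside Delta-S are defined.
#'
#' @param img numeric matrix (grayscale) or width x height x 3 array (RGB)
#'   with values in \[0, 1\].
#' @param gamma_mode `"linear"` or `"srgb"`.
#' @return an object of class `cone_catch`: list with matrices `lw`, `mw`,
#'   `sw`, `lum`.
#' @export
to_cone_catch <- function(img, gamma_mode = c("linear", "srgb")) {
  gamma_mode <- match.arg(gamma_mode)
  if (is.list(img) && inherits(img, "cone_catch")) return(img)
  if (min(img) < 0) stop("negative pixel values are not valid reflectances")
  if (max(img) > 1 + 1e-9) stop("pixel values must lie in [0, 1]")
  lin <- function(v) {
    v <- if (gamma_mode == "srgb") v^2.2 else v
    pmax(v, CATCH_FLOOR)
  }
  if (length(dim(img)) == 3) {
    lw <- lin(img[, , 1]); mw <- lin(img[, , 2]); sw <- lin(img[, , 3])
  } else {
    lw <- mw <- sw <- lin(as.matrix(img))
  }
  structure(list(lw = lw, mw = mw, sw = sw, lum = (lw + mw) / 2),
            class = "cone_catch")
}

#' Gaussian blur width implied by an observer's acuity
#'
#' One full cycle at the acuity limit subtends the minimum resolvable angle
#' (MRA); its footprint on the scene is
#' `viewing_distance_mm * tan(mra_deg * pi/180) * px_per_mm` pixels (3.72 px
#' for 72 cpd at 1300 mm and 11.8 px/mm). The blur standard deviation is
#' `sigma_per_footprint` times that footprint; the constant is exposed so the
#' sigma convention can be changed in one place. The default of 1.0 is the
#' convention under which the appendage scenarios reproduce the published
#' detectability ordering (see the methods vignette); with much smaller
#' constants the blur cannot mix appendage and background luminance across
#' realistic appendage spacings.
#'
#' @param viewer a [viewer_model()].
#' @param px_per_mm scene scale, pixels per millimetre.
#' @param sigma_per_footprint sigma as a fraction of the MRA footprint
#'   (default 1.0).
#' @return blur sigma in pixels.
#' @export
acuity_sigma_px <- function(viewer, px_per_mm, sigma_per_footprint = 1.0) {
  stopifnot(px_per_mm > 0)
  footprint <- viewer$viewing_distance_mm * tan(viewer$mra_deg * pi / 180) *
    px_per_mm
  footprint * sigma_per_footprint
}

#' Apply spatial-acuity blur to a raster
#'
#' Gaussian blur with the sigma given by [acuity_sigma_px()]. The convolution
#' uses a circular boundary, so the image mean is preserved exactly. Blurs
#' below 0.3 px are skipped (sub-pixel blur) with a notice.
#'
#' @param img numeric matrix.
#' @inheritParams acuity_sigma_px
#' @return blurred matrix of the same dimensions.
#' @export
acuity_blur <- function(img, viewer, px_per_mm, sigma_per_footprint = 1.0) {
  sigma <- acuity_sigma_px(viewer, px_per_mm, sigma_per_footprint)
  if (sigma < 0.3) {
    message("acuity blur sigma ", signif(sigma, 3),
            " px is below pixel scale; image returned unblurred")
    return(img)
  }
  out <- EBImage::gblur(img, sigma = sigma, boundary = "circular")
  matrix(EBImage::imageData(out), nrow = nrow(img))
}

#' Achromatic (luminance) receptor-noise contrast
#'
#' `Delta-S = |ln(qa/qb)| / weber_lum`. Symmetric, nonnegative and invariant
#' to joint rescaling of both catches. Vectorised.
#'
#' @param qa,qb strictly positive luminance catches.
#' @param weber_lum luminance Weber fraction (default 0.1).
#' @return Delta-S value(s).
#' @export
delta_s_lum <- function(qa, qb, weber_lum = 0.1) {
  if (any(qa <= 0) || any(qb <= 0)) stop("cone catches must be positive")
  abs(log(qa) - log(qb)) / weber_lum
}

#' Chromatic receptor-noise contrast (trichromatic Vorobyev-Osorio form)
#'
#' With `Df_i = ln(qa_i / qb_i)` and channel Weber fractions `e_i`,
#' \deqn{\Delta S^2 = \frac{e_{sw}^2 (Df_{lw}-Df_{mw})^2 +
#'   e_{mw}^2 (Df_{lw}-Df_{sw})^2 + e_{lw}^2 (Df_{mw}-Df_{sw})^2}
#'   {(e_{lw} e_{mw})^2 + (e_{lw} e_{sw})^2 + (e_{mw} e_{sw})^2}}
#' Zero for any pure luminance shift (all channels scaled equally).
#'
#' @param qa,qb length-3 vectors (lw, mw, sw) or lists of three matrices.
#' @param viewer a [viewer_model()] supplying the Weber fractions.
#' @return Delta-S value(s).
#' @export
delta_s_chromatic <- function(qa, qb, viewer = viewer_model()) {
  get3 <- function(q) {
    if (is.list(q)) list(q$lw, q$mw, q$sw) else list(q[1], q[2], q[3])
  }
  a <- get3(qa); b <- get3(qb)
  if (any(unlist(lapply(c(a, b), function(x) any(x <= 0)))))
    stop("cone catches must be positive")
  dl <- log(a[[1]] / b[[1]]); dm <- log(a[[2]] / b[[2]]); ds <- log(a[[3]] / b[[3]])
  el <- viewer$weber_lw; em <- viewer$weber_mw; es <- viewer$weber_sw
  num <- es^2 * (dl - dm)^2 + em^2 * (dl - ds)^2 + el^2 * (dm - ds)^2
  den <- (el * em)^2 + (el * es)^2 + (em * es)^2
  sqrt(num / den)
}

#' Edge-preserving receptor-noise-limited filter
#'
#' Iterative rank-augmented smoothing that removes sub-threshold noise while
#' reconstructing perceptually distinct edges. On each pass a focal pixel is
#' replaced by the spatially weighted mean of its own sub-threshold cluster:
#' the neighbours within `radius_px` whose luminance contrast to it -- and,
#' for colour images, whose chromatic [delta_s_chromatic()] to it -- is below
#' `threshold_delta_s`. Spatial weights are 1 up to `radius_px - falloff_px`
#' and decay linearly to 0 at `radius_px`; neighbours at or above the
#' threshold contribute nothing, so suprathreshold boundaries are never mixed
#' across.
#'
#' The rank augmentation is what makes the filter reconstruct edges rather
#' than merely preserve them: when the focal pixel's own cluster carries less
#' than `min_cluster_frac` of the kernel weight, the pixel is a minority
#' level -- typically a residual ring on the flank of a blurred
#' suprathreshold boundary -- and is snapped to the dominant local cluster
#' (the weighted mean of the neighbours within the threshold of the kernel's
#' weighted median luminance). A blurred step thereby converges back towards
#' a step, while plateaus, thick strokes and broad gradients (whose clusters
#' are majorities) are smoothed as usual.
#'
#' When all three channels are identical (grayscale scenes) the chromatic
#' contrast is identically zero and a single-channel fast path is used.
#'
#' @param img a `cone_catch` image (or plain matrix, treated as luminance).
#' @param params an [rnl_params()].
#' @param viewer a [viewer_model()].
#' @return filtered image of the same class as the input.
#' @export
rnl_filter <- function(img, params = rnl_params(), viewer = viewer_model()) {
  plain <- is.matrix(img)
  cc <- if (plain) to_cone_catch(img) else img
  gray <- identical(cc$lw, cc$mw) && identical(cc$lw, cc$sw)
  frac <- params$min_cluster_frac %||% 0.45
  if (gray) {
    lum <- rnl_filter_lum_cpp(cc$lum, params$iterations, params$radius_px,
                              params$falloff_px, params$threshold_delta_s,
                              viewer$weber_lum, frac)
    if (plain) return(lum)
    return(structure(list(lw = lum, mw = lum, sw = lum, lum = lum),
                     class = "cone_catch"))
  }
  ch <- rnl_filter_cpp(cc$lw, cc$mw, cc$sw, params$iterations,
                       params$radius_px, params$falloff_px,
                       params$threshold_delta_s, viewer$weber_lum,
                       viewer$weber_lw, viewer$weber_mw, viewer$weber_sw,
                       frac)
  out <- structure(list(lw = ch[[1]], mw = ch[[2]], sw = ch[[3]],
                        lum = (ch[[1]] + ch[[2]]) / 2),
                   class = "cone_catch")
  if (plain) out$lum else out
}
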