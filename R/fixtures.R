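# Seeded synthetic stand-ins for the paired-photograph experiment: a textured
# oval subject on a mottled background, rendered with and without a fringe of
# thin protruding strokes, plus outline / feather-boundary / shadow masks.
# These fixtures emulate the structure of the cropping protocol (same subject
# inserted into the same hiding spot twice); they are synthetic, not derived
# from any photograph.

with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# band-limited random field quantized into discrete luminance patches
mottle_field <- function(side, sigma, levels) {
  z <- matrix(stats::rnorm(side * side), side, side)
  z <- matrix(EBImage::imageData(EBImage::gblur(z, sigma = sigma,
                                                boundary = "circular")),
              nrow = side)
  qs <- stats::quantile(z, probs = seq_len(length(levels) - 1) / length(levels))
  idx <- findInterval(z, qs) + 1L
  matrix(levels[idx], side, side)
}

#' Generate a synthetic paired with/without-fringe scene
#'
#' Builds one subject fixture: a mottled background (band-limited noise
#' quantized into luminance patches), a textured oval subject, a fringe of
#' thin strokes of heterogeneous length protruding beyond the outline
#' (with-fringe image only), a reference image of the subject cropped onto a
#' uniform dark background, and outline / feather-boundary / shadow masks.
#' The with- and without-fringe images differ only in fringe pixels, and the
#' same seed always yields a byte-identical fixture.
#'
#' @param seed integer seed for the subject, background and shadow placement.
#' @param fringe_effect nonnegative knob scaling the density of fringe
#'   strokes; 0 renders no strokes (with- and without-fringe images are then
#'   identical). The default of 1 gives a fringe interrupting roughly a
#'   third of the outline, comparable to a downy chick.
#' @param shadow_fraction fraction of the contour band covered by the
#'   contiguous shadow arc, in \[0, 1).
#' @param side canvas side in px.
#' @param fringe_seed separate seed for the fringe stroke realisation
#'   (defaults to `seed`); used by the null-calibration mode, where two
#'   independent fringe realisations of the same subject are compared.
#' @param band_pad contour-band padding in px used for the shadow placement
#'   (and recorded for downstream analysis).
#' @param black_level luminance of the uniform reference background (a
#'   photographic black, default 0.02).
#' @param subject_levels,background_levels luminance levels of the quantized
#'   texture patches. The defaults keep the subject clearly lighter than the
#'   mottled ground so the outline is suprathreshold along its whole length,
#'   as for a downy chick against damp substrate.
#' @param stroke_px fringe stroke thickness in px (about 2 px: thin relative
#'   to the subject, but wide enough to survive the acuity blur).
#' @return an object of class `scene_fixture`: rasters `background_image`,
#'   `subject_with_fringe`, `subject_without_fringe`, `reference_image`;
#'   logical masks `outline_mask`, `feather_boundary_mask`, `shadow_mask`;
#'   plus the generation parameters.
#' @export
synth_chick_scene <- function(seed, fringe_effect = 1, shadow_fraction = 0.28,
                              side = 160, fringe_seed = seed, band_pad = 10,
                              black_level = 0.02,
                              subject_levels = c(0.55, 0.70, 0.85),
                              background_levels = c(0.10, 0.22, 0.38),
                              stroke_px = 2) {
  stopifnot(fringe_effect >= 0, shadow_fraction >= 0, shadow_fraction < 1,
            side >= 64)
  a <- 0.28 * side; b <- 0.21 * side
  fringe_len <- 0.12 * side
  ctr <- (side + 1) / 2

  outline <- ellipse_mask(side, a, b)
  feather <- ellipse_mask(side, a + fringe_len, b + fringe_len)

  base <- with_seed(seed, {
    bg <- mottle_field(side, sigma = side / 26, levels = background_levels)
    subj <- mottle_field(side, sigma = side / 40, levels = subject_levels)
    theta0 <- stats::runif(1, 0, 2 * pi)
    list(bg = bg, subj = subj, theta0 = theta0)
  })

  without <- base$bg
  without[outline] <- base$subj[outline]

  # fringe strokes: radial paths from the outline outward, heterogeneous
  # length, coloured like the adjacent plumage and increasingly translucent
  # towards the tip (downy tips are wispy, so their effective contrast fades)
  with_img <- without
  n_strokes <- round(fringe_effect * 0.18 *
                       pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b))))
  if (n_strokes > 0) {
    strokes <- with_seed(fringe_seed, {
      # roughly even angular placement with jitter, like natural down
      t_ang <- (seq_len(n_strokes) - 1 +
                  stats::runif(n_strokes, -0.35, 0.35)) * 2 * pi / n_strokes
      lens <- stats::runif(n_strokes, 0.6, 1) * fringe_len
      idx <- integer(0); cols <- numeric(0); alph <- numeric(0)
      for (k in seq_len(n_strokes)) {
        px <- a * cos(t_ang[k]); py <- b * sin(t_ang[k])
        nv <- c(cos(t_ang[k]) / a, sin(t_ang[k]) / b)
        nv <- nv / sqrt(sum(nv^2))
        colr <- base$subj[round(ctr + 0.9 * py), round(ctr + 0.9 * px)]
        s <- seq(0, lens[k], by = 0.4)
        al <- 1.0 - 0.75 * s / fringe_len
        ii0 <- round(ctr + py + s * nv[2]); jj0 <- round(ctr + px + s * nv[1])
        # thicken the stroke to stroke_px with a small pixel block
        grow <- seq_len(max(1L, round(stroke_px))) - 1L
        g2 <- length(grow)^2
        ii <- rep(ii0, each = g2) +
          rep(rep(grow, each = length(grow)), length(ii0))
        jj <- rep(jj0, each = g2) +
          rep(rep(grow, times = length(grow)), length(jj0))
        aa <- rep(al, each = g2)
        ok <- ii >= 1 & ii <= side & jj >= 1 & jj <= side
        lin <- ii[ok] + (jj[ok] - 1L) * side
        aa <- aa[ok]
        first <- !duplicated(lin)
        lin <- lin[first]; aa <- aa[first]
        keep2 <- !outline[lin]            # protruding part only
        idx <- c(idx, lin[keep2])
        cols <- c(cols, rep(colr, sum(keep2)))
        alph <- c(alph, aa[keep2])
      }
      list(idx = idx, cols = cols, alph = alph)
    })
    keep <- !duplicated(strokes$idx)
    li <- strokes$idx[keep]; al <- strokes$alph[keep]
    with_img[li] <- al * strokes$cols[keep] + (1 - al) * with_img[li]
  }

  reference <- matrix(black_level, side, side)
  reference[outline] <- base$subj[outline]

  band <- contour_band(outline, feather, pad_px = band_pad)
  shadow <- matrix(FALSE, side, side)
  if (shadow_fraction > 0) {
    co <- scene_coords(side)
    bidx <- which(band)
    ang <- (atan2(co$y[bidx], co$x[bidx]) - base$theta0) %% (2 * pi)
    k <- round(shadow_fraction * length(bidx))
    shadow[bidx[order(ang)[seq_len(k)]]] <- TRUE
  }

  structure(list(seed = seed, fringe_seed = fringe_seed,
                 fringe_effect = fringe_effect,
                 shadow_fraction = shadow_fraction,
                 side = side, band_pad = band_pad,
                 px_per_mm = 11.8, black_level = black_level,
                 background_image = base$bg,
                 subject_with_fringe = with_img,
                 subject_without_fringe = without,
                 reference_image = reference,
                 outline_mask = outline,
                 feather_boundary_mask = feather,
                 shadow_mask = shadow),
            class = "scene_fixture")
}
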