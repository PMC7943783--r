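# Mean Luminance Comparison: does the appendage region form a luminance
# transition zone between object and background?

#' Region mean luminances and the transition-zone score
#'
#' Means over the object, appendage and background regions; the appendage
#' region conceals the outline best when its mean sits at the midpoint
#' between object and background (`transition_score` = distance from the
#' midpoint; `is_intermediate` = strictly between the two).
#'
#' @param lum luminance matrix (by convention the observer-space image, i.e.
#'   after acuity blur and RNL filtering; the stage is the caller's choice).
#' @param regions an [mlc_regions()] result.
#' @return an object of class `mlc_result`.
#' @export
region_means <- function(lum, regions) {
  stopifnot(inherits(regions, "roi_set"))
  for (nm in c("object_region", "appendage_region", "background_region"))
    if (!any(regions[[nm]])) stop("empty region: ", nm)
  mo <- mean(lum[regions$object_region])
  ma <- mean(lum[regions$appendage_region])
  mb <- mean(lum[regions$background_region])
  midpoint <- (mo + mb) / 2
  structure(list(mean_object = mo, mean_appendage = ma, mean_background = mb,
                 midpoint = midpoint,
                 transition_score = abs(ma - midpoint),
                 is_intermediate = (ma > min(mo, mb)) && (ma < max(mo, mb))),
            class = "mlc_result")
}

#' Nominal appendage coverage of the appendage annulus
#'
#' Analytic line-area fraction
#' `count * thickness * length_eff / annulus_area`, capped at 1, where
#' `length_eff` averages the length profile and transparency scales the
#' effective coverage by `1 - transparency`. Solving coverage = 0.5 for the
#' basic geometry gives about 416 appendages. Rendered wedge coverage exceeds
#' this nominal value by the factor `(r_in + r_out) / (2 r_in)` (about 1.13
#' for the default geometry) because wedges widen with radius; at the
#' `"full"` stage the annulus is completely filled and the coverage is 1 by
#' construction.
#'
#' @param spec a [scenario_spec()].
#' @return fraction in \[0, 1\].
#' @export
coverage_fraction <- function(spec) {
  if (identical(spec$appendage_count, "full"))
    return(1 * (1 - spec$transparency))
  n <- resolve_appendage_count(spec)
  fr <- vapply(spec$length_profile, `[`, numeric(1), 1)
  lf <- vapply(spec$length_profile, `[`, numeric(1), 2)
  if (sum(fr) < 1 - 1e-9) { fr <- c(fr, 1 - sum(fr)); lf <- c(lf, 1) }
  len_eff <- spec$appendage_length_px * sum(fr * lf)
  r_in <- spec$object_radius_px
  r_out <- r_in + spec$appendage_length_px
  area <- pi * (r_out^2 - r_in^2)
  cov <- n * spec$appendage_thickness_px * len_eff / area
  min(cov, 1) * (1 - spec$transparency)
}
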