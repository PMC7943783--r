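# End-to-end orchestration of the two experiments: scene/fixture -> vision
# model -> LEIA -> ROI -> HEI / MLC statistics.

#' Observer-space luminance image
#'
#' The shared vision-model chain: cone-catch conversion, spatial-acuity blur,
#' edge-preserving RNL filter. Returns the filtered luminance matrix.
#'
#' @param img matrix/array in \[0, 1\] or a `cone_catch` image.
#' @param viewer a [viewer_model()].
#' @param px_per_mm scene scale in px/mm.
#' @param rnl an [rnl_params()].
#' @param gamma_mode passed to [to_cone_catch()].
#' @return luminance matrix.
#' @export
observer_lum <- function(img, viewer = viewer_model(), px_per_mm = 11.8,
                         rnl = rnl_params(), gamma_mode = "linear") {
  cc <- to_cone_catch(img, gamma_mode)
  lum <- acuity_blur(cc$lum, viewer, px_per_mm)
  rnl_filter(lum, rnl, viewer)
}

#' Process one artificial-object scene
#'
#' Renders the scene, applies the vision model at the scenario's acuity, and
#' runs LEIA on the requested region of interest.
#'
#' @param spec a [scenario_spec()].
#' @param viewer base [viewer_model()]; its acuity is replaced by
#'   `spec$acuity_cpd`.
#' @param rnl an [rnl_params()].
#' @param roi `"band"` (contour band) or `"rect"` (1500 px square).
#' @param pad_px contour-band padding.
#' @param rect_side_px side of the rectangular ROI.
#' @param masks optional precomputed mask set (from [exp1_masks()]) to avoid
#'   recomputing the morphology for every scene of the same geometry.
#' @return list with `analysis_values`, `lum` (filtered), `masks`, `sigma_px`.
#' @export
process_scene <- function(spec, viewer = viewer_model(), rnl = rnl_params(),
                          roi = c("band", "rect"), pad_px = 30,
                          rect_side_px = 1500, masks = NULL) {
  roi <- match.arg(roi)
  v <- viewer_model(acuity_cpd = spec$acuity_cpd,
                    viewing_distance_mm = viewer$viewing_distance_mm,
                    weber_lw = viewer$weber_lw, weber_mw = viewer$weber_mw,
                    weber_sw = viewer$weber_sw, weber_lum = viewer$weber_lum)
  img <- render_object_scene(spec)
  if (is.null(masks)) masks <- exp1_masks(spec, pad_px, rect_side_px)
  lum <- observer_lum(img, v, spec$px_per_mm, rnl)
  roi_mask <- if (roi == "band") masks$band else masks$rect
  if (is.null(roi_mask))
    stop("rectangular ROI does not fit this scene's canvas")
  vals <- leia_analysis_values(lum, roi_mask, v$weber_lum)
  list(analysis_values = vals, lum = lum, masks = masks,
       sigma_px = acuity_sigma_px(v, spec$px_per_mm))
}

#' Masks shared by all scenes of one artificial-object geometry
#'
#' @param spec a [scenario_spec()] (geometry fields only are used).
#' @param pad_px contour-band padding.
#' @param rect_side_px side of the rectangular ROI.
#' @return list with `outline`, `feather`, `band`, `rect`, `regions`.
#' @export
exp1_masks <- function(spec, pad_px = 30, rect_side_px = 1500) {
  side <- canvas_side(spec)
  outline <- disc_mask(side, spec$object_radius_px)
  feather <- disc_mask(side, spec$object_radius_px + spec$appendage_length_px)
  rect <- if (side >= rect_side_px) rect_roi(side, rect_side_px) else NULL
  list(outline = outline, feather = feather,
       band = contour_band(outline, feather, pad_px),
       rect = rect,
       regions = mlc_regions(outline, feather))
}

#' Run the proof-of-principle experiment
#'
#' Renders every scenario of the requested families, applies the vision model
#' and LEIA, determines the HEI fraction `q` once from the zero-appendage
#' basic reference (reused for every image), and reports per-image mean HEI
#' and mean-luminance-comparison statistics plus the per-family argmin
#' summary. Fully deterministic.
#'
#' @param families character vector of [scenario_grid()] families.
#' @param viewer base [viewer_model()].
#' @param rnl an [rnl_params()].
#' @param roi `"band"` or `"rect"`.
#' @param pad_px contour-band padding in px.
#' @param mlc_stage `"filtered"` (observer-space image, default) or `"raw"`
#'   (rendered image) for the luminance comparison.
#' @param counts optional subset of count stages to run (e.g.
#'   `list(0, 256)`); default all seven.
#' @param spec_overrides named list of [scenario_spec()] overrides applied to
#'   every scenario (and the reference).
#' @param verbose print progress to stderr.
#' @return list of class `exp1_result`: `results` (data.frame, one row per
#'   image), `argmin` (per family x level), `q`, `hei_reference`, `roi`.
#' @export
run_experiment1 <- function(families = c("basic", "thickness", "transparency",
                                         "length", "background", "acuity"),
                            viewer = viewer_model(), rnl = rnl_params(),
                            roi = c("band", "rect"), pad_px = 30,
                            mlc_stage = c("filtered", "raw"),
                            counts = NULL, spec_overrides = list(),
                            verbose = FALSE) {
  roi <- match.arg(roi); mlc_stage <- match.arg(mlc_stage)
  say <- function(...) if (verbose) message(...)

  ref_spec <- do.call(scenario_spec, c(list(appendage_count = 0,
                                            scenario_id = "basic_reference"),
                                       spec_overrides))
  masks <- exp1_masks(ref_spec, pad_px)
  say("reference: zero-appendage basic scene")
  ref <- process_scene(ref_spec, viewer, rnl, roi, pad_px, masks = masks)
  hei_ref <- hei_threshold_from_reference(ref$analysis_values,
                                          mode = "fraction")
  say(sprintf("  q = %.4f (%.2f%% of %d pixels above antimode %.3f)",
              hei_ref$q, 100 * hei_ref$q, hei_ref$n_total,
              hei_ref$threshold_value))

  grids <- unlist(lapply(families, scenario_grid), recursive = FALSE)
  if (length(spec_overrides))
    grids <- lapply(grids, function(sp) {
      at <- attributes(sp)
      sp2 <- do.call(scenario_spec,
                     utils::modifyList(unclass(sp)[setdiff(names(unclass(sp)),
                                                           "scenario_id")],
                                       c(spec_overrides,
                                         list(scenario_id = sp$scenario_id))))
      attr(sp2, "family") <- at$family; attr(sp2, "level") <- at$level
      sp2
    })
  if (!is.null(counts))
    grids <- Filter(function(sp) {
      any(vapply(counts, identical, logical(1), sp$appendage_count))
    }, grids)

  rows <- lapply(grids, function(sp) {
    say("scenario ", sp$scenario_id)
    res <- tryCatch({
      pr <- process_scene(sp, viewer, rnl, roi, pad_px, masks = masks)
      h <- mean_hei(pr$analysis_values, hei_ref)
      mlc_img <- if (mlc_stage == "filtered") pr$lum else render_object_scene(sp)
      m <- region_means(mlc_img, masks$regions)
      data.frame(scenario_id = sp$scenario_id,
                 family = attr(sp, "family") %||% "basic",
                 level = attr(sp, "level") %||% "basic",
                 count_stage = as.character(sp$appendage_count),
                 count = resolve_appendage_count(sp),
                 acuity_cpd = sp$acuity_cpd,
                 q = hei_ref$q,
                 mean_hei = h$mean_hei,
                 n_hei = h$n_pixels,
                 n_analysis = h$n_total,
                 mean_object = m$mean_object,
                 mean_appendage = m$mean_appendage,
                 mean_background = m$mean_background,
                 transition_score = m$transition_score,
                 is_intermediate = m$is_intermediate,
                 coverage = coverage_fraction(sp),
                 sigma_px = pr$sigma_px,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      warning("scenario ", sp$scenario_id, " failed: ", conditionMessage(e))
      NULL
    })
    res
  })
  results <- do.call(rbind, rows)
  structure(c(scenario_curve(results),
              list(results = results, q = hei_ref$q, hei_reference = hei_ref,
                   roi = roi, pad_px = pad_px, mlc_stage = mlc_stage)),
            class = "exp1_result")
}

# shared per-subject processing for the paired experiment
exp2_process_subject <- function(fix, viewer, rnl, hei_mode, pad_px = NULL) {
  pad <- pad_px %||% fix$band_pad
  band <- contour_band(fix$outline_mask, fix$feather_boundary_mask, pad)
  shaded <- apply_shadow_exclusion(band, fix$shadow_mask)

  ref_lum <- observer_lum(fix$reference_image, viewer, fix$px_per_mm, rnl)
  ref_vals <- leia_analysis_values(ref_lum, band, viewer$weber_lum)
  hei <- hei_threshold_from_reference(ref_vals, mode = hei_mode)

  score <- function(img) {
    lum <- observer_lum(img, viewer, fix$px_per_mm, rnl)
    vals <- leia_analysis_values(lum, shaded$mask, viewer$weber_lum)
    mean_hei(vals, hei)
  }
  hw <- score(fix$subject_with_fringe)
  ho <- score(fix$subject_without_fringe)
  list(mean_hei_with = hw$mean_hei, mean_hei_without = ho$mean_hei,
       threshold_value = hei$threshold_value, q = hei$q,
       retained_fraction = shaded$retained_fraction)
}

#' Run the paired with/without-appendage experiment
#'
#' For each subject: the HEI threshold is determined from the subject's
#' reference image (cropped subject on a uniform dark background), the mean
#' HEI edge intensity is measured on the shadow-excluded contour band of the
#' with- and without-fringe images, and the per-subject pairs are compared
#' with a two-sided paired t-test.
#'
#' Subjects are either seeded synthetic fixtures (default; see
#' [synth_chick_scene()]) or photographs read from `path`. A photograph
#' directory holds, per subject id, the files `<id>_with.png`,
#' `<id>_without.png`, `<id>_reference.png`, `<id>_outline.png`,
#' `<id>_feather.png`, `<id>_shadow.png` (masks as 0/255 PNG). Subjects with
#' missing files are skipped with a message.
#'
#' @param n_subjects number of synthetic subjects.
#' @param seed base seed; subject seeds are derived deterministically.
#' @param fringe_effect,shadow_fraction,side passed to [synth_chick_scene()].
#' @param path optional photograph directory (overrides fixture generation).
#' @param gamma_mode linearisation for photographs read from `path`.
#' @param px_per_mm scene scale for photographs.
#' @param hei_mode `"value"` (antimode reused as an absolute cut, default) or
#'   `"fraction"`.
#' @param viewer a [viewer_model()].
#' @param rnl an [rnl_params()].
#' @param pad_px contour-band padding; defaults to the fixture's own, or 30
#'   for photographs.
#' @param null_calibration when `TRUE`, both members of each pair carry an
#'   independent fringe realisation at the same `fringe_effect`, so no
#'   systematic with/without difference exists; used to calibrate the size of
#'   the paired test.
#' @return list of class `exp2_result`: `comparison`
#'   (a [paired_comparison()]), `subjects` (per-subject table with thresholds
#'   and retained fractions), `mean_retained_fraction`.
#' @export
run_experiment2 <- function(n_subjects = 15, seed = 1, fringe_effect = 1,
                            shadow_fraction = 0.28, side = 160,
                            path = NULL, gamma_mode = "srgb", px_per_mm = 11.8,
                            hei_mode = c("value", "fraction"),
                            viewer = viewer_model(), rnl = rnl_params(),
                            pad_px = NULL, null_calibration = FALSE) {
  hei_mode <- match.arg(hei_mode)
  if (is.null(path)) {
    subject_seeds <- seed + 7919L * seq_len(n_subjects)
    fixtures <- lapply(seq_len(n_subjects), function(i) {
      if (null_calibration) {
        A <- synth_chick_scene(subject_seeds[i], fringe_effect,
                               shadow_fraction, side,
                               fringe_seed = subject_seeds[i] + 104729L)
        B <- synth_chick_scene(subject_seeds[i], fringe_effect,
                               shadow_fraction, side,
                               fringe_seed = subject_seeds[i] + 224737L)
        A$subject_without_fringe <- B$subject_with_fringe
        A
      } else {
        synth_chick_scene(subject_seeds[i], fringe_effect, shadow_fraction,
                          side)
      }
    })
    ids <- paste0("subject", seq_len(n_subjects))
  } else {
    loaded <- read_fixture_dir(path, gamma_mode, px_per_mm)
    fixtures <- loaded$fixtures; ids <- loaded$ids
    if (length(fixtures) < 3) stop("fewer than 3 complete subjects in ", path)
  }
  rows <- mapply(function(fix, id) {
    r <- exp2_process_subject(fix, viewer, rnl, hei_mode, pad_px)
    cbind(data.frame(subject_id = id), as.data.frame(r))
  }, fixtures, ids, SIMPLIFY = FALSE)
  tab <- do.call(rbind, rows)
  cmp <- paired_comparison(tab$mean_hei_with, tab$mean_hei_without,
                           tab$subject_id)
  structure(list(comparison = cmp, subjects = tab,
                 mean_retained_fraction = mean(tab$retained_fraction),
                 mean_threshold = mean(tab$threshold_value),
                 hei_mode = hei_mode, seed = seed,
                 fringe_effect = fringe_effect,
                 null_calibration = null_calibration),
            class = "exp2_result")
}

#' Size calibration of the paired test on null fixtures
#'
#' Repeats the paired experiment on exchangeable pairs (two independent
#' fringe realisations per subject, same subjects across replicates) and
#' returns the fraction of replicates rejecting at `alpha`.
#'
#' @param n_replicates number of replicates.
#' @param alpha nominal test size.
#' @inheritParams run_experiment2
#' @return list with `rejection_rate`, `p_values`.
#' @export
exp2_null_rejection_rate <- function(n_replicates = 200, alpha = 0.05,
                                     n_subjects = 15, seed = 1,
                                     fringe_effect = 1, shadow_fraction = 0.28,
                                     side = 160,
                                     hei_mode = c("value", "fraction"),
                                     viewer = viewer_model(),
                                     rnl = rnl_params()) {
  hei_mode <- match.arg(hei_mode)
  subject_seeds <- seed + 7919L * seq_len(n_subjects)
  # subject bases, bands and thresholds are fixed across replicates; only the
  # two fringe realisations per subject are redrawn
  bases <- lapply(subject_seeds, function(s)
    synth_chick_scene(s, fringe_effect, shadow_fraction, side))
  prep <- lapply(bases, function(fix) {
    band <- contour_band(fix$outline_mask, fix$feather_boundary_mask,
                         fix$band_pad)
    shaded <- apply_shadow_exclusion(band, fix$shadow_mask)
    ref_lum <- observer_lum(fix$reference_image, viewer, fix$px_per_mm, rnl)
    hei <- hei_threshold_from_reference(
      leia_analysis_values(ref_lum, band, viewer$weber_lum), mode = hei_mode)
    list(mask = shaded$mask, hei = hei)
  })
  score <- function(fix, img, pr) {
    lum <- observer_lum(img, viewer, fix$px_per_mm, rnl)
    mean_hei(leia_analysis_values(lum, pr$mask, viewer$weber_lum),
             pr$hei)$mean_hei
  }
  p_values <- vapply(seq_len(n_replicates), function(r) {
    w <- numeric(length(bases)); o <- numeric(length(bases))
    for (i in seq_along(bases)) {
      fa <- synth_chick_scene(subject_seeds[i], fringe_effect,
                              shadow_fraction, side,
                              fringe_seed = subject_seeds[i] + 2L * r)
      fb <- synth_chick_scene(subject_seeds[i], fringe_effect,
                              shadow_fraction, side,
                              fringe_seed = subject_seeds[i] + 2L * r + 1L)
      w[i] <- score(fa, fa$subject_with_fringe, prep[[i]])
      o[i] <- score(fb, fb$subject_with_fringe, prep[[i]])
    }
    paired_comparison(w, o)$p
  }, numeric(1))
  list(rejection_rate = mean(p_values < alpha), p_values = p_values,
       alpha = alpha)
}
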