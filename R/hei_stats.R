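# High-edge-intensity (HEI) pixel statistics: modal-threshold determination
# from a reference image's edge-intensity distribution, the mean edge
# intensity of HEI pixels, and the paired with/without comparison.

#' Determine the HEI threshold from a reference edge-intensity sample
#'
#' Outline pixels form a distinct high-intensity modal area in the (log)
#' edge-intensity distribution. A kernel density estimate locates the
#' highest-intensity mode and the antimode (local density minimum) separating
#' it from the rest of the distribution. In `"fraction"` mode the result is
#' the share `q` of region-of-interest pixels above the antimode (reused as a
#' fixed pixel count on other images of the same ROI); in `"value"` mode it
#' is the antimode itself, reused as an absolute cut.
#'
#' Two robustness choices, both exposed: (1) the default bandwidth is
#' Sheather-Jones computed on the nonzero values -- the mass clamped at
#' exactly 0 is a point-mass artefact of the negative-log clamp and carries
#' no shape information, and Silverman's rule badly oversmooths the valley of
#' a strongly bimodal sample (its sd-based width spans both clusters);
#' (2) adjacent modes whose separating valley does not dip below
#' `merge_ratio` times the lower flanking peak are merged, so shallow density
#' ripples (for example the rasterisation rings of synthetic scenes) do not
#' masquerade as distinct modal areas.
#'
#' @param values numeric vector of collapsed log edge intensities (the
#'   analysis set of the reference image). An `n_roi` attribute, when
#'   present (see [postprocess_stack()]), supplies `n_total`.
#' @param mode `"fraction"` or `"value"`.
#' @param bw numeric bandwidth, `"nrd0"` (Silverman on all values),
#'   `"nrd0_positive"` (Silverman on nonzero values) or `"sj_positive"`
#'   (Sheather-Jones on nonzero values; default, falling back to Silverman
#'   when the Sheather-Jones solver fails).
#' @param n_grid density grid size.
#' @param min_mode_height local maxima below this fraction of the global
#'   density maximum are ignored as numerical ripples.
#' @param merge_ratio valley-prominence criterion: a valley separates two
#'   modes only if its density is below `merge_ratio` times the lower
#'   flanking peak.
#' @param min_values minimum sample size.
#' @param bw_floor_frac lower bound on the bandwidth as a fraction of the
#'   full value range, so that quantised samples (synthetic scenes hold a
#'   handful of discrete contrast levels) form modal areas rather than
#'   isolated spikes.
#' @param n_total denominator for `q`: total pixels in the region of
#'   interest. Defaults to the `n_roi` attribute of `values`, else
#'   `length(values)`.
#' @return an object of class `hei_result`: list with `mode`, `q`,
#'   `threshold_value` (the antimode), `mean_hei` (mean of reference values
#'   above the antimode), `n_pixels`, `n_total`.
#' @export
hei_threshold_from_reference <- function(values, mode = c("fraction", "value"),
                                         bw = "sj_positive", n_grid = 512,
                                         min_mode_height = 1e-3,
                                         merge_ratio = 0.5,
                                         min_values = 1000,
                                         bw_floor_frac = 0.02,
                                         n_total = NULL) {
  mode <- match.arg(mode)
  n_total <- n_total %||% attr(values, "n_roi") %||% length(values)
  values <- as.vector(values[is.finite(values)])
  if (length(values) < min_values)
    stop("need at least ", min_values, " edge-intensity values, got ",
         length(values))
  if (max(values) - min(values) < .Machine$double.eps^0.5)
    stop("no HEI mode: edge-intensity distribution is degenerate (constant)")
  pos <- values[values > 0]
  if (is.character(bw) && bw %in% c("nrd0_positive", "sj_positive")) {
    if (length(pos) > 1 && stats::sd(pos) > 0) {
      bw <- if (identical(bw, "sj_positive"))
        tryCatch(stats::bw.SJ(pos), error = function(e) stats::bw.nrd0(pos))
      else stats::bw.nrd0(pos)
    } else bw <- "nrd0"
  }
  if (is.numeric(bw))
    bw <- max(bw, bw_floor_frac * diff(range(values)))
  d <- stats::density(values, bw = bw, n = n_grid)
  y <- d$y; m <- length(y)
  is_max <- c(y[1] > y[2],
              y[2:(m - 1)] > y[1:(m - 2)] & y[2:(m - 1)] >= y[3:m],
              y[m] > y[m - 1])
  modes <- which(is_max & y >= min_mode_height * max(y))
  # merge adjacent modes separated only by shallow valleys
  repeat {
    if (length(modes) < 2) break
    merged <- FALSE
    for (k in seq_len(length(modes) - 1)) {
      valley_y <- min(y[modes[k]:modes[k + 1]])
      if (valley_y > merge_ratio * min(y[modes[k]], y[modes[k + 1]])) {
        drop <- if (y[modes[k]] < y[modes[k + 1]]) k else k + 1L
        modes <- modes[-drop]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  if (length(modes) < 2)
    stop("no HEI mode: edge-intensity distribution is unimodal")
  hi <- modes[length(modes)]                 # highest-intensity mode
  lo <- modes[length(modes) - 1L]            # nearest retained mode below it
  valley <- lo:hi
  # antimode: where the high mode first separates from the rest. In a wide
  # empty valley the density minimum is a plateau; take its lower edge so the
  # threshold stays usable as an absolute cut on other images.
  y_min <- min(y[valley])
  anti_idx <- valley[which(y[valley] <= y_min + 1e-6 * max(y))[1]]
  threshold_value <- d$x[anti_idx]
  sel <- values > threshold_value
  if (!any(sel)) stop("no HEI mode: no values above the antimode")
  structure(list(mode = mode,
                 q = sum(sel) / n_total,
                 threshold_value = threshold_value,
                 mean_hei = mean(values[sel]),
                 n_pixels = sum(sel),
                 n_total = n_total,
                 bw = d$bw),
            class = "hei_result")
}

#' Mean edge intensity of the HEI pixels
#'
#' In `"fraction"` mode: the mean of the top `ceiling(q * n)` values, where
#' `n` is the ROI pixel count (`n_roi` attribute when present, else the
#' sample length), so the HEI pixel count is the same for every image
#' analysed under the same ROI. Values are sorted decreasingly; ties at the
#' cut are resolved by position, so the result is deterministic. In
#' `"value"` mode: the mean of all values strictly above `threshold_value`.
#'
#' @param values numeric vector of collapsed log edge intensities.
#' @param hei an `hei_result` (or a list with the needed fields).
#' @return the `hei_result` with `mean_hei`, `n_pixels`, `n_total` filled for
#'   this sample.
#' @export
mean_hei <- function(values, hei) {
  n_total <- attr(values, "n_roi") %||% length(values)
  values <- as.vector(values[is.finite(values)])
  if (length(values) == 0) stop("empty edge-intensity sample")
  if (hei$mode == "fraction") {
    if (hei$q * n_total < 1)
      stop("q * n < 1: too few values for the HEI fraction")
    k <- min(ceiling(hei$q * n_total), length(values))
    top <- sort(values, decreasing = TRUE)[seq_len(k)]
    hei$mean_hei <- mean(top)
    hei$n_pixels <- k
    hei$n_total <- n_total
    return(hei)
  } else {
    sel <- values > hei$threshold_value
    if (!any(sel)) stop("no values above the HEI threshold")
    hei$mean_hei <- mean(values[sel])
    hei$n_pixels <- sum(sel)
  }
  hei$n_total <- n_total
  hei
}

#' Paired with/without comparison of mean HEI values
#'
#' Two-sided paired t-test on the per-subject differences
#' `without - with`; a positive mean difference means the appendaged
#' (with) images have lower mean edge intensity, i.e. better outline
#' concealment.
#'
#' @param mean_hei_with,mean_hei_without equal-length numeric vectors.
#' @param subject_ids optional labels.
#' @return an object of class `paired_comparison`: list with `t`, `df`, `p`,
#'   `mean_diff`, `ci95`, `n_lower_with` (subjects whose with-value is
#'   lower) and the per-subject table.
#' @export
paired_comparison <- function(mean_hei_with, mean_hei_without,
                              subject_ids = seq_along(mean_hei_with)) {
  stopifnot(length(mean_hei_with) == length(mean_hei_without))
  n <- length(mean_hei_with)
  if (n < 3) stop("need at least 3 pairs")
  diffs <- mean_hei_without - mean_hei_with
  if (stats::var(diffs) == 0)
    stop("zero-variance differences: paired t-test undefined")
  tt <- stats::t.test(mean_hei_without, mean_hei_with, paired = TRUE,
                      alternative = "two.sided", conf.level = 0.95)
  structure(list(t = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p = tt$p.value,
                 mean_diff = unname(tt$estimate),
                 ci95 = as.numeric(tt$conf.int),
                 n_lower_with = sum(diffs > 0),
                 n = n,
                 subjects = data.frame(subject_id = subject_ids,
                                       mean_hei_with = mean_hei_with,
                                       mean_hei_without = mean_hei_without,
                                       diff = diffs)),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat("Paired comparison of mean HEI edge intensity (without - with)\n")
  cat(sprintf("  n = %d subjects; lower with appendages in %d/%d\n",
              x$n, x$n_lower_with, x$n))
  cat(sprintf("  t = %.3f, df = %d, p = %.4g\n", x$t, x$df, x$p))
  cat(sprintf("  mean difference = %.4f (95%% CI %.4f to %.4f)\n",
              x$mean_diff, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Per-family summary curve of mean HEI against appendage count
#'
#' @param results data.frame with columns `family`, `level`, `count_stage`,
#'   `count`, `mean_hei` (one row per processed image, as returned by
#'   [run_experiment1()]).
#' @return list with `curve` (the input, ordered) and `argmin` (one row per
#'   family x level: the count stage with the lowest mean HEI).
#' @export
scenario_curve <- function(results) {
  ord <- order(results$family, results$level, results$count)
  curve <- results[ord, , drop = FALSE]
  key <- interaction(curve$family, curve$level, drop = TRUE)
  argmin <- do.call(rbind, lapply(split(curve, key), function(g) {
    i <- which.min(g$mean_hei)
    data.frame(family = g$family[1], level = g$level[1],
               argmin_stage = g$count_stage[i], argmin_count = g$count[i],
               min_mean_hei = g$mean_hei[i])
  }))
  rownames(argmin) <- NULL
  list(curve = curve, argmin = argmin)
}
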