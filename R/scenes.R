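# Procedural rendering of the proof-of-principle scenes: a uniformly coloured
# disc ("artificial chick") carrying radial appendages on a uniform or
# chessboard background. All geometry is hard pixel assignment (no
# anti-aliasing) so renders are bit-reproducible.

#' Scenario specification for an artificial object scene
#'
#' Describes one scene: a disc of `object_radius_px` (printed circumference
#' `object_circumference_px`) on a background, with `appendage_count` radial
#' appendages of `appendage_thickness_px` thickness and `appendage_length_px`
#' length attached orthogonally to the outline at regular angular intervals.
#' Appendages are modelled as radial wedges whose width equals the nominal
#' thickness at the object outline, so the full-circle stage tiles the
#' appendage annulus exactly.
#'
#' The two grey levels are not dictated by the geometry; the defaults (object
#' 0.70, background 0.25) give a strongly suprathreshold outline
#' (Delta-S about 10 at a luminance Weber fraction of 0.1).
#'
#' @param appendage_count nonnegative integer or `"full"` (the packing count
#'   `floor(circumference / thickness)`).
#' @param appendage_thickness_px line thickness in px (paper grid: 4, 8, 12).
#' @param transparency appendage transparency in \[0, 1\]; compositing alpha
#'   is `1 - transparency`.
#' @param length_profile list of `c(appendage_fraction, length_fraction)`
#'   pairs; fractions of appendages receiving each length factor. Assigned
#'   deterministically by interleaving around the circle.
#' @param background `"uniform"` or `"chessboard"`.
#' @param square_px chessboard square side in px (346 or 86 in the grid).
#' @param object_radius_px,object_circumference_px,appendage_length_px
#'   geometry in px.
#' @param px_per_mm scene scale (2950 px / 250 mm = 11.8).
#' @param object_level,background_level grey levels in (0, 1\].
#' @param acuity_cpd observer acuity attached to the scene (used by the
#'   pipeline to build the viewer; 72 unless the scenario varies acuity).
#' @param canvas_pad_px padding beyond the appendage tips when sizing the
#'   canvas; the default keeps the 1500 px square region of interest inside.
#' @param scenario_id free-form label.
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(appendage_count = 0,
                          appendage_thickness_px = 4,
                          transparency = 0,
                          length_profile = list(c(1, 1)),
                          background = c("uniform", "chessboard"),
                          square_px = NULL,
                          object_radius_px = 470,
                          object_circumference_px = 2950,
                          appendage_length_px = 118,
                          px_per_mm = 11.8,
                          object_level = 0.70,
                          background_level = 0.25,
                          acuity_cpd = 72,
                          canvas_pad_px = 200,
                          scenario_id = NULL) {
  background <- match.arg(background)
  stopifnot(object_radius_px > 0, appendage_length_px > 0,
            appendage_thickness_px > 0, object_circumference_px > 0,
            transparency >= 0, transparency <= 1,
            object_level > 0, object_level <= 1,
            background_level > 0, background_level <= 1,
            px_per_mm > 0, acuity_cpd > 0)
  if (background == "uniform" && object_level == background_level)
    stop("object_level and background_level must differ on a uniform background")
  if (background == "chessboard" && (is.null(square_px) || square_px <= 0))
    stop("chessboard background needs square_px > 0")
  fr <- vapply(length_profile, `[`, numeric(1), 1)
  lf <- vapply(length_profile, `[`, numeric(1), 2)
  if (any(fr <= 0) || sum(fr) > 1 + 1e-9)
    stop("appendage fractions in length_profile must be positive and sum to <= 1")
  if (any(lf <= 0) || any(lf > 1))
    stop("length fractions in length_profile must lie in (0, 1]")
  if (!identical(appendage_count, "full")) {
    appendage_count <- as.integer(appendage_count)
    stopifnot(appendage_count >= 0)
  }
  if (is.null(scenario_id))
    scenario_id <- paste0("r", object_radius_px, "_t", appendage_thickness_px,
                          "_n", appendage_count)
  structure(list(scenario_id = scenario_id,
                 object_radius_px = object_radius_px,
                 object_circumference_px = object_circumference_px,
                 appendage_length_px = appendage_length_px,
                 appendage_thickness_px = appendage_thickness_px,
                 appendage_count = appendage_count,
                 transparency = transparency,
                 length_profile = length_profile,
                 background = background, square_px = square_px,
                 px_per_mm = px_per_mm,
                 object_level = object_level,
                 background_level = background_level,
                 acuity_cpd = acuity_cpd,
                 canvas_pad_px = canvas_pad_px),
            class = "scenario_spec")
}

#' Number of appendages packed into the full circle
#'
#' `"full"` resolves to `floor(circumference / thickness)`: appendages of the
#' nominal thickness packed side by side along the printed object
#' circumference (737 for 4 px on 2950 px).
#'
#' @param spec a [scenario_spec()].
#' @return integer count.
#' @export
resolve_appendage_count <- function(spec) {
  if (identical(spec$appendage_count, "full"))
    floor(spec$object_circumference_px / spec$appendage_thickness_px)
  else
    spec$appendage_count
}

#' Canvas side implied by a scenario
#' @param spec a [scenario_spec()].
#' @return integer canvas side in px.
#' @export
canvas_side <- function(spec) {
  2L * as.integer(ceiling(spec$object_radius_px + spec$appendage_length_px +
                          spec$canvas_pad_px))
}

# pixel-centre coordinate grids about the canvas centre
scene_coords <- function(side) {
  ctr <- (side + 1) / 2
  x <- matrix(rep(seq_len(side) - ctr, each = side), nrow = side)  # column
  y <- matrix(rep(seq_len(side) - ctr, times = side), nrow = side) # row
  list(x = x, y = y, r = sqrt(x^2 + y^2))
}

#' Render a background raster
#'
#' Uniform level, or a two-level chessboard whose phase is anchored at the
#' canvas origin (corner square starts with `level_a`).
#'
#' @param kind `"uniform"` or `"chessboard"`.
#' @param side canvas side in px.
#' @param level_a primary level (uniform level; first chessboard square).
#' @param level_b second chessboard level.
#' @param square_px chessboard square side in px.
#' @return numeric `side x side` matrix.
#' @export
render_background <- function(kind = c("uniform", "chessboard"), side,
                              level_a = 0.25, level_b = 0.70,
                              square_px = NULL) {
  kind <- match.arg(kind)
  if (kind == "uniform") return(matrix(level_a, side, side))
  stopifnot(!is.null(square_px), square_px > 0)
  idx <- (seq_len(side) - 1) %/% square_px
  parity <- outer(idx, idx, `+`) %% 2
  matrix(ifelse(parity == 0, level_a, level_b), side, side)
}

# Deterministic interleaving of length-profile classes around the circle:
# classes are expanded to the smallest repeating cycle and spread by the
# fractional-rank schedule, so the same spec always renders the same image.
length_profile_cycle <- function(length_profile, max_cycle = 64L) {
  fr <- vapply(length_profile, `[`, numeric(1), 1)
  lf <- vapply(length_profile, `[`, numeric(1), 2)
  if (sum(fr) < 1 - 1e-9) {  # remainder keeps full length
    fr <- c(fr, 1 - sum(fr)); lf <- c(lf, 1)
  }
  L <- 1L
  while (L < max_cycle && any(abs(fr * L - round(fr * L)) > 1e-9)) L <- L + 1L
  n_i <- round(fr * L)
  key <- unlist(lapply(seq_along(n_i),
                       function(i) (seq_len(n_i[i]) - 0.5) / n_i[i]))
  cls <- rep(seq_along(n_i), n_i)
  lf[cls[order(key, cls)]]
}

#' Composite radial appendages onto a scene
#'
#' Appendages are radial wedges starting at the object outline
#' (`r = object_radius_px`), equally spaced in angle, with angular width
#' `thickness / radius` radians -- the nominal thickness measured at the
#' outline, widening slightly towards the tip. At the `"full"` stage the
#' wedges tile the circle exactly, so the extended outline is completely
#' filled. The union of all appendages is composited once with alpha
#' `1 - transparency` over whatever lies beneath, so overlapping appendages
#' are drawn idempotently. Length factors from `length_profile` are
#' interleaved deterministically around the circle.
#'
#' @param base numeric matrix to composite onto (background + object disc).
#' @param spec a [scenario_spec()].
#' @param strict_capacity error when a numeric count exceeds the `"full"`
#'   packing capacity (overlap is otherwise allowed and idempotent).
#' @return matrix with appendages composited.
#' @export
place_appendages <- function(base, spec, strict_capacity = FALSE) {
  n <- resolve_appendage_count(spec)
  if (n == 0) return(base)
  capacity <- floor(spec$object_circumference_px / spec$appendage_thickness_px)
  if (strict_capacity && n > capacity)
    stop("appendage_count ", n, " exceeds full-circle capacity ", capacity)
  side <- nrow(base)
  co <- scene_coords(side)
  r_in <- spec$object_radius_px
  len <- spec$appendage_length_px * length_profile_cycle(spec$length_profile)
  len_k <- rep_len(len, n)                     # length of appendage k (1-based)
  # at the "full" stage the wedges tile the circle exactly (the extended
  # outline is completely filled); otherwise width = thickness at the outline
  half_ang <- if (identical(spec$appendage_count, "full")) pi / n
              else spec$appendage_thickness_px / (2 * r_in)
  dth <- 2 * pi / n

  sel <- which(co$r > r_in & co$r <= r_in + max(len_k))
  phi <- atan2(co$y[sel], co$x[sel]) %% (2 * pi)
  r <- co$r[sel]
  covered <- rep(FALSE, length(sel))
  m_max <- min(ceiling(half_ang / dth) + 1L, ceiling(n / 2))
  k0 <- round(phi / dth)
  for (m in -m_max:m_max) {
    k <- (k0 + m) %% n
    d <- abs(phi - k * dth)
    d <- pmin(d, 2 * pi - d)
    covered <- covered | (d <= half_ang & r <= r_in + len_k[k + 1])
  }
  alpha <- 1 - spec$transparency
  idx <- sel[covered]
  out <- base
  out[idx] <- alpha * spec$object_level + (1 - alpha) * base[idx]
  out
}

#' Render a complete artificial-object scene
#'
#' Background, then the object disc at `object_level`, then the appendages
#' (see [place_appendages()]). Hard pixel assignment throughout.
#'
#' @inheritParams place_appendages
#' @param spec a [scenario_spec()].
#' @return numeric square matrix with values in (0, 1\].
#' @export
render_object_scene <- function(spec, strict_capacity = FALSE) {
  side <- canvas_side(spec)
  need <- 2 * (spec$object_radius_px + spec$appendage_length_px + 30)
  if (side < need)
    stop("canvas side ", side, " px cannot hold the feather boundary + 30 px pad")
  img <- render_background(spec$background, side,
                           level_a = spec$background_level,
                           level_b = spec$object_level,
                           square_px = spec$square_px)
  co <- scene_coords(side)
  img[co$r <= spec$object_radius_px] <- spec$object_level
  place_appendages(img, spec, strict_capacity = strict_capacity)
}

#' The factorial scenario grids of the proof-of-principle study
#'
#' Each family runs the seven appendage-count stages
#' 0, 32, 64, 128, 256, 512, full. `basic` is the reference family (4 px
#' opaque equal-length appendages, uniform background, 72 cpd); the other
#' families vary one property at two levels each:
#' \describe{
#'   \item{thickness}{8 and 12 px appendages.}
#'   \item{transparency}{25\% and 50\% transparent appendages.}
#'   \item{length}{half the appendages at 50\% length; half at 25\% plus a
#'     quarter at 50\% length.}
#'   \item{background}{chessboard squares of 346 and 86 px.}
#'   \item{acuity}{observer acuity 30 and 10 cycles per degree.}
#' }
#'
#' @param family one of `"basic"`, `"thickness"`, `"transparency"`,
#'   `"length"`, `"background"`, `"acuity"`.
#' @param ... overrides passed to every [scenario_spec()] in the grid.
#' @return list of `scenario_spec` objects with attributes `family` and
#'   `level` on each element.
#' @export
scenario_grid <- function(family = c("basic", "thickness", "transparency",
                                     "length", "background", "acuity"), ...) {
  family <- match.arg(family)
  counts <- list(0L, 32L, 64L, 128L, 256L, 512L, "full")
  levels <- switch(family,
    basic        = list(list()),
    thickness    = list(list(appendage_thickness_px = 8),
                        list(appendage_thickness_px = 12)),
    transparency = list(list(transparency = 0.25),
                        list(transparency = 0.50)),
    length       = list(list(length_profile = list(c(0.5, 1), c(0.5, 0.5))),
                        list(length_profile = list(c(0.25, 1), c(0.5, 0.25),
                                                   c(0.25, 0.5)))),
    background   = list(list(background = "chessboard", square_px = 346),
                        list(background = "chessboard", square_px = 86)),
    acuity       = list(list(acuity_cpd = 30), list(acuity_cpd = 10)))
  level_tag <- switch(family,
    basic = "basic", thickness = c("8px", "12px"),
    transparency = c("25pct", "50pct"), length = c("half50", "mixed2550"),
    background = c("sq346", "sq86"), acuity = c("30cpd", "10cpd"))
  out <- list()
  for (li in seq_along(levels)) {
    for (cn in counts) {
      args <- c(list(appendage_count = cn), levels[[li]], list(...))
      args$scenario_id <- paste0(family, "_", level_tag[li], "_n",
                                 if (identical(cn, "full")) "full" else cn)
      sp <- do.call(scenario_spec, args)
      attr(sp, "family") <- family
      attr(sp, "level") <- level_tag[li]
      out[[length(out) + 1L]] <- sp
    }
  }
  out
}

#' Serialise a scenario grid to a data frame
#'
#' One record per [scenario_spec()]; suitable for writing to CSV as a run
#' configuration.
#'
#' @param grid list of `scenario_spec` objects.
#' @return data.frame.
#' @export
grid_as_config <- function(grid) {
  do.call(rbind, lapply(grid, function(sp) {
    data.frame(scenario_id = sp$scenario_id,
               family = attr(sp, "family") %||% NA_character_,
               level = attr(sp, "level") %||% NA_character_,
               appendage_count = as.character(sp$appendage_count),
               thickness_px = sp$appendage_thickness_px,
               transparency = sp$transparency,
               length_profile = paste(vapply(sp$length_profile, paste,
                                             character(1), collapse = ":"),
                                      collapse = ";"),
               background = sp$background,
               square_px = sp$square_px %||% NA_real_,
               object_level = sp$object_level,
               background_level = sp$background_level,
               acuity_cpd = sp$acuity_cpd,
               stringsAsFactors = FALSE)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
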