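# Raster I/O: grayscale PNG/TIFF scenes, 0/255 PNG masks, floating-point
# multi-page TIFF edge stacks, and the per-subject photograph directory layout
# consumed by run_experiment2().

#' Write a grayscale image
#'
#' Grayscale PNG or TIFF; values are clamped to \[0, 1\]. TIFF honours
#' 16-bit samples; PNG is always stored at 8 bits per sample by the
#' underlying writer, so use TIFF where full precision matters.
#'
#' @param img numeric matrix.
#' @param path output file (`.png` or `.tif`/`.tiff`).
#' @param bits 8 or 16 (effective for TIFF).
#' @export
write_gray_image <- function(img, path, bits = 16) {
  stopifnot(bits %in% c(8, 16))
  EBImage::writeImage(EBImage::Image(pmin(pmax(img, 0), 1)), path,
                      bits.per.sample = bits)
  invisible(path)
}

#' Write a binary mask as 0/255 PNG
#' @param mask logical matrix.
#' @param path output PNG path.
#' @export
write_mask_png <- function(mask, path) {
  EBImage::writeImage(EBImage::Image((mask > 0) * 1), path,
                      bits.per.sample = 8)
  invisible(path)
}

#' Read a raster image
#'
#' @param path PNG/TIFF/JPEG file.
#' @return numeric matrix (grayscale) or array (colour), values in \[0, 1\].
#' @export
read_raster <- function(path) {
  x <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(x)) == 3 && dim(x)[3] == 1) x <- x[, , 1]
  if (length(dim(x)) == 3 && dim(x)[3] > 3) x <- x[, , 1:3]
  x
}

read_mask <- function(path) {
  x <- read_raster(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  x > 0.5
}

#' Persist an edge stack as a multi-page floating-point TIFF
#'
#' Four orientation slices followed by the collapsed map (when present).
#' TIFF sample values are stored in \[0, 1\], so pages are divided by a
#' common scale factor recorded in a `<path>.scale` sidecar;
#' [read_edge_stack_tiff()] restores the original Delta-S values.
#'
#' @param stack an [leia_stack()] (optionally post-processed) result.
#' @param path output TIFF path.
#' @export
write_edge_stack_tiff <- function(stack, path) {
  pages <- stack$slices
  if (!is.null(stack$collapsed))
    pages <- c(pages, list(collapsed = stack$collapsed))
  scale <- max(unlist(lapply(pages, max)), 1)
  tiff::writeTIFF(lapply(unname(pages), function(p) p / scale), path,
                  bits.per.sample = 32L, reduce = FALSE)
  writeLines(format(scale, digits = 17), paste0(path, ".scale"))
  invisible(path)
}

#' Read back an edge stack written by [write_edge_stack_tiff()]
#'
#' @param path TIFF path (with its `.scale` sidecar next to it).
#' @return list of matrices (orientation slices, plus `collapsed` if it was
#'   written).
#' @export
read_edge_stack_tiff <- function(path) {
  scale <- as.numeric(readLines(paste0(path, ".scale"))[1])
  lapply(tiff::readTIFF(path, all = TRUE), function(p) p * scale)
}

#' Export an edge-stack analysis set as CSV
#'
#' Pixel coordinates (row, col) and collapsed edge intensity of every
#' retained in-ROI position.
#'
#' @param stack a post-processed edge stack.
#' @param path output CSV path.
#' @export
write_analysis_csv <- function(stack, path) {
  if (is.null(stack$analysis_mask)) stop("stack is not post-processed")
  idx <- which(stack$analysis_mask, arr.ind = TRUE)
  utils::write.csv(data.frame(row = idx[, 1], col = idx[, 2],
                              edge_intensity = stack$collapsed[stack$analysis_mask]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a fixture as a per-subject photograph set
#'
#' Writes the six files `<id>_with.png`, `<id>_without.png`,
#' `<id>_reference.png` (16-bit grayscale) and `<id>_outline.png`,
#' `<id>_feather.png`, `<id>_shadow.png` (0/255 masks) that
#' [run_experiment2()] reads from a photograph directory.
#'
#' @param fix a [synth_chick_scene()] fixture.
#' @param dir output directory (created if needed).
#' @param id subject identifier used as the filename prefix.
#' @export
write_fixture_set <- function(fix, dir, id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(part) file.path(dir, paste0(id, "_", part, ".png"))
  write_gray_image(fix$subject_with_fringe, p("with"))
  write_gray_image(fix$subject_without_fringe, p("without"))
  write_gray_image(fix$reference_image, p("reference"))
  write_mask_png(fix$outline_mask, p("outline"))
  write_mask_png(fix$feather_boundary_mask, p("feather"))
  write_mask_png(fix$shadow_mask, p("shadow"))
  invisible(dir)
}

# read every complete subject in a photograph directory; incomplete subjects
# are skipped with a message
read_fixture_dir <- function(path, gamma_mode = "srgb", px_per_mm = 11.8,
                             band_pad = 30) {
  files <- list.files(path, pattern = "_with\\.(png|tif|tiff|jpg|jpeg)$")
  ids <- sub("_with\\.[^.]+$", "", files)
  fixtures <- list(); kept <- character(0)
  for (id in ids) {
    part <- function(nm) {
      hits <- list.files(path, pattern = paste0("^", id, "_", nm,
                                                "\\.(png|tif|tiff|jpg|jpeg)$"),
                         full.names = TRUE)
      if (length(hits)) hits[1] else NA_character_
    }
    paths <- vapply(c("with", "without", "reference", "outline", "feather",
                      "shadow"), part, character(1))
    if (anyNA(paths)) {
      message("subject ", id, " skipped: missing ",
              paste(names(paths)[is.na(paths)], collapse = ", "))
      next
    }
    lin <- function(f) {
      x <- read_raster(f)
      to_cone_catch(x, gamma_mode)$lum
    }
    fixtures[[length(fixtures) + 1]] <- structure(list(
      subject_with_fringe = lin(paths["with"]),
      subject_without_fringe = lin(paths["without"]),
      reference_image = lin(paths["reference"]),
      outline_mask = read_mask(paths["outline"]),
      feather_boundary_mask = read_mask(paths["feather"]),
      shadow_mask = read_mask(paths["shadow"]),
      band_pad = band_pad, px_per_mm = px_per_mm),
      class = "scene_fixture")
    kept <- c(kept, id)
  }
  list(fixtures = fixtures, ids = kept)
}
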