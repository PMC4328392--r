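# Core raster containers and the single um <-> px conversion utility.

#' Convert micrometres to pixels
#'
#' All micrometre-to-pixel conversions in the package flow through this one
#' function so that a single rounding convention (round half to even, R's
#' `round()`) applies everywhere — ROI sides, structuring-element radii,
#' cutoffs alike.
#'
#' @param um Length(s) in micrometres.
#' @param resolution Pixels per micrometre (the imaging calibration; the
#'   package default throughout is 7 px/um).
#' @param even If `TRUE`, round to the nearest even integer instead (used for
#'   ROI sides so the 90-degree rotation control maps the square onto itself).
#' @return Integer pixel length(s).
#' @examples
#' um_to_px(30, 7)   # 210
#' um_to_px(120, 7)  # 840
#' @export
um_to_px <- function(um, resolution, even = FALSE) {
  stopifnot(resolution > 0)
  if (even) {
    px <- 2L * as.integer(round(um * resolution / 2))
  } else {
    px <- as.integer(round(um * resolution))
  }
  px
}

#' Calibrated single-channel image
#'
#' A 2-D intensity raster together with its pixel-size calibration and a
#' channel label. Intensities are stored as floating point on the 16-bit count
#' scale (0..65535) regardless of file depth.
#'
#' @param pixels Numeric matrix of non-negative, finite intensities.
#' @param resolution Pixels per micrometre, > 0.
#' @param channel Channel label, e.g. `"EGFP"`, `"5-HT"`, `"DAPI"`.
#' @return An object of class `calibrated_image`.
#' @export
calibrated_image <- function(pixels, resolution, channel = "unknown") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    abort("pixels must be a numeric matrix", class = "fiberlayer_invalid_input")
  if (!all(is.finite(pixels)))
    abort("intensities must be finite", class = "fiberlayer_invalid_input")
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0)
    abort("resolution must be a single positive number (px/um)",
          class = "fiberlayer_invalid_input")
  structure(list(pixels = pixels, resolution = resolution,
                 channel = as.character(channel)),
            class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("<calibrated_image> %s: %d x %d px @ %.3g px/um, range [%.4g, %.4g]\n",
              x$channel, nrow(x$pixels), ncol(x$pixels), x$resolution,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.calibrated_image <- function(x) dim(x$pixels)

#' Anatomical layer-label mask
#'
#' An integer label raster on the same grid as its companion images: 0 marks
#' background, positive integers mark anatomical layers named by `legend`.
#'
#' @param labels Integer matrix of layer labels (0 = background).
#' @param resolution Pixels per micrometre.
#' @param legend Named integer vector mapping layer names to label values,
#'   e.g. `c(GCL = 1L, EPL = 2L, GL = 3L)`.
#' @return An object of class `layer_mask`.
#' @export
layer_mask <- function(labels, resolution,
                       legend = c(GCL = 1L, EPL = 2L, GL = 3L)) {
  if (!is.matrix(labels)) abort("labels must be a matrix",
                                class = "fiberlayer_invalid_input")
  storage.mode(labels) <- "integer"
  if (is.null(names(legend)) || any(!nzchar(names(legend))))
    abort("legend must be a named integer vector", class = "fiberlayer_invalid_input")
  if (!is.numeric(resolution) || resolution <= 0)
    abort("resolution must be positive", class = "fiberlayer_invalid_input")
  structure(list(labels = labels, resolution = resolution,
                 legend = stats::setNames(as.integer(legend), names(legend))),
            class = "layer_mask")
}

#' @export
print.layer_mask <- function(x, ...) {
  cat(sprintf("<layer_mask> %d x %d px @ %.3g px/um; layers: %s\n",
              nrow(x$labels), ncol(x$labels), x$resolution,
              paste(sprintf("%s=%d", names(x$legend), x$legend), collapse = ", ")))
  invisible(x)
}

#' @export
dim.layer_mask <- function(x) dim(x$labels)

layer_label <- function(mask, layer) {
  if (is.character(layer)) {
    if (!layer %in% names(mask$legend))
      abort(sprintf("layer '%s' not in mask legend", layer),
            class = "fiberlayer_missing_layer")
    return(unname(mask$legend[[layer]]))
  }
  as.integer(layer)
}

layer_name <- function(mask, label) {
  nm <- names(mask$legend)[match(label, mask$legend)]
  ifelse(is.na(nm), as.character(label), nm)
}

check_same_grid <- function(img, mask) {
  if (!identical(dim(img$pixels), dim(mask$labels)))
    abort("image and mask do not share a pixel grid",
          class = "fiberlayer_calibration_mismatch")
  if (!isTRUE(all.equal(img$resolution, mask$resolution)))
    abort("image and mask calibrations differ",
          class = "fiberlayer_calibration_mismatch")
  invisible(TRUE)
}

#' Rotate a square raster by 90 degrees
#'
#' Clockwise quarter-turn used by the colocalization null: an exact pixel
#' permutation, no resampling. Applying it four times is the identity.
#'
#' @param m Square numeric matrix.
#' @return The rotated matrix.
#' @export
rotate90 <- function(m) {
  if (nrow(m) != ncol(m))
    abort("rotate90 requires a square raster", class = "fiberlayer_invalid_input")
  t(m[nrow(m):1, , drop = FALSE])
}

# deterministic sub-seed derivation: one user seed fans out to independent
# stage/channel streams without ever reusing a stream
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

# 16-bit grayscale TIFF round trip on the 0..65535 count scale
write_image_tiff <- function(img, path) {
  px <- pmin(pmax(img$pixels, 0), 65535) / 65535
  tiff::writeTIFF(px, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

read_image_tiff <- function(path, resolution, channel = "unknown") {
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  calibrated_image(round(px * 65535), resolution, channel)
}

write_mask_tiff <- function(mask, path) {
  tiff::writeTIFF(mask$labels / 255, path, bits.per.sample = 8L,
                  compression = "none")
  invisible(path)
}

read_mask_tiff <- function(path, resolution, legend = c(GCL = 1L, EPL = 2L, GL = 3L)) {
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  layer_mask(matrix(as.integer(round(px * 255)), nrow(px), ncol(px)),
             resolution, legend)
}
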