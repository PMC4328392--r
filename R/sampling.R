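# Layer-stratified ROI placement: square sampling windows drawn from the
# anatomy mask alone (never the signal channel), at most one per angular
# sector about the layer centroid.

#' Sampling configuration
#'
#' Defaults encode the stratified design: ten 120 x 120 um samples per layer,
#' one placed uniformly at random within each 36-degree sector.
#'
#' @param roi_side_um ROI side in um (default 120).
#' @param n_per_layer Number of ROIs per layer (default 10).
#' @param sector_deg Angular sector width in degrees (default 36;
#'   `n_per_layer * sector_deg` must be 360).
#' @param max_attempts Attempt cap for rejection-based generators (default
#'   1000; ROI placement itself enumerates candidates exactly).
#' @param seed Integer seed for the uniform candidate draws.
#' @return A validated list.
#' @export
sampling_config <- function(roi_side_um = 120, n_per_layer = 10L,
                            sector_deg = 36, max_attempts = 1000L, seed = 1L) {
  if (roi_side_um <= 0) abort("roi_side_um must be > 0",
                              class = "fiberlayer_invalid_parameter")
  if (n_per_layer * sector_deg != 360)
    abort("n_per_layer * sector_deg must equal 360",
          class = "fiberlayer_invalid_parameter")
  if (max_attempts < 1) abort("max_attempts must be >= 1",
                              class = "fiberlayer_invalid_parameter")
  list(roi_side_um = roi_side_um, n_per_layer = as.integer(n_per_layer),
       sector_deg = sector_deg, max_attempts = as.integer(max_attempts),
       seed = as.integer(seed))
}

#' Place layer-stratified square ROIs
#'
#' For one layer: the centroid of the layer's pixels defines the angular
#' origin (0 degrees at "3 o'clock", increasing counter-clockwise); each
#' 36-degree sector contributes at most one ROI whose centre is drawn
#' uniformly from all pixels of that sector from which the full square
#' footprint fits inside the layer. Candidate centres are enumerated exactly
#' (binary erosion of the layer mask by the footprint), so a sector fails only
#' when it genuinely admits no placement; failed sectors are reported in the
#' `failed_sectors` attribute. The ROI side in px is rounded to the nearest
#' even integer so the 90-degree rotation control maps the square onto itself.
#'
#' Placement uses only the layer mask — the signature makes it impossible to
#' condition on signal intensities.
#'
#' @param mask A [layer_mask()].
#' @param layer Layer name (or label integer) to sample.
#' @param cfg A [sampling_config()].
#' @return Tibble with one row per placed ROI: `layer`, `sector`,
#'   `center_row`, `center_col`, `row0`, `col0` (1-based top-left), `side_px`;
#'   attribute `failed_sectors` lists sectors without any valid candidate.
#' @export
place_rois <- function(mask, layer, cfg = sampling_config()) {
  stopifnot(inherits(mask, "layer_mask"))
  lab <- layer_label(mask, layer)
  if (!any(mask$labels == lab))
    abort(sprintf("layer '%s' absent from mask", as.character(layer)),
          class = "fiberlayer_missing_layer")
  side_px <- um_to_px(cfg$roi_side_um, mask$resolution, even = TRUE)
  nr <- nrow(mask$labels)
  in_layer <- mask$labels == lab
  valid <- erode_square_cpp(in_layer, side_px)
  cand <- which(valid)
  if (length(cand) == 0L)
    abort("no valid ROI candidate centres in any sector",
          class = "fiberlayer_placement_failure")
  # angle about the layer centroid; origin +column ("3 o'clock"), CCW positive
  lay_idx <- which(in_layer)
  rows_l <- ((lay_idx - 1) %% nr) + 1
  cols_l <- ((lay_idx - 1) %/% nr) + 1
  cen <- c(mean(rows_l), mean(cols_l))
  rows <- ((cand - 1) %% nr) + 1
  cols <- ((cand - 1) %/% nr) + 1
  ang <- (atan2(-(rows - cen[1]), cols - cen[2]) * 180 / pi) %% 360
  sector <- pmin(floor(ang / cfg$sector_deg), cfg$n_per_layer - 1L)
  rois <- list(); failed <- integer(0)
  withr::with_seed(derive_seed(cfg$seed, "rois", lab), {
    for (s in 0:(cfg$n_per_layer - 1L)) {
      pool <- which(sector == s)
      if (length(pool) == 0L) { failed <- c(failed, s); next }
      pick <- pool[sample.int(length(pool), 1L)]
      cr <- rows[pick]; cc <- cols[pick]
      rois[[length(rois) + 1L]] <- tibble(
        layer = layer_name(mask, lab), sector = s,
        center_row = cr, center_col = cc,
        row0 = cr - side_px %/% 2L, col0 = cc - side_px %/% 2L,
        side_px = side_px)
    }
  })
  if (length(rois) == 0L)
    abort("ROI placement failed in every sector (layer band narrower than the ROI side?)",
          class = "fiberlayer_placement_failure")
  out <- dplyr::bind_rows(rois)
  attr(out, "failed_sectors") <- failed
  out
}

#' Extract sample rasters for a set of ROIs
#'
#' @param img A [calibrated_image()] on the same grid as the mask the ROIs
#'   were placed on.
#' @param rois Tibble from [place_rois()] (rows may be pooled across layers).
#' @return The `rois` tibble with a `pixels` list-column of
#'   `side_px x side_px` matrices, in ROI order.
#' @export
extract_samples <- function(img, rois) {
  stopifnot(inherits(img, "calibrated_image"))
  nr <- nrow(img$pixels); nc <- ncol(img$pixels)
  if (any(rois$row0 < 1 | rois$col0 < 1 |
            rois$row0 + rois$side_px - 1 > nr |
            rois$col0 + rois$side_px - 1 > nc))
    abort("ROI outside image bounds: image and mask grids do not match",
          class = "fiberlayer_calibration_mismatch")
  px <- purrr::pmap(list(rois$row0, rois$col0, rois$side_px),
                    function(r0, c0, s)
                      img$pixels[r0:(r0 + s - 1L), c0:(c0 + s - 1L)])
  dplyr::mutate(rois, pixels = px)
}

#' Verify ROI purity against the mask
#'
#' Asserts pixel-wise that every ROI footprint carries only its own layer's
#' label. Used in tests and reports.
#'
#' @param mask A [layer_mask()].
#' @param rois Tibble from [place_rois()].
#' @return `TRUE` invisibly; aborts on violation.
#' @export
check_roi_purity <- function(mask, rois) {
  for (i in seq_len(nrow(rois))) {
    r <- rois[i, ]
    lab <- layer_label(mask, r$layer)
    block <- mask$labels[r$row0:(r$row0 + r$side_px - 1L),
                         r$col0:(r$col0 + r$side_px - 1L)]
    if (!all(block == lab))
      abort(sprintf("ROI %d (layer %s, sector %d) crosses a layer boundary",
                    i, r$layer, r$sector), class = "fiberlayer_roi_impure")
  }
  invisible(TRUE)
}
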