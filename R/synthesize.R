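# Synthetic laminar-section generator: concentric layer masks, a nuclei
# channel, constant-width curvilinear fibers at controlled per-layer area
# density, channel pairs with a known shared-fiber fraction, point-marker sets
# with unambiguous colocalization truth, and an additive noise model
# (smooth background + Gaussian sensor noise + strictly single-pixel
# impulses). Every quantity downstream stages estimate is known exactly here.

#' Section geometry for the synthetic generator
#'
#' Describes a coronal-section-like concentric laminar layout: a central
#' granule-cell disc (GCL), an external plexiform annulus (EPL) and an outer
#' glomerular annulus (GL), on a pixel raster with a px/um calibration.
#'
#' @param layer_radii Strictly increasing outer boundary radii in um for the
#'   layers from inside out, named; default `c(GCL = 250, EPL = 450, GL = 650)`
#'   — a compact section that preserves the layer topology and leaves every
#'   band wide enough for a 120 um sampling square.
#' @param resolution Pixels per um (default 7, the calibration assumed
#'   throughout).
#' @param image_shape Optional `(rows, cols)`; by default just large enough to
#'   hold the outer layer plus `margin_um`.
#' @param center Optional centre `(row, col)` in px; default the raster centre.
#' @param margin_um Background margin outside the outer layer (default 5).
#' @return A `section_geometry` list.
#' @export
section_geometry <- function(layer_radii = c(GCL = 250, EPL = 450, GL = 650),
                             resolution = 7, image_shape = NULL, center = NULL,
                             margin_um = 5) {
  if (is.null(names(layer_radii)))
    names(layer_radii) <- paste0("L", seq_along(layer_radii))
  if (any(diff(layer_radii) <= 0) || any(layer_radii <= 0))
    abort("layer_radii must be positive and strictly increasing",
          class = "fiberlayer_invalid_geometry")
  if (resolution <= 0) abort("resolution must be > 0",
                             class = "fiberlayer_invalid_geometry")
  r_px <- max(layer_radii) * resolution
  if (is.null(image_shape)) {
    side <- 2L * ceiling(r_px + margin_um * resolution) + 1L
    image_shape <- c(side, side)
  }
  image_shape <- as.integer(image_shape)
  if (is.null(center)) center <- (image_shape + 1) / 2
  fit <- min(center[1] - 1, image_shape[1] - center[1],
             center[2] - 1, image_shape[2] - center[2])
  if (r_px > fit)
    abort("outer layer radius does not fit inside the raster",
          class = "fiberlayer_invalid_geometry")
  structure(list(layer_radii = layer_radii, resolution = resolution,
                 image_shape = image_shape, center = center),
            class = "section_geometry")
}

#' Generate a layer mask and nuclei channel
#'
#' Builds the concentric layer-label raster for a geometry and a DAPI-like
#' nuclei channel: small bright discs, dense in the cell-rich GCL and GL and
#' sparse in the EPL, mirroring what delineates the layers in real sections.
#'
#' @param geometry A [section_geometry()].
#' @param seed Integer seed; output is bit-identical for identical inputs.
#' @param nuclei_per_100um2 Named per-layer nucleus counts per 100 um^2.
#'   Unnamed layers default to 0.
#' @param nuclei_radius_um,nuclei_amplitude Disc radius (um) and intensity.
#' @return A list with elements `mask` ([layer_mask()]) and `nuclei`
#'   ([calibrated_image()], channel `"DAPI"`).
#' @export
generate_section <- function(geometry, seed = 1L,
                             nuclei_per_100um2 = c(GCL = 0.6, EPL = 0.05, GL = 0.3),
                             nuclei_radius_um = 2.5, nuclei_amplitude = 8000) {
  stopifnot(inherits(geometry, "section_geometry"))
  res <- geometry$resolution
  nr <- geometry$image_shape[1]; nc <- geometry$image_shape[2]
  labels <- label_annuli_cpp(nr, nc, geometry$center[1], geometry$center[2],
                             geometry$layer_radii * res)
  legend <- stats::setNames(seq_along(geometry$layer_radii),
                            names(geometry$layer_radii))
  mask <- layer_mask(labels, res, legend)
  dapi <- matrix(0, nr, nc)
  withr::with_seed(derive_seed(seed, "nuclei"), {
    for (ly in names(legend)) {
      rate <- if (ly %in% names(nuclei_per_100um2)) nuclei_per_100um2[[ly]] else 0
      if (rate <= 0) next
      idx <- which(labels == legend[[ly]])
      n_nuc <- round(rate * length(idx) / (100 * res^2))
      if (n_nuc < 1) next
      at <- sample(idx, n_nuc, replace = TRUE)
      stamp_discs_cpp(dapi,
                      ((at - 1) %% nr) + 1 + runif(n_nuc, -0.5, 0.5),
                      ((at - 1) %/% nr) + 1 + runif(n_nuc, -0.5, 0.5),
                      nuclei_radius_um * res, nuclei_amplitude)
    }
  })
  list(mask = mask, nuclei = calibrated_image(dapi, res, "DAPI"))
}

#' Fiber-field specification
#'
#' Target per-layer signal area densities and the morphology of the synthetic
#' fibers: constant-width random-walk polylines, rasterized without
#' anti-aliasing so true signal area is an exact pixel count.
#'
#' @param per_layer_density Named vector of target densities, um^2 signal per
#'   100 um^2 of layer (the unit used for all density reporting).
#' @param fiber_width_um Stroke width (default 0.6 um, a thin axon at optical
#'   scale; at 7 px/um a 4 px stroke that survives 3x3 median filtering).
#' @param fiber_amplitude Stroke intensity (16-bit counts; default 12000).
#' @param step_length_um,n_steps,turn_sd Random-walk segment length (um),
#'   number of segments, and per-step heading change SD (radians). Defaults
#'   (1.2 um, 2 steps, 0.4 rad) give short fiber fragments of the size seen in
#'   a thin optical section.
#' @param tolerance Relative tolerance on the achieved density (default 0.1);
#'   only an unreachable target (packing limit) is an error — whole-fiber
#'   quantization in very small or very sparse layers is recorded honestly in
#'   the ground truth instead.
#' @param seed Integer seed.
#' @return A `fiber_field_spec` list.
#' @export
fiber_field_spec <- function(per_layer_density, fiber_width_um = 0.6,
                             fiber_amplitude = 12000, step_length_um = 1.2,
                             n_steps = 2, turn_sd = 0.4, tolerance = 0.1,
                             seed = 1L) {
  if (any(per_layer_density < 0) || is.null(names(per_layer_density)))
    abort("per_layer_density must be a named non-negative vector",
          class = "fiberlayer_invalid_input")
  if (fiber_width_um <= 0 || fiber_amplitude <= 0 || step_length_um <= 0 ||
      n_steps < 1 || turn_sd < 0 || tolerance <= 0)
    abort("invalid fiber field parameters", class = "fiberlayer_invalid_input")
  structure(list(per_layer_density = per_layer_density,
                 fiber_width_um = fiber_width_um,
                 fiber_amplitude = fiber_amplitude,
                 step_length_um = step_length_um, n_steps = n_steps,
                 turn_sd = turn_sd, tolerance = tolerance,
                 seed = as.integer(seed)),
            class = "fiber_field_spec")
}

# propose one random-walk polyline starting uniformly inside the layer;
# coordinates are fractional (row, col) px
propose_fiber <- function(layer_idx, nr, spec, res) {
  start <- sample(layer_idx, 1L)
  r <- ((start - 1) %% nr) + 1 + runif(1, -0.5, 0.5)
  c <- ((start - 1) %/% nr) + 1 + runif(1, -0.5, 0.5)
  theta <- runif(1, 0, 2 * pi)
  step <- spec$step_length_um * res
  pr <- numeric(spec$n_steps + 1); pc <- numeric(spec$n_steps + 1)
  pr[1] <- r; pc[1] <- c
  for (k in seq_len(spec$n_steps)) {
    theta <- theta + rnorm(1, 0, spec$turn_sd)
    pr[k + 1] <- pr[k] + step * sin(theta)
    pc[k + 1] <- pc[k] + step * cos(theta)
  }
  list(r = pr, c = pc)
}

# render fibers into one layer until the achieved pixel count is as close to
# the target as whole fibers allow
fill_layer <- function(mask, layer_lab, target_px, spec, painted_env) {
  nr <- nrow(mask$labels)
  layer_idx <- which(mask$labels == layer_lab)
  hw <- spec$fiber_width_um * mask$resolution / 2
  fibers <- list(); achieved <- 0L
  zero_rejects <- 0L; proposals <- 0L; quantized_stop <- FALSE
  # add whole fibers while each brings the count closer to the target; stop at
  # the closest whole-fiber count (never trim mid-fiber). Repeated proposals
  # that paint no new pixel mean the layer is saturated (packing limit).
  while (achieved < target_px && zero_rejects < 50L && proposals < 20000L) {
    proposals <- proposals + 1L
    fb <- propose_fiber(layer_idx, nr, spec, mask$resolution)
    px <- stroke_pixels_cpp(mask$labels, fb$r, fb$c, hw, layer_lab)
    px <- px[!(px %in% painted_env$idx)]
    npx <- length(px)
    if (npx == 0L) { zero_rejects <- zero_rejects + 1L; next }
    if (abs(achieved + npx - target_px) < target_px - achieved) {
      achieved <- achieved + npx
      painted_env$idx <- c(painted_env$idx, px)
      fibers[[length(fibers) + 1L]] <- c(fb, list(px = px))
      zero_rejects <- 0L
    } else { quantized_stop <- TRUE; break }
  }
  if (achieved < target_px * (1 - spec$tolerance) && !quantized_stop)
    abort(sprintf("could not reach target density in layer %s (packing limit)",
                  layer_name(mask, layer_lab)),
          class = "fiberlayer_generation_failure")
  list(fibers = fibers, fiber_px = achieved, layer_px = length(layer_idx))
}

#' Generate one fiber channel with exact ground truth
#'
#' Renders random-walk fibers clipped to each layer, adding whole fibers until
#' the rasterized area is as close to the per-layer target density as possible,
#' and records the achieved (not target) density as ground truth.
#'
#' @param mask A [layer_mask()].
#' @param spec A [fiber_field_spec()]; layers absent from
#'   `spec$per_layer_density` get no fibers.
#' @param channel Channel label for the output image.
#' @return A list: `image` (constant-amplitude fiber raster,
#'   [calibrated_image()]), `truth` (tibble with `layer`, `target_density`,
#'   `achieved_density` in um^2/100 um^2, `fiber_px`, `layer_px`, `n_fibers`),
#'   and `fibers` (per-layer polylines, reused by [generate_channel_pair()]).
#' @export
generate_fiber_channel <- function(mask, spec, channel = "EGFP") {
  stopifnot(inherits(mask, "layer_mask"), inherits(spec, "fiber_field_spec"))
  layers <- intersect(names(mask$legend), names(spec$per_layer_density))
  img <- matrix(0, nrow(mask$labels), ncol(mask$labels))
  truth <- list(); fibers <- list()
  for (ly in layers) {
    lab <- mask$legend[[ly]]
    layer_px <- sum(mask$labels == lab)
    target <- spec$per_layer_density[[ly]]
    target_px <- round(target / 100 * layer_px)
    painted <- new.env(parent = emptyenv()); painted$idx <- integer(0)
    fl <- if (target_px > 0) {
      withr::with_seed(derive_seed(spec$seed, "fibers", ly),
                       fill_layer(mask, lab, target_px, spec, painted))
    } else list(fibers = list(), fiber_px = 0L, layer_px = layer_px)
    for (fb in fl$fibers) img[fb$px] <- spec$fiber_amplitude
    fibers[[ly]] <- fl$fibers
    truth[[ly]] <- tibble(
      layer = ly, target_density = target,
      achieved_density = 100 * fl$fiber_px / fl$layer_px,
      fiber_px = fl$fiber_px, layer_px = fl$layer_px,
      n_fibers = length(fl$fibers))
  }
  list(image = calibrated_image(img, mask$resolution, channel),
       truth = dplyr::bind_rows(truth), fibers = fibers)
}

#' Noise model specification
#'
#' Additive image noise emulating what the despeckle and background-subtraction
#' stages remove: a smooth low-order polynomial background gradient, Gaussian
#' sensor noise, and strictly single-pixel bright impulses ("speckle"; enforced
#' isolated so a 3x3 median removes them exactly).
#'
#' @param gaussian_sd Sensor noise SD (counts; default 50).
#' @param speckle_rate Fraction of pixels hit by impulses (default 1e-4).
#' @param impulse_amplitude Impulse height (default 20000).
#' @param background_scale Peak amplitude of the smooth quadratic background
#'   field (default 300 counts).
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(gaussian_sd = 50, speckle_rate = 1e-4,
                       impulse_amplitude = 20000, background_scale = 300) {
  if (gaussian_sd < 0 || speckle_rate < 0 || speckle_rate > 1 ||
      impulse_amplitude < 0 || background_scale < 0)
    abort("invalid noise parameters", class = "fiberlayer_invalid_input")
  structure(list(gaussian_sd = gaussian_sd, speckle_rate = speckle_rate,
                 impulse_amplitude = impulse_amplitude,
                 background_scale = background_scale),
            class = "noise_spec")
}

#' Apply the noise model to an image
#'
#' @param img A [calibrated_image()].
#' @param noise A [noise_spec()].
#' @param seed Integer seed (noise is independent across channels when
#'   different seeds are supplied).
#' @return The noisy [calibrated_image()], clipped at 0.
#' @export
apply_noise <- function(img, noise, seed = 1L) {
  stopifnot(inherits(img, "calibrated_image"), inherits(noise, "noise_spec"))
  px <- img$pixels
  nr <- nrow(px); nc <- ncol(px); n <- nr * nc
  withr::with_seed(derive_seed(seed, "noise"), {
    if (noise$background_scale > 0) {
      a <- runif(6, -1, 1)
      u <- seq(-1, 1, length.out = nc)  # column coordinate
      v <- seq(-1, 1, length.out = nr)  # row coordinate
      fc <- a[1] + a[2] * u + a[5] * u^2       # column-only terms
      gv <- a[3] * v + a[6] * v^2              # row-only terms
      cross <- a[4] * outer(v, u)
      field <- cross + rep(fc, each = nr) + gv
      field <- (field - min(field)) / max(1e-12, diff(range(field)))
      px <- px + noise$background_scale * field
      rm(field, cross)
    }
    if (noise$gaussian_sd > 0) px <- px + rnorm(n, 0, noise$gaussian_sd)
    n_imp <- round(noise$speckle_rate * n)
    if (n_imp > 0) {
      cand <- sample.int(n, min(n, 3 * n_imp))
      kept <- integer(0); seen <- new.env(hash = TRUE, parent = emptyenv())
      for (id in cand) {
        if (length(kept) >= n_imp) break
        r <- ((id - 1) %% nr) + 1; c <- ((id - 1) %/% nr) + 1
        clash <- FALSE
        for (dc in -1:1) for (dr in -1:1) {
          key <- as.character(id + dr + dc * nr)
          if (!is.null(seen[[key]])) clash <- TRUE
        }
        if (!clash && r > 1 && r < nr && c > 1 && c < nc) {
          kept <- c(kept, id)
          assign(as.character(id), TRUE, envir = seen)
        }
      }
      px[kept] <- px[kept] + noise$impulse_amplitude
    }
  })
  px[px < 0] <- 0
  calibrated_image(px, img$resolution, img$channel)
}

#' Generate a two-channel pair with a known shared-fiber fraction
#'
#' A stated fraction of the fibers is rendered in both channels (the second
#' copy translated by a small Gaussian jitter); the remainder is split
#' alternately between channel-exclusive sets. Noise is applied independently
#' per channel. This is the substrate for the shift-correlation colocalization
#' assay.
#'
#' @param mask A [layer_mask()].
#' @param spec A [fiber_field_spec()].
#' @param shared_fraction Fraction of fibers present in both channels, 0..1.
#' @param jitter_sd_um SD of the per-fiber translation of the second copy
#'   (default 0.25 um, sub-resolution registration error).
#' @param noise A [noise_spec()], or `NULL` for clean rasters.
#' @param channels Labels for the two channels.
#' @return A list: `a`, `b` ([calibrated_image()]s) and `truth` (per-layer
#'   tibble with `n_fibers`, `n_shared`, `n_a_only`, `n_b_only`, plus the
#'   per-channel fiber-pixel counts).
#' @export
generate_channel_pair <- function(mask, spec, shared_fraction,
                                  jitter_sd_um = 0.25, noise = noise_spec(),
                                  channels = c("EGFP", "5-HT")) {
  if (shared_fraction < 0 || shared_fraction > 1)
    abort("shared_fraction must lie in [0, 1]", class = "fiberlayer_invalid_input")
  base <- generate_fiber_channel(mask, spec, channels[1])
  nr <- nrow(mask$labels)
  res <- mask$resolution
  hw <- spec$fiber_width_um * res / 2
  img_a <- matrix(0, nr, ncol(mask$labels))
  img_b <- matrix(0, nr, ncol(mask$labels))
  truth <- list()
  withr::with_seed(derive_seed(spec$seed, "pair"), {
    for (ly in names(base$fibers)) {
      fbs <- base$fibers[[ly]]
      lab <- mask$legend[[ly]]
      n <- length(fbs)
      n_shared <- round(shared_fraction * n)
      asgn <- rep("shared", n)
      if (n > n_shared)
        asgn[(n_shared + 1):n] <- rep(c("a", "b"), length.out = n - n_shared)
      for (k in seq_len(n)) {
        fb <- fbs[[k]]
        if (asgn[k] %in% c("shared", "a")) img_a[fb$px] <- spec$fiber_amplitude
        if (asgn[k] %in% c("shared", "b")) {
          dr <- rnorm(1, 0, jitter_sd_um * res)
          dc <- rnorm(1, 0, jitter_sd_um * res)
          if (asgn[k] == "shared" && jitter_sd_um > 0) {
            px <- stroke_pixels_cpp(mask$labels, fb$r + dr, fb$c + dc, hw, lab)
          } else if (asgn[k] == "shared") {
            px <- fb$px
          } else {
            px <- fb$px
          }
          img_b[px] <- spec$fiber_amplitude
        }
      }
      truth[[ly]] <- tibble(
        layer = ly, n_fibers = n, n_shared = n_shared,
        n_a_only = sum(asgn == "a"), n_b_only = sum(asgn == "b"))
    }
  })
  a <- calibrated_image(img_a, res, channels[1])
  b <- calibrated_image(img_b, res, channels[2])
  if (!is.null(noise)) {
    a <- apply_noise(a, noise, derive_seed(spec$seed, "noise-a"))
    b <- apply_noise(b, noise, derive_seed(spec$seed, "noise-b"))
  }
  list(a = a, b = b, truth = dplyr::bind_rows(truth))
}

#' Generate two point-marker sets with unambiguous colocalization truth
#'
#' `n_shared` pairs are placed as Gaussian-displaced partners; all remaining
#' (channel-exclusive) points and the pair sites are mutually separated by at
#' least `3 * cutoff_um`, so the true colocalization count is unambiguous for
#' any matching cutoff near the nominal one.
#'
#' @param region_um Extent `(width, height)` of the field in um.
#' @param n_a,n_b,n_shared Point counts per channel and number of true pairs
#'   (`n_shared <= min(n_a, n_b)`).
#' @param shared_offset_sd SD (um) of the within-pair displacement.
#' @param seed Integer seed.
#' @param cutoff_um Nominal matching cutoff the separation rule is anchored to
#'   (default 12 um).
#' @param max_attempts Rejection-sampling cap per point.
#' @return A list: `a`, `b` (tibbles `x_um`, `y_um`, `channel`) and `truth`
#'   (`n_shared`, `pair_distances_um`).
#' @export
generate_marker_sets <- function(region_um = c(400, 400), n_a, n_b, n_shared,
                                 shared_offset_sd = 1, seed = 1L,
                                 cutoff_um = 12, max_attempts = 1000) {
  if (n_shared > min(n_a, n_b))
    abort("n_shared must not exceed min(n_a, n_b)",
          class = "fiberlayer_invalid_input")
  if (shared_offset_sd < 0) abort("shared_offset_sd must be >= 0",
                                  class = "fiberlayer_invalid_input")
  sep <- 3 * cutoff_um
  n_sites <- n_shared + (n_a - n_shared) + (n_b - n_shared)
  withr::with_seed(derive_seed(seed, "markers"), {
    sites <- matrix(NA_real_, n_sites, 2)
    placed <- 0L
    for (k in seq_len(n_sites)) {
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        p <- c(runif(1, 0, region_um[1]), runif(1, 0, region_um[2]))
        if (placed == 0L ||
            min(sqrt(colSums((t(sites[seq_len(placed), , drop = FALSE]) - p)^2))) >= sep) {
          sites[k, ] <- p; placed <- placed + 1L; ok <- TRUE; break
        }
      }
      if (!ok)
        abort("region too small to honour the marker separation constraint",
              class = "fiberlayer_generation_failure")
    }
    ish <- seq_len(n_shared)
    off <- matrix(rnorm(2 * n_shared, 0, shared_offset_sd), ncol = 2)
    a_pts <- rbind(sites[ish, , drop = FALSE],
                   sites[n_shared + seq_len(n_a - n_shared), , drop = FALSE])
    b_pts <- rbind(sites[ish, , drop = FALSE] + off,
                   sites[n_shared + (n_a - n_shared) + seq_len(n_b - n_shared),
                         , drop = FALSE])
  })
  list(
    a = tibble(x_um = a_pts[, 1], y_um = a_pts[, 2], channel = "A"),
    b = tibble(x_um = b_pts[, 1], y_um = b_pts[, 2], channel = "B"),
    truth = list(n_shared = as.integer(n_shared),
                 pair_distances_um =
                   if (n_shared > 0) sqrt(rowSums(off^2)) else numeric(0)))
}
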