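# Orchestration of the two experiment shapes — layer-density profiling per
# injection group and the colocalization assay — over an on-disk cohort:
# synthesize writes a complete runnable fixture directory, density / coloc /
# associate consume it. Every run is deterministic given (config, seed) and
# writes a provenance YAML (config snapshot, package version, seeds; no
# timestamps, so reruns are bit-identical).

#' Run configuration
#'
#' One place for every tunable the pipeline stages take; all um<->px
#' conversions downstream use the single `resolution` here.
#'
#' @param resolution Pixels per um (default 7).
#' @param n_animals Cohort size for synthesis (default 3).
#' @param layer_radii Section geometry radii (um), see [section_geometry()].
#' @param per_layer_density Target densities (um^2/100 um^2); defaults to the
#'   serotonergic laminar profile `c(GL = 0.014, EPL = 0.0007, GCL = 0.0008)`.
#' @param fiber_width_um Synthetic fiber stroke width in um (default 0.6;
#'   coarse calibrations need a width of at least 2 px / resolution so the
#'   despeckle stage does not erase the strokes).
#' @param preprocess A [preprocess_config()].
#' @param sampling A [sampling_config()].
#' @param k Threshold multiplier (default 6).
#' @param max_shift Shift-correlation range in px (default 50).
#' @param cutoff_um Marker-matching cutoff (default 12).
#' @param shared_fraction Shared-fiber fraction for coloc fixtures (default
#'   0.8).
#' @param n_coloc_samples Channel-pair samples for the coloc assay (default
#'   10).
#' @param coloc_side_um Side of the square coloc sample field in um (default
#'   90).
#' @param coloc_density Fiber density of the coloc field (default 0.3
#'   um^2/100 um^2, a densely innervated glomerular field).
#' @param count_pseudocount,density_pseudocount Association stabilizers.
#' @param noise A [noise_spec()] or `NULL`.
#' @param seed Integer master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(resolution = 7, n_animals = 3L,
                       layer_radii = c(GCL = 250, EPL = 450, GL = 650),
                       per_layer_density = c(GL = 0.014, EPL = 0.0007, GCL = 0.0008),
                       fiber_width_um = 0.6,
                       preprocess = preprocess_config(),
                       sampling = sampling_config(),
                       k = 6, max_shift = 50L, cutoff_um = 12,
                       shared_fraction = 0.8, n_coloc_samples = 10L,
                       coloc_side_um = 90, coloc_density = 0.3,
                       count_pseudocount = 1, density_pseudocount = 1e-4,
                       noise = noise_spec(), seed = 1L) {
  structure(list(resolution = resolution, n_animals = as.integer(n_animals),
                 layer_radii = layer_radii,
                 per_layer_density = per_layer_density,
                 fiber_width_um = fiber_width_um,
                 preprocess = preprocess, sampling = sampling, k = k,
                 max_shift = as.integer(max_shift), cutoff_um = cutoff_um,
                 shared_fraction = shared_fraction,
                 n_coloc_samples = as.integer(n_coloc_samples),
                 coloc_side_um = coloc_side_um, coloc_density = coloc_density,
                 count_pseudocount = count_pseudocount,
                 density_pseudocount = density_pseudocount,
                 noise = noise, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Scalar fields override the [run_config()] defaults; nested `preprocess`,
#' `sampling` and `noise` blocks override those constructors' defaults.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("preprocess", "sampling", "noise"))]
  for (nm in c("layer_radii", "per_layer_density"))
    if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
  if (!is.null(y$preprocess))
    args$preprocess <- do.call(preprocess_config, y$preprocess)
  if (!is.null(y$sampling)) args$sampling <- do.call(sampling_config, y$sampling)
  if (!is.null(y$noise)) args$noise <- do.call(noise_spec, y$noise)
  do.call(run_config, args)
}

write_provenance <- function(cfg, out_dir, stage) {
  prov <- list(stage = stage,
               package = "fiberlayer",
               version = as.character(utils::packageVersion("fiberlayer")),
               seed = cfg$seed,
               config = serialize_config(cfg))
  yaml::write_yaml(prov, file.path(out_dir, paste0("provenance_", stage, ".yaml")))
}

serialize_config <- function(cfg) {
  c(cfg[c("resolution", "n_animals", "fiber_width_um", "k", "max_shift", "cutoff_um",
          "shared_fraction", "n_coloc_samples", "coloc_side_um",
          "coloc_density", "count_pseudocount", "density_pseudocount",
          "seed")],
    list(layer_radii = as.list(cfg$layer_radii),
         per_layer_density = as.list(cfg$per_layer_density),
         preprocess = cfg$preprocess, sampling = cfg$sampling,
         noise = if (is.null(cfg$noise)) NULL else unclass(cfg$noise)))
}

#' Synthesize a complete runnable cohort on disk
#'
#' Writes, per animal: the layer mask (8-bit label TIFF + YAML legend), the
#' nuclei and signal channels (16-bit TIFF), and the fiber ground truth (CSV).
#' Also writes the channel-pair samples for the coloc assay, a marker-set
#' pair, the mixed-injection cohort summary (graded MRN:DRN composition), and
#' a provenance YAML. Deterministic: identical (config, seed) gives
#' bit-identical files.
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
run_synthesize <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  geom <- section_geometry(cfg$layer_radii, cfg$resolution)
  for (i in seq_len(cfg$n_animals)) {
    ad <- file.path(out_dir, sprintf("animal_%02d", i))
    dir.create(ad, showWarnings = FALSE)
    sec <- generate_section(geom, seed = derive_seed(cfg$seed, "animal", i))
    spec <- fiber_field_spec(cfg$per_layer_density,
                             fiber_width_um = cfg$fiber_width_um,
                             seed = derive_seed(cfg$seed, "fibers", i))
    ch <- generate_fiber_channel(sec$mask, spec)
    img <- if (is.null(cfg$noise)) ch$image else
      apply_noise(ch$image, cfg$noise, derive_seed(cfg$seed, "img-noise", i))
    write_mask_tiff(sec$mask, file.path(ad, "mask.tif"))
    yaml::write_yaml(as.list(sec$mask$legend), file.path(ad, "legend.yaml"))
    write_image_tiff(sec$nuclei, file.path(ad, "dapi.tif"))
    write_image_tiff(img, file.path(ad, "signal.tif"))
    write.csv(ch$truth, file.path(ad, "truth.csv"), row.names = FALSE)
    rm(sec, ch, img); gc(verbose = FALSE)
  }
  # channel-pair samples for the coloc assay: one flat single-layer field each
  cd <- file.path(out_dir, "coloc"); dir.create(cd, showWarnings = FALSE)
  side <- um_to_px(cfg$coloc_side_um, cfg$resolution, even = TRUE)
  flat <- layer_mask(matrix(1L, side, side), cfg$resolution, c(field = 1L))
  pair_truth <- list()
  for (s in seq_len(cfg$n_coloc_samples)) {
    spec <- fiber_field_spec(c(field = cfg$coloc_density),
                             fiber_width_um = cfg$fiber_width_um,
                             seed = derive_seed(cfg$seed, "coloc", s))
    pr <- generate_channel_pair(flat, spec, cfg$shared_fraction,
                                noise = cfg$noise)
    write_image_tiff(pr$a, file.path(cd, sprintf("sample_%02d_a.tif", s)))
    write_image_tiff(pr$b, file.path(cd, sprintf("sample_%02d_b.tif", s)))
    pair_truth[[s]] <- dplyr::mutate(pr$truth, sample = s, .before = 1)
  }
  write.csv(dplyr::bind_rows(pair_truth), file.path(cd, "truth.csv"),
            row.names = FALSE)
  # marker sets
  md <- file.path(out_dir, "markers"); dir.create(md, showWarnings = FALSE)
  mk <- generate_marker_sets(region_um = c(400, 400), n_a = 20, n_b = 18,
                             n_shared = 8, shared_offset_sd = 1,
                             seed = derive_seed(cfg$seed, "markers"),
                             cutoff_um = cfg$cutoff_um)
  write.csv(mk$a, file.path(md, "markers_a.csv"), row.names = FALSE)
  write.csv(mk$b, file.path(md, "markers_b.csv"), row.names = FALSE)
  write.csv(tibble(n_shared = mk$truth$n_shared),
            file.path(md, "truth.csv"), row.names = FALSE)
  # mixed-injection cohort summary (synthetic; graded MRN:DRN composition)
  cohort <- simulate_association_cohort(seed = derive_seed(cfg$seed, "assoc"))
  write.csv(cohort, file.path(out_dir, "cohort_summary.csv"), row.names = FALSE)
  write_provenance(cfg, out_dir, "synthesize")
  invisible(out_dir)
}

#' Run the layer-density profiling pipeline over a cohort directory
#'
#' For every `animal_*` directory: read mask and signal channel, place ten
#' 120 um ROIs per layer from the mask alone, extract and preprocess the
#' samples (despeckle, rolling ball), fit the pooled mean + k SD threshold per
#' animal, and compute per-layer densities; then the across-layer ANOVA and
#' Tukey HSD over animals. Persists ROIs, densities and the stats report.
#'
#' @param cfg A [run_config()].
#' @param in_dir Cohort directory (from [run_synthesize()] or equivalent
#'   layout).
#' @param out_dir Output directory (default `in_dir`).
#' @return A list: `densities` tibble and `comparison`
#'   ([compare_layers()] result, `NULL` if fewer than 2 animals).
#' @export
run_density <- function(cfg, in_dir, out_dir = in_dir) {
  stopifnot(inherits(cfg, "run_config"))
  animals <- sort(list.dirs(in_dir, recursive = FALSE))
  animals <- animals[grepl("animal_", basename(animals))]
  if (length(animals) == 0L)
    abort("no animal_* directories found", class = "fiberlayer_no_data")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  all_dens <- list(); all_rois <- list()
  for (ad in animals) {
    an <- basename(ad)
    legend <- unlist(yaml::read_yaml(file.path(ad, "legend.yaml")))
    mask <- read_mask_tiff(file.path(ad, "mask.tif"), cfg$resolution, legend)
    img <- read_image_tiff(file.path(ad, "signal.tif"), cfg$resolution, "EGFP")
    scfg <- cfg$sampling
    scfg$seed <- derive_seed(cfg$seed, "rois", an)
    rois <- dplyr::bind_rows(lapply(names(legend), function(ly)
      place_rois(mask, ly, scfg)))
    samples <- extract_samples(img, rois)
    samples$pixels <- lapply(samples$pixels, function(m)
      preprocess_sample(calibrated_image(m, cfg$resolution), cfg$preprocess)$pixels)
    model <- fit_threshold(samples, k = cfg$k)
    all_dens[[an]] <- estimate_densities(samples, model, cfg$resolution, an)
    all_rois[[an]] <- dplyr::mutate(rois, animal = an, .before = 1)
    rm(mask, img, samples); gc(verbose = FALSE)
  }
  densities <- dplyr::bind_rows(all_dens)
  write.csv(dplyr::bind_rows(all_rois), file.path(out_dir, "rois.csv"),
            row.names = FALSE)
  write.csv(densities, file.path(out_dir, "densities.csv"), row.names = FALSE)
  comparison <- NULL
  if (length(animals) >= 2L) {
    comparison <- compare_layers(densities)
    write.csv(tidy(comparison), file.path(out_dir, "tukey.csv"),
              row.names = FALSE)
    write.csv(glance(comparison), file.path(out_dir, "anova.csv"),
              row.names = FALSE)
    writeLines(utils::capture.output(print(comparison)),
               file.path(out_dir, "density_report.txt"))
  }
  write_provenance(cfg, out_dir, "density")
  list(densities = densities, comparison = comparison)
}

#' Run the colocalization assay over a cohort directory
#'
#' Reads the channel-pair samples, computes the shift-correlation curve and
#' its rotated-control counterpart per sample (on preprocessed rasters), and
#' the paired test of peak r against the control. Persists curves and report.
#'
#' @param cfg A [run_config()].
#' @param in_dir Cohort directory containing `coloc/sample_*_{a,b}.tif`.
#' @param out_dir Output directory (default `in_dir`).
#' @return A list: `curves` (long tibble `sample`, `dx`, `r_test`,
#'   `r_control`) and `test` ([coloc_test()] result).
#' @export
run_coloc <- function(cfg, in_dir, out_dir = in_dir) {
  stopifnot(inherits(cfg, "run_config"))
  cd <- file.path(in_dir, "coloc")
  fa <- sort(Sys.glob(file.path(cd, "sample_*_a.tif")))
  if (length(fa) == 0L)
    abort("no coloc samples found", class = "fiberlayer_no_data")
  fb <- sub("_a\\.tif$", "_b.tif", fa)
  if (!all(file.exists(fb)))
    abort("missing second channel for some coloc samples",
          class = "fiberlayer_invalid_input")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list(); long <- list()
  for (i in seq_along(fa)) {
    a <- preprocess_sample(read_image_tiff(fa[i], cfg$resolution, "A"),
                           cfg$preprocess)
    b <- preprocess_sample(read_image_tiff(fb[i], cfg$resolution, "B"),
                           cfg$preprocess)
    test <- shift_correlation(a, b, cfg$max_shift)
    ctrl <- rotated_control(a, b, cfg$max_shift)
    rows[[i]] <- tibble(test = list(test), control = list(ctrl))
    long[[i]] <- tibble(sample = i, dx = test$dx, r_test = test$r,
                        r_control = ctrl$r)
  }
  curves <- dplyr::bind_rows(long)
  res <- coloc_test(dplyr::bind_rows(rows))
  write.csv(curves, file.path(out_dir, "shift_curves.csv"), row.names = FALSE)
  write.csv(glance(res), file.path(out_dir, "coloc_report.csv"),
            row.names = FALSE)
  writeLines(utils::capture.output(print(res)),
             file.path(out_dir, "coloc_report.txt"))
  write_provenance(cfg, out_dir, "coloc")
  list(curves = curves, test = res)
}

#' Run the infection-vs-projection association over a cohort summary
#'
#' @param cfg A [run_config()].
#' @param in_dir Directory containing `cohort_summary.csv` (columns `animal`,
#'   `injection_target`, `n_drn`, `n_mrn`, `d_gl`, `d_gcl`).
#' @param out_dir Output directory (default `in_dir`).
#' @return The [correlate_composition()] result.
#' @export
run_associate <- function(cfg, in_dir, out_dir = in_dir) {
  stopifnot(inherits(cfg, "run_config"))
  path <- file.path(in_dir, "cohort_summary.csv")
  if (!file.exists(path))
    abort("cohort_summary.csv not found", class = "fiberlayer_no_data")
  summaries <- as_tibble(read.csv(path))
  res <- correlate_composition(summaries, cfg$count_pseudocount,
                               cfg$density_pseudocount)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(glance(res), file.path(out_dir, "association.csv"),
            row.names = FALSE)
  write.csv(dplyr::bind_cols(tidy(res), abundance_color(tidy(res)$abundance)),
            file.path(out_dir, "association_points.csv"), row.names = FALSE)
  write_provenance(cfg, out_dir, "associate")
  res
}
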