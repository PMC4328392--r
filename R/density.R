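# Per-animal global thresholding (pooled mean + k SD), layer-resolved signal
# density in um^2 / 100 um^2, and the across-layer group statistics (one-way
# ANOVA with the animal as unit, Tukey HSD post hoc).

#' Fit the per-animal global threshold
#'
#' Pools the pixels of all preprocessed samples of one animal (across layers)
#' and returns the pooled mean, pooled population SD, and the detection
#' threshold `mean + k * SD`. Signal is defined as pixels strictly above this
#' threshold; k = 6 by default.
#'
#' @param samples A tibble with a `pixels` list-column (from
#'   [extract_samples()], after [preprocess_sample()]), or a plain list of
#'   numeric matrices.
#' @param k Threshold multiplier (default 6).
#' @return A `threshold_model` list: `global_mean`, `global_sd`, `k`,
#'   `threshold`, `n_pixels`.
#' @export
fit_threshold <- function(samples, k = 6) {
  px <- sample_list(samples)
  if (length(px) == 0L)
    abort("no samples supplied", class = "fiberlayer_no_data")
  n <- 0; s1 <- 0; s2 <- 0
  for (m in px) { n <- n + length(m); s1 <- s1 + sum(m); s2 <- s2 + sum(m^2) }
  mu <- s1 / n
  sdv <- sqrt(max(0, s2 / n - mu^2))  # population SD over the pooled pixels
  structure(list(global_mean = mu, global_sd = sdv, k = k,
                 threshold = mu + k * sdv, n_pixels = n),
            class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf("<threshold_model> mean %.4g, SD %.4g, k = %g -> threshold %.4g (%d px pooled)\n",
              x$global_mean, x$global_sd, x$k, x$threshold, x$n_pixels))
  invisible(x)
}

sample_list <- function(samples) {
  if (is.data.frame(samples)) {
    if (!"pixels" %in% names(samples))
      abort("samples tibble must carry a 'pixels' list-column",
            class = "fiberlayer_invalid_input")
    samples$pixels
  } else if (is.list(samples) && !is.data.frame(samples)) {
    samples
  } else abort("samples must be a tibble or list of matrices",
               class = "fiberlayer_invalid_input")
}

#' Detect signal pixels
#'
#' A pixel is signal iff its value is strictly above the model threshold
#' ("above" is strict; a pixel exactly at the threshold is background).
#'
#' @param sample Numeric matrix (one preprocessed sample raster).
#' @param model A [fit_threshold()] model fitted on the same animal's pooled
#'   samples.
#' @return Logical matrix of detections.
#' @export
detect_signal <- function(sample, model) {
  stopifnot(inherits(model, "threshold_model"))
  sample > model$threshold
}

#' Layer-resolved signal density
#'
#' Density is detected pixels over total pixels, times 100: the um^2
#' conversions of numerator and denominator cancel, so the value is directly
#' in um^2 of signal per 100 um^2 of tissue analysed. The calibration is
#' carried along for traceability.
#'
#' @param detections List of logical detection rasters (one animal, one
#'   layer).
#' @param resolution Pixels per um.
#' @param animal,layer Identifiers copied into the record.
#' @return One-row tibble: `animal`, `layer`, `detected_px`, `total_px`,
#'   `density` (um^2/100 um^2), `resolution`.
#' @export
layer_density <- function(detections, resolution, animal = NA_character_,
                          layer = NA_character_) {
  if (length(detections) == 0L)
    abort("no detection rasters supplied", class = "fiberlayer_no_data")
  det <- sum(vapply(detections, sum, numeric(1)))
  tot <- sum(vapply(detections, length, numeric(1)))
  if (tot == 0) abort("zero pixels analysed", class = "fiberlayer_no_data")
  tibble(animal = animal, layer = layer,
         detected_px = det, total_px = tot,
         density = 100 * det / tot, resolution = resolution)
}

#' Densities for all layers of one animal
#'
#' Convenience wrapper: preprocessed samples of one animal (tibble with
#' `layer` and `pixels` columns), one threshold model, one density record per
#' layer.
#'
#' @param samples Tibble with `layer` and `pixels` columns.
#' @param model A [fit_threshold()] model.
#' @param resolution Pixels per um.
#' @param animal Animal identifier.
#' @return Tibble of per-layer density records.
#' @export
estimate_densities <- function(samples, model, resolution,
                               animal = NA_character_) {
  stopifnot(is.data.frame(samples), all(c("layer", "pixels") %in% names(samples)))
  samples |>
    dplyr::group_by(.data$layer) |>
    dplyr::group_map(function(g, key) {
      dets <- lapply(g$pixels, detect_signal, model = model)
      layer_density(dets, resolution, animal = animal, layer = key$layer)
    }) |>
    dplyr::bind_rows()
}

#' Compare signal densities across layers
#'
#' One-way ANOVA of density on layer with the animal as the experimental unit
#' (one density per animal per layer), followed by Tukey HSD adjusted pairwise
#' comparisons, plus per-layer mean and SEM. When all groups are identical the
#' F statistic is reported as 0 with p = 1 (no between-group variation).
#'
#' @param records Tibble of density records with columns `animal`, `layer`,
#'   `density` (from [layer_density()] / [estimate_densities()]).
#' @return A `layer_comparison` object; see [tidy.layer_comparison()] and
#'   [glance.layer_comparison()].
#' @export
compare_layers <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("animal", "layer", "density") %in% names(records)))
  counts <- dplyr::count(records, .data$layer)
  if (nrow(counts) < 2L)
    abort("need at least two layers", class = "fiberlayer_degrees_of_freedom")
  if (any(counts$n < 2L))
    abort(sprintf("layer(s) with a single animal: %s",
                  paste(counts$layer[counts$n < 2], collapse = ", ")),
          class = "fiberlayer_degrees_of_freedom")
  dat <- data.frame(density = records$density, layer = factor(records$layer))
  fit <- aov(density ~ layer, data = dat)
  an <- summary(fit)[[1]]
  ssb <- an["layer", "Sum Sq"]
  if (isTRUE(all.equal(ssb, 0)) || !is.finite(an["layer", "F value"])) {
    f_stat <- 0; p_val <- 1
  } else {
    f_stat <- an["layer", "F value"]; p_val <- an["layer", "Pr(>F)"]
  }
  tk <- TukeyHSD(fit)$layer
  tukey <- tibble(contrast = rownames(tk), diff = tk[, "diff"],
                  lwr = tk[, "lwr"], upr = tk[, "upr"],
                  p_adj = tk[, "p adj"])
  per_layer <- records |>
    dplyr::group_by(.data$layer) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$density),
                     sem = sd(.data$density) / sqrt(dplyr::n()),
                     .groups = "drop")
  structure(list(f_statistic = f_stat, p_value = p_val,
                 df = unname(an[, "Df"]), tukey = tukey,
                 per_layer = per_layer, fit = fit),
            class = "layer_comparison")
}

#' @export
print.layer_comparison <- function(x, ...) {
  cat(sprintf("<layer_comparison> one-way ANOVA: F(%d, %d) = %.4g, p = %.3g\n",
              x$df[1], x$df[2], x$f_statistic, x$p_value))
  cat("per-layer mean +/- SEM (um^2/100 um^2):\n")
  print(as.data.frame(x$per_layer), row.names = FALSE)
  cat("Tukey HSD adjusted p-values:\n")
  print(as.data.frame(x$tukey[, c("contrast", "diff", "p_adj")]),
        row.names = FALSE)
  invisible(x)
}

#' @rdname compare_layers
#' @param x A `layer_comparison` object.
#' @param ... Unused.
#' @method tidy layer_comparison
#' @export
tidy.layer_comparison <- function(x, ...) x$tukey

#' @rdname compare_layers
#' @method glance layer_comparison
#' @export
glance.layer_comparison <- function(x, ...) {
  tibble(f_statistic = x$f_statistic, p_value = x$p_value,
         df_between = x$df[1], df_within = x$df[2])
}

#' Threshold-sensitivity sweep
#'
#' Recomputes per-layer densities over a range of threshold multipliers k, as
#' a robustness report on the (otherwise fixed) k = 6 cutoff.
#'
#' @param samples Tibble with `layer` and `pixels` columns (one animal).
#' @param resolution Pixels per um.
#' @param k_values Multipliers to sweep (default 4..8).
#' @param animal Animal identifier.
#' @return Tibble: `k`, plus the [estimate_densities()] columns.
#' @export
threshold_sensitivity <- function(samples, resolution, k_values = 4:8,
                                  animal = NA_character_) {
  purrr::map_dfr(k_values, function(k) {
    model <- fit_threshold(samples, k = k)
    dplyr::mutate(estimate_densities(samples, model, resolution, animal),
                  k = k, .before = 1)
  })
}
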