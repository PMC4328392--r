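# Pixel-level colocalization by shift correlation (Pearson r vs horizontal
# displacement, after van Steensel) with a 90-degree-rotated null pairing,
# and point-marker colocalization by one-to-one proximity matching.

#' Shift-correlation curve between two channels
#'
#' For every integer displacement dx in `-max_shift..max_shift`, channel `b`
#' is translated horizontally by dx (positive dx moves `b` toward larger
#' column indices) and the Pearson correlation with `a` is computed over the
#' overlapping region only — no zero padding, so r at large displacement is
#' not artificially damped. Genuine colocalization shows a distinct peak at
#' dx = 0. Vertical displacement (equivalent by symmetry) is available via
#' `axis = "row"`.
#'
#' @param a,b Numeric matrices (same square shape), or [calibrated_image()]s.
#' @param max_shift Maximum displacement in px (default 50; must be below
#'   half the side so the overlap never falls under 50%).
#' @param axis `"col"` (default) for horizontal displacement, `"row"` for
#'   vertical.
#' @return A `shift_corr` tibble with columns `dx`, `r` and attributes
#'   `peak_dx` (integer argmax of r; ties broken toward 0) and `peak_r`.
#' @export
shift_correlation <- function(a, b, max_shift = 50L, axis = c("col", "row")) {
  axis <- match.arg(axis)
  a <- as_pixels(a); b <- as_pixels(b)
  if (!identical(dim(a), dim(b)))
    abort("rasters must share a shape", class = "fiberlayer_invalid_input")
  if (axis == "row") { a <- t(a); b <- t(b) }
  n <- ncol(a)
  max_shift <- as.integer(max_shift)
  if (max_shift >= n / 2)
    abort("max_shift must be below half the raster side",
          class = "fiberlayer_invalid_input")
  if (sd(a) == 0 || sd(b) == 0)
    abort("correlation undefined for a constant raster",
          class = "fiberlayer_undefined_correlation")
  dx <- seq.int(-max_shift, max_shift)
  r <- vapply(dx, function(d) {
    if (d >= 0) {
      av <- a[, (1 + d):n, drop = FALSE]; bv <- b[, 1:(n - d), drop = FALSE]
    } else {
      av <- a[, 1:(n + d), drop = FALSE]; bv <- b[, (1 - d):n, drop = FALSE]
    }
    suppressWarnings(cor(as.vector(av), as.vector(bv)))
  }, numeric(1))
  out <- tibble(dx = dx, r = r)
  ord <- order(abs(dx), dx)
  pk <- ord[which.max(r[ord])]
  attr(out, "peak_dx") <- dx[pk]
  attr(out, "peak_r") <- r[pk]
  class(out) <- c("shift_corr", class(out))
  out
}

as_pixels <- function(x) {
  if (inherits(x, "calibrated_image")) x$pixels
  else if (is.matrix(x) && is.numeric(x)) x
  else abort("expected a matrix or calibrated_image",
             class = "fiberlayer_invalid_input")
}

#' Peak of a shift-correlation curve
#' @param curve A `shift_corr` tibble.
#' @return Named list `peak_dx`, `peak_r`.
#' @export
curve_peak <- function(curve) {
  list(peak_dx = attr(curve, "peak_dx"), peak_r = attr(curve, "peak_r"))
}

#' Rotated-image control curve
#'
#' The null pairing: channel `b` is rotated by 90 degrees (an exact pixel
#' permutation on the square, even-sided sample) before the shift correlation,
#' destroying true spatial correspondence while preserving image statistics.
#'
#' @inheritParams shift_correlation
#' @return A `shift_corr` tibble on the identical dx grid.
#' @export
rotated_control <- function(a, b, max_shift = 50L, axis = c("col", "row")) {
  b <- as_pixels(b)
  if (nrow(b) != ncol(b))
    abort("rotated control requires square rasters",
          class = "fiberlayer_invalid_input")
  shift_correlation(a, rotate90(b), max_shift = max_shift, axis = axis)
}

#' Colocalization test across samples
#'
#' Per sample: the integer displacement of the test-curve peak and the peak r
#' of both the test and the rotated-control curves. Across samples: mean and
#' SEM of the peak displacement, and a two-sided paired t-test of test peak r
#' against control peak r. Constant differences (zero variance) are flagged
#' `degenerate`; their p is reported at the machine-epsilon bound (or 1 when
#' the constant difference is 0).
#'
#' @param curves Tibble with one row per sample: list-columns `test` and
#'   `control` holding `shift_corr` curves (see [run_coloc()] for assembly),
#'   or columns `peak_dx`, `peak_r_test`, `peak_r_control`.
#' @return A `coloc_test` object; see [tidy.coloc_test()] /
#'   [glance.coloc_test()].
#' @export
coloc_test <- function(curves) {
  stopifnot(is.data.frame(curves))
  if (all(c("test", "control") %in% names(curves))) {
    peaks <- tibble(
      peak_dx = vapply(curves$test, function(cv) curve_peak(cv)$peak_dx, numeric(1)),
      peak_r_test = vapply(curves$test, function(cv) curve_peak(cv)$peak_r, numeric(1)),
      peak_r_control = vapply(curves$control, function(cv) curve_peak(cv)$peak_r, numeric(1)))
  } else if (all(c("peak_dx", "peak_r_test", "peak_r_control") %in% names(curves))) {
    peaks <- curves
  } else abort("curves must carry test/control curves or peak columns",
               class = "fiberlayer_invalid_input")
  n <- nrow(peaks)
  if (n < 2L)
    abort("need >= 2 samples for the paired test",
          class = "fiberlayer_degrees_of_freedom")
  d <- peaks$peak_r_test - peaks$peak_r_control
  degenerate <- isTRUE(all.equal(sd(d), 0))
  if (degenerate) {
    if (isTRUE(all.equal(mean(d), 0))) { t_stat <- 0; p_val <- 1 }
    else { t_stat <- sign(mean(d)) * Inf; p_val <- .Machine$double.eps }
  } else {
    tt <- t.test(peaks$peak_r_test, peaks$peak_r_control, paired = TRUE)
    t_stat <- unname(tt$statistic); p_val <- tt$p.value
  }
  structure(list(
    peaks = peaks, n = n,
    mean_peak_dx = mean(peaks$peak_dx),
    sem_peak_dx = sd(peaks$peak_dx) / sqrt(n),
    mean_diff = mean(d), t_statistic = t_stat, p_value = p_val,
    degenerate = degenerate), class = "coloc_test")
}

#' @export
print.coloc_test <- function(x, ...) {
  cat(sprintf("<coloc_test> n = %d samples; peak at %.3g +/- %.3g px\n",
              x$n, x$mean_peak_dx, x$sem_peak_dx))
  cat(sprintf("paired t vs rotated control: t = %.4g, p = %.3g%s\n",
              x$t_statistic, x$p_value,
              if (x$degenerate) " (degenerate: zero-variance differences)" else ""))
  invisible(x)
}

#' @rdname coloc_test
#' @param x A `coloc_test` object.
#' @param ... Unused.
#' @method tidy coloc_test
#' @export
tidy.coloc_test <- function(x, ...) x$peaks

#' @rdname coloc_test
#' @method glance coloc_test
#' @export
glance.coloc_test <- function(x, ...) {
  tibble(n = x$n, mean_peak_dx = x$mean_peak_dx, sem_peak_dx = x$sem_peak_dx,
         mean_diff = x$mean_diff, t_statistic = x$t_statistic,
         p_value = x$p_value, degenerate = x$degenerate)
}

#' Match point markers across channels by proximity
#'
#' One-to-one matching: repeatedly pair the globally closest unmatched
#' cross-channel pair whose distance is at most the cutoff, until none
#' remains (12 um cutoff by default). Pairs for which either endpoint had
#' more than one in-cutoff candidate are flagged ambiguous.
#'
#' @param a,b Tibbles with `x_um`, `y_um` columns (marker coordinates in um).
#' @param cutoff_um Matching cutoff in um (> 0; default 12).
#' @return A `marker_match` object: `pairs` (tibble `index_a`, `index_b`,
#'   `distance_um`, `ambiguous`), `n_colocalized`, `unmatched_a`,
#'   `unmatched_b`.
#' @export
match_markers <- function(a, b, cutoff_um = 12) {
  if (cutoff_um <= 0) abort("cutoff must be > 0",
                            class = "fiberlayer_invalid_parameter")
  na <- nrow(a); nb <- nrow(b)
  pairs <- tibble(index_a = integer(0), index_b = integer(0),
                  distance_um = numeric(0), ambiguous = logical(0))
  if (na > 0 && nb > 0) {
    D <- sqrt(outer(a$x_um, b$x_um, `-`)^2 + outer(a$y_um, b$y_um, `-`)^2)
    n_cand_a <- rowSums(D <= cutoff_um)
    n_cand_b <- colSums(D <= cutoff_um)
    W <- D
    repeat {
      m <- which.min(W)
      if (length(m) == 0L || W[m] > cutoff_um) break
      ia <- ((m - 1) %% na) + 1L; ib <- ((m - 1) %/% na) + 1L
      pairs <- dplyr::bind_rows(pairs, tibble(
        index_a = ia, index_b = ib, distance_um = D[ia, ib],
        ambiguous = n_cand_a[ia] > 1 || n_cand_b[ib] > 1))
      W[ia, ] <- Inf; W[, ib] <- Inf
      if (all(!is.finite(W))) break
    }
  }
  structure(list(pairs = pairs, n_colocalized = nrow(pairs),
                 unmatched_a = na - nrow(pairs),
                 unmatched_b = nb - nrow(pairs),
                 cutoff_um = cutoff_um),
            class = "marker_match")
}

#' @export
print.marker_match <- function(x, ...) {
  cat(sprintf("<marker_match> %d colocalized (cutoff %g um); %d / %d unmatched in A / B\n",
              x$n_colocalized, x$cutoff_um, x$unmatched_a, x$unmatched_b))
  if (any(x$pairs$ambiguous))
    cat(sprintf("  %d pair(s) flagged ambiguous\n", sum(x$pairs$ambiguous)))
  invisible(x)
}

#' @rdname match_markers
#' @param x A `marker_match` object.
#' @param ... Unused.
#' @method tidy marker_match
#' @export
tidy.marker_match <- function(x, ...) x$pairs

#' @rdname match_markers
#' @method glance marker_match
#' @export
glance.marker_match <- function(x, ...) {
  tibble(n_colocalized = x$n_colocalized, unmatched_a = x$unmatched_a,
         unmatched_b = x$unmatched_b, cutoff_um = x$cutoff_um,
         n_ambiguous = sum(x$pairs$ambiguous))
}

#' Aggregate manual-count replicates
#'
#' Mean and SD of total and colocalized counts across repeat counts of the
#' same material (manual counting repeated to account for manual error). With
#' a single replicate the SD is reported absent (`NA`).
#'
#' @param counts Tibble with one row per replicate: `total`, `colocalized`
#'   (a list of [match_markers()] results is also accepted, using
#'   `n_colocalized` and `n_colocalized + unmatched_a` as colocalized/total).
#' @return One-row tibble: `n_replicates`, `total_mean`, `total_sd`,
#'   `colocalized_mean`, `colocalized_sd`.
#' @export
aggregate_counts <- function(counts) {
  if (is.list(counts) && !is.data.frame(counts) &&
      all(vapply(counts, inherits, logical(1), "marker_match"))) {
    counts <- purrr::map_dfr(counts, function(m)
      tibble(total = m$n_colocalized + m$unmatched_a,
             colocalized = m$n_colocalized))
  }
  stopifnot(is.data.frame(counts),
            all(c("total", "colocalized") %in% names(counts)))
  if (nrow(counts) == 0L) abort("no replicates", class = "fiberlayer_no_data")
  n <- nrow(counts)
  tibble(n_replicates = n,
         total_mean = mean(counts$total),
         total_sd = if (n > 1) sd(counts$total) else NA_real_,
         colocalized_mean = mean(counts$colocalized),
         colocalized_sd = if (n > 1) sd(counts$colocalized) else NA_real_)
}
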