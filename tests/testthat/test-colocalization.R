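# Shift correlation, rotated null, paired test, and marker matching.

test_that("self-correlation peaks at exactly r(0) = 1", {
  withr::with_seed(1, a <- matrix(runif(100 * 100), 100, 100))
  cv <- shift_correlation(a, a, max_shift = 10)
  expect_equal(cv$r[cv$dx == 0], 1)
  pk <- curve_peak(cv)
  expect_equal(pk$peak_dx, 0L)
  expect_equal(pk$peak_r, 1)
  expect_true(all(cv$r >= -1 & cv$r <= 1))
  expect_identical(cv$dx, -10:10)
})

test_that("a known translation is recovered exactly for all shifts", {
  withr::with_seed(2, a <- matrix(runif(120 * 120), 120, 120))
  for (d in -10:10) {
    b <- matrix(0, 120, 120)
    if (d >= 0) b[, (1 + d):120] <- a[, 1:(120 - d)]
    else b[, 1:(120 + d)] <- a[, (1 - d):120]
    # b holds a translated by +d columns: the curve must peak at dx = -d
    pk <- curve_peak(shift_correlation(a, b, max_shift = 15))
    expect_equal(pk$peak_dx, -d)
  }
})

test_that("independent noise gives a flat near-zero curve", {
  withr::with_seed(3, {
    a <- matrix(rnorm(840 * 840), 840, 840)
    b <- matrix(rnorm(840 * 840), 840, 840)
  })
  cv <- shift_correlation(a, b, max_shift = 50)
  expect_lt(max(abs(cv$r)), 0.01)
})

test_that("constant rasters and bad shapes are rejected", {
  a <- matrix(1, 50, 50)
  withr::with_seed(1, b <- matrix(runif(2500), 50, 50))
  expect_error(shift_correlation(a, b, 5),
               class = "fiberlayer_undefined_correlation")
  expect_error(shift_correlation(b, b[, 1:40], 5),
               class = "fiberlayer_invalid_input")
  expect_error(shift_correlation(b, b, 25),
               class = "fiberlayer_invalid_input")
})

test_that("row-axis displacement mirrors column-axis displacement", {
  withr::with_seed(9, a <- matrix(runif(80 * 80), 80, 80))
  b <- matrix(0, 80, 80); b[(1 + 3):80, ] <- a[1:(80 - 3), ]
  pk <- curve_peak(shift_correlation(a, b, 10, axis = "row"))
  expect_equal(pk$peak_dx, -3)
})

test_that("rotation fixes rotation-invariant images and is of order four", {
  n <- 64
  cen <- (n + 1) / 2
  disc <- 1 * (sqrt(outer((seq_len(n) - cen)^2, (seq_len(n) - cen)^2, `+`)) < 20)
  cv <- rotated_control(disc, disc, max_shift = 10)
  expect_equal(cv$r[cv$dx == 0], 1)
  withr::with_seed(4, m <- matrix(runif(n * n), n, n))
  expect_identical(rotate90(rotate90(rotate90(rotate90(m)))), m)
  expect_error(rotated_control(m, matrix(0, 4, 5), 1),
               class = "fiberlayer_invalid_input")
})

test_that("colocalized pairs beat their rotated control; unshared do not", {
  mask <- make_field_mask(420, 7)
  spec <- fiber_field_spec(c(field = 0.3), seed = 21)
  pr <- generate_channel_pair(mask, spec, shared_fraction = 0.8)
  a <- preprocess_sample(pr$a); b <- preprocess_sample(pr$b)
  test <- shift_correlation(a, b, 50)
  ctrl <- rotated_control(a, b, 50)
  expect_gt(curve_peak(test)$peak_r, 0.5)
  expect_lt(curve_peak(ctrl)$peak_r, 0.1)
  expect_lte(abs(curve_peak(test)$peak_dx), 2)
})

test_that("the paired colocalization test behaves at its edges", {
  flat <- tibble::tibble(peak_dx = c(0, 0, 0),
                         peak_r_test = c(0.5, 0.6, 0.7),
                         peak_r_control = c(0.5, 0.6, 0.7))
  r0 <- coloc_test(flat)
  expect_equal(r0$t_statistic, 0)
  expect_equal(r0$p_value, 1)
  expect_true(r0$degenerate)
  const <- tibble::tibble(peak_dx = c(1, -1), peak_r_test = c(1, 1),
                          peak_r_control = c(0, 0))
  rc <- coloc_test(const)
  expect_true(rc$degenerate)
  expect_lte(rc$p_value, .Machine$double.eps)
  expect_error(coloc_test(flat[1, ]), class = "fiberlayer_degrees_of_freedom")
})

test_that("the paired test matches t.test on non-degenerate peaks", {
  withr::with_seed(6, {
    pk <- tibble::tibble(peak_dx = sample(-1:1, 8, TRUE),
                         peak_r_test = runif(8, 0.4, 0.9),
                         peak_r_control = runif(8, 0.0, 0.2))
  })
  res <- coloc_test(pk)
  ref <- t.test(pk$peak_r_test, pk$peak_r_control, paired = TRUE)
  expect_equal(res$t_statistic, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value)
  expect_equal(res$mean_peak_dx, mean(pk$peak_dx))
  expect_equal(res$sem_peak_dx, sd(pk$peak_dx) / sqrt(8))
})

test_that("marker matching applies the cutoff and the global-closest rule", {
  two <- function(d) match_markers(
    tibble::tibble(x_um = 0, y_um = 0),
    tibble::tibble(x_um = d, y_um = 0))$n_colocalized
  expect_equal(two(5), 1)
  expect_equal(two(13), 0)
  expect_equal(formals(match_markers)$cutoff_um, 12)
  a <- tibble::tibble(x_um = c(0, 10), y_um = c(0, 0))
  b <- tibble::tibble(x_um = 4, y_um = 0)
  m <- match_markers(a, b)
  expect_equal(m$pairs$index_a, 1L)  # global closest: 4 um beats 6 um
  expect_equal(m$pairs$distance_um, 4)
  expect_equal(m$unmatched_a, 1)
})

test_that("matching is symmetric in its arguments", {
  withr::with_seed(8, {
    for (i in 1:5) {
      a <- tibble::tibble(x_um = runif(6, 0, 50), y_um = runif(6, 0, 50))
      b <- tibble::tibble(x_um = runif(5, 0, 50), y_um = runif(5, 0, 50))
      mab <- match_markers(a, b, 12)
      mba <- match_markers(b, a, 12)
      expect_equal(mab$n_colocalized, mba$n_colocalized)
      ab <- with(mab$pairs, paste(index_a, index_b))
      ba <- with(mba$pairs, paste(index_b, index_a))
      expect_setequal(ab, ba)
    }
  })
})

test_that("greedy matching attains the enumerated optimum on small sets", {
  withr::with_seed(15, {
    for (i in 1:8) {
      a <- tibble::tibble(x_um = runif(4, 0, 40), y_um = runif(4, 0, 40))
      b <- tibble::tibble(x_um = runif(5, 0, 40), y_um = runif(5, 0, 40))
      m <- match_markers(a, b, 12)
      best <- oracle_match_count(a, b, 12)
      expect_lte(m$n_colocalized, best)
      if (!any(m$pairs$ambiguous)) {
        expect_equal(m$n_colocalized, best)
      } else {
        expect_gte(m$n_colocalized, best - 1L)  # greedy may drop one in a clash
      }
    }
  })
})

test_that("counts on unambiguous sets are invariant for cutoffs 10 to 14 um", {
  mk <- generate_marker_sets(c(500, 500), n_a = 15, n_b = 12, n_shared = 7,
                             shared_offset_sd = 1.5, seed = 31)
  counts <- vapply(c(10, 11, 12, 13, 14), function(cut)
    match_markers(mk$a, mk$b, cut)$n_colocalized, numeric(1))
  expect_true(all(counts == 7))
})

test_that("replicate count aggregation reports mean and SD", {
  agg <- aggregate_counts(tibble::tibble(total = c(300, 303, 306),
                                         colocalized = c(40, 43, 46)))
  expect_equal(agg$total_mean, 303)
  expect_equal(agg$total_sd, 3)
  expect_equal(agg$colocalized_mean, 43)
  one <- aggregate_counts(tibble::tibble(total = 300, colocalized = 12))
  expect_true(is.na(one$total_sd))
  eq <- aggregate_counts(tibble::tibble(total = c(5, 5), colocalized = c(2, 2)))
  expect_equal(eq$total_sd, 0)
})
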