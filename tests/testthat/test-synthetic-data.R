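# The generator is first-class: its ground truth must be exact, deterministic
# and independently recountable, because every downstream stage is judged
# against it.

test_that("section mask has concentric layers with the expected areas", {
  geom <- section_geometry(c(GCL = 300, EPL = 400, GL = 500), resolution = 2)
  sec <- generate_section(geom, seed = 1)
  labs <- sec$mask$labels
  expect_setequal(unique(as.vector(labs)), 0:3)
  # pixel count of each annulus matches the closed-form area within 1%
  res <- 2
  expected <- c(pi * (300 * res)^2,
                pi * ((400^2 - 300^2) * res^2),
                pi * ((500^2 - 400^2) * res^2))
  counts <- tabulate(labs + 1L, 4L)[2:4]
  expect_true(all(abs(counts - expected) / expected < 0.01))
})

test_that("section generation is bit-identical for identical seed", {
  geom <- section_geometry(c(GCL = 60, EPL = 100, GL = 140), resolution = 2)
  s1 <- generate_section(geom, seed = 7)
  s2 <- generate_section(geom, seed = 7)
  expect_identical(s1$mask$labels, s2$mask$labels)
  expect_identical(s1$nuclei$pixels, s2$nuclei$pixels)
  s3 <- generate_section(geom, seed = 8)
  expect_false(identical(s3$nuclei$pixels, s2$nuclei$pixels))
})

test_that("geometry that does not fit the raster is rejected", {
  expect_error(section_geometry(c(A = 100), resolution = 2,
                                image_shape = c(150, 150)),
               class = "fiberlayer_invalid_geometry")
  expect_error(section_geometry(c(A = 100, B = 90), resolution = 2),
               class = "fiberlayer_invalid_geometry")
})

test_that("fiber ground truth is an exact independent recount", {
  geom <- section_geometry(c(GCL = 60, EPL = 100, GL = 140), resolution = 3)
  mask <- generate_section(geom, seed = 1)$mask
  spec <- fiber_field_spec(c(GL = 0.5, EPL = 0.2, GCL = 0.3), seed = 5)
  ch <- generate_fiber_channel(mask, spec)
  for (ly in c("GCL", "EPL", "GL")) {
    lab <- mask$legend[[ly]]
    recount <- sum(ch$image$pixels > 0 & mask$labels == lab)
    row <- ch$truth[ch$truth$layer == ly, ]
    expect_identical(recount, as.integer(row$fiber_px))
    expect_equal(row$achieved_density, 100 * recount / sum(mask$labels == lab))
    expect_lt(abs(row$achieved_density - row$target_density) /
                row$target_density, spec$tolerance)
  }
})

test_that("zero target density yields a blank channel and zero truth", {
  mask <- make_field_mask(80, 3)
  ch <- generate_fiber_channel(mask, fiber_field_spec(c(field = 0), seed = 1))
  expect_true(all(ch$image$pixels == 0))
  expect_equal(ch$truth$achieved_density, 0)
  expect_equal(ch$truth$n_fibers, 0L)
})

test_that("doubling the target density doubles the achieved density", {
  mask <- make_field_mask(300, 3)
  d1 <- generate_fiber_channel(mask, fiber_field_spec(c(field = 0.25), seed = 3))
  d2 <- generate_fiber_channel(mask, fiber_field_spec(c(field = 0.5), seed = 3))
  ratio <- d2$truth$achieved_density / d1$truth$achieved_density
  expect_lt(abs(ratio - 2), 2 * 0.1 * 2)  # both ends carry the 10% tolerance
})

test_that("unreachable target density fails naming the layer", {
  mask <- make_field_mask(40, 3)
  expect_error(
    generate_fiber_channel(mask, fiber_field_spec(c(field = 150), seed = 1)),
    regexp = "field", class = "fiberlayer_generation_failure")
})

test_that("with all-zero noise every nonzero pixel is rendered structure", {
  geom <- section_geometry(c(GCL = 60, EPL = 100, GL = 140), resolution = 3)
  sec <- generate_section(geom, seed = 2)
  ch <- generate_fiber_channel(sec$mask, fiber_field_spec(c(GL = 0.4), seed = 2))
  # no noise applied: the fiber channel is exactly the rendered strokes
  expect_setequal(unique(as.vector(ch$image$pixels)), c(0, 12000))
  # nuclei channel: nonzero only where discs were stamped (positive multiples)
  expect_true(all(sec$nuclei$pixels %% 8000 == 0))
})

test_that("noise application is deterministic and clipped at zero", {
  img <- calibrated_image(matrix(100, 50, 50), 7)
  n1 <- apply_noise(img, noise_spec(gaussian_sd = 200), seed = 3)
  n2 <- apply_noise(img, noise_spec(gaussian_sd = 200), seed = 3)
  expect_identical(n1$pixels, n2$pixels)
  expect_gte(min(n1$pixels), 0)
})

test_that("speckle impulses are strictly isolated single pixels", {
  img <- calibrated_image(matrix(0, 200, 200), 7)
  ns <- noise_spec(gaussian_sd = 0, speckle_rate = 5e-3,
                   impulse_amplitude = 1000, background_scale = 0)
  out <- apply_noise(img, ns, seed = 11)$pixels
  hits <- which(out > 0, arr.ind = TRUE)
  expect_gt(nrow(hits), 50)
  d <- as.matrix(dist(hits))
  diag(d) <- Inf
  expect_true(all(d > 1.5))  # no impulse within the 8-neighbourhood of another
})

test_that("channel pair bookkeeping records shared and exclusive fibers", {
  mask <- make_field_mask(300, 3)
  spec <- fiber_field_spec(c(field = 0.4), seed = 9)
  pr <- generate_channel_pair(mask, spec, shared_fraction = 0.5, noise = NULL)
  expect_equal(pr$truth$n_shared, round(0.5 * pr$truth$n_fibers))
  expect_equal(pr$truth$n_shared + pr$truth$n_a_only + pr$truth$n_b_only,
               pr$truth$n_fibers)
  pr0 <- generate_channel_pair(mask, spec, shared_fraction = 0, noise = NULL)
  expect_equal(pr0$truth$n_shared, 0)
})

test_that("fully shared, unjittered, noiseless pair gives identical rasters", {
  mask <- make_field_mask(200, 3)
  spec <- fiber_field_spec(c(field = 0.4), seed = 4)
  pr <- generate_channel_pair(mask, spec, shared_fraction = 1,
                              jitter_sd_um = 0, noise = NULL)
  expect_identical(pr$a$pixels, pr$b$pixels)
})

test_that("marker generation honours pair and separation contracts", {
  mk <- generate_marker_sets(c(400, 400), n_a = 10, n_b = 10, n_shared = 10,
                             shared_offset_sd = 1, seed = 2)
  expect_equal(nrow(mk$a), 10)
  expect_equal(mk$truth$n_shared, 10)
  expect_true(all(mk$truth$pair_distances_um < 12))
  mk0 <- generate_marker_sets(c(500, 500), n_a = 8, n_b = 6, n_shared = 0,
                              seed = 3)
  m <- match_markers(mk0$a, mk0$b, 12)
  expect_equal(m$n_colocalized, 0)
  expect_error(generate_marker_sets(c(400, 400), 5, 5, 6, seed = 1),
               class = "fiberlayer_invalid_input")
  expect_error(generate_marker_sets(c(30, 30), 12, 12, 0, seed = 1),
               class = "fiberlayer_generation_failure")
})

test_that("pair offsets follow the expected Rayleigh distance scale", {
  # Monte-Carlo: with per-axis SD 2 um the pair distance is Rayleigh(2):
  # mean 2 * sqrt(pi / 2) ~ 2.51 um, and essentially always far below 12 um
  ds <- unlist(lapply(1:40, function(s)
    generate_marker_sets(c(2000, 2000), 25, 25, 25, shared_offset_sd = 2,
                         seed = s)$truth$pair_distances_um))
  expect_gt(length(ds), 900)
  expect_lt(abs(mean(ds) - 2 * sqrt(pi / 2)), 0.15)
  expect_gt(mean(ds < 12), 0.99)
})
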