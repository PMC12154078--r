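test_that("generators are bit-identical under a fixed seed", {
  f1 <- gen_fiber_image(fiber_field_spec(image_size = 96, n_fibers = 4, seed = 7))
  f2 <- gen_fiber_image(fiber_field_spec(image_size = 96, n_fibers = 4, seed = 7))
  expect_identical(f1$image, f2$image)
  expect_identical(f1$truth, f2$truth)
  t1 <- gen_calcium_trace(transient_spec(noise_sd = 0.05, seed = 3))
  t2 <- gen_calcium_trace(transient_spec(noise_sd = 0.05, seed = 3))
  expect_identical(t1$ratio, t2$ratio)
  w1 <- gen_wound_image(wound_field_spec(image_size = 96, gap_width = 30, seed = 5))
  w2 <- gen_wound_image(wound_field_spec(image_size = 96, gap_width = 30, seed = 5))
  expect_identical(w1$image, w2$image)
  p1 <- gen_plate_table(c(1, 2), c(0.1, 0.1), 3, seed = 9)
  p2 <- gen_plate_table(c(1, 2), c(0.1, 0.1), 3, seed = 9)
  expect_identical(p1$value, p2$value)
})

test_that("every generator output carries its ground-truth record", {
  f <- gen_fiber_image(fiber_field_spec(image_size = 96, n_fibers = 3, seed = 1))
  expect_equal(nrow(f$truth$fibers), 3)
  expect_length(f$truth$centerlines, 3)
  tr <- gen_calcium_trace(transient_spec(seed = 1))
  expect_named(tr$truth, c("baseline", "amplitude", "latency", "a", "b",
                           "duration", "area", "rising_velocity", "asymmetry"))
  w <- gen_wound_image(wound_field_spec(image_size = 96, gap_width = 30, seed = 1))
  expect_equal(w$truth$gap_width, 30)
  pt <- gen_plate_table(c(1, 2), c(0, 0), 2, seed = 1)
  expect_equal(attr(pt, "truth")$means, c(1, 2))
})

test_that("empty fiber field gives a blank background and zero downstream count", {
  f <- gen_fiber_image(fiber_field_spec(image_size = 96, n_fibers = 0,
                                        noise_sd = 0, seed = 1))
  expect_equal(nrow(f$truth$fibers), 0)
  # background gradient only: no pixel reaches fiber intensity
  expect_lt(max(f$image), 0.5)
  fs <- fiberscore(f$image, pixel_size = 0.25)
  expect_equal(fs$metrics$n_filaments, 0)
})

test_that("orientation concentration controls ground-truth polarity", {
  # near-infinite concentration: all orientations at the mode, polarity 1
  f <- gen_fiber_image(fiber_field_spec(image_size = 192, n_fibers = 6,
                                        orientation_concentration = 1e8, seed = 2))
  expect_equal(f$truth$polarity, 1, tolerance = 1e-6)
  expect_true(all(abs(f$truth$fibers$orientation - pi / 3) < 1e-3))
  # isotropic: polarity of 500 uniform axial orientations is small
  set.seed(11)
  th <- raxial_vonmises(500, 0, 0)
  dx <- mean(cos(2 * th)); dy <- mean(sin(2 * th))
  expect_lt(sqrt(dx^2 + dy^2), 0.1)
  expect_equal(orientation_polarity(th)$polarity, sqrt(dx^2 + dy^2))
})

test_that("triangular transient truth values follow closed forms", {
  tr <- gen_calcium_trace(transient_spec(baseline = 1, amplitude = 1, latency = 2,
                                         rise_time = 2, fall_time = 6, noise_sd = 0))
  expect_equal(tr$truth$area, 4)              # (a + b) * amplitude / 2
  expect_equal(tr$truth$rising_velocity, 0.5) # amplitude / a
  expect_equal(tr$truth$asymmetry, 3)         # b / a
  expect_equal(tr$truth$duration, 10)         # latency + a + b
})

test_that("wound truth is the constructed gap, independent of sparsity and angle", {
  for (ang in c(90, 60)) {
    w <- gen_wound_image(wound_field_spec(image_size = 128, gap_width = 40,
                                          gap_orientation = ang, seed = 1))
    expect_equal(w$truth$gap_width, 40)
  }
  w <- gen_wound_image(wound_field_spec(image_size = 128, gap_width = 40,
                                        cell_sparsity = 0.3, seed = 1))
  expect_equal(w$truth$gap_width, 40)
  # the gap interior carries no texture, only noise (vertical band at 90 deg)
  expect_lt(max(abs(w$image[, 55:74])), 0.3)
})

test_that("zero-noise plate tables give exact normalized values", {
  tab <- gen_plate_table(c(0.5, 0.25), c(0, 0), 3, seed = 1)
  norm <- normalize_to_control(tab)
  expect_equal(norm$normalized, c(100, 50))
  adh <- gen_plate_table(c(120, 240), c(0, 0), 3, seed = 1)
  expect_equal(normalize_to_control(adh, percent = FALSE)$normalized, c(1, 2))
})

test_that("invalid generator specs are rejected", {
  expect_error(fiber_field_spec(n_fibers = -1), "n_fibers")
  expect_error(fiber_field_spec(orientation_concentration = -1), "kappa")
  expect_error(fiber_field_spec(pixel_size = 0), "pixel_size")
  expect_error(fiber_field_spec(image_size = 64, pixel_size = 0.25,
                                length_dist = c(100, 1)), "diagonal")
  expect_error(transient_spec(sampling_interval = 3, rise_time = 2), "sampling")
  expect_error(transient_spec(latency = -1), "time fields")
  expect_error(wound_field_spec(gap_width = 300, image_size = 256), "gap_width")
  expect_error(wound_field_spec(cell_sparsity = 1), "sparsity")
  expect_error(gen_plate_table(c(1, 2), c(0.1, -0.1), 3), "negative sd")
  expect_error(gen_plate_table(c(1, 2), c(0.1, 0.1), 1), "n_per_group")
  expect_error(gen_plate_table(c(1, 2), c(0.1), 3), "equal length")
})
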