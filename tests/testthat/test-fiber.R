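test_that("template bank has evenly spaced orientations and odd windows", {
  bank <- build_template_bank(fiberscore_params(K = 10))
  expect_equal(bank$angles, (0:9) * pi / 10)
  expect_true(all(vapply(bank$templates, function(t) all(dim(t) == 13), logical(1))))
  expect_true(all(vapply(bank$templates, sum, numeric(1)) == 13))
  b1 <- build_template_bank(fiberscore_params(K = 1))
  expect_length(b1$templates, 1)
  # single horizontal template: the center row is fully set
  expect_equal(b1$templates[[1]][7, ], rep(1, 13))
  expect_equal(sum(b1$templates[[1]]), 13)
  # full-size kernel interpretation
  pf <- fiberscore_params(L = 13, kernel = "full")
  expect_equal(pf$L, 6L)
})

test_that("parameter validation enforces the documented ranges", {
  expect_error(fiberscore_params(TC = 1.5), "TC")
  expect_error(fiberscore_params(TC = 0), "TC")
  expect_error(fiberscore_params(L = 0), "L")
  expect_error(fiberscore_params(N = 0.5), "N")
  expect_error(fiberscore_params(T = 1), "T")
  expect_error(fiberscore_params(M = 0), "M")
})

test_that("a straight line at a bank angle is detected at that angle", {
  img <- make_line_image(angle_deg = 18, len_px = 30)
  map <- correlate_fibers(img)
  expect_gt(sum(map$mask), 20)
  th <- map$orientation[map$mask] * 180 / pi
  # sub-bin refinement recovers the angle to a fraction of the 18-degree bin
  expect_lt(abs(stats::median(th) - 18), 1.5)
  expect_true(all(abs(th - 18) < 4.5))
  expect_true(all(map$fiber_index[map$mask] >= map$params$TC))
})

test_that("blank and constant images yield an empty mask without NaN", {
  expect_equal(sum(correlate_fibers(matrix(0, 64, 64))$mask), 0)
  map <- correlate_fibers(matrix(0.7, 64, 64))
  expect_equal(sum(map$mask), 0)
  expect_false(any(is.na(map$fiber_index)))
})

test_that("detection is equivariant under a 90 degree rotation", {
  img <- make_line_image(angle_deg = 36, len_px = 40, size = 96)
  map <- correlate_fibers(img)
  img90 <- t(img)[ncol(img):1, ]  # counterclockwise quarter turn
  map90 <- correlate_fibers(img90)
  expect_equal(sum(map90$mask), sum(map$mask), tolerance = 0.1)
  th <- mean(map$orientation[map$mask])
  th90 <- mean(map90$orientation[map90$mask])
  expect_equal((th90 - th) %% pi, pi / 2, tolerance = 0.02)
})

test_that("detection is deterministic for fixed image and parameters", {
  f <- gen_fiber_image(fiber_field_spec(image_size = 96, n_fibers = 4, seed = 3))
  m1 <- correlate_fibers(f$image)
  m2 <- correlate_fibers(f$image)
  expect_identical(m1$mask, m2$mask)
  expect_identical(m1$orientation, m2$orientation)
})

test_that("polarity follows the doubled-angle resultant", {
  # all pixels at one orientation: polarity exactly 1
  m <- make_fiber_map(rep(0.7, 50))
  p <- compute_polarity(m)
  expect_equal(p$polarity, 1, tolerance = 1e-12)
  # balanced orthogonal orientations cancel: cos(0) and cos(pi) average to 0
  m2 <- make_fiber_map(rep(c(0, pi / 2), 25))
  expect_equal(compute_polarity(m2)$polarity, 0, tolerance = 1e-12)
  # uniform over the bank angles: resultant of 10 evenly spaced doubled angles
  m3 <- make_fiber_map(rep((0:9) * pi / 10, 5))
  expect_lt(compute_polarity(m3)$polarity, 1e-10)
  # empty mask errors
  m4 <- make_fiber_map(numeric(0))
  expect_error(compute_polarity(m4), "no fibers detected")
})

test_that("polarity distribution FWHM matches hand-computed values", {
  # degenerate: all cells in one bin
  d <- polarity_distribution(rep(0.8, 30), binwidth = 0.05)
  expect_equal(d$fwhm, 0.05)
  expect_equal(sum(d$counts), 30)
  # symmetric triangular histogram: counts 1,2,3,2,1 in adjacent bins.
  # half max = 1.5; crossings interpolate half a bin beyond the 2-count bins:
  # left = mid(bin1) + 0.5*bw, right = mid(bin5) - 0.5*bw -> FWHM = 3*bw
  pol <- c(rep(0.125, 1), rep(0.175, 2), rep(0.225, 3), rep(0.275, 2), rep(0.325, 1))
  d2 <- polarity_distribution(pol, binwidth = 0.05)
  expect_equal(sum(d2$counts), 9)
  expect_equal(d2$mode, 0.225)
  expect_equal(d2$fwhm, 0.15)
  expect_error(polarity_distribution(numeric(0)), "at least one")
})

test_that("filament measurement applies the minimum-length rule", {
  # one straight 50 px line at 0.25 um/px: 49 unit steps = 12.25 um
  m <- matrix(FALSE, 60, 60)
  m[30, 5:54] <- TRUE
  sk <- thin_fiber_map(m, pixel_size = 0.25)
  met <- measure_filaments(sk, min_length = 5)
  expect_equal(met$n_filaments, 1)
  expect_equal(met$mean_length, 12.25)
  # two disjoint lines both above threshold
  m2 <- m; m2[10, 5:54] <- TRUE
  expect_equal(measure_filaments(thin_fiber_map(m2, 0.25), 5)$n_filaments, 2)
  # everything shorter than the minimum: zero count, flagged
  met0 <- measure_filaments(sk, min_length = 20)
  expect_equal(met0$n_filaments, 0)
  expect_equal(met0$mean_length, 0)
  expect_true(met0$no_filaments)
})

test_that("parameter scan returns the contour table and argmax", {
  f <- gen_fiber_image(fiber_field_spec(image_size = 128, n_fibers = 5, seed = 4))
  # singleton grid at the defaults equals a direct measurement
  scan1 <- optimize_parameters(f$image, list(TC = 0.55), pixel_size = 0.25)
  direct <- measure_filaments(thin_fiber_map(correlate_fibers(f$image), 0.25),
                              5, 30)$n_filaments
  expect_equal(scan1$table$n_filaments, direct)
  expect_equal(nrow(scan1$table), 1)
  # near-unity intensity threshold excludes everything
  scanT <- optimize_parameters(f$image, list(T = 0.99), pixel_size = 0.25)
  expect_equal(scanT$table$n_filaments, 0)
  expect_error(optimize_parameters(f$image, list()), "grid")
  expect_error(optimize_parameters(f$image, list(Q = 1)), "grid names")
})

test_that("per-cell metrics respect a label mask", {
  f <- gen_fiber_image(fiber_field_spec(image_size = 128, n_fibers = 4, seed = 6))
  labels <- matrix(1L, 128, 128)
  labels[, 65:128] <- 2L
  fs <- fiberscore(f$image, pixel_size = 0.25, labels = labels)
  expect_equal(nrow(fs$cells), 2)
  expect_true(all(c("cell_id", "n_filaments", "mean_length_um", "Dx", "Dy",
                    "polarity") %in% names(fs$cells)))
  expect_gte(min(fs$cells$n_filaments), 0)
})
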