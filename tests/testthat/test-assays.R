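test_that("normalization to control reproduces worked ratios", {
  tab <- gen_plate_table(c(0.5, 0.25), c(0, 0), 3, seed = 1, assay = "viability")
  expect_equal(normalize_to_control(tab)$normalized, c(100, 50))
  same <- gen_plate_table(c(0.4, 0.4), c(0, 0), 3, seed = 1)
  expect_equal(normalize_to_control(same)$normalized, c(100, 100))
  # TNF-alpha positive control doubling adhesion: ratio 2.0
  adh <- gen_plate_table(c(100, 200), c(0, 0), 3, seed = 1,
                         conditions = c("control", "tnf"), assay = "adhesion")
  expect_equal(normalize_to_control(adh, percent = FALSE)$normalized, c(1, 2))
  zero <- gen_plate_table(c(0, 1), c(0, 0), 3, seed = 1)
  expect_error(normalize_to_control(zero), "control mean")
})

test_that("per-nucleus normalization divides total signal by nuclei count", {
  expect_equal(ros_per_cell(5000, 25), 200)
  expect_equal(ros_per_cell(0, 10), 0)
  expect_error(ros_per_cell(100, 0), "nuclei_count")
  # synthetic raster: uniform signal s over area A with 10 disk nuclei
  gn <- gen_nuclei_image(n_nuclei = 10, image_size = 96, signal_per_pixel = 2,
                         seed = 4)
  expect_equal(count_nuclei(gn$nuclei), 10)
  total <- sum(gn$signal)
  expect_equal(total, 2 * 96 * 96)
  expect_equal(ros_per_cell(total, count_nuclei(gn$nuclei)), 2 * 96 * 96 / 10)
})

test_that("permeability coefficient reproduces the worked example", {
  # Q = 1.2, 2.4, 3.6 ug at 15, 30, 45 min; C0 = 200 ug/mL; A = 0.33 cm^2
  p <- permeability_coefficient(c(15, 30, 45), c(1.2, 2.4, 3.6), 200, 0.33)
  expect_equal(p$slope_ug_min, 0.08, tolerance = 1e-12)
  expect_equal(p$papp_cm_s, (0.08 / 60) / (0.33 * 200), tolerance = 1e-12)
  expect_equal(signif(p$papp_cm_s, 4), 2.020e-05)
  # normalization to a control value
  expect_equal(permeability_coefficient(c(15, 30, 45), c(1.2, 2.4, 3.6), 200,
                                        0.33, control_papp = p$papp_cm_s)$normalized, 1)
  # zero slope flagged, Papp 0
  pz <- permeability_coefficient(c(15, 30, 45), c(2, 2, 2), 200, 0.33)
  expect_equal(pz$papp_cm_s, 0)
  neg <- permeability_coefficient(c(15, 30, 45), c(3, 2, 1), 200, 0.33)
  expect_true(neg$negative_slope)
  expect_error(permeability_coefficient(c(15), c(1), 200, 0.33), "2 time points")
})

test_that("Papp scales linearly with flux and inversely with A and C0", {
  t <- c(15, 30, 45)
  base <- permeability_coefficient(t, c(1, 2, 3), 200, 0.33)$papp_cm_s
  expect_equal(permeability_coefficient(t, 2 * c(1, 2, 3), 200, 0.33)$papp_cm_s,
               2 * base, tolerance = 1e-12)
  expect_equal(permeability_coefficient(t, c(1, 2, 3), 400, 0.33)$papp_cm_s,
               base / 2, tolerance = 1e-12)
  expect_equal(permeability_coefficient(t, c(1, 2, 3), 200, 0.66)$papp_cm_s,
               base / 2, tolerance = 1e-12)
})

test_that("ANOVA matches a brute-force sums-of-squares decomposition", {
  for (s in 1:10) {
    set.seed(s)
    k <- sample(3:5, 1); n <- sample(3:6, 1)
    tab <- gen_plate_table(runif(k, 0.5, 2), runif(k, 0.05, 0.3), n, seed = s)
    rep_ <- anova_posthoc(tab)
    # independent oracle: explicit decomposition
    gm <- mean(tab$value)
    means <- tapply(tab$value, tab$condition, mean)
    ns <- tapply(tab$value, tab$condition, length)
    ss_b <- sum(ns * (means - gm)^2)
    ss_w <- sum((tab$value - means[tab$condition])^2)
    f_oracle <- (ss_b / (k - 1)) / (ss_w / (sum(ns) - k))
    expect_equal(rep_$f_value, f_oracle, tolerance = 1e-10)
    p_oracle <- stats::pf(f_oracle, k - 1, sum(ns) - k, lower.tail = FALSE)
    expect_equal(rep_$p_omnibus, p_oracle, tolerance = 1e-10)
  }
})

test_that("Bonferroni scaling, gating and star codes behave as documented", {
  tab <- gen_plate_table(c(1, 1.4, 1.8, 0.6, 1.2, 0.9), rep(0.1, 6), 4, seed = 3)
  bon <- anova_posthoc(tab, "bonferroni")
  expect_equal(bon$comparisons$p_adjusted,
               pmin(bon$comparisons$p_raw * 5, 1), tolerance = 1e-15)
  expect_true(all(bon$comparisons$p_adjusted >= bon$comparisons$p_raw))
  lsd <- anova_posthoc(tab, "fisher_lsd")
  expect_equal(lsd$comparisons$p_adjusted, lsd$comparisons$p_raw)
  # star thresholds
  expect_equal(endoquant:::star_code(c(0.0005, 0.005, 0.03, 0.2)),
               c("***", "**", "*", "ns"))
  # zero within-group variance rejected
  flat <- gen_plate_table(c(1, 2), c(0, 0), 3, seed = 1)
  expect_error(anova_posthoc(flat), "variance")
})

test_that("assay tables enforce replicate and control structure", {
  expect_error(assay_table(data.frame(condition = c("a", "b"), value = 1:2)),
               "2 replicates")
  df <- data.frame(condition = rep(c("t1", "control"), each = 3), value = 1:6)
  tab <- assay_table(df, control = "control")
  expect_equal(levels(tab$condition)[1], "control")
})
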