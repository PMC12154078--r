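test_that("background subtraction follows the ratio arithmetic", {
  tm <- seq(0, 30, 0.1)
  n <- length(tm)
  # raw channels exactly double their backgrounds: ratio = b340/b380
  tr <- preprocess_trace(rep(40, n), rep(20, n), b340 = 20, b380 = 10,
                         time = tm, stimulus_time = 15)
  expect_equal(unique(tr$ratio), 2)
  # zero background: plain channel ratio
  tr2 <- preprocess_trace(rep(3, n), rep(2, n), time = tm, stimulus_time = 15)
  expect_equal(unique(tr2$ratio), 1.5)
  # non-positive denominator flagged invalid, not propagated
  r380 <- rep(20, n); r380[5] <- 5
  tr3 <- preprocess_trace(rep(40, n), r380, b340 = 0, b380 = 10,
                          time = tm, stimulus_time = 15)
  expect_true(is.na(tr3$ratio[5]))
  expect_false(anyNA(tr3$ratio[-5]))
  expect_error(preprocess_trace(rep(1, n), rep(1, n), b380 = 2,
                                time = tm, stimulus_time = 15), "invalid")
})

test_that("noiseless triangular transients are recovered exactly", {
  tr <- gen_calcium_trace(transient_spec(baseline = 1, amplitude = 1, latency = 2,
                                         rise_time = 2, fall_time = 6,
                                         sampling_interval = 0.1, noise_sd = 0))
  p <- extract_params(tr)
  dt <- 0.1
  expect_false(p$no_transient)
  expect_equal(p$amplitude, 1, tolerance = 1e-9)
  expect_equal(p$latency, 2, tolerance = dt)
  expect_equal(p$duration, 10, tolerance = dt)
  expect_equal(p$area, 4, tolerance = 0.01)
  expect_equal(p$rising_velocity, 0.5, tolerance = 1e-9)
  expect_equal(p$asymmetry, 3, tolerance = 0.1)
  expect_equal(p$a, 2, tolerance = dt)
  expect_equal(p$b, 6, tolerance = dt)
})

test_that("flat traces yield a flagged no-transient result", {
  fl <- calcium_trace(seq(0, 60, 0.1), rep(1, 601), 30)
  p <- extract_params(fl)
  expect_true(p$no_transient)
  expect_equal(p$amplitude, 0)
  expect_equal(p$area, 0)
})

test_that("parameters are invariant to baseline offset and time shift", {
  sp <- transient_spec(baseline = 1, amplitude = 1, noise_sd = 0)
  p0 <- extract_params(gen_calcium_trace(sp))
  tr_up <- gen_calcium_trace(sp)
  tr_up$ratio <- tr_up$ratio + 0.5
  p_up <- extract_params(tr_up)
  for (f in c("amplitude", "latency", "duration", "area", "rising_velocity",
              "asymmetry"))
    expect_equal(p_up[[f]], p0[[f]], tolerance = 1e-9, label = f)
  expect_equal(p_up$baseline, p0$baseline + 0.5)
  tr_sh <- gen_calcium_trace(sp)
  tr_sh$time <- tr_sh$time + 50
  tr_sh$stimulus_time <- tr_sh$stimulus_time + 50
  p_sh <- extract_params(tr_sh)
  expect_equal(p_sh$latency, p0$latency, tolerance = 1e-9)
  expect_equal(p_sh$duration, p0$duration, tolerance = 1e-9)
})

test_that("area never exceeds amplitude times the transient span", {
  for (s in 1:10) {
    set.seed(s)
    sp <- transient_spec(amplitude = runif(1, 0.5, 2), latency = runif(1, 1, 3),
                         rise_time = runif(1, 1, 3), fall_time = runif(1, 2, 8),
                         noise_sd = 0)
    p <- extract_params(gen_calcium_trace(sp))
    expect_lte(p$area, p$amplitude * (p$duration - p$latency) + 1e-9)
  }
})

test_that("pre-stimulus baseline needs at least 10 samples", {
  tr <- calcium_trace(seq(0, 10, 0.5), rep(1, 21), stimulus_time = 2)
  expect_error(extract_params(tr), "pre-stimulus")
})

test_that("parameter correlations obey the Pearson contracts", {
  set.seed(42)
  df <- data.frame(amplitude = rnorm(20, 1, 0.2))
  df$duration <- 2 * df$amplitude          # duplicated information: r = 1
  df$area <- -df$amplitude                 # negated: r = -1
  df$latency <- rnorm(20)
  df$rising_velocity <- rnorm(20)
  df$asymmetry <- rnorm(20)
  cm <- correlate_params(df, condition = "control")$matrix
  expect_equal(cm["amplitude", "duration"], 1, tolerance = 1e-12)
  expect_equal(cm["amplitude", "area"], -1, tolerance = 1e-12)
  expect_true(isSymmetric(unname(cm)))
  expect_equal(unname(diag(cm)), rep(1, ncol(cm)))
  expect_true(all(cm >= -1 - 1e-12 & cm <= 1 + 1e-12, na.rm = TRUE))
  # mean-centered orthogonal columns: r = 0
  df2 <- data.frame(amplitude = c(-1, 0, 1, 0), duration = c(0, -1, 0, 1),
                    area = 1:4, latency = 1:4,
                    rising_velocity = 1:4, asymmetry = 1:4)
  expect_equal(correlate_params(df2)$matrix["amplitude", "duration"], 0,
               tolerance = 1e-12)
  # constant column reported as missing, never NaN
  df3 <- df; df3$asymmetry <- 2
  cm3 <- correlate_params(df3)$matrix
  expect_true(all(is.na(cm3["asymmetry", setdiff(colnames(cm3), "asymmetry")])))
  expect_false(any(is.nan(cm3)))
  expect_error(correlate_params(df[1:2, ]), "3 cells")
})

test_that("condition summaries report ratios to the control mean", {
  set.seed(1)
  ctl <- data.frame(amplitude = rnorm(30, 1, 0.1), duration = rnorm(30, 10, 1),
                    area = rnorm(30, 4, 0.5), latency = rnorm(30, 2, 0.2),
                    rising_velocity = rnorm(30, 0.5, 0.05),
                    asymmetry = rnorm(30, 3, 0.3))
  same <- summarize_condition(ctl, ctl)
  expect_equal(same$ratio, rep(1, 6))
  trt <- ctl; trt$amplitude <- ctl$amplitude * 1.2
  up <- summarize_condition(trt, ctl)
  expect_equal(up$ratio[up$parameter == "amplitude"], 1.2, tolerance = 1e-12)
  expect_error(summarize_condition(ctl[0, ], ctl), "empty treatment")
  zero <- ctl; zero$latency <- 0
  expect_error(summarize_condition(ctl, zero), "zero control mean")
})
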