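test_that("trace construction enforces the protocol invariants", {
  t <- seq(0, 300, by = 0.1)
  tr <- nadh_trace(t, rep(20, length(t)))
  expect_s3_class(tr, "nadh_trace")
  expect_error(nadh_trace(c(0, 0.1, 0.3), c(1, 2, 3)), "non-uniform")
  expect_error(nadh_trace(t, c(NA, rep(20, length(t) - 1))), "finite")
  expect_error(nadh_trace(t, rep(20, length(t)), glucose_time = 200,
                          kcn_time = 140), "event times")
})

test_that("trace CSV round-trips losslessly with its metadata sidecar", {
  tr <- generate_trace(trace_preset("x2180"), seed = 5, replicate = 2L)
  f <- file.path(tempdir(), "roundtrip_trace.csv")
  write_trace(tr, f)
  expect_true(file.exists(file.path(tempdir(), "roundtrip_trace.meta.json")))
  back <- read_trace(f)
  expect_equal(back$intensity, tr$intensity, tolerance = 1e-15)
  expect_equal(back$time_s, tr$time_s, tolerance = 1e-15)
  expect_identical(attr(back, "strain"), "x2180")
  expect_equal(attr(back, "kcn_time"), 140)
  expect_equal(attr(back, "ground_truth")$period, 27.67)

  # missing sidecar: protocol defaults
  f2 <- file.path(tempdir(), "bare_trace.csv")
  utils::write.csv(data.frame(time_s = seq(0, 300, 0.1), intensity = 20),
                   f2, row.names = FALSE)
  bare <- read_trace(f2)
  expect_equal(attr(bare, "glucose_time"), 60)
  expect_equal(attr(bare, "kcn_time"), 140)
  expect_error(read_trace(textConnection("a,b\n1,2")), "columns")
})

test_that("window selection covers a sinusoid that starts at KCN", {
  rate <- 10
  t <- seq(0, 1320, by = 1 / rate)
  x <- 20 + ifelse(t >= 140, 2 * sin(2 * pi * (t - 140) / 26), 0)
  tr <- nadh_trace(t, x)
  w <- select_oscillating_window(tr)
  expect_true(w$oscillatory)
  expect_gt(w$t_start, 140)
  covered <- (w$t_end - w$t_start) / (1320 - 140)
  expect_gte(covered, 0.95)
})

test_that("window selection skips the induction transient on synthetic wild type", {
  tr <- generate_trace(trace_preset("by4743"), seed = 2)
  gt <- attr(tr, "ground_truth")
  w <- select_oscillating_window(tr)
  expect_true(w$oscillatory)
  # start within two nominal periods of the true onset
  expect_lt(abs(w$t_start - gt$t_onset), 2 * gt$period)
  # the sustained plateau is fully inside the window
  expect_lte(w$t_end - 2 * gt$period, 1320)
  expect_gte(w$t_end, gt$t_plateau_end - 2 * gt$period)
})

test_that("a non-oscillatory phenotype yields a verdict, not an error", {
  tr <- generate_trace(trace_preset("pfk2"), seed = 2)
  w <- select_oscillating_window(tr)
  expect_false(w$oscillatory)
  f <- trace_features(tr)
  expect_false(f$oscillatory)
  expect_true(is.na(f$period))
})

test_that("linear detrending removes lines exactly and centres the window", {
  t <- seq(0, 300, by = 0.1)
  tr <- nadh_trace(t, 15 + 0.01 * t)
  d <- detrend_window(tr, c(150, 250))
  expect_equal(max(abs(d$values)), 0, tolerance = 1e-9)
  expect_equal(mean(d$values), 0, tolerance = 1e-9)

  # sine on a drifting baseline: recovered over a protocol-length window
  # with residual drift below 1% of the injected slope
  tl <- seq(0, 1320, by = 0.1)
  x <- 15 + 0.01 * tl + 1.5 * sin(2 * pi * tl / 26)
  tr2 <- nadh_trace(tl, x)
  d2 <- detrend_window(tr2, c(140, 1320))
  truth <- 1.5 * sin(2 * pi * d2$time_s / 26)
  err <- d2$values - (truth - mean(truth))
  expect_lt(max(abs(err)) / 1.5, 0.01)
  expect_lt(abs(stats::coef(stats::lm(err ~ d2$time_s))[2]) / 0.01, 0.01)

  expect_error(detrend_window(tr, c(100, 100.05)), "3 samples")
})

test_that("spectral amplitude is sinusoid-calibrated on an on-bin tone", {
  rate <- 10
  t <- seq(0, 1320, by = 1 / rate)
  # period chosen so an integer number of cycles fits the analysis window
  a <- 2.3
  x <- 20 + ifelse(t >= 140, a * sin(2 * pi * (t - 140) / 26), 0)
  tr <- nadh_trace(t, x)
  f <- trace_features(tr)
  expect_true(f$oscillatory)
  # window selection trims the series, so the tone is near- but not
  # exactly on-bin: amplitude recovered within 5%
  expect_lt(abs(f$amplitude - a) / a, 0.05)
  expect_lt(abs(f$period - 26), 1)

  # exactly on-bin pure tone, full-series DFT: amplitude to 1e-6
  N <- 2600
  tt <- (0:(N - 1)) / rate
  xx <- a * sin(2 * pi * tt / 26)
  s <- dft(xx, dt = 1 / rate)
  k <- which.min(abs(s$freq - 1 / 26))
  expect_equal(2 * Mod(s$coef[k]) / N, a, tolerance = 1e-6)
})

test_that("constant traces are non-oscillatory", {
  t <- seq(0, 600, by = 0.1)
  set.seed(9)
  tr <- nadh_trace(t, 20 + rnorm(length(t), sd = 0.05))
  expect_false(trace_features(tr)$oscillatory)
})

test_that("replicate summaries compute sample statistics across replicates", {
  mk <- function(fr, am, strain = "by4743") structure(
    list(oscillatory = TRUE, period = 1 / fr, frequency = fr,
         amplitude = am, window = c(160, 1300), noise_sd = 0.04,
         strain = strain, replicate = 1L), class = "trace_features")
  fs <- list(mk(0.038, 1.9), mk(0.040, 2.0), mk(0.042, 2.1))
  s <- replicate_summary(fs)
  expect_equal(s$mean_frequency, 0.040)
  expect_equal(s$sd_frequency, 0.002)
  expect_equal(s$n, 3)

  one <- replicate_summary(fs[1])
  expect_equal(one$n, 1)
  expect_equal(one$sd_frequency, 0)

  same <- replicate_summary(list(mk(0.04, 2), mk(0.04, 2), mk(0.04, 2)))
  expect_equal(same$sd_frequency, 0)
  expect_equal(same$sd_amplitude, 0)

  expect_error(replicate_summary(list(mk(0.04, 2), mk(0.04, 2, "x2180"))),
               "mixed strains")
})
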