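all_presets <- c("by4743", "x2180", "hxk1", "hxk2", "pfk1", "tdh1",
                 "tdh2", "pfk2", "tdh3", "pde2", "ira2")

test_that("presets carry the documented phenotypes", {
  expect_equal(trace_preset("by4743")$phenotype$period, 26.05)
  expect_equal(trace_preset("x2180")$phenotype$period, 27.67)

  pfk2 <- trace_preset("pfk2")$phenotype
  expect_false(pfk2$oscillatory)
  expect_false(pfk2$spike)
  expect_true(pfk2$drop)
  for (lab in c("tdh3", "pde2", "ira2"))
    expect_false(trace_preset(lab)$phenotype$oscillatory)

  # hexokinase deletions: reduced amplitude, extended duration, hxk2
  # more extreme and slower
  wt <- trace_preset("by4743")$phenotype
  h1 <- trace_preset("hxk1")$phenotype
  h2 <- trace_preset("hxk2")$phenotype
  expect_true(h2$amplitude_frac < h1$amplitude_frac)
  expect_true(h1$amplitude_frac < wt$amplitude_frac)
  expect_true(h2$duration_min > h1$duration_min)
  expect_true(h1$duration_min > wt$duration_min)
  expect_gt(h2$period, wt$period)

  expect_error(trace_preset("nosuch"), "available")
})

test_that("all presets satisfy the spec invariants", {
  for (lab in all_presets) {
    sp <- trace_preset(lab)
    expect_s3_class(sp, "synthetic_trace_spec")
    expect_gt(sp$duration, sp$kcn_time)
    expect_gt(sp$rate, 0)
    expect_gte(sp$noise_sd, 0)
    ph <- sp$phenotype
    if (ph$oscillatory) {
      expect_gt(ph$period, 0)
      expect_gt(ph$amplitude_frac, 0)
      expect_gt(ph$duration_min, 0)
    }
  }
})

test_that("traces follow the measurement protocol", {
  for (lab in all_presets) {
    tr <- generate_trace(trace_preset(lab), seed = 4)
    expect_equal(nrow(tr), 1320 * 10 + 1)
    expect_equal(tr$time_s[2] - tr$time_s[1], 0.1)
    expect_equal(attr(tr, "glucose_time"), 60)
    expect_equal(attr(tr, "kcn_time"), 140)
    expect_true(all(tr$intensity > 10 & tr$intensity < 30))
  }
})

test_that("the generator is deterministic by seed and noise-free when asked", {
  sp <- trace_preset("by4743")
  a <- generate_trace(sp, seed = 99)
  b <- generate_trace(sp, seed = 99)
  expect_identical(a$intensity, b$intensity)
  c <- generate_trace(sp, seed = 100)
  expect_false(identical(a$intensity, c$intensity))

  # degenerate noise-free non-oscillatory trace is the closed-form curve
  sp0 <- trace_preset("tdh3", noise_frac = 0)
  sp0$drift_slope <- 0
  tr0 <- generate_trace(sp0)
  t <- tr0$time_s
  expected <- 18 + ifelse(t >= 60, 6 * exp(-(t - 60) / 30), 0)
  expect_equal(tr0$intensity, expected, tolerance = 1e-12)
})

test_that("generated wild-type periods are recoverable by the analysis pipeline", {
  for (lab in c("by4743", "x2180")) {
    sp <- trace_preset(lab)
    tr <- generate_trace(sp, seed = 31)
    f <- trace_features(tr)
    expect_true(f$oscillatory)
    bin <- 1 / diff(f$window)
    expect_lt(abs(f$frequency - 1 / sp$phenotype$period), bin)
  }
})

test_that("cohorts count out and their sub-seeds are disjoint", {
  coh <- generate_cohort(all_presets, n_replicates = 3, seed = 12)
  expect_length(coh$traces, 33)
  expect_equal(nrow(coh$manifest), 33)
  expect_equal(anyDuplicated(coh$manifest$seed), 0)

  # same master seed reproduces; different replicates differ
  coh2 <- generate_cohort(all_presets, n_replicates = 3, seed = 12)
  expect_identical(coh$manifest$seed, coh2$manifest$seed)
  by <- which(coh$manifest$label == "by4743")
  expect_false(identical(coh$traces[[by[1]]]$intensity,
                         coh$traces[[by[2]]]$intensity))
})

test_that("cohort replicate statistics straddle the generator truth", {
  coh <- generate_cohort("by4743", n_replicates = 3, seed = 8)
  fs <- lapply(coh$traces, trace_features)
  s <- replicate_summary(fs)
  expect_equal(s$n_oscillatory, 3)
  expect_gt(s$sd_frequency, 0)
  bins <- sapply(fs, function(f) 1 / diff(f$window))
  expect_lt(abs(s$mean_frequency - 1 / 26.05), max(bins))
})

test_that("cohorts can be written to disk with a manifest", {
  dir <- file.path(tempdir(), "cohort_out")
  coh <- generate_cohort("pfk2", n_replicates = 2, seed = 3, dir = dir)
  expect_true(file.exists(file.path(dir, "trace_pfk2_1.csv")))
  expect_true(file.exists(file.path(dir, "trace_pfk2_1.meta.json")))
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 2)
  back <- read_trace(file.path(dir, "trace_pfk2_2.csv"))
  expect_equal(back$intensity, coh$traces[[2]]$intensity,
               tolerance = 1e-15)
  unlink(dir, recursive = TRUE)
})
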