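test_that("generation is bit-reproducible given the spec", {
  sp <- quick_spec(seed = 42)
  r1 <- generate_recording(sp)
  r2 <- generate_recording(sp)
  expect_identical(r1$left, r2$left)
  expect_identical(r1$right, r2$right)
  expect_identical(r1$cci_sample, round(90 * sp$fs))
})

test_that("fully shared band sources give unit coherence, independent ones low", {
  all1 <- c(delta = 1, theta = 1, alpha = 1, beta = 1)
  rp1 <- regime_params(shared_fraction = all1, spike_rate = 0)
  rec <- generate_recording(quick_spec(baseline = rp1, post = rp1, seed = 3))
  ep <- extract_epochs(rec, "baseline", filtered = FALSE)$baseline
  cs <- eeg_coherence(ep$left, ep$right, rec$fs)
  expect_true(all(cs$cxy > 1 - 1e-10))

  rp0 <- regime_params(shared_fraction = all1 * 0, spike_rate = 0)
  # threshold frozen from a 50-seed Monte-Carlo null of the mean band
  # coherence at this window count (95th percentile was < 0.09)
  means <- vapply(1:5, function(s) {
    rec0 <- generate_recording(quick_spec(baseline = rp0, post = rp0, seed = s))
    ep0 <- extract_epochs(rec0, "baseline", filtered = FALSE)$baseline
    mean(eeg_coherence(ep0$left, ep0$right, rec0$fs)$cxy)
  }, 0)
  expect_true(all(means < 0.12))
})

test_that("estimated band coherence is monotone in shared_fraction", {
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  est <- vapply(grid, function(s) {
    sf <- c(delta = s, theta = s, alpha = s, beta = s)
    rp <- regime_params(shared_fraction = sf, spike_rate = 0)
    mean(vapply(1:3, function(seed) {
      rec <- generate_recording(quick_spec(baseline = rp, post = rp, seed = seed))
      ep <- extract_epochs(rec, "baseline", filtered = FALSE)$baseline
      band_coherence(eeg_coherence(ep$left, ep$right, rec$fs), "delta")
    }, 0))
  }, 0)
  expect_true(all(diff(est) >= 0))
})

test_that("percent band power increases strictly with the band gain", {
  est <- vapply(c(0.5, 1, 2, 4), function(g) {
    rp <- regime_params(band_gains = c(delta = 1, theta = g, alpha = 0.7,
                                       beta = 0.35), spike_rate = 0)
    rec <- generate_recording(quick_spec(baseline = rp, post = rp, seed = 5))
    ep <- extract_epochs(rec, "baseline", filtered = FALSE)$baseline
    pct_band_power(eeg_psd(ep$left, rec$fs), "theta")
  }, 0)
  expect_true(all(diff(est) > 0))
})

test_that("burst suppression lowers spectral entropy", {
  ent <- function(am, seed) {
    rp <- regime_params(am_depth = am, spike_rate = 0)
    rec <- generate_recording(quick_spec(baseline = rp, post = rp, seed = seed))
    ep <- extract_epochs(rec, "baseline", filtered = FALSE)$baseline
    spectral_entropy(eeg_psd(ep$left, rec$fs))
  }
  d <- vapply(1:20, function(s) ent(0.9, s) - ent(0, s), 0)
  expect_lt(mean(d), 0)
  expect_true(mean(d < 0) > 0.9)
})

test_that("sparse large transients push kurtosis above the Gaussian value", {
  k <- vapply(1:20, function(s) {
    rp <- regime_params(spike_rate = 1, spike_amp = 8)
    rec <- generate_recording(quick_spec(baseline = rp, post = rp, seed = s))
    ep <- extract_epochs(rec, "baseline", filtered = FALSE)$baseline
    kurtosis(ep$left)
  }, 0)
  expect_gte(mean(k > 3), 0.95)
})

test_that("strain presets encode the published qualitative structure", {
  pr <- strain_presets()
  expect_gt(pr$PPKR$baseline$band_gains[["delta"]],
            pr$PPKS$baseline$band_gains[["delta"]])
  expect_true(all(pr$PPKR$baseline$band_gains[c("theta", "alpha", "beta")] <
                    pr$PPKS$baseline$band_gains[c("theta", "alpha", "beta")]))
  expect_identical(pr$PPKS$post$band_gains, pr$PPKS$baseline$band_gains)
  expect_gt(pr$PPKR$post$shared_fraction[["delta"]],
            pr$PPKS$post$shared_fraction[["delta"]])
  expect_lt(pr$PPKS$post$shared_fraction[["delta"]],
            pr$SD$post$shared_fraction[["delta"]])
  # ipsilateral-only mechanisms: right channel carries them
  expect_gt(pr$PPKS$post$am_depth[2], 0)
  expect_identical(pr$PPKS$post$am_depth[1], 0)
  expect_gt(pr$PPKR$post$spike_rate[2], pr$PPKR$post$spike_rate[1])
})

test_that("cohort generation counts, reproducibility and manifest round-trip", {
  pr <- strain_presets(fs = 128)
  m1 <- cohort_manifest(4, seed = 7, presets = pr)
  m2 <- cohort_manifest(4, seed = 7, presets = pr)
  expect_identical(m1, m2)
  expect_identical(nrow(m1), 12L)
  expect_identical(sum(m1$strain == "PPKS"), 4L)
  expect_error(cohort_manifest(0, seed = 7, presets = pr), "positive")

  co <- generate_cohort(2, seed = 9, presets = pr)
  expect_length(co$recordings, 6L)
  # manifest rows regenerate recordings exactly
  rec <- generate_recording(spec_from_manifest(co$manifest[3, ]))
  expect_identical(rec$left, co$recordings[[3]]$left)
})

test_that("invalid geometry is rejected", {
  expect_error(subject_spec("SD", fs = 60), "invalid fs")
  expect_error(subject_spec("SD", cci_time = 50), "baseline epoch")
  expect_error(subject_spec("SD", cci_time = 120, duration = 500),
               "too short")
  expect_error(regime_params(shared_fraction = c(delta = 1.2, theta = 0.5,
                                                 alpha = 0.5, beta = 0.5)),
               "shared_fraction")
  expect_error(regime_params(am_depth = -0.1), "am_depth")
})

test_that("recording CSV round-trips with its sidecar", {
  rec <- generate_recording(quick_spec(seed = 2))
  path <- file.path(tempdir(), "rec_roundtrip.csv")
  write_recording_csv(rec, path)
  back <- read_recording_csv(path)
  expect_equal(back$left, rec$left, tolerance = 1e-12)
  expect_equal(back$cci_sample, rec$cci_sample)
  expect_equal(back$fs, rec$fs)
  unlink(c(path, paste0(path, ".json")))
})
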