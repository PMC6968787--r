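test_that("psd locates a sinusoid and satisfies Parseval", {
  fs <- 256
  t <- (0:(60 * fs - 1)) / fs
  sp <- eeg_psd(sin(2 * pi * 10 * t), fs)
  expect_identical(sp$freq[which.max(sp$power)], 10)
  expect_length(sp$power, 64L)

  set.seed(4)
  x <- rnorm(60 * fs, sd = 3)
  # Parseval oracle: the full-band one-sided density must integrate to the
  # time-domain variance (windowing error < 5%)
  W <- acuteqeeg:::.welch(x, fs = fs)
  tot <- sum(W$pxx) * fs / 2048
  expect_lt(abs(tot - var(x)) / var(x), 0.05)

  expect_identical(eeg_psd(numeric(2048), fs)$power, rep(0, 64))
  expect_error(eeg_psd(numeric(100), fs), "window")
})

test_that("baseline normalization is plain division with provenance", {
  sp <- make_spec(rep(0.5, 64))
  nn <- normalize_to_baseline(sp, 2)
  expect_identical(nn$power, rep(0.25, 64))
  expect_true(nn$normalized)
  expect_identical(nn$norm_constant, 2)
  # a baseline spectrum normalized by its own total integrates to 1
  sp2 <- make_spec(runif(64))
  self <- normalize_to_baseline(sp2, total_power(sp2))
  expect_equal(sum(self$power) * 0.5, 1)
  expect_error(normalize_to_baseline(sp, 0), "positive")
  expect_error(normalize_to_baseline(nn, 2), "already normalized")
})

test_that("total power integrates the binned density and guards normalization", {
  expect_identical(total_power(make_spec(rep(2, 64))), 64)
  expect_identical(total_power(make_spec(rep(0, 64))), 0)
  expect_error(total_power(make_spec(rep(1, 64), normalized = TRUE, norm_constant = 1)),
               "non-normalized")
  # Parseval: binned total power matches the variance of a bandpassed signal
  # whose energy lies inside the passband (white noise restricted to 1-30 Hz,
  # so the filter transition bands hold no energy)
  fs <- 256
  set.seed(8)
  n <- 90 * fs
  spec <- complex(length.out = n)
  f <- (1:(n / 2)) * fs / n
  keep <- which(f >= 1 & f <= 30)
  spec[1 + keep] <- complex(real = rnorm(length(keep)),
                            imaginary = rnorm(length(keep)))
  spec[n + 1 - keep] <- Conj(spec[1 + keep])
  x <- bandpass(10 * Re(fft(spec, inverse = TRUE)) / sqrt(n), fs)
  mid <- x[(15 * fs):(75 * fs)]
  expect_lt(abs(total_power(eeg_psd(mid, fs)) - var(mid)) / var(mid), 0.05)
})

test_that("percent band power partitions the 64 bins", {
  flat <- make_spec(rep(1, 64))
  expect_identical(pct_band_power(flat, "delta"), 100 * 8 / 64)
  expect_identical(pct_band_power(flat, "theta"), 100 * 8 / 64)
  expect_identical(pct_band_power(flat, "alpha"), 100 * 10 / 64)
  expect_identical(pct_band_power(flat, "beta"), 100 * 38 / 64)
  single <- make_spec(replace(rep(0, 64), 40, 5))  # 20 Hz bin
  expect_identical(pct_band_power(single, "beta"), 100)
  expect_identical(pct_band_power(single, "delta"), 0)
  set.seed(1)
  r <- make_spec(rexp(64))
  expect_equal(sum(vapply(c("delta", "theta", "alpha", "beta"),
                          function(b) pct_band_power(r, b), 0)), 100,
               tolerance = 1e-9)
  expect_error(pct_band_power(make_spec(rep(0, 64)), "delta"), "zero total")
})

test_that("coherence identities: self-coherence and scale invariance", {
  fs <- 256
  set.seed(2)
  x <- rnorm(10 * fs)
  cs <- eeg_coherence(x, x, fs)
  expect_true(all(abs(cs$cxy - 1) < 1e-10))
  cs3 <- eeg_coherence(x, 3 * x, fs)
  expect_true(all(abs(cs3$cxy - 1) < 1e-10))
  expect_true(all(cs$cxy >= 0 & cs$cxy <= 1))
  expect_error(eeg_coherence(x[1:600], x[1:600], fs), "two Welch windows")
})

test_that("independent channels stay below the Monte-Carlo null threshold", {
  fs <- 256
  # null distribution of the mean coherence for independent white channels
  set.seed(11)
  null_means <- vapply(1:200, function(i) {
    mean(eeg_coherence(rnorm(60 * fs), rnorm(60 * fs), fs)$cxy)
  }, 0)
  q95 <- quantile(null_means, 0.95)
  expect_lt(q95, 0.1)   # 37 Welch windows keep the null bias small
  set.seed(77)
  obs <- mean(eeg_coherence(rnorm(60 * fs), rnorm(60 * fs), fs)$cxy)
  expect_lt(obs, q95)
})

test_that("spectral entropy attains its analytic bounds", {
  expect_equal(spectral_entropy(make_spec(rep(1, 64))), log(64), tolerance = 1e-12)
  expect_identical(spectral_entropy(make_spec(replace(rep(0, 64), 17, 3))), 0)
  expect_equal(spectral_entropy(make_spec(replace(rep(0, 64), c(5, 9), 2))),
               log(2), tolerance = 1e-12)
  expect_error(spectral_entropy(make_spec(rep(0, 64))), "all-zero")
})

test_that("kurtosis is the population fourth standardized moment", {
  set.seed(3)
  expect_equal(kurtosis(rnorm(1e6)), 3, tolerance = 0.1)
  expect_identical(kurtosis(rep(c(1, -1), 500)), 1)
  x <- rnorm(61440)
  expect_gt(kurtosis(c(x, 20)), 3)
  expect_error(kurtosis(rep(5, 100)), "constant")
})

test_that("line length follows the planar path formula", {
  expect_identical(line_length(rep(7, 100)), 99)
  expect_equal(line_length(as.numeric(1:100)), 99 * sqrt(2), tolerance = 1e-12)
  a <- 2.5
  alt <- rep(c(a, -a), 50)
  expect_equal(line_length(alt), 99 * sqrt(1 + 4 * a^2), tolerance = 1e-12)
  expect_equal(line_length(alt, type = "amplitude"), 99 * 2 * a, tolerance = 1e-12)
  expect_error(line_length(1), "at least 2")
})

test_that("psd and coherence match the direct-DFT oracle on 2-window signals", {
  fs <- 1024
  n <- 512 + 384   # exactly two Welch windows
  set.seed(5)
  common <- rnorm(n)
  x <- common + rnorm(n)
  y <- common + rnorm(n)
  o <- dft_welch_oracle(x, y, fs)
  sp <- eeg_psd(x, fs)
  expect_equal(sp$power, o$pxx, tolerance = 1e-8)
  cs <- eeg_coherence(x, y, fs)
  expect_equal(cs$cxy, o$cxy[match(cs$freq, o$freq)], tolerance = 1e-8)
})

test_that("feature vectors carry the 19 canonical features", {
  fs <- 256
  t <- (0:(60 * fs - 1)) / fs
  set.seed(6)
  delta_only <- make_epoch(sin(2 * pi * 2 * t), sin(2 * pi * 2.5 * t), fs)
  fv <- build_features(delta_only)
  expect_true(all(feature_names() %in% names(fv)))
  expect_length(feature_names(), 19L)
  expect_equal(fv$pct_delta_ipsi, 100, tolerance = 1e-6)
  expect_equal(fv$pct_delta_contra, 100, tolerance = 1e-6)

  # relabeling: swapping the ipsilateral flag swaps exactly the side labels
  l <- rnorm(60 * fs)
  r <- rnorm(60 * fs) + 0.5 * l
  ep <- make_epoch(l, r, fs)
  f_r <- build_features(ep, ipsilateral = "right")
  f_l <- build_features(ep, ipsilateral = "left")
  expect_equal(f_r$entropy_ipsi, f_l$entropy_contra)
  expect_equal(f_r$kurtosis_contra, f_l$kurtosis_ipsi)
  expect_equal(f_r$pct_beta_ipsi, f_l$pct_beta_contra)
  expect_equal(f_r$coh_delta, f_l$coh_delta)
  expect_equal(f_r$total_power, f_l$total_power)
})
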