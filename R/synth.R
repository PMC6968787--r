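#' Regime parameters for the synthetic EEG generator
#'
#' A regime describes the stationary statistical structure of the two-channel
#' signal on one side of the impact (baseline or post-injury). Channels are
#' built per frequency band as mixtures of a common and a private Gaussian
#' source, so interhemispheric coherence is controlled band-by-band by
#' `shared_fraction`; `band_gains` and `psd_exponent` set the spectral shape;
#' `am_depth` adds burst-suppression-like amplitude modulation that
#' periodically attenuates the supra-delta content, concentrating power into
#' the delta band and lowering spectral entropy; `spike_rate`/`spike_amp`
#' inject sparse sharp transients (raising kurtosis).
#'
#' @param psd_exponent 1/f slope of the underlying spectrum (dimensionless).
#' @param band_gains named numeric, multiplicative gain per band
#'   (`delta`, `theta`, `alpha`, `beta`).
#' @param shared_fraction named numeric in `[0,1]` per band: fraction of
#'   variance from a source common to both channels.
#' @param am_depth burst-modulation depth in `[0,1]`; scalar (both channels)
#'   or length 2 (`left`, `right`).
#' @param spike_rate Poisson rate of additive transients, events/s; scalar or
#'   length 2.
#' @param spike_amp transient amplitude in units of the channel SD; scalar or
#'   length 2.
#' @param rms target channel RMS in microvolts.
#' @return an object of class `regime_params`.
#' @export
regime_params <- function(psd_exponent = 1.1,
                          band_gains = c(delta = 1, theta = 0.9, alpha = 0.7, beta = 0.35),
                          shared_fraction = c(delta = 0.65, theta = 0.7, alpha = 0.7, beta = 0.6),
                          am_depth = 0, spike_rate = 0, spike_amp = 8, rms = 50) {
  bands <- c("delta", "theta", "alpha", "beta")
  band_gains <- band_gains[bands]
  shared_fraction <- shared_fraction[bands]
  if (anyNA(band_gains) || any(band_gains < 0))
    stop("band_gains must be named (delta/theta/alpha/beta) and non-negative")
  if (anyNA(shared_fraction) || any(shared_fraction < 0 | shared_fraction > 1))
    stop("shared_fraction must be in [0, 1] for every band")
  if (any(am_depth < 0 | am_depth > 1)) stop("am_depth must lie in [0, 1]")
  if (any(spike_rate < 0)) stop("spike_rate must be >= 0")
  if (!length(rms) == 1L || rms <= 0) stop("rms must be a single positive value")
  if (!length(am_depth) %in% 1:2 || !length(spike_rate) %in% 1:2 ||
      !length(spike_amp) %in% 1:2)
    stop("am_depth, spike_rate and spike_amp must have length 1 or 2 (left, right)")
  structure(list(psd_exponent = psd_exponent, band_gains = band_gains,
                 shared_fraction = shared_fraction, am_depth = am_depth,
                 spike_rate = spike_rate, spike_amp = spike_amp, rms = rms),
            class = "regime_params")
}

#' Subject specification for a synthetic recording
#'
#' @param strain one of `"PPKS"`, `"SD"`, `"PPKR"`.
#' @param baseline,post [regime_params()] for the pre- and post-impact regimes.
#' @param cci_time impact time in seconds from record start; at least 90 s so
#'   the baseline epoch (ending 30 s before impact) exists.
#' @param duration total record duration in seconds; must extend at least 16
#'   minutes past `cci_time` so all post-injury epochs exist.
#' @param fs sampling rate in Hz (default 1024).
#' @param seed integer seed; generation is bit-reproducible given the spec.
#' @param sex `"M"` or `"F"` (metadata only; the generator is sex-blind).
#' @param shape_sd SD of a smooth per-subject log-spectral perturbation
#'   (correlation length about 2 Hz, shared by both channels and regimes),
#'   emulating stable individual differences in spectral shape.
#' @return an object of class `subject_spec`.
#' @export
subject_spec <- function(strain = c("PPKS", "SD", "PPKR"),
                         baseline = regime_params(), post = regime_params(),
                         cci_time = 120, duration = 1080, fs = 1024,
                         seed = 1L, sex = "F", shape_sd = 0) {
  strain <- match.arg(strain)
  stopifnot(inherits(baseline, "regime_params"), inherits(post, "regime_params"))
  if (!is.numeric(fs) || fs <= 64)
    stop("invalid fs: must exceed 64 Hz (2 x the 32 Hz analysis limit)")
  if (cci_time < 90)
    stop("cci_time must be >= 90 s so the baseline epoch exists")
  if (duration - cci_time < 960)
    stop("duration too short for the epoch scheme: need >= 960 s (16 min) after the impact")
  structure(list(strain = strain, sex = sex, baseline = baseline, post = post,
                 cci_time = cci_time, duration = duration, fs = fs,
                 seed = as.numeric(seed), shape_sd = shape_sd),
            class = "subject_spec")
}

# band edges used by the generator (cover the 0.5 Hz analysis bins; the
# spectral tail above beta rolls off exponentially)
.synth_band_of <- function(f) {
  cut(f, breaks = c(0, 4.25, 8.25, 13.25, 32.25, Inf),
      labels = c("delta", "theta", "alpha", "beta", "tail"), right = TRUE)
}

.per_channel <- function(p, i) if (length(p) == 2L) p[i] else p[1L]

# one stationary two-channel segment; returns list(left, right)
# RNG draw order (fixed, documented): common spectrum, private L, private R,
# AM phase L, AM phase R, spikes L (count, times, signs), spikes R.
.synth_segment <- function(n, fs, rp, shape_curve = NULL) {
  nh <- floor(n / 2)
  f <- (1:nh) * fs / n
  sup <- which(f >= 0.25 & f <= 45)
  fi <- f[sup]
  band <- .synth_band_of(fi)
  gain <- numeric(length(fi))
  for (b in c("delta", "theta", "alpha", "beta"))
    gain[band == b] <- rp$band_gains[[b]]
  tail_idx <- band == "tail"
  gain[tail_idx] <- rp$band_gains[["beta"]] * exp(-(fi[tail_idx] - 32.25) / 4)
  sf <- numeric(length(fi))
  for (b in c("delta", "theta", "alpha", "beta"))
    sf[band == b] <- rp$shared_fraction[[b]]
  sf[tail_idx] <- rp$shared_fraction[["beta"]]

  amp <- gain * fi^(-rp$psd_exponent / 2)
  if (!is.null(shape_curve)) amp <- amp * shape_curve(fi)

  cnorm <- function(k) complex(real = stats::rnorm(k), imaginary = stats::rnorm(k)) / sqrt(2)
  Cm <- cnorm(length(fi))
  P1 <- cnorm(length(fi))
  P2 <- cnorm(length(fi))
  mix <- function(P) amp * (sqrt(sf) * Cm + sqrt(1 - sf) * P)

  to_time <- function(Z, keep) {
    # Hermitian completion of the one-sided spectrum restricted to `keep`
    full <- complex(length.out = n)
    zk <- Z
    zk[!keep] <- 0
    full[1 + sup] <- zk
    full[n + 1 - sup] <- Conj(zk)
    Re(stats::fft(full, inverse = TRUE)) / sqrt(n)
  }

  is_delta <- band == "delta"
  tt <- (0:(n - 1)) / fs
  build_channel <- function(Z, am_depth) {
    xd <- to_time(Z, is_delta)
    xr <- to_time(Z, !is_delta)
    phi <- stats::runif(1, 0, 2 * pi)   # always drawn: keeps streams aligned
    if (am_depth > 0) {
      # burst suppression: slow bursts attenuate the supra-delta content
      # while delta waves swell in anti-phase so the instantaneous total
      # variance stays constant -- this concentrates the spectrum into delta
      # (lowering spectral entropy) yet leaves the signal a constant-variance
      # Gaussian, so kurtosis is untouched by construction
      u <- 0.5 + 0.5 * cos(2 * pi * 0.8 * tt + phi)
      s <- 1 - am_depth * u
      ratio <- stats::var(xr) / stats::var(xd)
      e <- sqrt(1 + ratio * (1 - s^2))
      x <- xd * e + xr * s
    } else {
      x <- xd + xr
    }
    x * (rp$rms / stats::sd(x))
  }
  add_spikes <- function(x, rate, s_amp) {
    k <- stats::rpois(1, rate * n / fs)    # always drawn
    if (k > 0) {
      pos <- sort(pmax(1L, ceiling(stats::runif(k) * n)))
      sgn <- sample(c(-1, 1), k, replace = TRUE)
      wlen <- max(8L, round(0.03 * fs))
      tw <- seq(0, 1, length.out = wlen)
      w <- sin(2 * pi * tw) * sin(pi * tw)^2
      w <- w / max(abs(w))
      for (j in seq_len(k)) {
        idx <- pos[j] + seq_len(wlen) - 1L
        idx <- idx[idx <= length(x)]
        x[idx] <- x[idx] + sgn[j] * s_amp * rp$rms * w[seq_along(idx)]
      }
    }
    x
  }
  left <- build_channel(mix(P1), .per_channel(rp$am_depth, 1L))
  right <- build_channel(mix(P2), .per_channel(rp$am_depth, 2L))
  left <- add_spikes(left, .per_channel(rp$spike_rate, 1L), .per_channel(rp$spike_amp, 1L))
  right <- add_spikes(right, .per_channel(rp$spike_rate, 2L), .per_channel(rp$spike_amp, 2L))
  list(left = left, right = right)
}

#' Generate a synthetic two-channel EEG recording
#'
#' Builds a piecewise-stationary recording: the baseline regime up to the
#' impact sample, the post-injury regime after it, and a 0.5 s saturating
#' square artifact written across both channels at the impact (emulating the
#' electrical artifact of the impactor). Given the same `subject_spec`
#' (including its seed) the output is bit-identical across calls.
#'
#' @param spec a [subject_spec()].
#' @return an object of class `eeg_recording`: list with `left`, `right`
#'   (microvolts), `fs`, `cci_sample` (0-based index of the first post-impact
#'   sample), `ipsilateral` (`"right"`: the right hemisphere is injured) and
#'   `meta` (the spec).
#' @export
generate_recording <- function(spec) {
  stopifnot(inherits(spec, "subject_spec"))
  fs <- spec$fs
  n_pre <- round(spec$cci_time * fs)
  n_post <- round((spec$duration - spec$cci_time) * fs)
  with_seed(spec$seed, {
    shape_curve <- NULL
    if (spec$shape_sd > 0) {
      # smooth log-gain curve at the 64 analysis bins, Gaussian kernel bw 2 Hz
      fb <- seq(0.5, 32, by = 0.5)
      z <- stats::rnorm(64)
      Kk <- exp(-outer(fb, fb, "-")^2 / (2 * 2^2))
      eps <- as.vector(Kk %*% z)
      eps <- eps / stats::sd(eps) * spec$shape_sd
      shape_curve <- function(f) exp(stats::approx(fb, eps, xout = f, rule = 2)$y / 2)
    } else {
      invisible(stats::rnorm(64))   # keep stream position independent of shape_sd
    }
    pre <- .synth_segment(n_pre, fs, spec$baseline, shape_curve)
    post <- .synth_segment(n_post, fs, spec$post, shape_curve)
    left <- c(pre$left, post$left)
    right <- c(pre$right, post$right)
    art <- n_pre + seq_len(round(0.5 * fs))
    sat <- 20 * max(spec$baseline$rms, spec$post$rms)
    left[art] <- sat
    right[art] <- sat
    structure(list(left = left, right = right, fs = fs, cci_sample = n_pre,
                   ipsilateral = "right", meta = spec),
              class = "eeg_recording")
  })
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("eeg_recording: %s, %.0f s at %g Hz, impact at %.1f s (sample %d)\n",
              x$meta$strain, length(x$left) / x$fs, x$fs,
              x$cci_sample / x$fs, x$cci_sample))
  invisible(x)
}

#' Strain presets for the synthetic generator
#'
#' Encodes the qualitative pre/post-injury signal structure of the three rat
#' strains (perforant-path-kindling susceptible PPKS, outbred SD, and
#' kindling-resistant PPKR):
#' \itemize{
#'   \item PPKR baseline: excess slow (delta) power, deficit at 4--32 Hz.
#'   \item Post-injury spectral loss at intermediate/fast frequencies for SD
#'     (broadband) and PPKR (theta/beta), but unchanged band gains for PPKS.
#'   \item Post-injury interhemispheric coherence loss in the theta range for
#'     all strains, with delta-band coherence ordered PPKS < SD < PPKR.
#'   \item Post-injury ipsilateral (right) delta-burst modulation for PPKS and
#'     SD only (lowering spectral entropy).
#'   \item Post-injury ipsilateral sharp transients for PPKR only (raising
#'     kurtosis).
#' }
#'
#' @param fs,cci_time,duration,rms recording geometry and scale passed to
#'   [subject_spec()].
#' @return named list of `subject_spec` objects (seeds set to 0; cohort
#'   generation assigns per-subject seeds).
#' @export
strain_presets <- function(fs = 1024, cci_time = 120, duration = 1080, rms = 50) {
  base_gains <- c(delta = 1, theta = 0.9, alpha = 0.7, beta = 0.35)
  ppkr_gains <- c(delta = 1.7, theta = 0.6, alpha = 0.45, beta = 0.22)
  base_shared <- c(delta = 0.65, theta = 0.7, alpha = 0.7, beta = 0.6)
  base_spikes <- list(rate = 0.25, amp = 6)  # background transients, all strains
  mk <- function(strain, baseline, post)
    subject_spec(strain, baseline = baseline, post = post, cci_time = cci_time,
                 duration = duration, fs = fs, seed = 0)
  bl <- function(gains)
    regime_params(band_gains = gains, shared_fraction = base_shared,
                  spike_rate = base_spikes$rate, spike_amp = base_spikes$amp,
                  rms = rms)
  list(
    PPKS = mk("PPKS",
      bl(base_gains),
      regime_params(band_gains = base_gains,
                    shared_fraction = c(delta = 0.25, theta = 0.35, alpha = 0.7, beta = 0.6),
                    am_depth = c(0, 0.75),
                    spike_rate = base_spikes$rate, spike_amp = base_spikes$amp,
                    rms = rms)),
    SD = mk("SD",
      bl(base_gains),
      regime_params(band_gains = c(delta = 1, theta = 0.495, alpha = 0.385, beta = 0.193),
                    shared_fraction = c(delta = 0.5, theta = 0.35, alpha = 0.7, beta = 0.6),
                    am_depth = c(0, 0.45),
                    spike_rate = base_spikes$rate, spike_amp = base_spikes$amp,
                    rms = rms)),
    PPKR = mk("PPKR",
      bl(ppkr_gains),
      regime_params(band_gains = c(delta = 1.7, theta = 0.42, alpha = 0.45, beta = 0.165),
                    shared_fraction = c(delta = 0.82, theta = 0.4, alpha = 0.7, beta = 0.6),
                    spike_rate = c(0.25, 1.3), spike_amp = c(6, 9),
                    rms = rms))
  )
}

#' Between-subject jitter for cohort generation
#'
#' Controls how individual subjects deviate from their strain preset. Gain and
#' RMS multipliers are log-normal and shared between baseline and post regimes
#' (stable individual traits; within-subject contrasts are preserved), with a
#' smaller independent post-regime gain jitter; shared fractions are jittered
#' on the logit scale; `shape_sd` feeds the smooth per-subject spectral-shape
#' perturbation of [subject_spec()].
#'
#' @param gain_sd,post_gain_sd,shape_sd,shared_sd,rms_sd,exponent_sd,am_sd,spike_rate_sd
#'   jitter scales (log, logit or additive as described above).
#' @return a named list of class `cohort_jitter`.
#' @export
cohort_jitter <- function(gain_sd = 0.1, post_gain_sd = 0.05, shape_sd = 0.22,
                          shared_sd = 0.25, rms_sd = 0.15, exponent_sd = 0.05,
                          am_sd = 0.04, spike_rate_sd = 0.6) {
  structure(list(gain_sd = gain_sd, post_gain_sd = post_gain_sd,
                 shape_sd = shape_sd, shared_sd = shared_sd, rms_sd = rms_sd,
                 exponent_sd = exponent_sd, am_sd = am_sd,
                 spike_rate_sd = spike_rate_sd), class = "cohort_jitter")
}

.jitter_spec <- function(spec, jit, subject_seed) {
  with_seed(subject_seed, {
    g_subj <- exp(stats::rnorm(4, 0, jit$gain_sd))
    g_post <- exp(stats::rnorm(4, 0, jit$post_gain_sd))
    rms_m <- exp(stats::rnorm(1, 0, jit$rms_sd))
    exp_d <- stats::rnorm(1, 0, jit$exponent_sd)
    sh_b <- stats::rnorm(4, 0, jit$shared_sd)
    sh_p <- stats::rnorm(4, 0, jit$shared_sd)
    am_d <- stats::rnorm(2, 0, jit$am_sd)
    sr_m <- exp(stats::rnorm(2, 0, jit$spike_rate_sd))

    jl <- function(sf, d) ifelse(sf > 0 & sf < 1, stats::plogis(stats::qlogis(sf) + d), sf)
    tweak <- function(rp, gmul, shd, post = FALSE) {
      rp$band_gains <- rp$band_gains * gmul
      rp$shared_fraction[] <- jl(rp$shared_fraction, shd)
      rp$psd_exponent <- rp$psd_exponent + exp_d
      rp$rms <- rp$rms * rms_m
      if (post) {
        am <- rep(rp$am_depth, length.out = 2)
        am <- ifelse(am > 0, pmin(pmax(am + am_d, 0), 1), am)
        rp$am_depth <- am
      }
      sr <- rep(rp$spike_rate, length.out = 2)
      rp$spike_rate <- sr * ifelse(sr > 0, sr_m, 1)
      rp
    }
    spec$baseline <- tweak(spec$baseline, g_subj, sh_b)
    spec$post <- tweak(spec$post, g_subj * g_post, sh_p, post = TRUE)
    spec$shape_sd <- jit$shape_sd
    spec$seed <- (subject_seed + 1013904223) %% 2147483647
    spec
  })
}

.flatten_spec <- function(spec) {
  rp_cols <- function(rp, prefix) {
    am <- rep(rp$am_depth, length.out = 2)
    sr <- rep(rp$spike_rate, length.out = 2)
    sa <- rep(rp$spike_amp, length.out = 2)
    out <- c(as.list(stats::setNames(rp$band_gains, paste0(prefix, "_gain_", names(rp$band_gains)))),
             as.list(stats::setNames(rp$shared_fraction, paste0(prefix, "_shared_", names(rp$shared_fraction)))),
             stats::setNames(list(rp$psd_exponent, rp$rms, am[1], am[2], sr[1], sr[2], sa[1], sa[2]),
                             paste0(prefix, c("_exponent", "_rms", "_am_left", "_am_right",
                                              "_spike_rate_left", "_spike_rate_right",
                                              "_spike_amp_left", "_spike_amp_right"))))
    out
  }
  as.data.frame(c(list(strain = spec$strain, sex = spec$sex, fs = spec$fs,
                       cci_time = spec$cci_time, duration = spec$duration,
                       seed = spec$seed, shape_sd = spec$shape_sd),
                  rp_cols(spec$baseline, "baseline"), rp_cols(spec$post, "post")))
}

#' Cohort manifest: per-subject ground-truth parameters
#'
#' Draws `n_per_strain` subjects per strain from the presets, applying
#' between-subject jitter, and records every generator parameter per subject.
#' Subject seeds are derived from the master seed by a counter-based scheme
#' (`(seed * 48271 + index) mod (2^31 - 1)`, index in fixed strain order), so
#' the manifest does not depend on evaluation order and two calls with the
#' same seed are identical.
#'
#' @param n_per_strain subjects per strain (>= 1).
#' @param seed master integer seed.
#' @param presets named list of `subject_spec` (default [strain_presets()]).
#' @param jitter a [cohort_jitter()].
#' @return data.frame with one row per subject (`subject_id`, `strain`, seed,
#'   and all regime parameters).
#' @export
cohort_manifest <- function(n_per_strain, seed = 1L, presets = strain_presets(),
                            jitter = cohort_jitter()) {
  if (!.is_count(n_per_strain) || n_per_strain < 1)
    stop("n_per_strain must be a positive integer")
  rows <- list()
  idx <- 0L
  for (strain in names(presets)) {
    for (j in seq_len(n_per_strain)) {
      idx <- idx + 1L
      sseed <- .derive_seed(seed, idx)
      spec <- .jitter_spec(presets[[strain]], jitter, sseed)
      spec$sex <- if (j %% 2L == 0L) "M" else "F"
      row <- .flatten_spec(spec)
      row$subject_id <- sprintf("%s_%02d", strain, j)
      row$sex <- spec$sex
      rows[[idx]] <- row
    }
  }
  out <- do.call(rbind, rows)
  out[, c("subject_id", setdiff(names(out), "subject_id"))]
}

#' Rebuild a subject_spec from one manifest row
#'
#' @param row a single-row data.frame from [cohort_manifest()].
#' @return a `subject_spec` that regenerates that subject's recording exactly.
#' @export
spec_from_manifest <- function(row) {
  stopifnot(nrow(row) == 1L)
  rp_from <- function(prefix) {
    g <- function(nm) row[[paste0(prefix, "_", nm)]]
    regime_params(
      psd_exponent = g("exponent"),
      band_gains = c(delta = g("gain_delta"), theta = g("gain_theta"),
                     alpha = g("gain_alpha"), beta = g("gain_beta")),
      shared_fraction = c(delta = g("shared_delta"), theta = g("shared_theta"),
                          alpha = g("shared_alpha"), beta = g("shared_beta")),
      am_depth = c(g("am_left"), g("am_right")),
      spike_rate = c(g("spike_rate_left"), g("spike_rate_right")),
      spike_amp = c(g("spike_amp_left"), g("spike_amp_right")),
      rms = g("rms"))
  }
  subject_spec(row$strain, baseline = rp_from("baseline"), post = rp_from("post"),
               cci_time = row$cci_time, duration = row$duration, fs = row$fs,
               seed = row$seed, sex = row$sex, shape_sd = row$shape_sd)
}

#' Generate a synthetic cohort
#'
#' @inheritParams cohort_manifest
#' @return list with `recordings` (list of `eeg_recording`, one per manifest
#'   row) and `manifest` (the [cohort_manifest()] data.frame).
#' @export
generate_cohort <- function(n_per_strain, seed = 1L, presets = strain_presets(),
                            jitter = cohort_jitter()) {
  man <- cohort_manifest(n_per_strain, seed, presets, jitter)
  recs <- lapply(seq_len(nrow(man)), function(i) generate_recording(spec_from_manifest(man[i, ])))
  names(recs) <- man$subject_id
  list(recordings = recs, manifest = man)
}

#' Write / read a recording as CSV with a JSON sidecar manifest
#'
#' The CSV has columns `time_s`, `left_uv`, `right_uv`; the sidecar
#' (`<path>.json`) stores the sampling rate, impact sample, side mapping and
#' subject metadata needed to re-import the recording.
#'
#' @param rec an `eeg_recording`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  n <- length(rec$left)
  df <- data.frame(time_s = (0:(n - 1)) / rec$fs,
                   left_uv = rec$left, right_uv = rec$right)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- rec$meta
  side <- list(fs = rec$fs, cci_sample = rec$cci_sample,
               ipsilateral = rec$ipsilateral,
               strain = meta$strain, sex = meta$sex, seed = meta$seed,
               cci_time = meta$cci_time, duration = meta$duration)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording_csv
#' @param strain,sex metadata used if the sidecar is missing.
#' @export
read_recording_csv <- function(path, strain = "SD", sex = "F") {
  df <- utils::read.csv(path)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    fs <- side$fs
    cci <- side$cci_sample
    strain <- side$strain %||% strain
    sex <- side$sex %||% sex
    ipsi <- side$ipsilateral %||% "right"
  } else {
    fs <- 1 / stats::median(diff(df$time_s))
    cci <- which.max(abs(diff(df$left_uv)))  # artifact onset heuristic
    ipsi <- "right"
  }
  structure(list(left = df$left_uv, right = df$right_uv, fs = fs,
                 cci_sample = cci, ipsilateral = ipsi,
                 meta = list(strain = strain, sex = sex)),
            class = "eeg_recording")
}
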