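# --- Welch spectral machinery -------------------------------------------------
# Hamming window of 512 points with 128-point overlap (hop 384), segments
# mean-detrended, FFT zero-padded to 2048 so the native grid is 0.5 Hz at
# fs = 1024; one-sided density scaling 2 / (fs * sum(w^2)).

.hamming <- function(n) 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))

# returns list(freq, pxx[, pyy, pxy], n_windows) on the full one-sided grid
.welch <- function(x, y = NULL, fs, window = 512L, overlap = 128L, nfft = 2048L) {
  n <- length(x)
  hop <- window - overlap
  if (n < window)
    stop(sprintf("signal shorter than one %d-point window (%d samples)", window, n))
  m <- (n - window) %/% hop + 1L
  w <- .hamming(window)
  idx <- outer(seq_len(window), (0:(m - 1L)) * hop, "+")
  seg <- function(z) {
    S <- matrix(z[idx], nrow = window)
    S <- (S - rep(colMeans(S), each = window)) * w
    stats::mvfft(rbind(S, matrix(0, nfft - window, m)))
  }
  X <- seg(x)
  nh <- nfft %/% 2L
  keep <- 1:(nh + 1L)
  scale <- 1 / (fs * sum(w^2))
  onesided <- function(P) {
    P <- P[keep, , drop = FALSE]
    P[2:nh, ] <- 2 * P[2:nh, ]
    P * scale
  }
  avg <- function(P) if (is.complex(P)) {
    complex(real = rowMeans(Re(P)), imaginary = rowMeans(Im(P)))
  } else rowMeans(P)
  out <- list(freq = (0:nh) * fs / nfft, n_windows = m,
              pxx = avg(onesided(Mod(X)^2)))
  if (!is.null(y)) {
    if (length(y) != n) stop("x and y must have equal length")
    Y <- seg(y)
    out$pyy <- avg(onesided(Mod(Y)^2))
    out$pxy <- avg(onesided(X * Conj(Y)))
  }
  out
}

# indices of the 64 analysis bins (0.5, 1.0, ..., 32.0 Hz) on the Welch grid
.bin_index <- function(fs, nfft = 2048L) {
  step <- 0.5 * nfft / fs
  if (abs(step - round(step)) > 1e-9)
    stop("fs must place the 0.5 Hz bin grid on the FFT grid (fs in 1024/512/256/128 Hz)")
  1L + round(step) * (1:64)
}

#' Analysis frequency bins
#' @return the 64 bin centres, 0.5 to 32 Hz in 0.5 Hz steps.
#' @export
bin_freqs <- function() seq(0.5, 32, by = 0.5)

# bin indices per canonical band: delta 0.5-4, theta 4.5-8, alpha 8.5-13,
# beta 13.5-32 Hz (partitioning all 64 bins: 8 + 8 + 10 + 38)
.band_bins <- list(delta = 1:8, theta = 9:16, alpha = 17:26, beta = 27:64)

#' Canonical frequency bands
#' @return named list of bin indices into [bin_freqs()] for the delta
#'   (0.5--4 Hz), theta (4.5--8 Hz), alpha (8.5--13 Hz) and beta
#'   (13.5--32 Hz) bands.
#' @export
band_bins <- function() .band_bins

#' Binned Welch power spectral density
#'
#' Welch-averaged short-time power spectrum: Hamming window of 512 points,
#' 128-point overlap, per-segment mean removal, FFT zero-padded to 2048
#' points, one-sided density scaling. The density is returned on the 64-bin
#' analysis grid (0.5--32 Hz in 0.5 Hz steps); frequencies outside that range
#' are discarded.
#'
#' @param x numeric signal (microvolts).
#' @param fs sampling rate in Hz; must put the 0.5 Hz grid on the FFT grid.
#' @param window,overlap,nfft Welch parameters (defaults as above).
#' @return object of class `binned_spectrum`: `freq` (64 centres), `power`
#'   (uV^2/Hz), `fs`, `n_windows`, `normalized` flag, `norm_constant`.
#' @export
eeg_psd <- function(x, fs, window = 512L, overlap = 128L, nfft = 2048L) {
  W <- .welch(x, fs = fs, window = window, overlap = overlap, nfft = nfft)
  bi <- .bin_index(fs, nfft)
  structure(list(freq = bin_freqs(), power = W$pxx[bi], fs = fs,
                 n_windows = W$n_windows, normalized = FALSE,
                 norm_constant = NA_real_),
            class = "binned_spectrum")
}

#' @export
print.binned_spectrum <- function(x, ...) {
  cat(sprintf("binned_spectrum: 64 bins 0.5-32 Hz (%s), %d Welch windows\n",
              if (x$normalized) sprintf("normalized, constant %.4g uV^2", x$norm_constant)
              else "uV^2/Hz", x$n_windows))
  invisible(x)
}

#' Normalize a spectrum to a subject's baseline total power
#'
#' @param spec a `binned_spectrum` (non-normalized).
#' @param baseline_total the subject's baseline total power in uV^2 (> 0).
#' @return the spectrum with every bin divided by `baseline_total`, flagged
#'   as normalized with the constant recorded.
#' @export
normalize_to_baseline <- function(spec, baseline_total) {
  stopifnot(inherits(spec, "binned_spectrum"))
  if (!is.numeric(baseline_total) || length(baseline_total) != 1L ||
      !is.finite(baseline_total) || baseline_total <= 0)
    stop("baseline_total must be a single positive value")
  if (spec$normalized) stop("spectrum is already normalized")
  spec$power <- spec$power / baseline_total
  spec$normalized <- TRUE
  spec$norm_constant <- baseline_total
  spec
}

#' Total power of a binned spectrum
#'
#' Integral of the density over the 64 analysis bins, `sum(power) * 0.5` Hz.
#' Refuses normalized input so a baseline constant cannot be applied twice.
#'
#' @param spec a non-normalized `binned_spectrum`.
#' @return total power in uV^2.
#' @export
total_power <- function(spec) {
  stopifnot(inherits(spec, "binned_spectrum"))
  if (spec$normalized)
    stop("total_power expects a non-normalized spectrum")
  sum(spec$power) * 0.5
}

#' Percent band power
#'
#' @param spec a `binned_spectrum`.
#' @param band one of `"delta"`, `"theta"`, `"alpha"`, `"beta"`.
#' @return 100 * (band bin sum) / (all-bin sum). The four bands partition the
#'   64 bins, so the four percentages sum to 100.
#' @export
pct_band_power <- function(spec, band = c("delta", "theta", "alpha", "beta")) {
  stopifnot(inherits(spec, "binned_spectrum"))
  band <- match.arg(band)
  tot <- sum(spec$power)
  if (tot <= 0) stop("zero total power: percent band power undefined")
  100 * sum(spec$power[.band_bins[[band]]]) / tot
}

#' Interhemispheric magnitude-squared coherence
#'
#' `Cxy(f) = |Pxy|^2 / (Pxx * Pyy)` with the cross- and auto-spectra averaged
#' across Welch windows (Hamming 512, overlap 128, zero-padded to 2048)
#' before the ratio is formed; with a single window the ratio is identically
#' 1, so at least two windows are required. Returned on the 64-bin grid.
#'
#' @param x,y the two channels (equal length).
#' @param fs sampling rate in Hz.
#' @inheritParams eeg_psd
#' @return object of class `coherence_spectrum`: `freq`, `cxy` in `[0,1]`,
#'   `fs`, `n_windows`.
#' @export
eeg_coherence <- function(x, y, fs, window = 512L, overlap = 128L, nfft = 2048L) {
  hop <- window - overlap
  if ((length(x) - window) %/% hop + 1L < 2L)
    stop("coherence needs at least two Welch windows (single-window coherence is identically 1)")
  W <- .welch(x, y, fs = fs, window = window, overlap = overlap, nfft = nfft)
  cxy <- Mod(W$pxy)^2 / (W$pxx * W$pyy)
  cxy[!is.finite(cxy)] <- 0
  if (max(cxy) > 1 + 1e-9)
    stop("internal error: coherence exceeded 1 beyond numerical slack")
  cxy <- pmin(pmax(cxy, 0), 1)   # clip within 1e-12-scale float error only
  bi <- .bin_index(fs, nfft)
  structure(list(freq = bin_freqs(), cxy = cxy[bi], fs = fs,
                 n_windows = W$n_windows),
            class = "coherence_spectrum")
}

#' @export
print.coherence_spectrum <- function(x, ...) {
  cat(sprintf("coherence_spectrum: 64 bins 0.5-32 Hz, %d Welch windows\n",
              x$n_windows))
  invisible(x)
}

#' Mean band coherence
#'
#' @param cs a `coherence_spectrum`.
#' @param band band name; the summary is the unweighted mean of `cxy` over the
#'   band's bins.
#' @export
band_coherence <- function(cs, band = c("delta", "theta", "alpha", "beta")) {
  stopifnot(inherits(cs, "coherence_spectrum"))
  band <- match.arg(band)
  mean(cs$cxy[.band_bins[[band]]])
}

#' Spectral entropy of a binned spectrum
#'
#' Shannon entropy, in nats, of the spectrum renormalized to a probability
#' distribution over the 64 bins: `H = -sum(P * log(P))` with zero bins
#' contributing zero. Ranges from 0 (single-bin spectrum) to `log(64)`
#' (flat spectrum).
#'
#' @param spec a `binned_spectrum` (normalization state is irrelevant; the
#'   bins are renormalized to sum to one).
#' @return entropy in nats.
#' @export
spectral_entropy <- function(spec) {
  stopifnot(inherits(spec, "binned_spectrum"))
  p <- spec$power
  if (any(p < 0)) stop("negative power bin")
  tot <- sum(p)
  if (tot <= 0) stop("all-zero spectrum: entropy undefined")
  p <- p / tot
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Kurtosis (fourth standardized moment)
#'
#' Population (Pearson) estimator `mean((x - mean(x))^4) / var_pop(x)^2` with
#' the population variance in the denominator; no small-sample correction and
#' no subtraction of 3, so a Gaussian signal scores about 3 and the
#' alternating +1/-1 sequence scores exactly 1.
#'
#' @param x numeric signal; must not be constant.
#' @return kurtosis (dimensionless, >= 1 for any non-constant signal).
#' @export
kurtosis <- function(x) {
  m <- mean(x)
  v <- mean((x - m)^2)
  if (v == 0) stop("kurtosis undefined for a constant signal")
  mean((x - m)^4) / v^2
}

#' Line length
#'
#' Cumulative point-to-point path length of the signal trace. The default
#' (`type = "path"`) treats the trace as a planar curve with unit step along
#' the sample axis: `sum(sqrt(1 + diff(y)^2))`; the conventional
#' amplitude-only variant (`type = "amplitude"`) is `sum(abs(diff(y)))`.
#'
#' @param x numeric signal of length >= 2 (microvolts).
#' @param type `"path"` (default) or `"amplitude"`.
#' @return line length (dimensionless mixed units for `"path"`).
#' @export
line_length <- function(x, type = c("path", "amplitude")) {
  type <- match.arg(type)
  if (length(x) < 2L) stop("line length needs at least 2 samples")
  d <- diff(x)
  if (type == "path") sum(sqrt(1 + d^2)) else sum(abs(d))
}

#' Names of the 19 epoch features
#'
#' @return character vector: total power; percent band power per side and
#'   band (8); mean band coherence (4); entropy, kurtosis and line length per
#'   side (6).
#' @export
feature_names <- function() {
  c("total_power",
    paste0("pct_", rep(c("delta", "theta", "alpha", "beta"), 2), "_",
           rep(c("ipsi", "contra"), each = 4)),
    paste0("coh_", c("delta", "theta", "alpha", "beta")),
    paste0(rep(c("entropy", "kurtosis", "line_length"), each = 2), "_",
           c("ipsi", "contra")))
}

#' Compute the 19-feature vector of one epoch
#'
#' Total (non-normalized) power, averaged over the two channels; ipsilateral
#' and contralateral percent band power from the per-epoch non-normalized
#' spectra; mean interhemispheric magnitude-squared coherence per band;
#' spectral entropy, kurtosis and line length per side. The amplitude-only
#' line-length variant is appended as `line_length_amp_ipsi`/`_contra` for
#' sensitivity analyses but is not part of the canonical 19.
#'
#' @param epoch an `eeg_epoch` from [extract_epochs()].
#' @param ipsilateral which channel is ipsilateral to the injury; defaults to
#'   the epoch's own mapping (right hemisphere injured).
#' @return one-row data.frame with [feature_names()] plus the two
#'   `line_length_amp_*` columns.
#' @export
build_features <- function(epoch, ipsilateral = NULL) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  ipsilateral <- ipsilateral %||% epoch$ipsilateral
  ipsilateral <- match.arg(ipsilateral, c("right", "left"))
  ip <- if (ipsilateral == "right") epoch$right else epoch$left
  co <- if (ipsilateral == "right") epoch$left else epoch$right
  fs <- epoch$fs
  sp_ip <- eeg_psd(ip, fs)
  sp_co <- eeg_psd(co, fs)
  cs <- eeg_coherence(ip, co, fs)
  out <- c(total_power = mean(c(total_power(sp_ip), total_power(sp_co))))
  for (side in c("ipsi", "contra")) {
    sp <- if (side == "ipsi") sp_ip else sp_co
    for (b in c("delta", "theta", "alpha", "beta"))
      out[paste0("pct_", b, "_", side)] <- pct_band_power(sp, b)
  }
  for (b in c("delta", "theta", "alpha", "beta"))
    out[paste0("coh_", b)] <- band_coherence(cs, b)
  out["entropy_ipsi"] <- spectral_entropy(sp_ip)
  out["entropy_contra"] <- spectral_entropy(sp_co)
  out["kurtosis_ipsi"] <- kurtosis(ip)
  out["kurtosis_contra"] <- kurtosis(co)
  out["line_length_ipsi"] <- line_length(ip)
  out["line_length_contra"] <- line_length(co)
  out["line_length_amp_ipsi"] <- line_length(ip, "amplitude")
  out["line_length_amp_contra"] <- line_length(co, "amplitude")
  as.data.frame(as.list(out))
}
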