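# Independent oracles, coded from first principles (no shared code paths with
# the package internals).

# Direct-DFT Welch oracle: explicit complex exponential sums per window on
# the 64-bin analysis grid. Returns pxx (and pyy/cxy when y given).
dft_welch_oracle <- function(x, y = NULL, fs, window = 512L, overlap = 128L,
                             nfft = 2048L) {
  hop <- window - overlap
  m <- (length(x) - window) %/% hop + 1L
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(window - 1)) / (window - 1))
  freqs <- seq(0.5, 32, by = 0.5)
  # E[f, t] = exp(-2 pi i f t / fs), t = 0..window-1 (zero-padding beyond the
  # window contributes nothing to the sum)
  E <- exp(-2i * pi * outer(freqs, (0:(window - 1)) / fs))
  sxx <- syy <- numeric(64)
  sxy <- complex(64)
  for (j in seq_len(m)) {
    seg <- x[(j - 1) * hop + 1:window]
    X <- as.vector(E %*% ((seg - mean(seg)) * w))
    sxx <- sxx + Mod(X)^2
    if (!is.null(y)) {
      segy <- y[(j - 1) * hop + 1:window]
      Y <- as.vector(E %*% ((segy - mean(segy)) * w))
      syy <- syy + Mod(Y)^2
      sxy <- sxy + X * Conj(Y)
    }
  }
  scale <- 2 / (fs * sum(w^2)) / m    # one-sided density, window-averaged
  out <- list(freq = freqs, pxx = sxx * scale)
  if (!is.null(y)) {
    out$pyy <- syy * scale
    out$cxy <- Mod(sxy / m)^2 / ((sxx / m) * (syy / m))
  }
  out
}

# Naive risk-score enumeration oracle: plain loops over subsets, sign
# assignments and intercepts, log-likelihood computed per subject.
brute_risk_oracle <- function(X, y, max_terms = 5, pen = 4.5,
                              intercepts = -10:10) {
  p <- ncol(X)
  splits <- lapply(seq_len(p), function(j) find_split(X[[j]], y, names(X)[j]))
  ind <- sapply(seq_len(p), function(j) {
    s <- splits[[j]]
    if (s$direction == "<") X[[j]] < s$threshold else X[[j]] >= s$threshold
  })
  best <- list(obj = -Inf)
  for (k in 0:min(max_terms, p)) {
    subs <- if (k == 0) list(integer(0)) else asplit(utils::combn(p, k), 2)
    for (sub in subs) {
      signsets <- if (k == 0) list(numeric(0)) else
        asplit(as.matrix(do.call(expand.grid, rep(list(c(1, -1)), k))), 1)
      for (sg in signsets) for (b0 in intercepts) {
        lp <- b0 + (if (k == 0) 0 else as.vector(ind[, sub, drop = FALSE] %*% sg))
        ll <- sum(ifelse(y, stats::plogis(lp, log.p = TRUE),
                         stats::plogis(-lp, log.p = TRUE)))
        obj <- ll - pen * k
        if (obj > best$obj + 1e-9)
          best <- list(obj = obj, sub = as.integer(sub), sg = sg, b0 = b0)
      }
    }
  }
  best
}

# Naive split-scan oracle: recomputes the LogWorth-maximizing threshold with
# table()-based 2x2 statistics.
naive_split_oracle <- function(x, y) {
  ux <- sort(unique(x))
  thr <- (ux[-length(ux)] + ux[-1]) / 2
  lw <- vapply(thr, function(t) {
    tab <- table(factor(x < t, levels = c(TRUE, FALSE)),
                 factor(y, levels = c(TRUE, FALSE)))
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    p <- if (any(E < 1)) stats::fisher.test(tab)$p.value else {
      o <- as.vector(tab); e <- as.vector(E)
      stats::pchisq(2 * sum(ifelse(o > 0, o * log(o / e), 0)), 1,
                    lower.tail = FALSE)
    }
    -log10(p)
  }, 0)
  list(threshold = thr[which.max(lw)], logworth = max(lw), all = lw)
}

# manual construction of the package's spectral/epoch containers for
# arithmetic-level tests
make_spec <- function(power, normalized = FALSE, norm_constant = NA_real_) {
  structure(list(freq = bin_freqs(), power = power, fs = 1024,
                 n_windows = 1L, normalized = normalized,
                 norm_constant = norm_constant),
            class = "binned_spectrum")
}

make_epoch <- function(left, right, fs, label = "baseline") {
  structure(list(label = label, left = left, right = right, fs = fs,
                 ipsilateral = "right", subject = "TEST", start_sample = 0L,
                 filtered = TRUE),
            class = "eeg_epoch")
}

# short-duration recording specs are disallowed by the epoch scheme, so test
# fixtures use the minimum legal geometry at a reduced sampling rate
quick_spec <- function(strain = "SD", baseline = regime_params(),
                       post = regime_params(), fs = 128, seed = 1,
                       shape_sd = 0) {
  subject_spec(strain, baseline = baseline, post = post, cci_time = 90,
               duration = 1050, fs = fs, seed = seed, shape_sd = shape_sd)
}

# long-format 64-bin Gaussian data for bin-wise model tests
sim_binwise_data <- function(n_per_group, groups = c("A", "B"), effect = 0,
                             effect_bins = integer(0), sd = 1) {
  freqs <- bin_freqs()
  out <- expand.grid(subject = seq_len(n_per_group * length(groups)),
                     freq = freqs)
  out$strain <- rep(rep(groups, each = n_per_group), times = length(freqs))
  out$subject <- paste0(out$strain, out$subject)
  out$value <- stats::rnorm(nrow(out), sd = sd)
  sel <- out$strain == groups[2] & out$freq %in% freqs[effect_bins]
  out$value[sel] <- out$value[sel] + effect
  out
}

sim_binwise_null <- function(n_per_group) sim_binwise_data(n_per_group)
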