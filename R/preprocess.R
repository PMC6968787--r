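# Epoch scheme, locked to the impact sample (0-based, half-open intervals):
#   baseline  [cci - 90 s, cci - 30 s)   (60 s ending 0.5 min before impact)
#   post_0.5  [cci + 30 s, cci + 90 s)
#   post_5    [cci + 300 s, cci + 360 s)
#   post_10   [cci + 600 s, cci + 660 s)
#   post_15   [cci + 900 s, cci + 960 s)
.epoch_offsets <- c(baseline = -90, post_0.5 = 30, post_5 = 300,
                    post_10 = 600, post_15 = 900)

#' Epoch labels of the acute CCI analysis scheme
#' @return character vector of the five labels in temporal order.
#' @export
epoch_labels <- function() names(.epoch_offsets)

#' Extract the five 60 s analysis epochs around the impact
#'
#' Each epoch is a half-open sample interval `[start, start + 60 s)` with
#' 0-based start index `cci_sample + round(offset * fs)` (offsets -90, +30,
#' +300, +600, +900 s). The 0.5 s impact artifact lies in the excluded
#' `[cci - 30 s, cci + 30 s)` gap, so no epoch can overlap it. By default each
#' epoch is bandpass filtered (0.5--32 Hz, zero phase) after extraction, so
#' the artifact cannot ring into the analysed samples.
#'
#' @param rec an `eeg_recording`.
#' @param labels which epochs to extract (default all five).
#' @param filtered apply [bandpass()] per channel (default `TRUE`).
#' @param filt optional pre-designed `fir_filter` passed to [bandpass()].
#' @return named list of `eeg_epoch` objects: each has `label`, `left`,
#'   `right` (exactly `round(60 * fs)` samples), `fs`, `ipsilateral`,
#'   `subject` and `filtered`.
#' @export
extract_epochs <- function(rec, labels = epoch_labels(), filtered = TRUE,
                           filt = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  labels <- match.arg(labels, epoch_labels(), several.ok = TRUE)
  fs <- rec$fs
  n <- length(rec$left)
  len <- round(60 * fs)
  if (filtered && is.null(filt)) filt <- .cached_bandpass(fs)
  out <- list()
  for (lab in labels) {
    start <- rec$cci_sample + round(.epoch_offsets[[lab]] * fs)  # 0-based
    if (start < 0 || start + len > n)
      stop(sprintf("recording too short: epoch '%s' needs samples [%d, %d) but only %d available",
                   lab, start, start + len, n))
    sel <- (start + 1L):(start + len)   # convert to R's 1-based indexing
    l <- rec$left[sel]
    r <- rec$right[sel]
    if (filtered) {
      l <- bandpass(l, fs, filt)
      r <- bandpass(r, fs, filt)
    }
    out[[lab]] <- structure(
      list(label = lab, left = l, right = r, fs = fs,
           ipsilateral = rec$ipsilateral %||% "right",
           subject = rec$meta$strain %||% NA_character_,
           start_sample = start, filtered = filtered),
      class = "eeg_epoch")
  }
  out
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("eeg_epoch '%s': %d samples at %g Hz (%s)\n", x$label,
              length(x$left), x$fs,
              if (isTRUE(x$filtered)) "0.5-32 Hz bandpassed" else "raw"))
  invisible(x)
}
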