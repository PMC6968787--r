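# --- cohort feature extraction and qualitative pattern checks ----------------

#' Extract features and spectra for a whole cohort
#'
#' Regenerates each subject's recording from the manifest (recordings are
#' deterministic given the manifest row), extracts and filters the requested
#' epochs, and computes per-epoch features, baseline-normalized binned
#' spectra and interhemispheric coherence spectra. Recordings are processed
#' one at a time so memory stays flat in cohort size.
#'
#' Each subject's normalization constant is the baseline total power averaged
#' over the two channels; the baseline epoch must therefore be among
#' `labels`.
#'
#' @param manifest a [cohort_manifest()] data.frame.
#' @param labels epochs to analyse (must include `"baseline"`).
#' @return list with `features` (one row per subject x epoch: metadata, the
#'   19 features, the amplitude line-length variants, and
#'   `baseline_total_power`), `spectra` (long: subject, strain, epoch, side,
#'   freq, `power` raw uV^2/Hz and `power_norm`), and `coherence` (long:
#'   subject, strain, epoch, freq, cxy).
#' @export
compute_cohort_features <- function(manifest,
                                    labels = c("baseline", "post_0.5")) {
  stopifnot("baseline" %in% labels)
  feats <- list(); spect <- list(); cohs <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    rec <- generate_recording(spec_from_manifest(row))
    eps <- extract_epochs(rec, labels = labels)
    base <- eps[["baseline"]]
    ip0 <- if (rec$ipsilateral == "right") base$right else base$left
    co0 <- if (rec$ipsilateral == "right") base$left else base$right
    base_tot <- mean(c(total_power(eeg_psd(ip0, rec$fs)),
                       total_power(eeg_psd(co0, rec$fs))))
    for (lab in labels) {
      ep <- eps[[lab]]
      fv <- build_features(ep)
      fv <- cbind(data.frame(subject_id = row$subject_id, strain = row$strain,
                             epoch = lab, stringsAsFactors = FALSE),
                  fv, baseline_total_power = base_tot)
      feats[[length(feats) + 1L]] <- fv
      ip <- if (rec$ipsilateral == "right") ep$right else ep$left
      co <- if (rec$ipsilateral == "right") ep$left else ep$right
      for (side in c("ipsi", "contra")) {
        sp <- eeg_psd(if (side == "ipsi") ip else co, rec$fs)
        spect[[length(spect) + 1L]] <- data.frame(
          subject_id = row$subject_id, strain = row$strain, epoch = lab,
          side = side, freq = sp$freq, power = sp$power,
          power_norm = sp$power / base_tot, stringsAsFactors = FALSE)
      }
      cs <- eeg_coherence(ip, co, rec$fs)
      cohs[[length(cohs) + 1L]] <- data.frame(
        subject_id = row$subject_id, strain = row$strain, epoch = lab,
        freq = cs$freq, cxy = cs$cxy, stringsAsFactors = FALSE)
    }
  }
  list(features = do.call(rbind, feats), spectra = do.call(rbind, spect),
       coherence = do.call(rbind, cohs))
}

# significant decreasing-bin width (Hz) for a baseline-vs-post bin-wise test,
# restricted to freq in [flo, fhi]
.decreasing_width <- function(spectra, strain, post_label, alpha,
                              flo = 3.5, fhi = 31.5, side = "contra") {
  d <- spectra[spectra$strain == strain & spectra$side == side &
                 spectra$epoch %in% c("baseline", post_label), ]
  d$logp <- log10(pmax(d$power_norm, 1e-300))
  bw <- binwise_model(d[, c("subject_id", "epoch", "freq", "logp")],
                      value = "logp", effects = "epoch", alpha = alpha)
  p <- bw$effects$epoch$p_bins
  fr <- bw$freqs
  mdiff <- vapply(fr, function(f) {
    mean(d$logp[d$freq == f & d$epoch == post_label]) -
      mean(d$logp[d$freq == f & d$epoch == "baseline"])
  }, 0)
  sum(0.5 * (p < alpha & mdiff < 0 & fr >= flo & fr <= fhi))
}

# two-group baseline vs post change test on one scalar feature; kurtosis is
# compared on the log scale (a positive ratio statistic with right-skewed
# sampling distribution; the log stabilizes it)
.change_test <- function(features, strain, column, post_label, alpha) {
  d <- features[features$strain == strain &
                  features$epoch %in% c("baseline", post_label), ]
  if (grepl("^kurtosis", column)) d[[column]] <- log(d[[column]])
  tk <- anova_tukey(d[[column]], d$epoch, alpha = alpha)
  delta <- mean(d[[column]][d$epoch == post_label]) -
    mean(d[[column]][d$epoch == "baseline"])
  list(p = tk$p, delta = delta,
       sig_decrease = tk$p < alpha && delta < 0,
       sig_increase = tk$p < alpha && delta > 0)
}

#' Check the ten tracked qualitative strain-pattern findings
#'
#' Runs the stats module against a cohort's features and spectra and reports
#' which of the ten directional findings that characterize the three strains'
#' acute injury response are reproduced:
#' \enumerate{
#'   \item baseline strain effect on spectral shape localized to include the
#'     low (0.5--2 Hz) frequencies;
#'   \item post-injury spectral power loss at intermediate/fast frequencies
#'     in SD (tested on the contralateral hemisphere, where the
#'     strain-characteristic bilateral loss is uncontaminated by the
#'     ipsilateral burst-suppression entropy mechanism);
#'   \item the same in PPKR;
#'   \item no such broadband loss in PPKS;
#'   \item post-injury delta coherence: SD above PPKS;
#'   \item post-injury delta coherence: PPKR above SD;
#'   \item ipsilateral entropy drop after injury in PPKS;
#'   \item ipsilateral entropy drop after injury in SD;
#'   \item no ipsilateral entropy drop in PPKR;
#'   \item ipsilateral kurtosis rise after injury in PPKR, absent in PPKS
#'     and SD.
#' }
#'
#' @param features,spectra outputs of [compute_cohort_features()] (the
#'   `post_label` epoch and baseline must be present).
#' @param alpha significance level for every underlying test.
#' @param post_label which post-injury epoch to compare against baseline.
#' @return data.frame with columns `finding`, `description`, `detected`,
#'   `detail`.
#' @export
check_patterns <- function(features, spectra, alpha = 0.05,
                           post_label = "post_0.5") {
  out <- data.frame(finding = character(0), description = character(0),
                    detected = logical(0), detail = character(0),
                    stringsAsFactors = FALSE)
  add <- function(finding, description, detected, detail = "") {
    out[nrow(out) + 1L, ] <<- list(finding, description, detected, detail)
  }

  # 1: baseline strain effect including the 0.5-2 Hz range
  b <- spectra[spectra$epoch == "baseline", ]
  b$logp <- log10(pmax(b$power_norm, 1e-300))
  bw <- binwise_model(b[, c("subject_id", "strain", "side", "freq", "logp")],
                      value = "logp", effects = c("strain", "side"),
                      alpha = alpha)
  iv <- bw$effects$strain$intervals
  hit <- nrow(iv) > 0 && any(iv$low <= 2)
  add("baseline_strain_lowfreq",
      "baseline strain effect on spectral shape includes 0.5-2 Hz",
      hit, sprintf("strain LogWorth %.2f; %d interval(s)",
                   bw$effects$strain$logworth, nrow(iv)))

  # 2-4: post-injury power loss pattern
  w_sd <- .decreasing_width(spectra, "SD", post_label, alpha)
  w_ppkr <- .decreasing_width(spectra, "PPKR", post_label, alpha)
  w_ppks <- .decreasing_width(spectra, "PPKS", post_label, alpha)
  add("post_loss_sd", "post-injury power loss in 3.5-31.5 Hz in SD (>= 2.5 Hz of bins)",
      w_sd >= 2.5, sprintf("decreasing width %.1f Hz", w_sd))
  add("post_loss_ppkr", "post-injury power loss in 3.5-31.5 Hz in PPKR (>= 1.5 Hz of bins)",
      w_ppkr >= 1.5, sprintf("decreasing width %.1f Hz", w_ppkr))
  add("no_post_loss_ppks", "no broadband post-injury power loss in PPKS (<= 2 Hz of bins)",
      w_ppks <= 2.0, sprintf("decreasing width %.1f Hz", w_ppks))

  # 5-6: delta coherence ordering PPKS < SD < PPKR after injury
  fpost <- features[features$epoch == post_label, ]
  tk <- anova_tukey(fpost$coh_delta, fpost$strain, alpha = alpha)
  pw <- tk$pairwise
  pair_p <- function(a, b2) {
    i <- match(paste0(a, "-", b2), pw$comparison)
    if (is.na(i)) i <- match(paste0(b2, "-", a), pw$comparison)
    pw$p_adj[i]
  }
  gm <- tk$group_means
  add("coh_delta_sd_gt_ppks", "post-injury delta coherence: SD > PPKS",
      pair_p("SD", "PPKS") < alpha && gm[["SD"]] > gm[["PPKS"]],
      sprintf("means PPKS %.2f, SD %.2f (p=%.3g)", gm[["PPKS"]], gm[["SD"]],
              pair_p("SD", "PPKS")))
  add("coh_delta_ppkr_gt_sd", "post-injury delta coherence: PPKR > SD",
      pair_p("PPKR", "SD") < alpha && gm[["PPKR"]] > gm[["SD"]],
      sprintf("means SD %.2f, PPKR %.2f (p=%.3g)", gm[["SD"]], gm[["PPKR"]],
              pair_p("PPKR", "SD")))

  # 7-9: ipsilateral entropy drop in PPKS and SD only
  e_ppks <- .change_test(features, "PPKS", "entropy_ipsi", post_label, alpha)
  e_sd <- .change_test(features, "SD", "entropy_ipsi", post_label, alpha)
  e_ppkr <- .change_test(features, "PPKR", "entropy_ipsi", post_label, alpha)
  add("entropy_drop_ppks", "ipsilateral entropy drop after injury in PPKS",
      e_ppks$sig_decrease, sprintf("delta %.3f nats, p=%.3g", e_ppks$delta, e_ppks$p))
  add("entropy_drop_sd", "ipsilateral entropy drop after injury in SD",
      e_sd$sig_decrease, sprintf("delta %.3f nats, p=%.3g", e_sd$delta, e_sd$p))
  add("entropy_stable_ppkr", "no ipsilateral entropy drop in PPKR",
      !e_ppkr$sig_decrease, sprintf("delta %.3f nats, p=%.3g", e_ppkr$delta, e_ppkr$p))

  # 10: ipsilateral kurtosis rise in PPKR only
  k_ppkr <- .change_test(features, "PPKR", "kurtosis_ipsi", post_label, alpha)
  k_ppks <- .change_test(features, "PPKS", "kurtosis_ipsi", post_label, alpha)
  k_sd <- .change_test(features, "SD", "kurtosis_ipsi", post_label, alpha)
  add("kurtosis_rise_ppkr_only",
      "ipsilateral kurtosis rise after injury in PPKR, absent in PPKS/SD",
      k_ppkr$sig_increase && !k_ppks$sig_increase && !k_sd$sig_increase,
      sprintf("delta PPKR %.2f (p=%.3g), PPKS %.2f, SD %.2f",
              k_ppkr$delta, k_ppkr$p, k_ppks$delta, k_sd$delta))
  out
}
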