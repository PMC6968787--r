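# --- bin-wise least-squares construct tests ----------------------------------

# residual sum of squares per column of Y under design X (via one QR)
.rss_mat <- function(X, Y) {
  q <- qr(X)
  colSums(qr.resid(q, Y)^2)
}

# name the factor whose columns are aliased in a rank-deficient design
.check_rank <- function(X, terms_by_col) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    dropped <- q$pivot[(q$rank + 1L):ncol(X)]
    bad <- unique(terms_by_col[dropped])
    stop("rank-deficient design: factor(s) aliased: ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' Bin-wise least-squares model with construct-effect LogWorth
#'
#' Fits a fixed-effects linear model of a spectral quantity on experimental
#' factors across the 64 frequency bins. Two complementary fits are made:
#' \enumerate{
#'   \item a joint model over all bins with the bin as a blocking covariate
#'     (`value ~ bin + effects`), from which each construct effect gets an
#'     overall F test, p-value and LogWorth (`-log10 p`);
#'   \item independent per-bin fits, giving a per-bin per-effect p-value used
#'     to report maximal runs of significant bins as frequency intervals.
#' }
#' No multiple-testing correction is applied across bins by default
#' (`adjust = "none"`), mirroring uncorrected per-bin significance brackets;
#' Benjamini-Hochberg is available behind `adjust = "BH"`.
#'
#' @param data data.frame in long format: one row per subject x bin (x side,
#'   timepoint, ...) with the response column and factor columns.
#' @param value name of the response column (e.g. log normalized power).
#' @param effects character vector of factor column names to test.
#' @param bin name of the frequency-bin column (bin centres in Hz).
#' @param alpha per-bin significance level for interval extraction.
#' @param adjust `"none"` (default) or `"BH"` across the 64 bins.
#' @return object of class `binwise_result`: per effect a list with `F`,
#'   `df1`, `df2`, `p`, `logworth`, `p_bins` (per-bin p-values), and
#'   `intervals` (from [extract_intervals()]); plus `freqs` and `alpha`.
#' @export
binwise_model <- function(data, value = "value", effects = c("strain"),
                          bin = "freq", alpha = 0.05,
                          adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(is.data.frame(data), value %in% names(data), bin %in% names(data),
            all(effects %in% names(data)))
  for (e in effects) {
    data[[e]] <- factor(data[[e]])
    if (nlevels(data[[e]]) < 2L)
      stop(sprintf("effect '%s' needs >= 2 levels", e))
  }
  freqs <- sort(unique(data[[bin]]))
  nb <- length(freqs)

  # wide response: rows = observational units, columns = bins
  key_cols <- setdiff(names(data), c(value, bin))
  key <- do.call(paste, c(data[key_cols], sep = "\r"))
  units <- unique(key)
  Y <- matrix(NA_real_, length(units), nb)
  ri <- match(key, units)
  ci <- match(data[[bin]], freqs)
  Y[cbind(ri, ci)] <- data[[value]]
  if (anyNA(Y)) stop("unbalanced bins: every unit must contribute all bins")
  meta <- data[match(units, key), key_cols, drop = FALSE]
  for (e in effects)
    if (min(table(meta[[e]])) < 2L)
      stop(sprintf("effect '%s': need >= 2 subjects per cell", e))

  form <- stats::as.formula(paste("~", paste(effects, collapse = " + ")))
  Xf <- stats::model.matrix(form, meta)
  assign_f <- attr(Xf, "assign")
  terms_by_col <- c("(Intercept)", effects)[assign_f + 1L]
  .check_rank(Xf, terms_by_col)

  rss_f <- .rss_mat(Xf, Y)
  df_res <- nrow(Y) - ncol(Xf)

  # joint model: bin as blocking covariate
  nbins_f <- factor(rep(freqs, each = nrow(Y)))
  yl <- as.vector(Y)
  Xj_full <- cbind(stats::model.matrix(~ nbins_f),
                   do.call(rbind, replicate(nb, Xf[, -1L, drop = FALSE], simplify = FALSE)))
  rss_j_full <- sum(qr.resid(qr(Xj_full), yl)^2)
  df_j_res <- length(yl) - ncol(Xj_full)

  res <- list()
  for (e in effects) {
    drop_cols <- which(terms_by_col == e)
    Xr <- Xf[, -drop_cols, drop = FALSE]
    q <- length(drop_cols)
    # per-bin F tests
    rss_r <- .rss_mat(Xr, Y)
    Fb <- ((rss_r - rss_f) / q) / (rss_f / df_res)
    p_bins <- stats::pf(Fb, q, df_res, lower.tail = FALSE)
    if (adjust == "BH") p_bins <- stats::p.adjust(p_bins, "BH")
    # joint construct test
    keep <- setdiff(seq_len(ncol(Xf))[-1L], drop_cols)
    Xj_red <- cbind(stats::model.matrix(~ nbins_f),
                    do.call(rbind, replicate(nb, Xf[, keep, drop = FALSE], simplify = FALSE)))
    rss_j_red <- sum(qr.resid(qr(Xj_red), yl)^2)
    Fj <- ((rss_j_red - rss_j_full) / q) / (rss_j_full / df_j_res)
    pj <- max(stats::pf(Fj, q, df_j_res, lower.tail = FALSE), 1e-300)
    res[[e]] <- list(F = Fj, df1 = q, df2 = df_j_res, p = pj,
                     logworth = -log10(pj), F_bins = Fb, p_bins = p_bins,
                     intervals = extract_intervals(p_bins, alpha, freqs))
  }
  structure(list(effects = res, freqs = freqs, alpha = alpha, value = value),
            class = "binwise_result")
}

#' @export
print.binwise_result <- function(x, ...) {
  cat("Bin-wise least-squares construct tests (", length(x$freqs),
      " bins)\n", sep = "")
  for (e in names(x$effects)) {
    r <- x$effects[[e]]
    cat(sprintf("  %-10s F(%d, %d) = %.2f, p = %.3g, LogWorth = %.2f\n",
                e, r$df1, r$df2, r$F, r$p, r$logworth))
    if (nrow(r$intervals))
      cat("    significant bins: ",
          paste(sprintf("%.1f-%.1f Hz", r$intervals$low, r$intervals$high),
                collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Maximal runs of significant frequency bins
#'
#' @param p per-bin p-values (one per bin centre).
#' @param alpha significance level.
#' @param freqs bin centres (default the 64-bin grid).
#' @return data.frame with columns `low`, `high` (bin-centre Hz endpoints of
#'   each maximal run of consecutive bins with `p < alpha`) and `n_bins`.
#' @export
extract_intervals <- function(p, alpha = 0.05, freqs = bin_freqs()) {
  stopifnot(length(p) == length(freqs))
  sig <- !is.na(p) & p < alpha
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(low = freqs[starts[keep]], high = freqs[ends[keep]],
             n_bins = r$lengths[keep])
}

# --- one-way ANOVA with Tukey HSD --------------------------------------------

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' Omnibus F test plus all pairwise group comparisons with studentized-range
#' (Tukey HSD) adjustment; unequal group sizes are handled by the
#' Tukey-Kramer form (as in [stats::TukeyHSD()]).
#'
#' @param values numeric response, one per subject.
#' @param groups group labels (coerced to factor; >= 2 levels, >= 2 subjects
#'   per group).
#' @param alpha family significance level recorded in the result.
#' @return object of class `tukey_result`: `F`, `df1`, `df2`, `p` for the
#'   omnibus test and a `pairwise` data.frame (`comparison`, `diff`, `lwr`,
#'   `upr`, `p_adj`).
#' @export
anova_tukey <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (min(table(groups)) < 2L) stop("need >= 2 subjects per group")
  d <- data.frame(y = values, g = groups)
  fit <- stats::aov(y ~ g, data = d)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  pw <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                   lwr = tk[, "lwr"], upr = tk[, "upr"],
                   p_adj = tk[, "p adj"], row.names = NULL)
  structure(list(F = an[["F value"]][1], df1 = an[["Df"]][1],
                 df2 = an[["Df"]][2], p = an[["Pr(>F)"]][1],
                 group_means = tapply(values, groups, mean),
                 pairwise = pw, alpha = alpha),
            class = "tukey_result")
}

#' @export
print.tukey_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$df1, x$df2, x$F, x$p))
  cat("Tukey HSD pairwise comparisons:\n")
  print(x$pairwise, row.names = FALSE, digits = 4)
  invisible(x)
}
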