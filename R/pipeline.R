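# --- end-to-end pipeline ------------------------------------------------------

#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end analysis: cohort generation,
#' epoching/filtering geometry, statistical level and risk-score search
#' settings. All defaults mirror the acute-CCI analysis conditions (1024 Hz
#' sampling, 60 s epochs, alpha = 0.05, at most 5 risk factors).
#'
#' @param seed master seed for cohort generation.
#' @param n_per_strain subjects per strain.
#' @param fs sampling rate in Hz.
#' @param cci_time,duration,rms recording geometry passed to
#'   [strain_presets()].
#' @param jitter a [cohort_jitter()].
#' @param alpha significance level used throughout.
#' @param max_terms,l0_penalty,intercepts risk-score search settings.
#' @param labels epochs to analyse.
#' @return an object of class `run_config`; its md5 hash (over all fields) is
#'   embedded in every pipeline artifact.
#' @export
run_config <- function(seed = 1L, n_per_strain = 10L, fs = 1024,
                       cci_time = 120, duration = 1080, rms = 50,
                       jitter = cohort_jitter(), alpha = 0.05,
                       max_terms = 5L, l0_penalty = 4.5, intercepts = -10:10,
                       labels = epoch_labels()) {
  cfg <- structure(list(seed = seed, n_per_strain = n_per_strain, fs = fs,
                        cci_time = cci_time, duration = duration, rms = rms,
                        jitter = jitter, alpha = alpha, max_terms = max_terms,
                        l0_penalty = l0_penalty, intercepts = intercepts,
                        labels = labels),
                   class = "run_config")
  attr(cfg, "hash") <- .object_hash(unclass(cfg))
  cfg
}

.write_stage_csv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# acuteqeeg_config_hash: %s", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline stage artifact, enforcing configuration provenance
#'
#' Pipeline CSVs carry the configuration hash on a leading comment line;
#' reading with a non-matching `expect_hash` is refused, so artifacts from
#' different runs cannot be mixed silently.
#'
#' @param path CSV written by [run_pipeline()].
#' @param expect_hash hash to enforce (e.g. `attr(config, "hash")`), or
#'   `NULL` to skip the check.
#' @return the data.frame.
#' @export
read_stage_csv <- function(path, expect_hash = NULL) {
  first <- readLines(path, n = 1L)
  hash <- sub("^# acuteqeeg_config_hash: ", "", first)
  if (!is.null(expect_hash) && !identical(hash, expect_hash))
    stop("config hash mismatch for ", basename(path),
         ": expected ", expect_hash, ", found ", hash)
  utils::read.csv(path, comment.char = "#")
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Orchestrates cohort generation, epoching and filtering, feature and
#' spectrum extraction, group statistics, the qualitative pattern check and
#' risk-score fitting, writing one artifact per stage into `dir`:
#' `manifest.csv` (the synth-stage ground truth; recordings regenerate
#' deterministically from it), `features.csv`, `spectra.csv`,
#' `coherence.csv`, `stats.json`, `patterns.csv`, `scorecard.json` and
#' `run_info.json`. Every CSV carries the configuration hash; later stages
#' read earlier artifacts back from disk (hash-enforced), so each stage is
#' re-runnable from files.
#'
#' The risk score is trained on the 0.5-min post-injury feature vectors with
#' the susceptible class defined as the PPKS strain.
#'
#' @param config a [run_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with `manifest`, `features`, `spectra`,
#'   `coherence`, `stats`, `patterns`, `model`, `config` and `dir`. Any stage
#'   error propagates with the stage name prepended.
#' @export
run_pipeline <- function(config = run_config(), dir = tempfile("qeeg_run_")) {
  stopifnot(inherits(config, "run_config"))
  hash <- attr(config, "hash")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  t0 <- Sys.time()

  man <- stage("synth", {
    presets <- strain_presets(fs = config$fs, cci_time = config$cci_time,
                              duration = config$duration, rms = config$rms)
    m <- cohort_manifest(config$n_per_strain, config$seed, presets,
                         config$jitter)
    .write_stage_csv(m, file.path(dir, "manifest.csv"), hash)
    m
  })

  ft <- stage("features", {
    m <- read_stage_csv(file.path(dir, "manifest.csv"), hash)
    res <- compute_cohort_features(m, labels = config$labels)
    .write_stage_csv(res$features, file.path(dir, "features.csv"), hash)
    .write_stage_csv(res$spectra, file.path(dir, "spectra.csv"), hash)
    .write_stage_csv(res$coherence, file.path(dir, "coherence.csv"), hash)
    res
  })

  st <- stage("stats", {
    features <- read_stage_csv(file.path(dir, "features.csv"), hash)
    spectra <- read_stage_csv(file.path(dir, "spectra.csv"), hash)
    b <- spectra[spectra$epoch == "baseline", ]
    b$logp <- log10(pmax(b$power_norm, 1e-300))
    bw <- binwise_model(b[, c("subject_id", "strain", "side", "freq", "logp")],
                        value = "logp", effects = c("strain", "side"),
                        alpha = config$alpha)
    eff <- lapply(bw$effects, function(r)
      list(F = r$F, df1 = r$df1, df2 = r$df2, p = r$p, logworth = r$logworth,
           intervals = r$intervals))
    jsonlite::write_json(list(config_hash = hash, baseline_binwise = eff),
                         file.path(dir, "stats.json"), auto_unbox = TRUE,
                         digits = NA)
    bw
  })

  pat <- stage("patterns", {
    features <- read_stage_csv(file.path(dir, "features.csv"), hash)
    spectra <- read_stage_csv(file.path(dir, "spectra.csv"), hash)
    p <- check_patterns(features, spectra, alpha = config$alpha)
    .write_stage_csv(p, file.path(dir, "patterns.csv"), hash)
    p
  })

  model <- stage("riskscore", {
    features <- read_stage_csv(file.path(dir, "features.csv"), hash)
    fpost <- features[features$epoch == "post_0.5", ]
    X <- fpost[, feature_names()]
    ylab <- fpost$strain == "PPKS"
    m <- fit_risk_score(X, ylab, max_terms = config$max_terms,
                        l0_penalty = config$l0_penalty,
                        intercepts = config$intercepts)
    jsonlite::write_json(
      list(config_hash = hash, terms = m$terms, intercept = m$intercept,
           objective = m$objective, calibration = m$calibration,
           range_flags = m$range_flags),
      file.path(dir, "scorecard.json"), auto_unbox = TRUE, digits = NA)
    writeLines(scorecard_markdown(m), file.path(dir, "scorecard.md"))
    m
  })

  stage("report", {
    cfg <- unclass(config)
    cfg$jitter <- unclass(cfg$jitter)
    info <- list(config_hash = hash, config = cfg,
                 n_subjects = nrow(man),
                 patterns_detected = sum(pat$detected),
                 patterns_tracked = nrow(pat),
                 elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    jsonlite::write_json(info, file.path(dir, "run_info.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  invisible(list(manifest = man, features = ft$features, spectra = ft$spectra,
                 coherence = ft$coherence, stats = st, patterns = pat,
                 model = model, config = config, dir = dir))
}
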