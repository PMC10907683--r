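# Configuration-driven end-to-end pipeline:
# keyboard features -> accelerometer features -> temporal ICA -> fusion models,
# with attrition accounting and a provenance record at every stage.

#' Pipeline configuration
#'
#' All defaults are the analysis constants of the method: 6 s session
#' inactivity threshold, 750-press daily volume filter, second-order 4 Hz
#' zero-phase Butterworth, 0.95/1.05 inclusive stationary band, strict 8%
#' session-active rule, strict median-z < 0.1 with inclusive |median x| <= 0.2
#' upright rule, logcosh (a1 = 1) parallel FastICA. Anything the method leaves
#' open (sampling rate, component count, policies) is an explicit field.
#'
#' @param keypresses,accel,selfreport input CSV paths (may be `NULL` when the
#'   pipeline is run on in-memory tables).
#' @param output_dir where [runPipeline()] writes its artifacts (`NULL`: keep
#'   results in memory only).
#' @param q number of independent components (default 5).
#' @param inactivity_threshold session gap rule, seconds (default 6).
#' @param volume_threshold daily keypress filter (default 750).
#' @param sampling_rate accelerometer sampling rate, Hz (default 10).
#' @param cutoff,filter_order Butterworth design (defaults 4 Hz, order 2).
#' @param motion_threshold session active-fraction rule (default 0.08).
#' @param stationary_band inclusive magnitude band (default `c(0.95, 1.05)`).
#' @param upright_z_max,upright_x_bound upright rule (defaults 0.1, 0.2).
#' @param ica_seed,ica_tol,ica_max_iter FastICA settings.
#' @param restarts restarts for the stability report (0 disables it).
#' @param identifiability_policy `"drop-week"` or `"drop-participant"`.
#' @param method `"REML"` or `"ML"` for the reported component models.
#' @return a `PipelineConfig` list.
#' @export
pipelineConfig <- function(keypresses = NULL, accel = NULL, selfreport = NULL,
                           output_dir = NULL, q = 5,
                           inactivity_threshold = 6, volume_threshold = 750,
                           sampling_rate = 10, cutoff = 4, filter_order = 2,
                           motion_threshold = 0.08,
                           stationary_band = c(0.95, 1.05),
                           upright_z_max = 0.1, upright_x_bound = 0.2,
                           ica_seed = 1, ica_tol = 1e-4, ica_max_iter = 200,
                           restarts = 0,
                           identifiability_policy = c("drop-week",
                                                      "drop-participant"),
                           method = c("REML", "ML")) {
  cfg <- list(
    keypresses = keypresses, accel = accel, selfreport = selfreport,
    output_dir = output_dir, q = q,
    inactivity_threshold = inactivity_threshold,
    volume_threshold = volume_threshold,
    sampling_rate = sampling_rate, cutoff = cutoff,
    filter_order = filter_order, motion_threshold = motion_threshold,
    stationary_band = stationary_band, upright_z_max = upright_z_max,
    upright_x_bound = upright_x_bound, ica_seed = ica_seed,
    ica_tol = ica_tol, ica_max_iter = ica_max_iter, restarts = restarts,
    identifiability_policy = match.arg(identifiability_policy),
    method = match.arg(method)
  )
  for (f in c("q", "inactivity_threshold", "volume_threshold",
              "sampling_rate", "cutoff", "filter_order", "motion_threshold",
              "upright_z_max", "upright_x_bound", "ica_tol", "ica_max_iter")) {
    stopifnotScalarNumeric(cfg[[f]], f)
  }
  structure(cfg, class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror [pipelineConfig()] arguments.
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipelineConfig, vals)
}

#' Write a pipeline configuration to YAML
#'
#' @param config a `PipelineConfig`.
#' @param path output path. Round-trips through [readPipelineConfig()].
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(unclass(config)[!vapply(config, is.null, logical(1))], path)
  invisible(path)
}

#' Read the three input tables
#'
#' @param path CSV path.
#' @return `data.table` in the respective input contract.
#' @export
readKeypresses <- function(path) {
  dt <- fread(path)
  dt[, timestamp := asSeconds(timestamp)]
  dt[, date := asDate(date)]
  dt[]
}

#' @rdname readKeypresses
#' @export
readAccel <- function(path) {
  dt <- fread(path)
  dt[, date := asDate(date)]
  dt[]
}

#' @rdname readKeypresses
#' @export
readSelfreport <- function(path) {
  dt <- fread(path)
  dt[, date := asDate(date)]
  dt[]
}

#' Validate pipeline inputs
#'
#' Schema, type, duplicate-key and positivity checks for the three input
#' tables. Problems are split into fatal errors (malformed schema, duplicated
#' participant-days, non-positive Likert values) and warnings (e.g., unknown
#' extra columns).
#'
#' @param keypresses,accel,selfreport tables or CSV paths.
#' @return list with `ok` (logical), `errors`, `warnings` (character vectors).
#' @export
validateInputs <- function(keypresses = NULL, accel = NULL, selfreport = NULL) {
  errors <- character(0); warns <- character(0)
  load <- function(x, reader) if (is.character(x)) reader(x) else as.data.table(x)

  if (!is.null(keypresses)) {
    kp <- load(keypresses, readKeypresses)
    need <- c("participant_id", "timestamp", "date", "key_class")
    miss <- setdiff(need, names(kp))
    if (length(miss)) {
      errors <- c(errors, paste("keypresses: missing columns",
                                paste(miss, collapse = ", ")))
    } else {
      bad <- setdiff(unique(kp$key_class), KEY_CLASSES)
      if (length(bad)) {
        errors <- c(errors, paste("keypresses: unknown key_class",
                                  paste(bad, collapse = ", ")))
      }
      extra <- setdiff(names(kp), c(need, "keyboard_dismissed"))
      if (length(extra)) {
        warns <- c(warns, paste("keypresses: unknown extra columns",
                                paste(extra, collapse = ", ")))
      }
    }
  }
  if (!is.null(accel)) {
    ac <- load(accel, readAccel)
    need <- c("participant_id", "session_index", "date", "timestamp_s",
              "x", "y", "z")
    miss <- setdiff(need, names(ac))
    if (length(miss)) {
      errors <- c(errors, paste("accel: missing columns",
                                paste(miss, collapse = ", ")))
    } else if (any(!is.finite(ac$x) | !is.finite(ac$y) | !is.finite(ac$z))) {
      errors <- c(errors, "accel: non-finite x/y/z samples")
    }
  }
  if (!is.null(selfreport)) {
    sr <- load(selfreport, readSelfreport)
    need <- c("participant_id", "date")
    miss <- setdiff(need, names(sr))
    if (length(miss)) {
      errors <- c(errors, paste("selfreport: missing columns",
                                paste(miss, collapse = ", ")))
    } else {
      key <- paste(sr$participant_id, sr$date)
      if (anyDuplicated(key)) {
        errors <- c(errors, sprintf(
          "selfreport: duplicated (participant_id, date) rows, e.g. %s",
          key[duplicated(key)][1L]
        ))
      }
      items <- setdiff(names(sr), need)
      if (!length(items)) {
        errors <- c(errors, "selfreport: no item columns")
      } else {
        vals <- as.matrix(sr[, items, with = FALSE])
        if (any(is.finite(vals) & vals <= 0)) {
          errors <- c(errors,
                      "selfreport: non-positive Likert value (log undefined)")
        }
      }
    }
  }
  list(ok = length(errors) == 0L, errors = errors, warnings = warns)
}

#' Run the full fusion pipeline
#'
#' Executes keyboard feature extraction, accelerometer feature extraction,
#' temporal ICA of the self-report panel, complete-case alignment,
#' week-identifiability enforcement, feature standardization and per-component
#' mixed-effects fits with Bonferroni correction. Every stage's row counts are
#' recorded in a provenance log (rows in = rows out + rows excluded at each
#' filter). When `config$output_dir` is set, all intermediates are written:
#' `daily_keyboard.csv`, `daily_accel.csv`, `mixing_matrix.csv`,
#' `sources.csv`, `model_estimates.csv`, `random_effects.json`,
#' `stability_report.json` (if restarts were requested) and `provenance.json`.
#'
#' @param config a [pipelineConfig()].
#' @param keypresses,accel,selfreport in-memory tables overriding the config
#'   paths (used when driving the pipeline from [simulateStudy()] bundles).
#' @return list with `daily_keyboard`, `daily_accel`, `panel`, `ica`,
#'   `aligned` (standardized analysis table), `transform`, `exclusions`,
#'   `models` (see [fitAllComponentModels()]), `stability` (or `NULL`) and
#'   `provenance`.
#' @export
runPipeline <- function(config = pipelineConfig(), keypresses = NULL,
                        accel = NULL, selfreport = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  prov <- list(
    package_version = as.character(utils::packageVersion("phenofuse")),
    config = unclass(config), stages = list()
  )
  note <- function(name, ...) {
    prov$stages[[name]] <<- list(...)
  }

  kp <- keypresses %||% stage("read", readKeypresses(config$keypresses))
  ac <- accel %||% stage("read", readAccel(config$accel))
  sr <- selfreport %||% stage("read", readSelfreport(config$selfreport))
  kp <- as.data.table(kp); ac <- as.data.table(ac); sr <- as.data.frame(sr)

  daily_kb <- stage("keyboard", keyboardDailyFeatures(
    kp, config$inactivity_threshold, config$volume_threshold
  ))
  note("keyboard", events_in = nrow(kp), days_out = nrow(daily_kb),
       days_excluded_volume = sum(!daily_kb$included))

  daily_ac <- stage("accel", accelDailyFeatures(
    ac, config$sampling_rate, config$cutoff, config$filter_order,
    config$motion_threshold, config$stationary_band,
    config$upright_z_max, config$upright_x_bound
  ))
  note("accel", samples_in = nrow(ac), days_out = nrow(daily_ac))

  panel <- stage("ica", preparePanel(sr))
  dec <- stage("ica", fitICA(panel, q = config$q, seed = config$ica_seed,
                             tol = config$ica_tol,
                             max_iter = config$ica_max_iter))
  note("ica", panel_days = ncol(panel), q = config$q,
       converged = icaMeta(dec)$converged,
       iterations = icaMeta(dec)$iterations)
  stability <- NULL
  if (config$restarts >= 2) {
    stability <- stage("ica", restartStability(
      panel, q = config$q, R = config$restarts, base_seed = config$ica_seed,
      tol = config$ica_tol, max_iter = config$ica_max_iter
    ))
  }

  aligned_raw <- stage("align", alignModalities(daily_kb, daily_ac, dec))
  note("align",
       keyboard_days = nrow(daily_kb[included == TRUE]),
       accel_days = nrow(daily_ac), selfreport_days = ncol(panel),
       aligned_days = nrow(aligned_raw))

  enforced <- stage("identifiability", enforceWeekIdentifiability(
    aligned_raw, policy = config$identifiability_policy
  ))
  note("identifiability", rows_in = nrow(aligned_raw),
       rows_out = nrow(enforced$data),
       rows_excluded = nrow(aligned_raw) - nrow(enforced$data),
       weeks_dropped = nrow(enforced$exclusions))

  transform <- stage("standardize",
                     standardizeFeatures(as.data.frame(enforced$data)))
  analysis <- transform$data

  models <- stage("fusion", fitAllComponentModels(
    analysis, features = FUSION_FEATURES, method = config$method
  ))
  note("fusion", models = length(models$fits), CF = models$correction$CF,
       n_rows = nrow(analysis))

  result <- list(
    daily_keyboard = daily_kb, daily_accel = daily_ac, panel = panel,
    ica = dec, aligned = analysis, transform = transform,
    exclusions = enforced$exclusions, models = models,
    stability = stability, provenance = prov
  )
  if (!is.null(config$output_dir)) writePipelineOutputs(result, config)
  result
}

# Write all pipeline artifacts to config$output_dir.
writePipelineOutputs <- function(result, config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  outp <- function(f) file.path(config$output_dir, f)
  fwrite(result$daily_keyboard, outp("daily_keyboard.csv"))
  fwrite(result$daily_accel, outp("daily_accel.csv"))
  A <- mixingMatrix(result$ica)
  fwrite(data.table(item = rownames(A), as.data.table(A)),
         outp("mixing_matrix.csv"))
  idx <- as.data.frame(indexMap(result$ica))
  fwrite(cbind(as.data.table(idx), as.data.table(t(icaSources(result$ica)))),
         outp("sources.csv"))
  fwrite(as.data.table(result$models$estimates), outp("model_estimates.csv"))
  re <- lapply(result$models$fits, function(f) {
    list(sigma1_sq = f$sigma1_sq, sigma2_sq = f$sigma2_sq,
         sigma_sq = f$sigma_sq, logLik = f$logLik, converged = f$converged)
  })
  jsonlite::write_json(re, outp("random_effects.json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(result$stability)) {
    s <- result$stability
    jsonlite::write_json(list(
      clusters = s@clusters, tightness = s@tightness, runs = s@runs,
      failures = s@failures, meta = s@meta
    ), outp("stability_report.json"), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(result$provenance, outp("provenance.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(config$output_dir)
}
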