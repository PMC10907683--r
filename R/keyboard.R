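# Keyboard-dynamics feature extraction.
#
# Raw keypress event streams are segmented into typing sessions (a session ends
# at keyboard dismissal or after >= 6 s of inactivity), summarised per session
# into inter-key-delay (IKD) statistics and error-key rates, aggregated to the
# daily level, volume-filtered (>= 750 presses per day) and standardized.

KEY_CLASSES <- c("alphanumeric", "autocorrect", "backspace", "other")

KEYBOARD_FEATURES <- c(
  "median_ikd", "p95_ikd", "mad_ikd",
  "autocorrect_rate", "backspace_rate", "total_keypresses"
)

#' Segment a keypress stream into typing sessions
#'
#' A typing session begins at the first keypress and ends when the keyboard is
#' dismissed or when at least `inactivity_threshold` seconds elapse before the
#' next press. A gap of exactly the threshold closes the session. Each session
#' is assigned the participant-local calendar date of its first keypress;
#' sessions are never split across midnight.
#'
#' @param events data.frame with columns `participant_id`, `timestamp`
#'   (numeric seconds, POSIXct, or ISO-8601 strings), `date` (the
#'   participant-local civil date of the press), `key_class` (one of
#'   `"alphanumeric"`, `"autocorrect"`, `"backspace"`, `"other"`), and
#'   optionally `keyboard_dismissed` (0/1 flag: the keyboard was dismissed
#'   after this press). Must contain a single participant, sorted by timestamp.
#' @param inactivity_threshold session-closing gap in seconds (default 6).
#' @return A `data.table` of the input events with a `session_index` column
#'   (ordinal within participant) and the session's assigned `date`.
#' @examples
#' ev <- data.frame(
#'   participant_id = "p1",
#'   timestamp = c(0, 1, 2, 9),
#'   date = as.Date("2023-01-01"),
#'   key_class = "alphanumeric"
#' )
#' table(segmentSessions(ev)$session_index)  # sessions of 3 and 1 presses
#' @export
segmentSessions <- function(events, inactivity_threshold = 6) {
  stopifnotScalarNumeric(inactivity_threshold, "inactivity_threshold")
  events <- as.data.table(events)
  if (nrow(events) == 0L) {
    out <- copy(events)
    out[, session_index := integer(0)]
    return(out[])
  }
  required <- c("participant_id", "timestamp", "date", "key_class")
  missing_cols <- setdiff(required, names(events))
  if (length(missing_cols)) {
    stop("events is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (uniqueN(events$participant_id) > 1L) {
    stop("segmentSessions() expects events of a single participant; got ",
         uniqueN(events$participant_id))
  }
  bad_class <- setdiff(unique(events$key_class), KEY_CLASSES)
  if (length(bad_class)) {
    stop("unknown key_class value(s): ", paste(bad_class, collapse = ", "))
  }
  ts <- asSeconds(events$timestamp)
  if (is.unsorted(ts)) {
    stop("events must be sorted by timestamp within participant ",
         "(found a decreasing timestamp)")
  }
  out <- copy(events)
  out[, timestamp := ts]
  out[, date := asDate(date)]
  dismissed <- if ("keyboard_dismissed" %in% names(out)) {
    as.logical(out$keyboard_dismissed) %in% TRUE
  } else {
    rep(FALSE, nrow(out))
  }
  gap_break <- c(FALSE, diff(ts) >= inactivity_threshold)
  dismiss_break <- c(FALSE, dismissed[-length(dismissed)])
  out[, session_index := cumsum(gap_break | dismiss_break) + 1L]
  # session date = calendar day of its first keypress
  out[, date := date[1L], by = session_index]
  out[]
}

#' Per-session keyboard features
#'
#' Inter-key delays are the time differences between *immediately* successive
#' alphanumeric keypresses within the session; an intervening autocorrect,
#' backspace or other press breaks the pair. The median IKD inversely indexes
#' typing speed, the 95th percentile IKD captures within-session pausing, and
#' the mean absolute deviation (about the session median) captures typing-speed
#' variability. IKD statistics are `NA` (absent, not zero) when the session has
#' fewer than two adjacent alphanumeric presses.
#'
#' @param session one session's events (data.frame as in [segmentSessions()]).
#' @return list with `median_ikd`, `p95_ikd`, `mad_ikd` (seconds),
#'   `autocorrect_rate`, `backspace_rate` (fractions of all presses) and
#'   `n_keypresses`.
#' @export
sessionFeatures <- function(session) {
  if (nrow(session) == 0L) stop("session must contain at least one event")
  ts <- asSeconds(session$timestamp)
  kc <- session$key_class
  n <- length(ts)
  alpha <- kc == "alphanumeric"
  ikd <- if (n >= 2L) diff(ts)[alpha[-n] & alpha[-1L]] else numeric(0)
  if (length(ikd) >= 1L) {
    med <- stats::median(ikd)
    feats <- list(
      median_ikd = med,
      p95_ikd = percentile95(ikd),
      mad_ikd = meanAbsDeviation(ikd, med)
    )
  } else {
    feats <- list(median_ikd = NA_real_, p95_ikd = NA_real_, mad_ikd = NA_real_)
  }
  c(feats, list(
    autocorrect_rate = sum(kc == "autocorrect") / n,
    backspace_rate = sum(kc == "backspace") / n,
    n_keypresses = n
  ))
}

# Vectorized session-feature computation over a segmented event table
# (single or multiple participants). Returns one row per session.
sessionFeatureTable <- function(segmented) {
  segmented <- as.data.table(segmented)
  if (nrow(segmented) == 0L) {
    return(data.table(
      participant_id = character(0), session_index = integer(0),
      date = as.Date(character(0)), median_ikd = numeric(0),
      p95_ikd = numeric(0), mad_ikd = numeric(0),
      autocorrect_rate = numeric(0), backspace_rate = numeric(0),
      n_keypresses = integer(0)
    ))
  }
  segmented[, {
    n <- .N
    alpha <- key_class == "alphanumeric"
    ikd <- if (n >= 2L) diff(timestamp)[alpha[-n] & alpha[-1L]] else numeric(0)
    if (length(ikd)) {
      med <- stats::median(ikd)
      p95 <- percentile95(ikd)
      mad <- meanAbsDeviation(ikd, med)
    } else {
      med <- p95 <- mad <- NA_real_
    }
    list(
      date = date[1L],
      median_ikd = med, p95_ikd = p95, mad_ikd = mad,
      autocorrect_rate = sum(key_class == "autocorrect") / n,
      backspace_rate = sum(key_class == "backspace") / n,
      n_keypresses = n
    )
  }, by = .(participant_id, session_index)]
}

#' Aggregate session-level keyboard features to the daily level
#'
#' Session-level statistics are averaged per participant-day (sessions whose
#' IKD statistics are undefined are ignored in those means); total keypresses
#' are summed. Days with fewer than 750 presses are flagged excluded
#' (`included = FALSE`); the boundary day of exactly 750 presses is retained.
#'
#' @param session_table one row per session, as produced by
#'   [sessionFeatureTable()] or by applying [sessionFeatures()] to each session.
#' @param volume_threshold minimum daily keypress count (default 750).
#' @return `data.table` with one row per (participant, date): the six daily
#'   keyboard features plus `n_sessions` and the `included` flag.
#' @export
aggregateDailyKeyboard <- function(session_table, volume_threshold = 750) {
  stopifnotScalarNumeric(volume_threshold, "volume_threshold")
  st <- as.data.table(session_table)
  daily <- st[, .(
    median_ikd = if (all(is.na(median_ikd))) NA_real_ else
      mean(median_ikd, na.rm = TRUE),
    p95_ikd = if (all(is.na(p95_ikd))) NA_real_ else
      mean(p95_ikd, na.rm = TRUE),
    mad_ikd = if (all(is.na(mad_ikd))) NA_real_ else
      mean(mad_ikd, na.rm = TRUE),
    autocorrect_rate = mean(autocorrect_rate),
    backspace_rate = mean(backspace_rate),
    total_keypresses = sum(n_keypresses),
    n_sessions = .N
  ), by = .(participant_id, date)]
  daily[, included := total_keypresses >= volume_threshold]
  setkey(daily, participant_id, date)
  daily[]
}

#' Daily keyboard features from a raw keypress stream
#'
#' Convenience wrapper running segmentation, session features and daily
#' aggregation for one or many participants.
#'
#' @inheritParams segmentSessions
#' @inheritParams aggregateDailyKeyboard
#' @param events keypress events for any number of participants.
#' @return see [aggregateDailyKeyboard()].
#' @export
keyboardDailyFeatures <- function(events, inactivity_threshold = 6,
                                  volume_threshold = 750) {
  events <- as.data.table(events)
  if (nrow(events) == 0L) {
    return(aggregateDailyKeyboard(sessionFeatureTable(events),
                                  volume_threshold))
  }
  segmented <- segmentAll(events, inactivity_threshold)
  aggregateDailyKeyboard(sessionFeatureTable(segmented), volume_threshold)
}

# Multi-participant segmentation, one vectorized pass. Equivalent to applying
# segmentSessions() per participant (property-tested against it).
segmentAll <- function(events, inactivity_threshold = 6) {
  out <- as.data.table(events)[, .(
    participant_id, timestamp = asSeconds(timestamp), date = asDate(date),
    key_class,
    keyboard_dismissed = if ("keyboard_dismissed" %in% names(events)) {
      as.logical(keyboard_dismissed) %in% TRUE
    } else FALSE
  )]
  bad_class <- setdiff(unique(out$key_class), KEY_CLASSES)
  if (length(bad_class)) {
    stop("unknown key_class value(s): ", paste(bad_class, collapse = ", "))
  }
  setorder(out, participant_id, timestamp)
  first <- out$participant_id != shift(out$participant_id, fill = "\r")
  gap_break <- c(FALSE, diff(out$timestamp) >= inactivity_threshold)
  dismiss_break <- shift(out$keyboard_dismissed, fill = FALSE)
  out[, session_index := cumsum(first | gap_break | dismiss_break)]
  out[, session_index := session_index - session_index[1L] + 1L,
      by = participant_id]
  out[, date := date[1L], by = .(participant_id, session_index)]
  out[, keyboard_dismissed := NULL]
  out[]
}

#' Log-transform typing volume and standardize features
#'
#' Replaces `total_keypresses` by its natural logarithm, then z-scores every
#' feature against the grand mean and standard deviation of the supplied rows
#' (the analysis sample), so each standardized column has mean 0 and variance 1.
#' The fitted means and SDs are returned so the transform is reproducible and
#' invertible with [invertStandardization()].
#'
#' @param table data.frame of daily feature rows (volume filter already
#'   applied; `total_keypresses` strictly positive if present).
#' @param features character vector of feature columns to standardize.
#' @param log_features columns to log-transform first (natural log).
#' @return list of class `featureTransform` with elements `data` (the
#'   standardized table), `center`, `scale` (named numeric vectors) and
#'   `log_features`.
#' @export
standardizeFeatures <- function(table,
                                features = intersect(
                                  c(KEYBOARD_FEATURES,
                                    "movement_rate", "upright_rate"),
                                  names(table)),
                                log_features = intersect("total_keypresses",
                                                         features)) {
  table <- as.data.frame(table)
  missing_cols <- setdiff(features, names(table))
  if (length(missing_cols)) {
    stop("features not present in table: ", paste(missing_cols, collapse = ", "))
  }
  for (f in log_features) {
    if (any(!is.finite(table[[f]])) || any(table[[f]] <= 0)) {
      stop(sprintf("feature '%s' must be strictly positive for log transform", f))
    }
    table[[f]] <- log(table[[f]])
  }
  ctr <- vapply(table[features], mean, numeric(1))
  scl <- vapply(table[features], stats::sd, numeric(1))
  zero_var <- features[!is.finite(scl) | scl == 0]
  if (length(zero_var)) {
    stop("zero-variance feature(s) cannot be standardized: ",
         paste(zero_var, collapse = ", "))
  }
  for (f in features) table[[f]] <- (table[[f]] - ctr[[f]]) / scl[[f]]
  structure(
    list(data = table, center = ctr, scale = scl,
         features = features, log_features = log_features),
    class = "featureTransform"
  )
}

#' Invert a feature standardization
#'
#' @param transform a `featureTransform` from [standardizeFeatures()].
#' @param data standardized rows (defaults to `transform$data`).
#' @return the table on the original scale (log transforms undone).
#' @export
invertStandardization <- function(transform, data = transform$data) {
  stopifnot(inherits(transform, "featureTransform"))
  data <- as.data.frame(data)
  for (f in transform$features) {
    data[[f]] <- data[[f]] * transform$scale[[f]] + transform$center[[f]]
  }
  for (f in transform$log_features) data[[f]] <- exp(data[[f]])
  data
}

#' @export
print.featureTransform <- function(x, ...) {
  cat("featureTransform:", length(x$features), "standardized features over",
      nrow(x$data), "rows\n")
  cat("  log-transformed:",
      if (length(x$log_features)) paste(x$log_features, collapse = ", ")
      else "none", "\n")
  invisible(x)
}
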