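# In-session accelerometer preprocessing and classification.
#
# Traces are recorded only while the participant types. Each session's x/y/z
# series (in gravity units, g) is low-pass filtered with a zero-phase
# second-order Butterworth filter (4 Hz cutoff); samples whose filtered
# magnitude leaves the inclusive band [0.95, 1.05] are "active"; a session is
# active if strictly more than 8% of its samples are; a session is upright if
# the median filtered z is strictly below 0.1 and the median filtered x lies in
# [-0.2, 0.2]. Daily movement/upright rates are session-count fractions.

# Minimum series length for the padded zero-phase filter: pad length
# 3 * (order + 1) on each side requires at least one more interior sample.
minFilterLength <- function(order) 3L * (order + 1L) + 1L

#' Design a low-pass Butterworth filter
#'
#' @param sampling_rate sampling frequency in Hz.
#' @param cutoff cutoff frequency in Hz (must be below the Nyquist frequency).
#' @param order filter order (default 2).
#' @return list with coefficient vectors `b`, `a` and the design parameters.
#' @export
butterLowpass <- function(sampling_rate, cutoff = 4, order = 2) {
  stopifnotScalarNumeric(sampling_rate, "sampling_rate")
  stopifnotScalarNumeric(cutoff, "cutoff")
  if (cutoff >= sampling_rate / 2) {
    stop(sprintf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 cutoff, sampling_rate / 2))
  }
  bf <- signal::butter(order, cutoff / (sampling_rate / 2), type = "low")
  list(b = as.numeric(bf$b), a = as.numeric(bf$a),
       order = order, cutoff = cutoff, sampling_rate = sampling_rate)
}

# Causal IIR filter with steady-state initial conditions: the filter starts as
# if the input had been x[1] forever, so a constant series passes through
# exactly (unit DC gain) and the whole operation is linear in x.
lfilterSteady <- function(b, a, x) {
  nb <- length(b)
  v <- stats::filter(c(rep(x[1L], nb - 1L), x), b,
                     method = "convolution", sides = 1)
  v <- as.numeric(v)[-seq_len(nb - 1L)]
  as.numeric(stats::filter(v, -a[-1L], method = "recursive",
                           init = rep(x[1L], length(a) - 1L)))
}

# Column-wise variant: filters every column of X (series of equal length) in
# one pass; numerically identical to lfilterSteady per column. The moving-
# average part is an explicit shift-and-add (cheap); only the autoregressive
# part needs the C recursion in stats::filter.
lfilterSteadyMat <- function(b, a, X) {
  n <- nrow(X)
  m <- ncol(X)
  x1 <- X[1L, ]
  V <- b[1L] * X
  shifted <- X
  for (k in seq_along(b)[-1L]) {
    shifted <- rbind(matrix(x1, 1L, m), shifted[-n, , drop = FALSE])
    V <- V + b[k] * shifted
  }
  Y <- stats::filter(V, -a[-1L], method = "recursive",
                     init = matrix(x1, length(a) - 1L, m, byrow = TRUE))
  matrix(as.numeric(Y), n, m)
}

# Zero-phase filtering of every column of X; same algorithm as lowpassFilter
# (odd extension + forward/backward steady-state passes), batched.
filtfiltMat <- function(filt, X) {
  n <- nrow(X)
  pad <- 3L * (filt$order + 1L)
  left <- 2 * matrix(X[1L, ], pad, ncol(X), byrow = TRUE) -
    X[seq(pad + 1L, 2L), , drop = FALSE]
  right <- 2 * matrix(X[n, ], pad, ncol(X), byrow = TRUE) -
    X[seq(n - 1L, n - pad), , drop = FALSE]
  ext <- rbind(left, X, right)
  fwd <- lfilterSteadyMat(filt$b, filt$a, ext)
  rv <- fwd[rev(seq_len(nrow(fwd))), , drop = FALSE]
  bwd <- lfilterSteadyMat(filt$b, filt$a, rv)
  out <- bwd[rev(seq_len(nrow(bwd))), , drop = FALSE]
  out[seq(pad + 1L, pad + n), , drop = FALSE]
}

#' Zero-phase (bidirectional) low-pass filtering
#'
#' Applies the filter forward and backward so the net phase shift is zero and
#' the net gain is the squared single-pass magnitude response (0.5 at the
#' cutoff). The series is extended at both ends by odd reflection
#' (3 * (order + 1) samples) before filtering to suppress edge transients.
#'
#' @param x numeric series (one axis of one session).
#' @param filt filter design from [butterLowpass()], or `NULL` to design one
#'   from `sampling_rate`/`cutoff`/`order`.
#' @param sampling_rate,cutoff,order used when `filt` is `NULL`.
#' @return filtered series of the same length. Series shorter than
#'   3 * (order + 1) + 1 samples cannot be padded and are returned unchanged
#'   with attribute `unfiltered = TRUE`; callers classify those on raw
#'   magnitudes.
#' @export
lowpassFilter <- function(x, filt = NULL, sampling_rate = 10, cutoff = 4,
                          order = 2) {
  if (is.null(filt)) filt <- butterLowpass(sampling_rate, cutoff, order)
  if (anyNA(x) || any(!is.finite(x))) stop("series contains non-finite values")
  n <- length(x)
  pad <- 3L * (filt$order + 1L)
  if (n < minFilterLength(filt$order)) {
    return(structure(x, unfiltered = TRUE))
  }
  # odd (point-reflected) extension about the end samples
  left <- 2 * x[1L] - x[seq(pad + 1L, 2L)]
  right <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  ext <- c(left, x, right)
  fwd <- lfilterSteady(filt$b, filt$a, ext)
  bwd <- rev(lfilterSteady(filt$b, filt$a, rev(fwd)))
  bwd[seq(pad + 1L, pad + n)]
}

#' Classify accelerometer samples as active or stationary
#'
#' A sample is active when its (filtered) acceleration magnitude
#' \eqn{\sqrt{x^2+y^2+z^2}} falls strictly below 0.95 or strictly above 1.05 g;
#' magnitudes within the inclusive band are stationary (the phone is at rest
#' under gravity).
#'
#' @param x,y,z filtered acceleration components in g (vectors of equal length).
#' @param lower,upper stationary band bounds (default 0.95, 1.05, inclusive).
#' @return logical vector: `TRUE` = active.
#' @export
classifySampleMotion <- function(x, y, z, lower = 0.95, upper = 1.05) {
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(!is.finite(z))) {
    stop("accelerometer samples must be finite")
  }
  m <- sqrt(x^2 + y^2 + z^2)
  m < lower | m > upper
}

#' Classify a session as moving or stationary
#'
#' @param active logical per-sample labels from [classifySampleMotion()].
#' @param threshold active-sample fraction above which (strictly) the session
#'   is active (default 0.08).
#' @return `TRUE` if strictly more than `threshold` of the samples are active.
#' @export
classifySessionMotion <- function(active, threshold = 0.08) {
  if (length(active) == 0L) {
    stop("cannot classify a session with zero labeled samples")
  }
  mean(active) > threshold
}

#' Classify a session as upright
#'
#' Upright (e.g., phone held in front of the user) requires the median filtered
#' z strictly below `z_max` and the median filtered x within
#' `[-x_bound, x_bound]` (inclusive). Non-upright sessions may indicate typing
#' while lying down.
#'
#' @param x,z filtered x and z series of one session.
#' @param z_max strict upper bound on median z (default 0.1).
#' @param x_bound inclusive symmetric bound on median x (default 0.2).
#' @return logical scalar.
#' @export
classifySessionUpright <- function(x, z, z_max = 0.1, x_bound = 0.2) {
  if (length(x) == 0L) stop("cannot classify a session with zero samples")
  mz <- stats::median(z)
  mx <- stats::median(x)
  (mz < z_max) && (mx >= -x_bound) && (mx <= x_bound)
}

#' Label all accelerometer sessions of a sample table
#'
#' Filters each session's axes (sessions too short to pad are classified on raw
#' magnitudes and flagged) and applies the motion and upright rules.
#'
#' @param samples data.frame with columns `participant_id`, `session_index`,
#'   `date`, `timestamp_s` (seconds within session), `x`, `y`, `z` (g).
#' @param sampling_rate nominal sampling rate in Hz (default 10); samples are
#'   treated as regularly spaced (the magnitude/median rules tolerate mild
#'   timestamp jitter).
#' @param cutoff,order Butterworth design (defaults 4 Hz, order 2).
#' @param motion_threshold session active-fraction rule (default 0.08, strict).
#' @param band stationary magnitude band (default `c(0.95, 1.05)`, inclusive).
#' @param z_max,x_bound upright rule bounds (defaults 0.1 strict, 0.2 inclusive).
#' @return `data.table` with one row per session: `is_active`, `is_upright`,
#'   `n_samples`, `active_fraction`, `unfilterable`.
#' @export
labelAccelSessions <- function(samples, sampling_rate = 10, cutoff = 4,
                               order = 2, motion_threshold = 0.08,
                               band = c(0.95, 1.05), z_max = 0.1,
                               x_bound = 0.2) {
  samples <- as.data.table(samples)
  required <- c("participant_id", "session_index", "date", "x", "y", "z")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols)) {
    stop("samples is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  filt <- butterLowpass(sampling_rate, cutoff, order)
  keep <- intersect(c("participant_id", "session_index", "date",
                      "timestamp_s", "x", "y", "z"), names(samples))
  samples <- samples[, keep, with = FALSE]
  if ("timestamp_s" %in% names(samples)) {
    setorder(samples, participant_id, session_index, timestamp_s)
  } else {
    setorder(samples, participant_id, session_index)
  }
  if (any(!is.finite(samples$x) | !is.finite(samples$y) |
          !is.finite(samples$z))) {
    stop("accelerometer samples must be finite")
  }
  # batch zero-phase filtering: sessions of equal length share one matrix pass
  samples[, sid := rleid(participant_id, session_index)]
  len <- samples[, .N, by = sid]
  minlen <- minFilterLength(order)
  fx <- samples$x; fy <- samples$y; fz <- samples$z
  row0 <- c(0L, cumsum(len$N))
  for (n in unique(len$N[len$N >= minlen])) {
    g <- which(len$N == n)
    idx <- as.integer(outer(seq_len(n), row0[g], `+`))
    fx[idx] <- as.numeric(filtfiltMat(filt, matrix(samples$x[idx], n)))
    fy[idx] <- as.numeric(filtfiltMat(filt, matrix(samples$y[idx], n)))
    fz[idx] <- as.numeric(filtfiltMat(filt, matrix(samples$z[idx], n)))
  }
  samples[, `:=`(fx = fx, fy = fy, fz = fz)]
  samples[, active := classifySampleMotion(fx, fy, fz, band[1L], band[2L])]
  out <- samples[, .(
    date = asDate(date[1L]),
    is_active = mean(active) > motion_threshold,
    is_upright = classifySessionUpright(fx, fz, z_max, x_bound),
    n_samples = .N,
    active_fraction = mean(active),
    unfilterable = .N < minlen
  ), by = .(participant_id, session_index)]
  out[]
}

#' Aggregate session labels to daily movement and upright rates
#'
#' @param labels session label table from [labelAccelSessions()].
#' @return `data.table` with one row per (participant, date): `movement_rate`
#'   (fraction of sessions active), `upright_rate`, `n_sessions`. Days with
#'   zero labeled sessions emit no row.
#' @export
aggregateDailyAccel <- function(labels) {
  labels <- as.data.table(labels)
  out <- labels[, .(
    movement_rate = mean(is_active),
    upright_rate = mean(is_upright),
    n_sessions = .N
  ), by = .(participant_id, date)]
  setkey(out, participant_id, date)
  out[]
}

#' Daily accelerometer features from raw in-session samples
#'
#' Convenience wrapper over [labelAccelSessions()] and [aggregateDailyAccel()].
#'
#' @inheritParams labelAccelSessions
#' @return see [aggregateDailyAccel()].
#' @export
accelDailyFeatures <- function(samples, sampling_rate = 10, cutoff = 4,
                               order = 2, motion_threshold = 0.08,
                               band = c(0.95, 1.05), z_max = 0.1,
                               x_bound = 0.2) {
  aggregateDailyAccel(labelAccelSessions(
    samples, sampling_rate, cutoff, order, motion_threshold, band,
    z_max, x_bound
  ))
}
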