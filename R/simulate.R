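# Synthetic-study generator with known ground truth.
#
# Generates a complete synthetic study — raw keypress streams, in-session
# accelerometer traces, and daily Likert self-report panels — from a known
# mixing matrix, fixed effects and variance components, so that every upstream
# module and the end-to-end pipeline can be validated without access to any
# real participant data. Defaults mirror the scale of the motivating study
# (55 participants, ~33 days each, 34 items, 5 components).

#' Default self-report item catalogue
#'
#' 34 daily self-report items with the questionnaire family each one emulates:
#' symptom severity (DRSP-like, 6-point), agitation (BAM-like, 7-point),
#' irritability (BITe-like, 6-point), suicidal ideation (ASIQ-like, 7-point),
#' negative affect (PANAS-like, 5-point), interpersonal needs (INQ-like,
#' 7-point) and miscellaneous EMA items on 1-100 slider scales, including the
#' three positive-affect probes. Mixing coarse Likert items with
#' high-resolution sliders is typical of daily-diary batteries; each item's
#' baseline sits at the log-scale midpoint of its range.
#'
#' @return data.frame with columns `item`, `scale`, `scale_max` (top of the
#'   response range; the bottom is 1) and `base_log` (the item's baseline on
#'   the log scale).
#' @export
defaultItemCatalogue <- function() {
  items <- c(
    DepressedMood = "DRSP", Hopelessness = "DRSP", Worthlessness = "DRSP",
    Anxiety = "DRSP", MoodSwings = "DRSP", RejectionSensitivity = "DRSP",
    Anger = "DRSP", ConflictsWithOthers = "DRSP", LackingInterest = "DRSP",
    DifficultyConcentrating = "DRSP", Lethargy = "DRSP",
    Overwhelmed = "DRSP", OutOfControl = "DRSP", TroubleSleeping = "DRSP",
    InnerTension = "BAM", RacingThoughts = "BAM", Restless = "BAM",
    Grumpy = "BITe", MightExplode = "BITe", Irritable = "BITe",
    Annoyed = "BITe", AngryReactions = "BITe",
    LifeNotWorthLiving = "ASIQ", WishedNotAlive = "ASIQ",
    ThoughtsOfDeath = "ASIQ",
    Distressed = "PANAS", Upset = "PANAS",
    PerceivedBurden = "INQ", NotBelonging = "INQ",
    FeltHappy = "Misc", FeltCapable = "Misc", FeltConnected = "Misc",
    Anhedonia = "Misc", Unmotivated = "Misc"
  )
  p <- length(items)
  scale_max <- c(DRSP = 6, BAM = 7, BITe = 6, ASIQ = 7, PANAS = 5,
                 INQ = 7, Misc = 100)[unname(items)]
  data.frame(
    item = names(items), scale = unname(items),
    scale_max = unname(scale_max),
    base_log = log(sqrt(scale_max)) + 0.08 * sin(seq_len(p)),
    stringsAsFactors = FALSE
  )
}

#' Default ground-truth mixing matrix
#'
#' Five components patterned on the structures temporal ICA tends to find in
#' daily affect panels: a well-being contrast (positive-affect items against
#' the rest), an anhedonia component, an all-items participant-offset
#' component, an irritability/agitation component, and a weaker mixed
#' component. A small deterministic ripple keeps the columns well conditioned.
#'
#' @param catalogue item catalogue (see [defaultItemCatalogue()]).
#' @param q number of components (default 5; columns beyond 5 are ripple-only).
#' @return items-by-q numeric matrix with item row names.
#' @export
defaultMixingMatrix <- function(catalogue = defaultItemCatalogue(), q = 5) {
  p <- nrow(catalogue)
  A <- matrix(0, p, q, dimnames = list(catalogue$item,
                                       paste0("IC_", seq_len(q))))
  pos <- catalogue$item %in% c("FeltHappy", "FeltCapable", "FeltConnected")
  anh <- catalogue$item %in% c("LackingInterest", "Anhedonia", "Unmotivated",
                               "Lethargy")
  irr <- catalogue$scale %in% c("BAM", "BITe") |
    catalogue$item %in% c("Anger", "ConflictsWithOthers",
                          "RejectionSensitivity")
  # moderate loadings: items respond to the latent components without
  # saturating their bounded response ranges
  if (q >= 1) A[, 1] <- ifelse(pos, 0.35, -0.14)
  if (q >= 2) A[, 2] <- ifelse(anh, 0.32, ifelse(pos, -0.15, 0.035))
  if (q >= 3) A[, 3] <- -0.21 + 0.07 * sin(seq_len(p) * 1.3)
  if (q >= 4) A[, 4] <- ifelse(irr, 0.28, 0.015)
  if (q >= 5) A[, 5] <- ifelse(catalogue$scale == "BITe", -0.21,
                               0.07 * sin(seq_len(p) * 2.3))
  for (k in seq_len(q)) A[, k] <- A[, k] + 0.028 * sin(seq_len(p) * (k + 0.7))
  A
}

#' Ground truth for a synthetic digital-phenotyping study
#'
#' Bundles every generative parameter: the item catalogue and mixing matrix of
#' the self-report model, the fixed effects linking standardized passive
#' features to each component, per-component variance components of the nested
#' random-effects model, typing/accelerometer generation dials, per-modality
#' missingness rates and the master seed. Defaults target the scale of the
#' motivating study: 55 participants with 33 consecutive days each; the
#' headline planted effect is `beta1["IC_2", "movement_rate"] = -0.12`.
#'
#' `dist` controls the distribution of the random effects and residuals of the
#' latent component model: `"laplace"` (default; variance-matched, heavy
#' tailed) emulates the skewed, heavy-tailed daily-affect fluctuations real
#' panels show — and is what makes the components identifiable by ICA, which
#' cannot separate exactly Gaussian sources. Use `"gaussian"` for strictly
#' Gaussian random effects when validating the mixed-model stage in isolation.
#'
#' @param n_participants number of participants (default 55).
#' @param days_per_participant consecutive study days each (default 33).
#' @param q number of components (default 5).
#' @param catalogue item catalogue, see [defaultItemCatalogue()].
#' @param likert_max top of each item's response range (scalar or length-p
#'   vector; default: the catalogue's `scale_max`. The bottom is always 1).
#' @param A ground-truth mixing matrix (items x q).
#' @param beta0 per-component grand means (length q).
#' @param beta1 q x 8 matrix of fixed effects on the standardized features.
#' @param sigma1_sq,sigma2_sq,sigma_sq per-component variances of the
#'   participant intercept, week-within-participant intercept, and residual.
#' @param item_noise_sd log-scale measurement noise SD of the items.
#' @param dist `"laplace"` or `"gaussian"` latent noise (see Details).
#' @param feature_rho exchangeable correlation of the latent daily features
#'   (default 0: independent).
#' @param missingness named rates in `[0,1)` of missing-completely-at-random
#'   day dropout per modality (`keyboard`, `accel`, `selfreport`).
#' @param typing list of typing-stream dials: `sessions_range` (sessions per
#'   day, inclusive), `volume_median`/`volume_sdlog` (daily keypresses),
#'   `ikd_median`/`ikd_median_sdlog` (median inter-key delay, s),
#'   `ikd_sdlog_base`/`ikd_sdlog_scale` (within-session IKD spread),
#'   `autocorrect_base`, `backspace_base`, `other_rate`, `rate_scale`,
#'   `movement_base`, `movement_scale`, `upright_base`, `upright_scale`.
#' @param accel list of accelerometer dials: `sampling_rate` (Hz),
#'   `session_cap_s` (trace length cap per session), `noise_sd` (g),
#'   `burst_amp`, `burst_freq` (Hz), `burst_frac` (fraction of the session
#'   covered by the planted motion burst).
#' @param seed master seed; every downstream draw derives from it.
#' @return a validated `SyntheticTruth` list.
#' @export
syntheticTruth <- function(n_participants = 55,
                           days_per_participant = 33,
                           q = 5,
                           catalogue = defaultItemCatalogue(),
                           likert_max = catalogue$scale_max,
                           A = defaultMixingMatrix(catalogue, q),
                           beta0 = rep(0, q),
                           beta1 = defaultFixedEffects(q),
                           sigma1_sq = defaultVariance(q, "participant"),
                           sigma2_sq = defaultVariance(q, "week"),
                           sigma_sq = defaultVariance(q, "residual"),
                           item_noise_sd = 0.12,
                           dist = c("laplace", "gaussian"),
                           feature_rho = 0,
                           missingness = c(keyboard = 0.08, accel = 0.03,
                                           selfreport = 0.05),
                           typing = list(),
                           accel = list(),
                           seed = 1) {
  dist <- match.arg(dist)
  typing_defaults <- list(
    sessions_range = c(4L, 8L), volume_median = 1050, volume_sdlog = 0.30,
    ikd_median = 0.25, ikd_median_sdlog = 0.15,
    ikd_sdlog_base = 0.45, ikd_sdlog_scale = 0.20,
    autocorrect_base = 0.04, backspace_base = 0.08, other_rate = 0.02,
    rate_scale = 0.35, movement_base = 0.35, movement_scale = 0.9,
    upright_base = 0.6, upright_scale = 0.9
  )
  accel_defaults <- list(
    sampling_rate = 10, session_cap_s = 30, noise_sd = 0.01,
    burst_amp = 0.35, burst_freq = 0.4, burst_frac = 0.3
  )
  typing <- utils::modifyList(typing_defaults, typing)
  accel <- utils::modifyList(accel_defaults, accel)
  truth <- structure(list(
    n_participants = as.integer(n_participants),
    days_per_participant = as.integer(days_per_participant),
    q = as.integer(q), catalogue = catalogue, likert_max = likert_max,
    A = A, beta0 = beta0, beta1 = beta1,
    sigma1_sq = sigma1_sq, sigma2_sq = sigma2_sq, sigma_sq = sigma_sq,
    item_noise_sd = item_noise_sd, dist = dist, feature_rho = feature_rho,
    missingness = missingness, typing = typing, accel = accel,
    seed = as.integer(seed)
  ), class = "SyntheticTruth")
  validateTruth(truth)
  truth
}

defaultFixedEffects <- function(q) {
  b <- matrix(0, q, length(FUSION_FEATURES),
              dimnames = list(paste0("IC_", seq_len(q)), FUSION_FEATURES))
  if (q >= 1) b["IC_1", c("median_ikd", "upright_rate")] <- c(-0.05, 0.04)
  if (q >= 2) b["IC_2", c("median_ikd", "movement_rate")] <- c(0.10, -0.12)
  if (q >= 4) b["IC_4", c("median_ikd", "total_keypresses")] <- c(-0.09, 0.06)
  if (q >= 5) b["IC_5", "total_keypresses"] <- -0.06
  b
}

defaultVariance <- function(q, which) {
  base <- switch(which,
    participant = rep(0.25, q),
    week = rep(0.16, q),
    residual = rep(0.55, q)
  )
  # the third component is a participant-offset component: most of its
  # variance lives at the participant level
  if (q >= 3) {
    if (which == "participant") base[3] <- 0.70
    if (which == "week") base[3] <- 0.05
    if (which == "residual") base[3] <- 0.25
  }
  base
}

validateTruth <- function(truth) {
  with(truth, {
    if (n_participants < 1L) stop("n_participants must be >= 1")
    if (days_per_participant < 1L) stop("days_per_participant must be >= 1")
    if (ncol(A) != q || nrow(A) != nrow(catalogue)) {
      stop("A must be items x q")
    }
    if (!identical(dim(beta1), c(as.integer(q), length(FUSION_FEATURES)))) {
      stop("beta1 must be q x ", length(FUSION_FEATURES))
    }
    for (v in list(sigma1_sq, sigma2_sq, sigma_sq)) {
      if (length(v) != q || any(v < 0)) {
        stop("variance components must be length-q and non-negative")
      }
    }
    if (any(missingness < 0) || any(missingness >= 1)) {
      stop("missingness rates must lie in [0, 1)")
    }
  })
  invisible(truth)
}

#' @export
print.SyntheticTruth <- function(x, ...) {
  cat(sprintf(
    "SyntheticTruth: %d participants x %d days, %d items, q = %d, dist = %s, seed = %d\n",
    x$n_participants, x$days_per_participant, nrow(x$catalogue), x$q,
    x$dist, x$seed
  ))
  cat("  planted fixed effects (nonzero):\n")
  nz <- which(x$beta1 != 0, arr.ind = TRUE)
  for (r in seq_len(nrow(nz))) {
    cat(sprintf("    %s ~ %s: %+0.3f\n",
                rownames(x$beta1)[nz[r, 1]], colnames(x$beta1)[nz[r, 2]],
                x$beta1[nz[r, 1], nz[r, 2]]))
  }
  invisible(x)
}

# Zero-mean noise with the requested variance and family.
drawNoise <- function(n, variance, dist) {
  if (variance == 0) return(rep(0, n))
  if (dist == "gaussian") {
    stats::rnorm(n, sd = sqrt(variance))
  } else {
    b <- sqrt(variance / 2)  # Laplace(0, b) has variance 2 b^2
    stats::rexp(n, rate = 1 / b) - stats::rexp(n, rate = 1 / b)
  }
}

#' Participant-week-day index grid
#'
#' @param n_participants,weeks,days_per_week grid dimensions; dates are laid
#'   out so that day d of week w is calendar day `(w-1)*7 + d`.
#' @param origin first calendar date.
#' @return data.frame with `participant_id`, `date`, `week`, `day_of_week`.
#' @export
studyGrid <- function(n_participants, weeks, days_per_week,
                      origin = as.Date("2023-03-01")) {
  g <- expand.grid(
    day_of_week = seq_len(days_per_week), week = seq_len(weeks),
    participant_id = sprintf("P%03d", seq_len(n_participants)),
    stringsAsFactors = FALSE
  )
  g$date <- origin + (g$week - 1L) * 7L + (g$day_of_week - 1L)
  g[, c("participant_id", "date", "week", "day_of_week")]
}

#' Simulate latent component values from the nested mixed-effects model
#'
#' Draws, for each participant-day, the q component values
#' `y = beta0 + b_i + b_ij + beta1' x + eps` with participant intercepts
#' `b_i`, week-within-participant intercepts `b_ij` and residuals `eps` drawn
#' from the `dist` family at the truth's variances. The standardized daily
#' feature vector `x` is drawn from a correlated Gaussian unless supplied
#' (e.g., the realized, stream-derived features).
#'
#' @param truth a [syntheticTruth()].
#' @param index participant-day grid with `participant_id`, `date`, `week`
#'   columns; default: the truth's consecutive-day layout.
#' @param x optional n x 8 matrix of standardized features (columns
#'   `FUSION_FEATURES` order); drawn if `NULL`.
#' @param dist noise family override (default `truth$dist`).
#' @param seed seed (default `truth$seed`).
#' @return data.frame: the index columns, the eight feature columns, and
#'   `IC_1..IC_q` latent values.
#' @export
simulateLatents <- function(truth, index = NULL, x = NULL,
                            dist = truth$dist, seed = truth$seed) {
  if (is.null(index)) {
    d <- truth$days_per_participant
    index <- studyGrid(truth$n_participants, ceiling(d / 7), 7)
    index <- index[(index$week - 1L) * 7L + index$day_of_week <= d, ]
  }
  index <- as.data.frame(index)
  n <- nrow(index)
  q <- truth$q
  nf <- length(FUSION_FEATURES)
  withSeed(seed, {
    if (is.null(x)) {
      R <- matrix(truth$feature_rho, nf, nf); diag(R) <- 1
      x <- matrix(stats::rnorm(n * nf), n, nf) %*% chol(R)
      colnames(x) <- FUSION_FEATURES
    } else {
      x <- as.matrix(x)
      stopifnot(nrow(x) == n, ncol(x) == nf)
      colnames(x) <- FUSION_FEATURES
    }
    pid <- as.character(index$participant_id)
    pw <- paste(pid, index$week)
    u_p <- unique(pid); u_pw <- unique(pw)
    Y <- matrix(0, n, q, dimnames = list(NULL, paste0("IC_", seq_len(q))))
    for (k in seq_len(q)) {
      b_i <- drawNoise(length(u_p), truth$sigma1_sq[k], dist)
      b_ij <- drawNoise(length(u_pw), truth$sigma2_sq[k], dist)
      eps <- drawNoise(n, truth$sigma_sq[k], dist)
      Y[, k] <- truth$beta0[k] + b_i[match(pid, u_p)] +
        b_ij[match(pw, u_pw)] + as.numeric(x %*% truth$beta1[k, ]) + eps
    }
    cbind(index, as.data.frame(x), as.data.frame(Y))
  })
}

#' Simulate a daily Likert self-report panel from component values
#'
#' Log-scale item values are `base_log + A y + noise`; they are exponentiated,
#' rounded half-up and clipped to `[1, likert_max]`. The discretization is a
#' known (and documented) source of attenuation when the panel is decomposed
#' again.
#'
#' @param truth a [syntheticTruth()].
#' @param latents data.frame from [simulateLatents()] (needs `participant_id`,
#'   `date` and the `IC_*` columns).
#' @param discretize round half-up and clip to `[1, likert_max]` (default
#'   `TRUE`); `FALSE` returns the continuous positive responses.
#' @param seed seed for the item measurement noise.
#' @return data.frame panel: `participant_id`, `date`, one column per item.
#' @export
simulateSelfreport <- function(truth, latents, discretize = TRUE,
                               seed = truth$seed + 1) {
  ic_cols <- paste0("IC_", seq_len(truth$q))
  Y <- as.matrix(latents[ic_cols])
  n <- nrow(Y)
  p <- nrow(truth$catalogue)
  withSeed(seed, {
    L <- matrix(rep(truth$catalogue$base_log, each = n), n, p) +
      Y %*% t(truth$A)
    if (truth$item_noise_sd > 0) {
      L <- L + matrix(stats::rnorm(n * p, sd = truth$item_noise_sd), n, p)
    }
    V <- exp(L)
    if (discretize) {
      lmax <- rep_len(truth$likert_max, p)
      V <- pmin(pmax(floor(V + 0.5), 1), rep(lmax, each = n))
    }
    colnames(V) <- truth$catalogue$item
    cbind(latents[c("participant_id", "date")], as.data.frame(V))
  })
}

# Per-day natural-scale typing/accelerometer targets from standard-normal
# dials z (n x 8). Movement/upright propensities are discretized to counts
# over the day's sessions, so the planted daily rates are exactly achievable.
generatorTargets <- function(truth, index, seed) {
  ty <- truth$typing
  n <- nrow(index)
  withSeed(seed, {
    z <- matrix(stats::rnorm(n * 8), n, 8)
    M <- sample(seq(ty$sessions_range[1], ty$sessions_range[2]), n,
                replace = TRUE)
    data.table(
      participant_id = as.character(index$participant_id),
      date = asDate(index$date),
      n_sessions = M,
      volume = pmax(50L, as.integer(round(exp(
        log(ty$volume_median) + ty$volume_sdlog * z[, 1]
      )))),
      ikd_median = exp(log(ty$ikd_median) + ty$ikd_median_sdlog * z[, 2]),
      ikd_sdlog = ty$ikd_sdlog_base * exp(ty$ikd_sdlog_scale * z[, 3]),
      autocorrect_rate = stats::plogis(
        stats::qlogis(ty$autocorrect_base) + ty$rate_scale * z[, 4]),
      backspace_rate = stats::plogis(
        stats::qlogis(ty$backspace_base) + ty$rate_scale * z[, 5]),
      n_active = as.integer(round(stats::plogis(
        stats::qlogis(ty$movement_base) + ty$movement_scale * z[, 6]) * M)),
      n_upright = as.integer(round(stats::plogis(
        stats::qlogis(ty$upright_base) + ty$upright_scale * z[, 7]) * M))
    )
  })
}

#' Simulate raw keypress streams for planned participant-days
#'
#' Emits, for each planned day, `n_sessions` typing sessions whose inter-key
#' gaps are log-normal with the day's target median IKD and spread (capped
#' below the 6 s session rule), with autocorrect/backspace/other presses
#' planted at the target rates and the keyboard-dismissal flag set on each
#' session's last press. Sessions are separated by 60-600 s pauses starting at
#' 08:00 local time.
#'
#' @param plan data.table/data.frame with one row per participant-day:
#'   `participant_id`, `date`, `n_sessions`, `volume`, `ikd_median`,
#'   `ikd_sdlog`, `autocorrect_rate`, `backspace_rate` (see
#'   [syntheticTruth()]'s typing dials).
#' @param other_rate constant rate of "other" presses (default 0.02).
#' @param seed seed.
#' @return list with `events` (the raw keypress table in the input-CSV
#'   contract) and `sessions` (one row per session: start, duration, size —
#'   the session plan the accelerometer generator consumes).
#' @export
simulateKeystrokes <- function(plan, other_rate = 0.02, seed = 1) {
  plan <- as.data.table(plan)
  withSeed(seed, {
    # one row per session
    sess <- plan[, {
      M <- n_sessions
      sizes <- rep(volume %/% M, M)
      extra <- volume %% M
      if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
      list(session_in_day = seq_len(M), size = sizes,
           ikd_median = ikd_median, ikd_sdlog = ikd_sdlog,
           autocorrect_rate = autocorrect_rate,
           backspace_rate = backspace_rate)
    }, by = .(participant_id, date)]
    sess[, session_index := seq_len(.N), by = participant_id]
    # inter-key gaps for every non-first press, log-normal, capped below 6 s
    n_events <- sum(sess$size)
    ev <- sess[, {
      list(press = seq_len(size), size = size,
           ikd_median = ikd_median, ikd_sdlog = ikd_sdlog,
           autocorrect_rate = autocorrect_rate,
           backspace_rate = backspace_rate)
    }, by = .(participant_id, date, session_index)]
    gaps <- stats::rlnorm(n_events, meanlog = log(ev$ikd_median),
                          sdlog = ev$ikd_sdlog)
    gaps <- pmin(gaps, 5.5)
    gaps[ev$press == 1L] <- 0
    ev[, gap := gaps]
    ev[, offset := cumsum(gap), by = .(participant_id, session_index)]
    dur <- ev[, .(duration = offset[.N], size = size[1L]),
              by = .(participant_id, date, session_index)]
    # session start times: day starts at 08:00, 60-600 s pauses between sessions
    dur[, pause := stats::runif(.N, 60, 600)]
    dur[, day_epoch := as.numeric(as.POSIXct(paste(date, "08:00:00"),
                                             tz = "UTC"))]
    dur[, start := day_epoch +
          cumsum(c(0, head(duration + pause, -1L))), by = .(participant_id, date)]
    # ev and dur share the (participant, date, session) grouping order
    ev[, timestamp := rep(dur$start, dur$size) + offset]
    # plant key classes with exact per-session counts: the events holding the
    # k smallest of iid uniform draws within a session are k uniformly random
    # positions
    ev[, u := stats::runif(.N)]
    ev[, gid := rleid(participant_id, session_index)]
    setorder(ev, gid, u)  # row order is irrelevant from here on
    ev[, urank := seq_len(.N), by = gid]
    ev[, `:=`(
      k_auto = round(autocorrect_rate * size),
      k_back = round(backspace_rate * size),
      k_other = round(other_rate * size)
    )]
    ev[, key_class := fifelse(
      urank <= k_auto, "autocorrect",
      fifelse(urank <= k_auto + k_back, "backspace",
              fifelse(urank <= k_auto + k_back + k_other, "other",
                      "alphanumeric"))
    )]
    ev[, keyboard_dismissed := as.integer(press == size)]
    events <- ev[, .(participant_id, timestamp, date, key_class,
                     keyboard_dismissed)]
    setorder(events, participant_id, timestamp)
    sessions <- dur[, .(participant_id, date, session_index,
                        start, duration, size)]
    list(events = events[], sessions = sessions[])
  })
}

#' Simulate in-session accelerometer traces for a session plan
#'
#' Stationary sessions get a unit-magnitude gravity orientation plus small
#' noise; sessions planted active get a slow sinusoidal magnitude burst (well
#' inside the 4 Hz passband) covering `burst_frac` of the trace, so that far
#' more than 8% of samples leave the stationary band after filtering. Upright
#' sessions use a near-vertical orientation (median z near 0, median x near 0);
#' non-upright sessions a reclined one (median z near 0.9).
#'
#' @param sessions session plan from [simulateKeystrokes()] plus logical
#'   columns `active` and `upright` (the planted labels).
#' @param sampling_rate Hz (default 10).
#' @param session_cap_s maximum trace duration per session (default 30).
#' @param noise_sd per-axis noise SD in g (default 0.01).
#' @param burst_amp,burst_freq,burst_frac motion-burst dials.
#' @param seed seed.
#' @return data.table in the accelerometer input contract: `participant_id`,
#'   `session_index`, `date`, `timestamp_s`, `x`, `y`, `z`.
#' @export
simulateAccelerometer <- function(sessions, sampling_rate = 10,
                                  session_cap_s = 30, noise_sd = 0.01,
                                  burst_amp = 0.35, burst_freq = 0.4,
                                  burst_frac = 0.3, seed = 1) {
  sess <- as.data.table(sessions)
  stopifnot(all(c("active", "upright") %in% names(sess)))
  upright_base <- c(0, -sqrt(1 - 0.03^2), 0.03)
  reclined_base <- local({
    v <- c(0.05, -0.43, 0.90); v / sqrt(sum(v^2))
  })
  withSeed(seed, {
    sess[, n_samp := pmax(12L, pmin(
      as.integer(ceiling(duration * sampling_rate)),
      as.integer(session_cap_s * sampling_rate)
    ))]
    n <- sess$n_samp
    total <- sum(n)
    pos <- sequence(n)
    t <- (pos - 1L) / sampling_rate
    up <- rep(sess$upright, n)
    act <- rep(sess$active, n)
    # slow magnitude burst over a contiguous window of each active session
    i0 <- rep(floor(n * 0.35), n)
    ilen <- rep(pmax(1L, ceiling(n * burst_frac)), n)
    in_burst <- act & pos > i0 & pos <= i0 + ilen
    scale <- rep(1, total)
    scale[in_burst] <- 1 + burst_amp * sin(2 * pi * burst_freq * t[in_burst])
    bx <- ifelse(up, upright_base[1L], reclined_base[1L])
    by_ <- ifelse(up, upright_base[2L], reclined_base[2L])
    bz <- ifelse(up, upright_base[3L], reclined_base[3L])
    out <- data.table(
      participant_id = rep(sess$participant_id, n),
      session_index = rep(sess$session_index, n),
      date = rep(sess$date, n),
      timestamp_s = t,
      x = bx * scale + stats::rnorm(total, sd = noise_sd),
      y = by_ * scale + stats::rnorm(total, sd = noise_sd),
      z = bz * scale + stats::rnorm(total, sd = noise_sd)
    )
    out[]
  })
}

#' Simulate a complete synthetic study
#'
#' Generates the full study from a [syntheticTruth()]: raw keypress streams,
#' in-session accelerometer traces and the daily self-report panel, plus the
#' ground truth needed to score recovery. The component values are generated
#' from the *realized* daily features — the keyboard module is run on the
#' simulated streams and the planted movement/upright rates are used — and
#' standardized over the complete-case aligned days, so the planted fixed
#' effects are defined on exactly the scale the analysis pipeline sees.
#' Per-modality missing-completely-at-random day dropout is applied last.
#' Self-report days outside the aligned set receive latent features drawn from
#' the standard normal (they feed the ICA but never the fusion models).
#'
#' @param truth a [syntheticTruth()].
#' @param dir optional output directory; when given, writes `keypresses.csv`,
#'   `accel.csv`, `selfreport.csv` and `truth.json`.
#' @return a `SyntheticStudy` list: `keypresses`, `accel`, `selfreport` (the
#'   three input tables), and `truth` (ground-truth record: the generative
#'   parameters, the per-day true component values and realized features, the
#'   standardization parameters, and the aligned-day key set).
#' @export
simulateStudy <- function(truth, dir = NULL) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  seeds <- deriveSeeds(truth$seed, 6)
  d <- truth$days_per_participant
  index <- studyGrid(truth$n_participants, ceiling(d / 7), 7)
  index <- index[(index$week - 1L) * 7L + index$day_of_week <= d, ]
  index <- index[order(index$participant_id, index$date), ]

  targets <- generatorTargets(truth, index, seeds[1])
  ks <- simulateKeystrokes(targets, other_rate = truth$typing$other_rate,
                           seed = seeds[2])

  # planted session labels: exactly n_active / n_upright sessions per day
  sess <- merge(ks$sessions,
                targets[, .(participant_id, date, n_sessions, n_active,
                            n_upright)],
                by = c("participant_id", "date"))
  setorder(sess, participant_id, date, session_index)
  sess[, active := seq_len(.N) <= n_active[1L], by = .(participant_id, date)]
  sess[, upright := seq_len(.N) <= n_upright[1L], by = .(participant_id, date)]
  acc <- simulateAccelerometer(
    sess, sampling_rate = truth$accel$sampling_rate,
    session_cap_s = truth$accel$session_cap_s,
    noise_sd = truth$accel$noise_sd, burst_amp = truth$accel$burst_amp,
    burst_freq = truth$accel$burst_freq, burst_frac = truth$accel$burst_frac,
    seed = seeds[3]
  )

  # per-modality MCAR day dropout
  n_days <- nrow(index)
  drop <- withSeed(seeds[4], data.frame(
    kb = stats::runif(n_days) < truth$missingness[["keyboard"]],
    ac = stats::runif(n_days) < truth$missingness[["accel"]],
    sr = stats::runif(n_days) < truth$missingness[["selfreport"]]
  ))
  key <- paste(index$participant_id, index$date)
  day_key <- data.table(participant_id = index$participant_id,
                        date = asDate(index$date))
  kb_keep <- key[!drop$kb]
  ac_keep <- key[!(drop$kb | drop$ac)]  # accel exists only when typing happened
  sr_keep <- key[!drop$sr]
  events <- ks$events[day_key[!drop$kb], on = c("participant_id", "date"),
                      nomatch = 0L]
  acc <- acc[day_key[!(drop$kb | drop$ac)], on = c("participant_id", "date"),
             nomatch = 0L]

  # realized daily features on the retained streams, via the keyboard module
  kb_daily <- keyboardDailyFeatures(events)
  move_daily <- targets[, .(participant_id, date,
                            movement_rate = n_active / n_sessions,
                            upright_rate = n_upright / n_sessions)]
  feats <- merge(kb_daily, move_daily, by = c("participant_id", "date"))
  feats[, key := paste(participant_id, date)]
  aligned <- feats[included == TRUE & key %in% ac_keep & key %in% sr_keep &
                     stats::complete.cases(feats[, .(median_ikd, p95_ikd,
                                                     mad_ikd)])]
  st <- standardizeFeatures(as.data.frame(aligned))

  # latent components: realized features on aligned days, standard-normal
  # latent dials elsewhere (those days feed the ICA only)
  sr_index <- index[key %in% sr_keep, ]
  sr_key <- paste(sr_index$participant_id, sr_index$date)
  x <- withSeed(seeds[5] + 1,
                matrix(stats::rnorm(nrow(sr_index) * length(FUSION_FEATURES)),
                       nrow(sr_index), length(FUSION_FEATURES)))
  hit <- match(sr_key, paste(st$data$participant_id, st$data$date))
  x[!is.na(hit), ] <- as.matrix(st$data[stats::na.omit(hit),
                                        FUSION_FEATURES])
  latents <- simulateLatents(truth, index = sr_index, x = x,
                             dist = truth$dist, seed = seeds[5])
  panel <- simulateSelfreport(truth, latents, seed = seeds[6])

  truth_out <- list(
    parameters = truth,
    latents = latents[, c("participant_id", "date", "week",
                          paste0("IC_", seq_len(truth$q)))],
    realized_features = as.data.frame(aligned),
    standardization = list(center = st$center, scale = st$scale),
    aligned_days = aligned$key,
    seeds = seeds
  )
  bundle <- structure(list(
    keypresses = events, accel = acc, selfreport = panel, truth = truth_out
  ), class = "SyntheticStudy")
  if (!is.null(dir)) writeStudy(bundle, dir)
  bundle
}

#' @export
print.SyntheticStudy <- function(x, ...) {
  cat(sprintf(
    "SyntheticStudy: %d keypresses, %d accel samples, %d self-report days (%d aligned)\n",
    nrow(x$keypresses), nrow(x$accel), nrow(x$selfreport),
    length(x$truth$aligned_days)
  ))
  invisible(x)
}

# Write a study bundle to disk in the input-CSV contracts.
writeStudy <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ev <- copy(bundle$keypresses)
  ev[, timestamp := format(as.POSIXct(timestamp, origin = "1970-01-01",
                                      tz = "UTC"),
                           "%Y-%m-%dT%H:%M:%OS3")]
  fwrite(ev, file.path(dir, "keypresses.csv"))
  fwrite(bundle$accel, file.path(dir, "accel.csv"))
  fwrite(bundle$selfreport, file.path(dir, "selfreport.csv"))
  tr <- bundle$truth
  tr$parameters <- unclass(tr$parameters)
  jsonlite::write_json(tr, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(file.path(dir, c("keypresses.csv", "accel.csv", "selfreport.csv",
                             "truth.json")))
}
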