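# Independent brute-force oracles and random-fixture builders. These
# re-derive every quantity from first principles with plain loops, sharing no
# code with the package implementation.

# --- random fixtures ---------------------------------------------------------

randomKeypressStream <- function(n, n_participants = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pid <- sort(sample(sprintf("p%02d", seq_len(n_participants)), n,
                     replace = TRUE))
  ev <- do.call(rbind, lapply(unique(pid), function(p) {
    np <- sum(pid == p)
    data.frame(
      participant_id = p,
      timestamp = cumsum(stats::runif(np, 0, 4)),
      date = as.Date("2023-01-05"),
      key_class = sample(c("alphanumeric", "autocorrect", "backspace",
                           "other"), np, replace = TRUE,
                         prob = c(0.7, 0.1, 0.1, 0.1)),
      keyboard_dismissed = stats::rbinom(np, 1, 0.08)
    )
  }))
  rownames(ev) <- NULL
  ev
}

randomAccelSession <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base <- stats::rnorm(3)
  base <- base / sqrt(sum(base^2))
  amp <- stats::runif(1, 0, 0.3)
  t <- (seq_len(n) - 1) / 10
  w <- 1 + amp * sin(2 * pi * stats::runif(1, 0.2, 1.5) * t)
  data.frame(
    participant_id = "p1", session_index = 1L, date = as.Date("2023-01-05"),
    timestamp_s = t,
    x = base[1] * w + stats::rnorm(n, sd = 0.05),
    y = base[2] * w + stats::rnorm(n, sd = 0.05),
    z = base[3] * w + stats::rnorm(n, sd = 0.05)
  )
}

# --- keyboard oracles --------------------------------------------------------

# Brute-force segmentation: scan the stream, starting a new session at every
# gap >= threshold or after a dismissal flag. Returns session index per event.
oracleSegment <- function(timestamp, dismissed, threshold = 6) {
  n <- length(timestamp)
  idx <- integer(n)
  cur <- 1L
  for (i in seq_len(n)) {
    if (i > 1L) {
      if ((timestamp[i] - timestamp[i - 1L]) >= threshold ||
          isTRUE(dismissed[i - 1L] == 1)) {
        cur <- cur + 1L
      }
    }
    idx[i] <- cur
  }
  idx
}

# Brute-force session features: loop over successive event pairs.
oracleSessionFeatures <- function(timestamp, key_class) {
  n <- length(timestamp)
  ikds <- c()
  for (i in seq_len(max(0L, n - 1L))) {
    if (key_class[i] == "alphanumeric" && key_class[i + 1L] == "alphanumeric") {
      ikds <- c(ikds, timestamp[i + 1L] - timestamp[i])
    }
  }
  if (length(ikds) >= 1L) {
    med <- stats::median(ikds)
    list(median_ikd = med,
         p95_ikd = unname(stats::quantile(ikds, 0.95, type = 7)),
         mad_ikd = mean(abs(ikds - med)))
  } else {
    list(median_ikd = NA_real_, p95_ikd = NA_real_, mad_ikd = NA_real_)
  }
}

# --- accelerometer oracles ---------------------------------------------------

# Transfer-function gain of the designed filter at frequency f (Hz): the
# bidirectional pass applies |H|^2.
oracleFilterGain <- function(filt, f) {
  w <- 2 * pi * f / filt$sampling_rate
  z <- exp(-1i * w * (seq_along(filt$b) - 1))
  H <- sum(filt$b * z) / sum(filt$a * z)
  Mod(H)^2
}

# First-principles session labels from filtered axes.
oracleSessionLabels <- function(fx, fy, fz) {
  n <- length(fx)
  act <- logical(n)
  for (i in seq_len(n)) {
    m <- sqrt(fx[i]^2 + fy[i]^2 + fz[i]^2)
    act[i] <- (m < 0.95) || (m > 1.05)
  }
  list(
    is_active = (sum(act) / n) > 0.08,
    is_upright = (stats::median(fz) < 0.1) &&
      (stats::median(fx) >= -0.2) && (stats::median(fx) <= 0.2),
    active_fraction = sum(act) / n
  )
}

# --- shared synthetic model fixtures ----------------------------------------

# Laplace mixture fixture for ICA recovery checks.
laplaceMixture <- function(p, q, n, noise_sd, seed, max_kappa = 10) {
  set.seed(seed)
  repeat {
    A <- matrix(stats::rnorm(p * q), p, q)
    if (kappa(A, exact = TRUE) < max_kappa) break
  }
  S <- matrix(stats::rexp(q * n) - stats::rexp(q * n), q, n) / sqrt(2)
  X <- A %*% S + matrix(stats::rnorm(p * n, sd = noise_sd), p, n)
  list(A = A, S = S, X = X)
}

# Small mixed-model truth used across fusion tests: one component, eight
# features, known coefficients.
fusionTruth <- function(beta1 = c(0.10, -0.05, 0.03, 0, 0.08, -0.12, 0.06, 0),
                        sigma1_sq = 0.25, sigma2_sq = 0.16, sigma_sq = 0.5,
                        seed = 1) {
  b <- matrix(beta1, 1, 8,
              dimnames = list("IC_1", phenofuse:::FUSION_FEATURES))
  syntheticTruth(
    n_participants = 40, days_per_participant = 28, q = 1,
    catalogue = defaultItemCatalogue(), A = defaultMixingMatrix(q = 1),
    beta0 = 0.3, beta1 = b, sigma1_sq = sigma1_sq, sigma2_sq = sigma2_sq,
    sigma_sq = sigma_sq, dist = "gaussian", seed = seed
  )
}

# Draw one mixed-model dataset on an i x j x k grid from a fusion truth.
fusionDataset <- function(truth, n_part = 40, weeks = 6, days = 4, seed = 1) {
  idx <- studyGrid(n_part, weeks, days)
  simulateLatents(truth, index = idx, dist = "gaussian", seed = seed)
}
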