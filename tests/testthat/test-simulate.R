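# Synthetic-study generator: determinism, degenerate contracts, round-trip
# fidelity of the planted targets through the extraction modules.

smallTruth <- function(...) {
  syntheticTruth(n_participants = 5, days_per_participant = 10, seed = 123, ...)
}

test_that("latent model degenerates to the grand mean without noise or effects", {
  truth <- syntheticTruth(
    n_participants = 3, days_per_participant = 7, q = 2,
    A = defaultMixingMatrix(q = 2), beta0 = c(1.5, -2),
    beta1 = matrix(0, 2, 8), sigma1_sq = c(0, 0), sigma2_sq = c(0, 0),
    sigma_sq = c(0, 0), dist = "gaussian", seed = 1
  )
  lat <- simulateLatents(truth)
  expect_true(all(lat$IC_1 == 1.5))
  expect_true(all(lat$IC_2 == -2))
  # fixed seed reproduces everything
  lat2 <- simulateLatents(truth)
  expect_identical(lat, lat2)
})

test_that("latent variance follows the law of total variance", {
  truth <- syntheticTruth(
    n_participants = 300, days_per_participant = 28, q = 1,
    A = defaultMixingMatrix(q = 1), beta0 = 0,
    beta1 = matrix(c(0.3, 0, 0, 0, 0, -0.2, 0, 0), 1, 8),
    sigma1_sq = 0.3, sigma2_sq = 0.2, sigma_sq = 0.5,
    dist = "gaussian", seed = 5
  )
  lat <- simulateLatents(truth)
  want <- 0.3 + 0.2 + 0.5 + 0.3^2 + 0.2^2
  expect_lt(abs(var(lat$IC_1) - want) / want, 0.10)
  # same check under the heavy-tailed family (variance-matched)
  lat_l <- simulateLatents(truth, dist = "laplace", seed = 6)
  expect_lt(abs(var(lat_l$IC_1) - want) / want, 0.10)
})

test_that("self-report generation: exact inverse without noise, range with", {
  cat3 <- data.frame(item = c("i1", "i2", "i3"), scale = "Misc",
                     scale_max = 1000, base_log = 0)
  truth <- syntheticTruth(
    n_participants = 3, days_per_participant = 5, q = 3, catalogue = cat3,
    A = diag(3), beta0 = rep(2, 3), beta1 = matrix(0, 3, 8),
    sigma1_sq = rep(0.1, 3), sigma2_sq = rep(0.1, 3), sigma_sq = rep(0.2, 3),
    item_noise_sd = 0, dist = "gaussian", seed = 2
  )
  lat <- simulateLatents(truth)
  panel <- simulateSelfreport(truth, lat, discretize = FALSE)
  expect_equal(as.matrix(panel[c("i1", "i2", "i3")]),
               exp(as.matrix(lat[paste0("IC_", 1:3)])), ignore_attr = TRUE)

  # discretized outputs live in the declared range
  tt <- smallTruth()
  b <- simulateStudy(tt)
  items <- tt$catalogue$item
  vals <- as.matrix(b$selfreport[items])
  expect_true(all(vals >= 1))
  expect_true(all(vals <= rep(tt$catalogue$scale_max, each = nrow(vals))))
  expect_true(all(vals == floor(vals)))
})

test_that("keystroke round trip: rates, volume filter, median IKD", {
  plan <- data.frame(
    participant_id = "p1", date = as.Date("2023-04-01") + 0:1,
    n_sessions = 5L, volume = c(1000L, 500L),
    ikd_median = 0.3, ikd_sdlog = 0.4,
    autocorrect_rate = 0.05, backspace_rate = 0.2
  )
  ks <- simulateKeystrokes(plan, seed = 3)
  daily <- keyboardDailyFeatures(ks$events)
  d1 <- daily[daily$date == plan$date[1], ]
  # planted backspace rate recovered within 0.02 at volume 1000
  expect_lt(abs(d1$backspace_rate - 0.2), 0.02)
  expect_lt(abs(d1$autocorrect_rate - 0.05), 0.02)
  # volume targets met and the 750 filter applies to the 500-press day
  expect_equal(d1$total_keypresses, 1000L)
  d2 <- daily[daily$date == plan$date[2], ]
  expect_equal(d2$total_keypresses, 500L)
  expect_false(d2$included)
  expect_true(d1$included)
  # median IKD within 10% of target on the included day
  expect_lt(abs(d1$median_ikd - 0.3) / 0.3, 0.10)
  # no simulated gap may reach the 6 s session rule
  expect_equal(max(daily$n_sessions), 5L)
})

test_that("accelerometer round trip: planted labels recovered exactly", {
  sess <- data.frame(
    participant_id = "p1", date = as.Date("2023-04-01"),
    session_index = 1:10, start = 0, duration = 20, size = 60L,
    active = rep(c(TRUE, FALSE), c(4, 6)),
    upright = rep(c(TRUE, FALSE), c(7, 3))
  )
  acc <- simulateAccelerometer(sess, seed = 4)
  lab <- labelAccelSessions(acc)
  lab <- lab[order(lab$session_index), ]
  expect_equal(lab$is_active, sess$active)
  expect_equal(lab$is_upright, sess$upright)
  daily <- aggregateDailyAccel(lab)
  expect_equal(daily$movement_rate, 0.4)
  expect_equal(daily$upright_rate, 0.7)
  # planted flat session stays stationary: magnitudes hug 1 g
  flat <- acc[acc$session_index == 10, ]
  m <- sqrt(flat$x^2 + flat$y^2 + flat$z^2)
  expect_true(all(abs(m - 1) < 0.05))
})

test_that("study bundles are deterministic and complete without missingness", {
  tt0 <- syntheticTruth(n_participants = 4, days_per_participant = 9,
                        missingness = c(keyboard = 0, accel = 0,
                                        selfreport = 0), seed = 77)
  b1 <- simulateStudy(tt0)
  b2 <- simulateStudy(tt0)
  expect_identical(b1$keypresses, b2$keypresses)
  expect_identical(b1$accel, b2$accel)
  expect_identical(b1$selfreport, b2$selfreport)
  # complete panel: one self-report row per participant-day
  expect_equal(nrow(b1$selfreport), 4 * 9)
  # every planned day typed
  kb <- keyboardDailyFeatures(b1$keypresses)
  expect_equal(nrow(kb), 4 * 9)
})

test_that("missingness drops days per modality at roughly the configured rates", {
  tt <- syntheticTruth(n_participants = 12, days_per_participant = 30,
                       missingness = c(keyboard = 0.2, accel = 0.05,
                                       selfreport = 0.1), seed = 9)
  b <- simulateStudy(tt)
  n_days <- 12 * 30
  kb_days <- nrow(unique(b$keypresses[, c("participant_id", "date")]))
  sr_days <- nrow(b$selfreport)
  expect_lt(abs(kb_days / n_days - 0.8), 0.08)
  expect_lt(abs(sr_days / n_days - 0.9), 0.08)
  # accel days are a subset of keyboard days
  ackey <- unique(paste(b$accel$participant_id, b$accel$date))
  kbkey <- unique(paste(b$keypresses$participant_id, b$keypresses$date))
  expect_true(all(ackey %in% kbkey))
})

test_that("ground truth records the realized standardization and latents", {
  tt <- smallTruth()
  b <- simulateStudy(tt)
  expect_named(b$truth$standardization, c("center", "scale"))
  expect_true(all(paste0("IC_", 1:5) %in% names(b$truth$latents)))
  # aligned days all have self-report rows and included keyboard days
  srkey <- paste(b$selfreport$participant_id, b$selfreport$date)
  expect_true(all(b$truth$aligned_days %in% srkey))
  rf <- b$truth$realized_features
  expect_true(all(rf$included))
})

test_that("refit ICA on a generated panel recovers the true mixing structure", {
  tt <- syntheticTruth(n_participants = 55, days_per_participant = 33,
                       missingness = c(keyboard = 0, accel = 0,
                                       selfreport = 0), seed = 15)
  b <- simulateStudy(tt)
  cp <- preparePanel(b$selfreport)
  dec <- fitICA(cp, q = 5, seed = 2)
  m <- matchComponents(mixingMatrix(dec), tt$A)
  expect_gte(min(m$correlation), 0.9)  # despite Likert discretization
})
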