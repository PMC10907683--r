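# Fusion module: alignment, identifiability, nested mixed-effects fits,
# forwards-fitting, Bonferroni correction, diagnostics.

alignedFixture <- function(seed = 1, n_part = 20, weeks = 4, days = 4) {
  truth <- fusionTruth(seed = seed)
  d <- fusionDataset(truth, n_part, weeks, days, seed = seed)
  d
}

test_that("alignment keeps complete cases and assigns 7-day-block weeks", {
  kb <- data.frame(
    participant_id = "p1", date = as.Date("2023-01-01") + c(0, 3, 9, 12),
    median_ikd = 0.25, p95_ikd = 0.5, mad_ikd = 0.1,
    autocorrect_rate = 0.05, backspace_rate = 0.08,
    total_keypresses = 1000L, n_sessions = 5L, included = TRUE
  )
  ac <- data.frame(
    participant_id = "p1", date = as.Date("2023-01-01") + c(0, 3, 9, 20),
    movement_rate = 0.4, upright_rate = 0.6, n_sessions = 5L
  )
  src <- data.frame(
    participant_id = "p1", date = as.Date("2023-01-01") + c(0, 3, 9),
    IC_1 = c(0.1, -0.2, 0.3)
  )
  al <- alignModalities(kb, ac, src)
  # day 12: no self-report; day 20: no keyboard -> both excluded
  expect_equal(nrow(al), 3L)
  expect_equal(al$week, c(1L, 1L, 2L))
  expect_equal(al$day_of_week, c(1L, 4L, 3L))

  # excluded keyboard day drops out
  kb2 <- kb; kb2$included[1] <- FALSE
  expect_equal(nrow(alignModalities(kb2, ac, src)), 2L)

  # disjoint participants: explicit empty-dataset error with counts
  ac2 <- ac; ac2$participant_id <- "p9"
  expect_error(alignModalities(kb, ac2, src), "no complete participant-days")
})

test_that("week identifiability: drop-week vs drop-participant policies", {
  d <- data.frame(
    participant_id = rep(c("a", "b"), c(5, 2)),
    week = c(1L, 1L, 1L, 2L, 3L, 1L, 2L),
    y = rnorm(7)
  )
  # participant a: weeks 2 and 3 are singletons; participant b: both singleton
  dw <- enforceWeekIdentifiability(d, policy = "drop-week")
  expect_equal(nrow(dw$data), 3L)
  expect_true(all(dw$data$participant_id == "a"))
  expect_equal(nrow(dw$exclusions), 4L)
  dp <- enforceWeekIdentifiability(d, policy = "drop-participant")
  expect_equal(nrow(dp$data), 0L)
  # compliant data pass through unchanged
  d2 <- data.frame(participant_id = "a", week = rep(1:2, each = 2),
                   y = rnorm(4))
  expect_equal(nrow(enforceWeekIdentifiability(d2)$data), 4L)
  expect_equal(nrow(enforceWeekIdentifiability(d2)$exclusions), 0L)
})

test_that("component model recovers known parameters on generated data", {
  truth <- fusionTruth(seed = 3)
  d <- fusionDataset(truth, n_part = 60, weeks = 8, days = 5, seed = 3)
  fit <- fitComponentModel(d, "IC_1")
  expect_true(fit$converged)
  beta_true <- c(truth$beta0, as.numeric(truth$beta1))
  est <- fit$coefficients
  expect_equal(est$term, c("(Intercept)", colnames(truth$beta1)))
  # each estimate within 3 estimated standard errors of truth
  expect_true(all(abs(est$estimate - beta_true) <= 3 * est$se))
  # variance components in the right neighbourhood
  expect_lt(abs(fit$sigma1_sq - 0.25), 0.15)
  expect_lt(abs(fit$sigma2_sq - 0.16), 0.10)
  expect_lt(abs(fit$sigma_sq - 0.5), 0.10)
})

test_that("variance estimates shrink to the boundary when truth is zero", {
  truth <- fusionTruth(sigma1_sq = 0, sigma2_sq = 0, seed = 5)
  d <- fusionDataset(truth, n_part = 60, weeks = 8, days = 5, seed = 5)
  fit <- suppressMessages(fitComponentModel(d, "IC_1"))
  expect_lt(fit$sigma1_sq, 0.02)
  expect_lt(fit$sigma2_sq, 0.02)
})

test_that("precondition violations and missing columns are rejected", {
  d <- alignedFixture()
  d1 <- d[!(d$participant_id == "P001" & d$week == 1 &
              d$day_of_week > 1), ]
  expect_error(fitComponentModel(d1, "IC_1"), "fewer than 2")
  expect_error(fitComponentModel(d[, -3], "IC_9"), "missing columns")
})

test_that("rescaling a raw feature before standardization leaves fits identical", {
  d <- alignedFixture(seed = 11)
  feats <- phenofuse:::FUSION_FEATURES
  # two raw tables differing by a feature rescaling
  raw1 <- d
  raw1$total_keypresses <- exp(raw1$total_keypresses + 7)  # positive for log
  raw2 <- raw1
  raw2$median_ikd <- raw2$median_ikd * 1000
  s1 <- standardizeFeatures(raw1, features = feats)
  s2 <- standardizeFeatures(raw2, features = feats)
  f1 <- fitComponentModel(s1$data, "IC_1")
  f2 <- fitComponentModel(s2$data, "IC_1")
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-8)
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-8)
})

test_that("Bonferroni correction: CF arithmetic, cap, input validation", {
  expect_equal(bonferroniCorrect(0.001, n_ic = 5, n_fixed = 8), 0.04)
  expect_equal(bonferroniCorrect(0.5, n_ic = 5, n_fixed = 8), 1.0)
  expect_equal(bonferroniCorrect(0, n_ic = 5, n_fixed = 8), 0)
  expect_equal(bonferroniCorrect(c(0.01, 0.3), n_ic = 2, n_fixed = 8),
               c(0.16, 1.0))
  expect_error(bonferroniCorrect(1.2, 5), "\\[0, 1\\]")
  expect_error(bonferroniCorrect(-0.1, 5), "\\[0, 1\\]")
})

test_that("forwards-fitting keeps a strongly supported week term", {
  truth <- fusionTruth(sigma2_sq = 0.3, seed = 21)
  d <- fusionDataset(truth, n_part = 30, weeks = 4, days = 3, seed = 21)
  ff <- forwardFitRandomEffects(d, "IC_1")
  expect_equal(ff$table$term,
               c("fixed effects only", "participant intercept",
                 "week-within-participant intercept"))
  expect_true(all(ff$table$kept))
  expect_true(all(ff$table$p[-1] < 0.05))
  expect_true(all(diff(ff$table$logLik) >= 0))
  expect_s3_class(ff$final, "ComponentModelFit")
})

test_that("forwards-fitting power and boundary type-I behaviour", {
  # strong week effect: detected in >= 95% of 50 simulations
  truth_alt <- fusionTruth(sigma2_sq = 0.3, seed = 1)
  p_alt <- vapply(1:50, function(r) {
    d <- fusionDataset(truth_alt, n_part = 30, weeks = 4, days = 3, seed = r)
    ff <- suppressWarnings(forwardFitRandomEffects(d, "IC_1"))
    ff$table$p[ff$table$term == "week-within-participant intercept"]
  }, numeric(1))
  expect_gte(mean(p_alt < 0.05), 0.95)

  # no week effect: boundary-conservative 1-df chi-square rejects <= 10%
  truth_null <- fusionTruth(sigma2_sq = 0, seed = 2)
  p_null <- vapply(1:100, function(r) {
    d <- fusionDataset(truth_null, n_part = 30, weeks = 4, days = 3,
                       seed = 1000 + r)
    ff <- suppressMessages(forwardFitRandomEffects(d, "IC_1"))
    ff$table$p[ff$table$term == "week-within-participant intercept"]
  }, numeric(1))
  expect_lte(mean(p_null < 0.05), 0.10)
})

test_that("permuting the response within participant-weeks destroys a planted effect", {
  # movement_rate is the 7th feature
  truth <- fusionTruth(beta1 = c(0, 0, 0, 0, 0, 0, -0.3, 0), seed = 31)
  d <- fusionDataset(truth, n_part = 60, weeks = 8, days = 5, seed = 31)
  fit <- fitComponentModel(d, "IC_1")
  b_mov <- fit$coefficients$estimate[fit$coefficients$term == "movement_rate"]
  set.seed(99)
  perms <- vapply(1:11, function(r) {
    dp <- d
    grp <- paste(dp$participant_id, dp$week)
    dp$IC_1 <- ave(d$IC_1, grp, FUN = sample)  # permute y within each cell
    fp <- fitComponentModel(dp, "IC_1")
    fp$coefficients$estimate[fp$coefficients$term == "movement_rate"]
  }, numeric(1))
  expect_gte(abs(b_mov) / median(abs(perms)), 5)
})

test_that("model diagnostics report residual and random-effect tables", {
  truth <- fusionTruth(seed = 41)
  d <- fusionDataset(truth, n_part = 30, weeks = 4, days = 4, seed = 41)
  fit <- fitComponentModel(d, "IC_1")
  diag <- modelDiagnostics(fit)
  expect_equal(nrow(diag$residual_vs_fitted), nrow(d))
  expect_equal(nrow(diag$residual_qq), nrow(d))
  expect_equal(names(diag$ranef_qq),
               c("participant_id:week", "participant_id"))
  # Gaussian residuals from a well-specified fit: normality not rejected hard
  w_res <- diag$normality$p[diag$normality$set == "residuals"]
  expect_gt(w_res, 0.001)

  # planted heavy-tailed residuals are flagged
  d2 <- d
  set.seed(5)
  d2$IC_1 <- d2$IC_1 + rt(nrow(d2), df = 2) * 0.8
  fit2 <- fitComponentModel(d2, "IC_1")
  diag2 <- modelDiagnostics(fit2)
  expect_lt(diag2$normality$p[diag2$normality$set == "residuals"], 0.001)
})

test_that("family of component models shares one correction factor", {
  truth <- syntheticTruth(
    n_participants = 25, days_per_participant = 21, q = 3,
    A = defaultMixingMatrix(q = 3),
    beta1 = matrix(0, 3, 8, dimnames = list(paste0("IC_", 1:3),
                                            phenofuse:::FUSION_FEATURES)),
    beta0 = rep(0, 3), sigma1_sq = rep(0.2, 3), sigma2_sq = rep(0.1, 3),
    sigma_sq = rep(0.6, 3), dist = "gaussian", seed = 51
  )
  d <- simulateLatents(truth, index = studyGrid(25, 3, 4), seed = 51)
  all_fits <- fitAllComponentModels(d)
  expect_equal(all_fits$correction$CF, 24L)
  expect_equal(length(all_fits$fits), 3L)
  est <- all_fits$estimates
  fixed <- est[est$term != "(Intercept)", ]
  expect_equal(fixed$p_corrected, pmin(1, 24 * fixed$p_uncorrected))
  expect_true(all(is.na(est$p_corrected[est$term == "(Intercept)"])))
})
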