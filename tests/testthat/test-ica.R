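# Temporal ICA: panel preparation, FastICA fitting, canonicalization,
# restart stability, within-participant centring, offset correlation.

makePanel <- function(n_participants = 2, n_days = 3, items = c("a", "b", "c"),
                      seed = 1) {
  set.seed(seed)
  g <- expand.grid(date = as.Date("2023-01-01") + seq_len(n_days) - 1,
                   participant_id = sprintf("p%d", seq_len(n_participants)))
  out <- data.frame(participant_id = g$participant_id, date = g$date)
  for (it in items) out[[it]] <- sample(1:6, nrow(g), replace = TRUE)
  out
}

test_that("preparePanel: log transform, concatenation, complete-row rule", {
  panel <- makePanel()
  panel$a[1] <- 1
  cp <- preparePanel(panel)
  X <- SummarizedExperiment::assay(cp, "logvalues")
  expect_equal(dim(X), c(3L, 6L))
  expect_equal(unname(X["a", 1]), 0)  # log(1) = 0
  expect_equal(as.matrix(X), unname(t(log(as.matrix(panel[c("a", "b", "c")])))),
               ignore_attr = TRUE)
  cd <- SummarizedExperiment::colData(cp)
  expect_equal(length(cd$participant_id), 6L)
  # columns ordered by participant then date
  expect_equal(order(cd$participant_id, cd$date), seq_len(6))

  # a day missing one item is dropped entirely
  panel$b[4] <- NA
  expect_equal(ncol(preparePanel(panel)), 5L)

  # located error for non-positive values
  panel$c[2] <- 0
  expect_error(preparePanel(panel), "participant p1.*item c")

  # duplicate participant-days forbidden
  dup <- rbind(makePanel(), makePanel()[1, ])
  expect_error(preparePanel(dup), "duplicate")
})

test_that("q = p decomposition reconstructs the panel without error", {
  set.seed(3)
  A <- matrix(rnorm(25), 5, 5)
  S <- matrix(rexp(5 * 400) - rexp(5 * 400), 5, 400)
  X <- 2 + A %*% S
  d <- suppressWarnings(fitICA(X, q = 5, seed = 1))
  expect_lt(icaMeta(d)$residual_norm, 1e-8)
  expect_lt(max(abs(reconstruct(d) - X)), 1e-8)
  expect_lt(max(abs(residualMatrix(d))), 1e-8)
})

test_that("mixing-matrix recovery on a noisy Laplace mixture", {
  fx <- laplaceMixture(p = 10, q = 3, n = 2000, noise_sd = 0.1, seed = 21)
  d <- fitICA(fx$X, q = 3, seed = 2)
  m <- matchComponents(mixingMatrix(d), fx$A)
  expect_true(all(m$correlation >= 0.95))
  expect_equal(sort(m$perm), 1:3)  # a permutation, every component matched
})

test_that("purely Gaussian input still returns, with diagnostics", {
  set.seed(8)
  X <- matrix(rnorm(6 * 500), 6, 500)
  d <- suppressWarnings(fitICA(X, q = 3, seed = 1, max_iter = 30))
  expect_s4_class(d, "ICADecomposition")
  expect_true(is.logical(icaMeta(d)$converged))
  expect_true(icaMeta(d)$iterations >= 1)
})

test_that("fitICA validates q and rank", {
  X <- matrix(rnorm(4 * 100), 4, 100)
  expect_error(suppressWarnings(fitICA(X, q = 5)), "q must be")
  expect_error(suppressWarnings(fitICA(X, q = 0)), "q must be")
  Xr <- rbind(X[1, ], X[1, ], X[2, ])  # rank 2
  expect_error(suppressWarnings(fitICA(Xr, q = 3)), "rank deficient")
})

test_that("canonicalization: idempotent, sign/order invariant, product preserved", {
  fx <- laplaceMixture(p = 8, q = 3, n = 800, noise_sd = 0.05, seed = 5)
  d <- suppressWarnings(fitICA(fx$X, q = 3, seed = 1, canonical = FALSE))
  c1 <- canonicalize(d)
  # sources have unit sample variance; dominant loading positive; ordered
  expect_equal(unname(apply(icaSources(c1), 1, var)), rep(1, 3))
  for (k in 1:3) {
    col <- mixingMatrix(c1)[, k]
    expect_gt(col[which.max(abs(col))], 0)
  }
  expect_true(all(diff(colSums(mixingMatrix(c1)^2)) <= 1e-10))
  # product unchanged
  expect_lt(max(abs(mixingMatrix(c1) %*% icaSources(c1) -
                    mixingMatrix(d) %*% icaSources(d))), 1e-10)
  # idempotence
  c2 <- canonicalize(c1)
  expect_equal(mixingMatrix(c2), mixingMatrix(c1))
  expect_equal(icaSources(c2), icaSources(c1))
  # flipping a component's sign or permuting components changes nothing
  flipped <- d
  flipped@A[, 2] <- -flipped@A[, 2]
  flipped@S[2, ] <- -flipped@S[2, ]
  expect_equal(mixingMatrix(canonicalize(flipped)), mixingMatrix(c1))
  perm <- d
  perm@A <- perm@A[, c(2, 3, 1)]
  perm@S <- perm@S[c(2, 3, 1), ]
  expect_equal(unname(mixingMatrix(canonicalize(perm))),
               unname(mixingMatrix(c1)))
})

test_that("identical inputs and seed reproduce the decomposition", {
  fx <- laplaceMixture(p = 6, q = 2, n = 600, noise_sd = 0.1, seed = 9)
  d1 <- suppressWarnings(fitICA(fx$X, q = 2, seed = 33))
  d2 <- suppressWarnings(fitICA(fx$X, q = 2, seed = 33))
  expect_lt(max(abs(mixingMatrix(d1) - mixingMatrix(d2))), 1e-8)
})

test_that("residual norm is non-increasing in the component count", {
  fx <- laplaceMixture(p = 6, q = 6, n = 1200, noise_sd = 0.2, seed = 13)
  norms <- vapply(2:6, function(q) {
    suppressWarnings(icaMeta(fitICA(fx$X, q = q, seed = 1))$residual_norm)
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-6))
})

test_that("restart stability: determinism, pooling bound, separated sources", {
  fx <- laplaceMixture(p = 9, q = 3, n = 1200, noise_sd = 0.1, seed = 31)
  # identical seeds give identical canonical components
  d1 <- fitICA(fx$X, q = 3, seed = 50)
  d2 <- fitICA(fx$X, q = 3, seed = 50)
  expect_equal(unname(abs(diag(cor(mixingMatrix(d1), mixingMatrix(d2))))), rep(1, 3),
               tolerance = 1e-10)

  rep10 <- restartStability(fx$X, q = 3, R = 10, base_seed = 1)
  expect_lte(length(unique(rep10@clusters)), 10 * 3)
  expect_true(all(rep10@similarity >= 0) && all(rep10@similarity <= 1 + 1e-12))
  # three dominant clusters, each hit by >= 9 of 10 restarts, matching truth
  counts <- sort(table(rep10@clusters), decreasing = TRUE)
  expect_gte(sum(counts[1:3] >= 9), 3)
  top <- names(counts)[1:3]
  for (cl in top) {
    idx <- which(rep10@clusters == as.integer(cl))
    centroid <- rep10@components[, idx[1]]
    best <- max(abs(cor(centroid, fx$A)))
    expect_gte(best, 0.9)
  }
})

test_that("within-participant centring removes participant means, idempotently", {
  panel <- makePanel(n_participants = 3, n_days = 5, seed = 2)
  cp <- preparePanel(panel)
  cc <- centerWithinParticipant(cp)
  X <- SummarizedExperiment::assay(cc, "logvalues")
  pid <- SummarizedExperiment::colData(cc)$participant_id
  for (p in unique(pid)) {
    expect_lt(max(abs(rowSums(X[, pid == p]))), 1e-12)
  }
  cc2 <- centerWithinParticipant(cc)
  expect_equal(SummarizedExperiment::assay(cc2), X)
  # single-day participant becomes all zeros
  m <- matrix(c(1, 2), 2, 1)
  expect_equal(centerWithinParticipant(m, "p1"), matrix(0, 2, 1))
})

test_that("component-offset correlation finds planted participant offsets", {
  # plant a pure offset component: participants differ only in their mean level
  set.seed(17)
  n_part <- 12; n_days <- 30
  offs <- rnorm(n_part, sd = 1)
  grid <- expand.grid(day = seq_len(n_days), p = seq_len(n_part))
  y_off <- offs[grid$p] + rnorm(nrow(grid), sd = 0.1)
  y_ind <- rexp(nrow(grid)) - rexp(nrow(grid))
  A <- cbind(c(1, 1, 1, 1), c(1, -1, 1, -1))
  X <- A %*% rbind(y_off, y_ind) + 3 +
    matrix(rnorm(4 * nrow(grid), sd = 0.05), 4)
  panel <- data.frame(
    participant_id = sprintf("p%02d", grid$p),
    date = as.Date("2023-01-01") + grid$day,
    exp(t(X))
  )
  cp <- preparePanel(panel)
  dec <- fitICA(cp, q = 2, seed = 3)
  cors <- componentOffsetCorrelation(dec, cp)
  expect_gte(max(abs(cors)), 0.9)  # the offset component is visible
  k <- which.max(abs(cors))
  # sign-flipping the component negates the correlation
  flip <- dec
  flip@S[k, ] <- -flip@S[k, ]
  expect_equal(unname(componentOffsetCorrelation(flip, cp)[k]),
               -unname(cors[k]))
  # after within-participant centring no component tracks the offsets
  # refit on the centred panel: no component may track the original offsets
  dec_c <- fitICA(centerWithinParticipant(cp), q = 2, seed = 3)
  cors_c <- componentOffsetCorrelation(dec_c, cp)
  expect_lt(max(abs(cors_c)), 0.5)
})

test_that("offset correlation requires at least 3 participants", {
  panel <- makePanel(n_participants = 2, n_days = 4)
  cp <- preparePanel(panel)
  dec <- suppressWarnings(fitICA(cp, q = 2, seed = 1, max_iter = 20))
  expect_error(componentOffsetCorrelation(dec, cp), "3 participants")
})
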