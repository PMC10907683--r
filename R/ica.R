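# Temporal independent component analysis of the daily self-report panel.
#
# The panel (strictly positive Likert items) is log-transformed and the
# participants' day series are concatenated along the time axis, giving a
# p-items x n-days matrix X. FastICA (symmetric/parallel variant, logcosh
# contrast with a1 = 1) decomposes X = center + A S + epsilon: A is the
# time-free mixing matrix read as item loadings, S holds component time
# courses that stay on the daily time axis and can therefore be aligned with
# the passive features. When q = p the residual epsilon vanishes.

#' Prepare a self-report panel for temporal ICA
#'
#' Validates the panel (strictly positive Likert values, unique
#' participant-days), drops days with any missing item (complete-row rule; no
#' imputation), applies the natural log elementwise and concatenates
#' participant blocks along the time axis in participant order, then date
#' order.
#'
#' @param panel data.frame with `participant_id`, `date` and one column per
#'   Likert item (strictly positive integers or numerics).
#' @param items character vector naming the item columns (default: all columns
#'   except `participant_id`/`date`).
#' @param catalogue optional data.frame mapping `item` to `scale`
#'   (questionnaire of origin), stored in `rowData`.
#' @return a [ConcatenatedPanel].
#' @export
preparePanel <- function(panel, items = NULL, catalogue = NULL) {
  panel <- as.data.frame(panel)
  if (!all(c("participant_id", "date") %in% names(panel))) {
    stop("panel must have 'participant_id' and 'date' columns")
  }
  if (is.null(items)) items <- setdiff(names(panel), c("participant_id", "date"))
  if (length(items) == 0L) stop("panel has no item columns")
  panel$date <- asDate(panel$date)
  key <- paste(panel$participant_id, panel$date)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("duplicate (participant_id, date) rows in panel: ", dup)
  }
  vals <- as.matrix(panel[items])
  nonpos <- which(is.finite(vals) & vals <= 0, arr.ind = TRUE)
  if (nrow(nonpos)) {
    r <- nonpos[1L, 1L]; c <- nonpos[1L, 2L]
    stop(sprintf(
      "non-positive self-report value (participant %s, date %s, item %s): log undefined",
      panel$participant_id[r], panel$date[r], items[c]
    ))
  }
  keep <- stats::complete.cases(vals)
  panel <- panel[keep, , drop = FALSE]
  vals <- vals[keep, , drop = FALSE]
  ord <- order(panel$participant_id, panel$date)
  panel <- panel[ord, , drop = FALSE]
  vals <- vals[ord, , drop = FALSE]
  X <- t(log(vals))
  rownames(X) <- items
  cd <- S4Vectors::DataFrame(
    participant_id = panel$participant_id, date = panel$date
  )
  rd <- S4Vectors::DataFrame(item = items)
  if (!is.null(catalogue)) {
    rd$scale <- catalogue$scale[match(items, catalogue$item)]
  }
  new("ConcatenatedPanel", SummarizedExperiment::SummarizedExperiment(
    assays = list(logvalues = X), colData = cd, rowData = rd
  ))
}

# Extract the numeric matrix + index from ConcatenatedPanel or plain matrix.
panelMatrix <- function(x) {
  if (is(x, "ConcatenatedPanel")) {
    list(
      X = SummarizedExperiment::assay(x, "logvalues"),
      index = SummarizedExperiment::colData(x)[, c("participant_id", "date")]
    )
  } else if (is.matrix(x)) {
    list(X = x, index = S4Vectors::DataFrame(
      participant_id = rep(NA_character_, ncol(x)),
      date = rep(as.Date(NA), ncol(x))
    ))
  } else {
    stop("x must be a ConcatenatedPanel or a numeric matrix (items x days)")
  }
}

# Symmetric orthogonalization W <- (W W^T)^{-1/2} W.
symDecorrelate <- function(W) {
  e <- eigen(tcrossprod(W), symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(e$values), nrow = length(e$values)) %*%
    t(e$vectors) %*% W
}

#' Fit a temporal ICA with symmetric FastICA (logcosh contrast)
#'
#' Rows of `X` (items) are centered, whitened by PCA to `q` dimensions, and
#' unmixed with the parallel (symmetric) FastICA fixed-point iteration using
#' the logcosh contrast \eqn{G(u) = \log\cosh(a_1 u)/a_1} with `a1 = 1`.
#' Non-convergence within `max_iter` iterations is reported in the metadata,
#' never hidden. The returned decomposition satisfies
#' `X = center + A S + epsilon` with `epsilon = 0` (numerically) when `q`
#' equals the number of items.
#'
#' @param x a [ConcatenatedPanel] or a numeric items-by-days matrix.
#' @param q number of components, `1 <= q <= min(p, n)`.
#' @param seed integer seed for the random initial unmixing matrix.
#' @param tol convergence tolerance on the fixed-point update (default 1e-4).
#' @param max_iter maximum fixed-point iterations (default 200).
#' @param a1 logcosh contrast parameter (default 1).
#' @param canonical canonicalize the result (default `TRUE`); see
#'   [canonicalize()].
#' @return an [ICADecomposition].
#' @export
fitICA <- function(x, q, seed = 1, tol = 1e-4, max_iter = 200, a1 = 1,
                   canonical = TRUE) {
  pm <- panelMatrix(x)
  X <- pm$X
  p <- nrow(X); n <- ncol(X)
  if (!is.numeric(q) || length(q) != 1L || q < 1 || q > min(p, n)) {
    stop(sprintf("q must be in [1, min(p, n)] = [1, %d]", min(p, n)))
  }
  q <- as.integer(q)
  if (n < 3 * p) {
    warning(sprintf(
      "only %d days for %d items; ICA estimates may be unstable", n, p
    ))
  }
  center <- rowMeans(X)
  Xc <- X - center
  # PCA whitening to q dimensions
  covX <- tcrossprod(Xc) / (n - 1)
  e <- eigen(covX, symmetric = TRUE)
  if (e$values[q] <= max(e$values[1L], 0) * 1e-12) {
    stop(sprintf(
      "data are rank deficient for q = %d (eigenvalue %d is numerically zero)",
      q, q
    ))
  }
  K <- diag(1 / sqrt(e$values[seq_len(q)]), nrow = q) %*%
    t(e$vectors[, seq_len(q), drop = FALSE])
  Z <- K %*% Xc
  W <- withSeed(seed, matrix(stats::rnorm(q * q), q, q))
  W <- symDecorrelate(W)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    U <- W %*% Z
    gU <- tanh(a1 * U)
    g1 <- a1 * (1 - gU^2)
    W1 <- (gU %*% t(Z)) / n - diag(rowMeans(g1), nrow = q) %*% W
    W1 <- symDecorrelate(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  S <- W %*% Z
  # least-squares mixing matrix; rows of S are uncorrelated with ~unit variance
  A <- tcrossprod(Xc, S) %*% solve(tcrossprod(S))
  rownames(A) <- rownames(X)
  colnames(A) <- paste0("IC_", seq_len(q))
  rownames(S) <- colnames(A)
  eps <- Xc - A %*% S
  res_norm <- sqrt(sum(eps^2))
  dec <- new("ICADecomposition",
    A = A, S = S, epsilon = eps, center = center,
    index = S4Vectors::DataFrame(pm$index),
    meta = list(
      q = q, seed = seed, fun = "logcosh", a1 = a1, tol = tol,
      max_iter = max_iter, iterations = iter, converged = converged,
      canonical = FALSE, residual_norm = res_norm
    )
  )
  if (canonical) canonicalize(dec) else dec
}

#' @rdname ICADecomposition-accessors
#' @aliases mixingMatrix icaSources residualMatrix nComponents indexMap icaMeta
#' @export
setMethod("mixingMatrix", "ICADecomposition", function(object) object@A)

#' @rdname ICADecomposition-accessors
#' @export
setMethod("icaSources", "ICADecomposition", function(object) object@S)

#' @rdname ICADecomposition-accessors
#' @export
setMethod("nComponents", "ICADecomposition", function(object) ncol(object@A))

#' @rdname ICADecomposition-accessors
#' @export
setMethod("indexMap", "ICADecomposition", function(object) object@index)

#' @rdname ICADecomposition-accessors
#' @export
setMethod("icaMeta", "ICADecomposition", function(object) object@meta)

#' @export
setMethod("reconstruct", "ICADecomposition", function(object) {
  object@center + object@A %*% object@S
})

#' @rdname ICADecomposition-accessors
#' @export
setMethod("residualMatrix", "ICADecomposition", function(object) object@epsilon)

#' @export
setMethod("canonicalize", "ICADecomposition", function(object) {
  A <- object@A; S <- object@S
  q <- ncol(A)
  sds <- apply(S, 1L, stats::sd)
  if (any(sds == 0)) sds[sds == 0] <- 1
  A <- sweep(A, 2L, sds, `*`)
  S <- sweep(S, 1L, sds, `/`)
  for (k in seq_len(q)) {
    sgn <- sign(A[which.max(abs(A[, k])), k])
    if (sgn < 0) { A[, k] <- -A[, k]; S[k, ] <- -S[k, ] }
  }
  ord <- order(colSums(A^2), decreasing = TRUE)
  A <- A[, ord, drop = FALSE]
  S <- S[ord, , drop = FALSE]
  colnames(A) <- paste0("IC_", seq_len(q))
  rownames(S) <- colnames(A)
  meta <- object@meta
  meta$canonical <- TRUE
  new("ICADecomposition", A = A, S = S, epsilon = object@epsilon,
      center = object@center, index = object@index, meta = meta)
})

#' Stability of ICA solutions across FastICA restarts
#'
#' Runs `R` independent FastICA fits with distinct seeds, pools all canonical
#' mixing columns, and clusters them by average-linkage agglomeration on the
#' dissimilarity `1 - |cor|` at `cut_height`. Restarts that fail to converge
#' are recorded in the report and excluded from clustering, never silently
#' dropped. Tight clusters populated by (nearly) every restart indicate stable
#' components.
#'
#' @inheritParams fitICA
#' @param R number of restarts (>= 2).
#' @param base_seed seed of the first restart; restart r uses `base_seed + r - 1`.
#' @param cut_height dendrogram cut height on `1 - |cor|` (default 0.3).
#' @return a [StabilityReport].
#' @export
restartStability <- function(x, q, R = 10, base_seed = 1, cut_height = 0.3,
                             tol = 1e-4, max_iter = 200) {
  if (R < 2) stop("R must be at least 2")
  seeds <- base_seed + seq_len(R) - 1
  fits <- lapply(seeds, function(s) {
    fitICA(x, q, seed = s, tol = tol, max_iter = max_iter, canonical = TRUE)
  })
  conv <- vapply(fits, function(f) isTRUE(f@meta$converged), logical(1))
  failures <- data.frame(run = which(!conv), seed = seeds[!conv])
  pooled <- do.call(cbind, lapply(which(conv), function(r) {
    A <- mixingMatrix(fits[[r]])
    colnames(A) <- sprintf("run%d_IC%d", r, seq_len(ncol(A)))
    A
  }))
  runs <- do.call(rbind, lapply(which(conv), function(r) {
    data.frame(run = r, component = seq_len(q), seed = seeds[r])
  }))
  sim <- abs(stats::cor(pooled))
  hc <- stats::hclust(stats::as.dist(1 - sim), method = "average")
  clusters <- stats::cutree(hc, h = cut_height)
  tightness <- vapply(sort(unique(clusters)), function(cl) {
    idx <- which(clusters == cl)
    if (length(idx) == 1L) return(1)
    sub <- sim[idx, idx]
    mean(sub[upper.tri(sub)])
  }, numeric(1))
  names(tightness) <- paste0("cluster_", sort(unique(clusters)))
  new("StabilityReport",
    components = pooled, runs = runs, similarity = sim,
    clusters = as.integer(clusters), tightness = tightness,
    failures = failures,
    meta = list(R = R, q = q, cut_height = cut_height, base_seed = base_seed)
  )
}

#' Within-participant mean-centring
#'
#' Subtracts, for every participant and item, that participant's mean (of the
#' log values) — the supplementary variant that removes participant-level
#' offsets from the panel before refitting the ICA. Idempotent.
#'
#' @param x a [ConcatenatedPanel], or a numeric items-by-days matrix with a
#'   `participant` vector.
#' @param participant participant id per column (ignored for
#'   `ConcatenatedPanel`).
#' @return an object of the same type with centred values.
#' @export
centerWithinParticipant <- function(x, participant = NULL) {
  if (is(x, "ConcatenatedPanel")) {
    X <- SummarizedExperiment::assay(x, "logvalues")
    pid <- SummarizedExperiment::colData(x)$participant_id
    Xc <- centerWithinParticipant(X, pid)
    SummarizedExperiment::assay(x, "logvalues") <- Xc
    return(x)
  }
  if (is.null(participant) || length(participant) != ncol(x)) {
    stop("participant must be supplied, one id per column")
  }
  for (pid in unique(participant)) {
    idx <- participant == pid
    x[, idx] <- x[, idx, drop = FALSE] -
      rowMeans(x[, idx, drop = FALSE])
  }
  x
}

#' Correlation of a component with participant mean response levels
#'
#' Computes the Pearson correlation between per-participant mean responses
#' (mean of the log panel over items and days) and the per-participant mean of
#' one component's time course — the check used to identify an "offset"
#' component that merely tracks how high each participant rates everything.
#'
#' @param dec an [ICADecomposition] fitted to `x` (index map required).
#' @param x the [ConcatenatedPanel] the decomposition was fitted to.
#' @param component component index (default: every component).
#' @return named numeric vector of correlations.
#' @export
componentOffsetCorrelation <- function(dec, x, component = seq_len(nComponents(dec))) {
  stopifnot(is(dec, "ICADecomposition"), is(x, "ConcatenatedPanel"))
  X <- SummarizedExperiment::assay(x, "logvalues")
  pid <- as.character(SummarizedExperiment::colData(x)$participant_id)
  if (ncol(X) != ncol(icaSources(dec))) {
    stop("panel and decomposition have different numbers of days")
  }
  ids <- unique(pid)
  if (length(ids) < 3L) {
    stop("offset correlation is undefined with fewer than 3 participants")
  }
  day_means <- colMeans(X)
  part_means <- vapply(ids, function(i) mean(day_means[pid == i]), numeric(1))
  S <- icaSources(dec)
  out <- vapply(component, function(k) {
    sk <- vapply(ids, function(i) mean(S[k, pid == i]), numeric(1))
    stats::cor(part_means, sk)
  }, numeric(1))
  names(out) <- rownames(S)[component]
  out
}

#' Match estimated components to a reference mixing matrix
#'
#' Resolves permutation and sign indeterminacy when scoring recovery of a known
#' mixing matrix: finds the component pairing maximizing the summed absolute
#' column correlations (exhaustive over permutations for q <= 7, greedy
#' otherwise).
#'
#' @param A_est,A_ref mixing matrices with matching row order (items x q).
#' @return list with `perm` (reference column matched to each estimated
#'   column), `sign`, and `correlation` (matched absolute correlations, one per
#'   reference component).
#' @export
matchComponents <- function(A_est, A_ref) {
  q <- ncol(A_ref)
  stopifnot(ncol(A_est) == q, nrow(A_est) == nrow(A_ref))
  cmat <- stats::cor(A_ref, A_est)  # q_ref x q_est
  absc <- abs(cmat)
  if (q <= 7L) {
    perms <- permuteAll(q)
    scores <- vapply(perms, function(p) sum(absc[cbind(seq_len(q), p)]),
                     numeric(1))
    best <- perms[[which.max(scores)]]
  } else {
    best <- integer(q)
    taken <- rep(FALSE, q)
    for (k in order(apply(absc, 1L, max), decreasing = TRUE)) {
      j <- which.max(ifelse(taken, -Inf, absc[k, ]))
      best[k] <- j
      taken[j] <- TRUE
    }
  }
  list(
    perm = best,
    sign = sign(cmat[cbind(seq_len(q), best)]),
    correlation = absc[cbind(seq_len(q), best)]
  )
}

# All permutations of 1..n (n small).
permuteAll <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- permuteAll(n - 1L)
  out <- vector("list", n * length(sub))
  i <- 0L
  for (s in sub) {
    for (pos in seq_len(n)) {
      i <- i + 1L
      out[[i]] <- append(s, n, after = pos - 1L)
    }
  }
  out
}
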