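# Fusion of passive daily features with independent-component time courses.
#
# For each component k the model is
#   y_ijk = beta0 + b_i + b_ij + beta1' x_ijk + eps_ijk,
#   b_i ~ N(0, sigma1^2), b_ij ~ N(0, sigma2^2), eps_ijk ~ N(0, sigma^2),
# with i the participant, j the week within participant (7-day blocks from the
# participant's first retained day) and k the day within week. The eight fixed
# effects are the standardized daily features. p values from all component
# models are Bonferroni-corrected with CF = n_IC * n_fixed.

FUSION_FEATURES <- c(
  "median_ikd", "p95_ikd", "mad_ikd", "autocorrect_rate", "backspace_rate",
  "total_keypresses", "movement_rate", "upright_rate"
)

#' Align keyboard, accelerometer and component modalities on participant-days
#'
#' Inner-joins the three daily tables on (participant, date), keeping only
#' complete cases: days with volume-included keyboard features (all IKD
#' statistics defined), accelerometer rates, and component scores. Week indices
#' are 7-day blocks counted from each participant's first retained day
#' (`week = 1 + floor((date - first)/7)`), and `day_of_week` is the position
#' within that block.
#'
#' @param daily_keyboard output of [keyboardDailyFeatures()].
#' @param daily_accel output of [accelDailyFeatures()].
#' @param sources an [ICADecomposition] (its index map supplies the
#'   participant-days) or a data.frame `participant_id, date, IC_1..IC_q`.
#' @return `data.table` with identifiers `participant_id, date, week,
#'   day_of_week`, the raw (unstandardized) features, and the IC columns.
#' @export
alignModalities <- function(daily_keyboard, daily_accel, sources) {
  kb <- as.data.table(daily_keyboard)
  ac <- as.data.table(daily_accel)
  if (is(sources, "ICADecomposition")) {
    idx <- as.data.frame(indexMap(sources))
    S <- t(icaSources(sources))
    src <- data.table(participant_id = idx$participant_id,
                      date = asDate(idx$date))
    src <- cbind(src, as.data.table(S))
  } else {
    src <- as.data.table(sources)
  }
  ic_cols <- grep("^IC_", names(src), value = TRUE)
  if (!length(ic_cols)) stop("sources must contain IC_* columns")
  kb <- kb[included == TRUE & stats::complete.cases(
    kb[, c("median_ikd", "p95_ikd", "mad_ikd"), with = FALSE])]
  kb[, date := asDate(date)]
  ac[, date := asDate(date)]
  src[, date := asDate(date)]
  merged <- merge(
    kb[, c("participant_id", "date", FUSION_FEATURES[1:6]), with = FALSE],
    ac[, .(participant_id, date, movement_rate, upright_rate)],
    by = c("participant_id", "date")
  )
  merged <- merge(merged, src[, c("participant_id", "date", ic_cols),
                              with = FALSE],
                  by = c("participant_id", "date"))
  if (nrow(merged) == 0L) {
    stop(sprintf(
      paste0("no complete participant-days after alignment ",
             "(keyboard: %d days, accelerometer: %d days, components: %d days)"),
      nrow(kb), nrow(ac), nrow(src)
    ))
  }
  setorder(merged, participant_id, date)
  merged[, week := 1L + as.integer(floor(
    as.numeric(date - min(date)) / 7)), by = participant_id]
  merged[, day_of_week := as.integer(
    as.numeric(date - min(date)) %% 7) + 1L, by = participant_id]
  merged[]
}

#' Enforce identifiability of the week-within-participant random effect
#'
#' The nested random intercept b_ij needs at least `min_obs` observations per
#' participant-week. Under the default `"drop-week"` policy only the offending
#' weeks are removed (participants keep their compliant weeks); under
#' `"drop-participant"` any participant with at least one offending week is
#' removed entirely. Every exclusion is logged.
#'
#' @param data aligned rows from [alignModalities()].
#' @param policy `"drop-week"` (default) or `"drop-participant"`.
#' @param min_obs minimum rows per participant-week (default 2).
#' @return list with `data` (the filtered rows) and `exclusions` (a
#'   data.frame logging participant, week, rows removed, and the policy).
#' @export
enforceWeekIdentifiability <- function(data,
                                       policy = c("drop-week",
                                                  "drop-participant"),
                                       min_obs = 2L) {
  policy <- match.arg(policy)
  data <- as.data.table(data)
  counts <- data[, .N, by = .(participant_id, week)]
  bad <- counts[N < min_obs]
  if (nrow(bad) == 0L) {
    return(list(data = data[], exclusions = data.frame(
      participant_id = character(0), week = integer(0), rows_removed = integer(0),
      policy = character(0)
    )))
  }
  if (policy == "drop-week") {
    keep <- !data[, paste(participant_id, week)] %in%
      bad[, paste(participant_id, week)]
  } else {
    keep <- !data$participant_id %in% unique(bad$participant_id)
  }
  removed <- data[!keep, .N, by = .(participant_id, week)]
  exclusions <- data.frame(
    participant_id = removed$participant_id, week = removed$week,
    rows_removed = removed$N, policy = policy
  )
  list(data = data[keep][], exclusions = exclusions)
}

# Shared formula builder.
fusionFormula <- function(response, features, random = c("participant", "week")) {
  fixed <- paste(features, collapse = " + ")
  re <- c()
  if ("participant" %in% random) re <- c(re, "(1 | participant_id)")
  if ("week" %in% random) re <- c(re, "(1 | participant_id:week)")
  stats::as.formula(paste(response, "~", paste(c(fixed, re), collapse = " + ")))
}

#' Fit the nested mixed-effects model for one component
#'
#' Fits `y ~ features + (1 | participant) + (1 | participant:week)` with lme4.
#' Wald 95% confidence intervals and p values use a t reference with the
#' residual-based degrees-of-freedom approximation `df = n - n_fixed - 1`
#' (exact small-sample df methods are out of scope).
#'
#' @param data aligned, identifiability-enforced rows with standardized
#'   features.
#' @param component response column name (e.g., `"IC_2"`).
#' @param features fixed-effect columns (default the 8 standard passive
#'   features).
#' @param method `"REML"` (default, for reported estimates) or `"ML"` (for
#'   likelihood-ratio sequences).
#' @return a `ComponentModelFit` list: `component`, `beta0`, `coefficients`
#'   (data.frame with estimate, SE, df, CI bounds, p_uncorrected),
#'   `sigma1_sq`, `sigma2_sq`, `sigma_sq`, `logLik`, `n`, `method`,
#'   `converged`, `messages`, and the underlying `model`.
#' @export
fitComponentModel <- function(data, component, features = FUSION_FEATURES,
                              method = c("REML", "ML")) {
  method <- match.arg(method)
  data <- as.data.frame(data)
  missing_cols <- setdiff(c(component, features, "participant_id", "week"),
                          names(data))
  if (length(missing_cols)) {
    stop("data is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  cell_counts <- table(paste(data$participant_id, data$week))
  if (any(cell_counts < 2L)) {
    stop("participant-weeks with fewer than 2 observations present; ",
         "run enforceWeekIdentifiability() first")
  }
  form <- fusionFormula(component, features)
  fit <- lme4::lmer(form, data = data, REML = (method == "REML"))
  msgs <- unlist(fit@optinfo$conv$lme4$messages) %||% character(0)
  converged <- fit@optinfo$conv$opt == 0 && length(msgs) == 0L
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  n <- nrow(data)
  df <- n - length(features) - 1L
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df = df)
  crit <- stats::qt(0.975, df = df)
  coefs <- data.frame(
    term = names(beta), estimate = unname(beta), se = unname(se),
    df = df, ci_lower = unname(beta - crit * se),
    ci_upper = unname(beta + crit * se), t = unname(tval),
    p_uncorrected = unname(pval), row.names = NULL
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v)) v[1L] else NA_real_
  }
  structure(list(
    component = component,
    beta0 = unname(beta[["(Intercept)"]]),
    coefficients = coefs,
    sigma1_sq = getv("participant_id"),
    sigma2_sq = getv("participant_id:week"),
    sigma_sq = getv("Residual"),
    logLik = as.numeric(stats::logLik(fit)),
    n = n, method = method, converged = converged, messages = msgs,
    model = fit
  ), class = "ComponentModelFit")
}

#' @export
print.ComponentModelFit <- function(x, ...) {
  cat(sprintf("ComponentModelFit [%s], %s, n = %d, converged = %s\n",
              x$component, x$method, x$n, format(x$converged)))
  cat(sprintf("  variance components: participant %.4f, week-in-participant %.4f, residual %.4f\n",
              x$sigma1_sq, x$sigma2_sq, x$sigma_sq))
  print(x$coefficients[, c("term", "estimate", "ci_lower", "ci_upper",
                           "p_uncorrected")], digits = 3)
  invisible(x)
}

#' Fit all component models and apply the family-wise correction
#'
#' @param data aligned, enforced, standardized rows.
#' @param components IC column names (default all `IC_*` columns).
#' @inheritParams fitComponentModel
#' @return list with `fits` (one [fitComponentModel()] result per component)
#'   and `estimates`, a long data.frame with one row per (component, term)
#'   carrying `p_uncorrected` and Bonferroni `p_corrected`
#'   (CF = n_IC * n_fixed).
#' @export
fitAllComponentModels <- function(data, components = NULL,
                                  features = FUSION_FEATURES,
                                  method = "REML") {
  data <- as.data.frame(data)
  if (is.null(components)) {
    components <- grep("^IC_", names(data), value = TRUE)
  }
  fits <- lapply(components, function(k) {
    fitComponentModel(data, k, features, method)
  })
  names(fits) <- components
  est <- do.call(rbind, lapply(fits, function(f) {
    cbind(component = f$component, f$coefficients)
  }))
  rownames(est) <- NULL
  is_fixed <- est$term != "(Intercept)"
  est$p_corrected <- NA_real_
  est$p_corrected[is_fixed] <- bonferroniCorrect(
    est$p_uncorrected[is_fixed],
    n_ic = length(components), n_fixed = length(features)
  )
  list(fits = fits, estimates = est,
       correction = list(n_ic = length(components),
                         n_fixed = length(features),
                         CF = length(components) * length(features)))
}

#' Bonferroni correction across the family of component models
#'
#' `p_corrected = min(1, CF * p)` with `CF = n_IC * n_fixed`, the number of
#' components times the number of fixed-effect terms excluding the intercept.
#'
#' @param p uncorrected p values in `[0, 1]`.
#' @param n_ic number of independent components (models).
#' @param n_fixed number of fixed-effect terms per model, excluding the
#'   intercept (default 8).
#' @return corrected p values, capped at 1.
#' @export
bonferroniCorrect <- function(p, n_ic, n_fixed = 8L) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p values must lie in [0, 1]")
  }
  cf <- as.integer(n_ic) * as.integer(n_fixed)
  if (cf < 1L) stop("correction factor must be a positive integer")
  pmin(1, cf * p)
}

#' Forwards-fitting of the random-effects structure
#'
#' Fits a nested sequence of models by maximum likelihood, adding one random
#' term at a time (participant intercept, then week-within-participant
#' intercept, then optional per-feature random slopes), and reports the
#' likelihood-ratio statistic and p value for each addition against a 1-df
#' chi-square reference — conservative at the variance boundary (no mixture
#' correction). The selected structure is refit with REML for reporting.
#'
#' @param data aligned, enforced, standardized rows.
#' @param component response column name.
#' @param features fixed-effect columns.
#' @param slope_features features for which uncorrelated per-participant
#'   random slopes are tried after the intercepts (default none).
#' @param alpha retention threshold for an addition (default 0.05).
#' @return list with `table` (one row per step: term, logLik, LRT statistic,
#'   df, p value, kept) and `final` (the REML refit of the selected model, a
#'   `ComponentModelFit` when the full nested-intercept structure is kept).
#' @export
forwardFitRandomEffects <- function(data, component,
                                    features = FUSION_FEATURES,
                                    slope_features = character(0),
                                    alpha = 0.05) {
  data <- as.data.frame(data)
  fixed <- paste(features, collapse = " + ")
  base_form <- stats::as.formula(paste(component, "~", fixed))
  ll_prev <- as.numeric(stats::logLik(stats::lm(base_form, data = data)))
  steps <- data.frame(
    term = "fixed effects only", logLik = ll_prev, lrt = NA_real_,
    df = NA_integer_, p = NA_real_, kept = TRUE, stringsAsFactors = FALSE
  )
  re_terms <- character(0)
  candidates <- c("(1 | participant_id)", "(1 | participant_id:week)",
                  sprintf("(0 + %s | participant_id)", slope_features))
  labels <- c("participant intercept", "week-within-participant intercept",
              sprintf("random slope: %s", slope_features))
  for (i in seq_along(candidates)) {
    try_terms <- c(re_terms, candidates[i])
    form <- stats::as.formula(paste(
      component, "~", fixed, "+", paste(try_terms, collapse = " + ")
    ))
    fit <- lme4::lmer(form, data = data, REML = FALSE)
    ll <- as.numeric(stats::logLik(fit))
    lrt <- max(0, 2 * (ll - ll_prev))
    p <- stats::pchisq(lrt, df = 1L, lower.tail = FALSE)
    kept <- p < alpha
    steps <- rbind(steps, data.frame(
      term = labels[i], logLik = ll, lrt = lrt, df = 1L, p = p, kept = kept,
      stringsAsFactors = FALSE
    ))
    if (kept) {
      re_terms <- try_terms
      ll_prev <- ll
    }
  }
  final <- NULL
  if (identical(re_terms[seq_len(min(2L, length(re_terms)))],
                c("(1 | participant_id)", "(1 | participant_id:week)")) &&
      length(re_terms) == 2L) {
    final <- fitComponentModel(data, component, features, method = "REML")
  } else if (length(re_terms)) {
    form <- stats::as.formula(paste(
      component, "~", fixed, "+", paste(re_terms, collapse = " + ")
    ))
    final <- lme4::lmer(form, data = data, REML = TRUE)
  }
  list(table = steps, final = final, selected = re_terms)
}

#' Model diagnostics for a fitted component model
#'
#' Emits the tables behind the standard visual checks: residual quantiles
#' against theoretical normal quantiles (QQ), the same for each random-effect
#' set, standardized residuals against fitted values (heteroskedasticity), and
#' a Shapiro-Wilk normality statistic per set as a scalar summary.
#'
#' @param fit a `ComponentModelFit`.
#' @return a `DiagnosticsBundle` list: `residual_qq`, `ranef_qq` (list per
#'   grouping), `residual_vs_fitted`, `normality` (data.frame of Shapiro-Wilk
#'   W and p per set).
#' @export
modelDiagnostics <- function(fit) {
  stopifnot(inherits(fit, "ComponentModelFit"))
  model <- fit$model
  res <- stats::residuals(model)
  sres <- res / stats::sd(res)
  qq <- function(v) {
    v <- sort(as.numeric(v))
    data.frame(
      theoretical = stats::qnorm(stats::ppoints(length(v))),
      sample = v
    )
  }
  sw <- function(v) {
    v <- as.numeric(v)
    if (length(v) > 4999L) v <- v[seq(1L, length(v), length.out = 4999L)]
    if (length(v) < 3L || stats::sd(v) == 0) {
      return(c(W = NA_real_, p = NA_real_))
    }
    t <- stats::shapiro.test(v)
    c(W = unname(t$statistic), p = t$p.value)
  }
  re <- lme4::ranef(model)
  ranef_qq <- lapply(re, function(g) qq(g[[1L]]))
  norm_rows <- rbind(
    data.frame(set = "residuals", t(sw(sres))),
    do.call(rbind, lapply(names(re), function(g) {
      data.frame(set = paste0("ranef:", g), t(sw(re[[g]][[1L]])))
    }))
  )
  structure(list(
    residual_qq = qq(sres),
    ranef_qq = ranef_qq,
    residual_vs_fitted = data.frame(
      fitted = as.numeric(stats::fitted(model)),
      standardized_residual = as.numeric(sres)
    ),
    normality = norm_rows
  ), class = "DiagnosticsBundle")
}

#' @export
print.DiagnosticsBundle <- function(x, ...) {
  cat("DiagnosticsBundle:", nrow(x$residual_vs_fitted), "observations\n")
  print(x$normality, digits = 3)
  invisible(x)
}
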