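# Scoring pipeline output against a synthetic study's ground truth.

#' Score recovery of a planted fixed effect from a pipeline run
#'
#' Matches the estimated independent components to the generator's true
#' component time courses (maximum absolute correlation over the shared
#' participant-days), then rescales the fitted coefficient of `feature` in the
#' matched component's model back to the ground-truth units: estimated sources
#' are canonicalized to unit variance, so estimates are multiplied by the
#' sample SD of the true component (and the matching sign) before comparison
#' with the planted value.
#'
#' @param bundle a `SyntheticStudy` from [simulateStudy()].
#' @param result the [runPipeline()] output for that bundle.
#' @param component true component whose planted effect is scored
#'   (default `"IC_2"`).
#' @param feature fixed-effect term of interest (default `"movement_rate"`).
#' @return list: `matched` (estimated component name), `match_cor` (absolute
#'   matching correlation), `beta_true`, `beta_scaled`, `ci_scaled`
#'   (length 2), `covered` (CI contains the planted value), `negative`
#'   (estimated sign), `p_corrected`.
#' @export
scorePlantedEffect <- function(bundle, result, component = "IC_2",
                               feature = "movement_rate") {
  stopifnot(inherits(bundle, "SyntheticStudy"))
  tr <- bundle$truth$latents
  idx <- as.data.frame(indexMap(result$ica))
  pos <- match(paste(tr$participant_id, tr$date),
               paste(idx$participant_id, idx$date))
  ok <- !is.na(pos)
  S <- icaSources(result$ica)[, pos[ok], drop = FALSE]
  y_true <- tr[[component]][ok]
  cors <- as.numeric(stats::cor(t(S), y_true))
  k <- which.max(abs(cors))
  sgn <- sign(cors[k])
  scale <- stats::sd(tr[[component]])
  est <- result$models$estimates
  row <- est[est$component == rownames(S)[k] & est$term == feature, ]
  ci <- sort(sgn * c(row$ci_lower, row$ci_upper)) * scale
  beta_true <- bundle$truth$parameters$beta1[component, feature]
  list(
    matched = rownames(S)[k],
    match_cor = abs(cors[k]),
    beta_true = beta_true,
    beta_scaled = sgn * row$estimate * scale,
    ci_scaled = ci,
    covered = ci[1] <= beta_true && beta_true <= ci[2],
    negative = (sgn * row$estimate) < 0,
    p_corrected = row$p_corrected
  )
}
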