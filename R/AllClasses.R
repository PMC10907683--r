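# S4 containers for the temporal-ICA stage.

#' ConcatenatedPanel: log-transformed self-report panel, participants
#' concatenated along the time axis
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single assay
#' (`"logvalues"`) is the p-items-by-n-participant-days matrix fed to the ICA
#' (Likert responses, natural-log transformed). `colData` carries the
#' participant/date provenance of every column; columns are ordered by
#' participant, then date. Rows are the self-report items; `rowData` may carry
#' a `scale` label (questionnaire of origin).
#'
#' @export
setClass("ConcatenatedPanel", contains = "SummarizedExperiment")

setValidity("ConcatenatedPanel", function(object) {
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("participant_id", "date") %in% colnames(cd))) {
    return("colData must contain 'participant_id' and 'date'")
  }
  if (!"logvalues" %in% SummarizedExperiment::assayNames(object)) {
    return("assay 'logvalues' is required")
  }
  key <- paste(cd$participant_id, cd$date)
  if (anyDuplicated(key)) {
    return("duplicate (participant_id, date) columns are forbidden")
  }
  m <- SummarizedExperiment::assay(object, "logvalues")
  if (any(!is.finite(m))) return("assay contains non-finite values")
  TRUE
})

#' ICADecomposition: result of a temporal ICA fit
#'
#' Holds the decomposition `X = center + A S + epsilon` of a
#' [ConcatenatedPanel]: the p-by-q mixing matrix `A` (item loadings), the
#' q-by-n source matrix `S` (component time courses), the per-item centering
#' vector, the participant-day index of the columns, and fitting metadata
#' (seed, contrast function, tolerance, iterations, convergence flag,
#' canonicalization state). After [canonicalize()], source rows have unit
#' sample variance, each component's largest-magnitude loading is positive and
#' components are ordered by the variance they explain.
#'
#' @slot A numeric matrix, items x components (mixing matrix / loadings).
#' @slot S numeric matrix, components x participant-days (sources).
#' @slot epsilon numeric matrix, items x participant-days residual.
#' @slot center numeric vector of per-item means removed before fitting.
#' @slot index `DataFrame` mapping columns to (participant_id, date).
#' @slot meta list of fitting metadata.
#' @export
setClass("ICADecomposition",
  representation(
    A = "matrix", S = "matrix", epsilon = "matrix", center = "numeric",
    index = "DataFrame", meta = "list"
  )
)

setValidity("ICADecomposition", function(object) {
  p <- nrow(object@A); q <- ncol(object@A); n <- ncol(object@S)
  if (nrow(object@S) != q) return("ncol(A) must equal nrow(S)")
  if (length(object@center) != p) return("center length must equal nrow(A)")
  if (nrow(object@index) != n) return("index must have one row per column of S")
  if (!identical(dim(object@epsilon), c(p, n))) {
    return("epsilon must be items x days")
  }
  TRUE
})

#' StabilityReport: restart stability of an ICA decomposition
#'
#' Pools the canonical mixing columns of R independent FastICA restarts,
#' computes their pairwise similarity (absolute Pearson correlation) and
#' clusters them by average-linkage agglomeration on 1 - |cor| at a fixed cut
#' height, in the spirit of ICASSO. Tight, well-populated clusters indicate
#' components that are stable across restarts.
#'
#' @slot components pooled mixing columns (items x (runs*q)), converged runs only.
#' @slot runs data.frame describing each pooled column (run, component, seed).
#' @slot similarity absolute-correlation similarity matrix of pooled columns.
#' @slot clusters integer cluster assignment per pooled column.
#' @slot tightness mean within-cluster similarity per cluster.
#' @slot failures data.frame of non-converged restarts (possibly 0 rows).
#' @slot meta list (R, q, cut height, base seed).
#' @export
setClass("StabilityReport",
  representation(
    components = "matrix", runs = "data.frame", similarity = "matrix",
    clusters = "integer", tightness = "numeric", failures = "data.frame",
    meta = "list"
  )
)

setMethod("show", "ICADecomposition", function(object) {
  cat(sprintf(
    "ICADecomposition: %d items x %d components over %d participant-days\n",
    nrow(object@A), ncol(object@A), ncol(object@S)
  ))
  cat(sprintf(
    "  contrast=%s (a1=%g), seed=%s, converged=%s after %d iterations\n",
    object@meta$fun, object@meta$a1,
    format(object@meta$seed), format(object@meta$converged),
    object@meta$iterations
  ))
  cat(sprintf("  canonical=%s, residual Frobenius norm=%.4g\n",
              format(isTRUE(object@meta$canonical)),
              object@meta$residual_norm))
  invisible(NULL)
})

setMethod("show", "StabilityReport", function(object) {
  nc <- length(unique(object@clusters))
  cat(sprintf(
    "StabilityReport: %d restarts x %d components -> %d pooled columns in %d clusters\n",
    object@meta$R, object@meta$q, ncol(object@components), nc
  ))
  if (nrow(object@failures)) {
    cat(sprintf("  %d restart(s) failed to converge (excluded from clustering)\n",
                nrow(object@failures)))
  }
  cat(sprintf("  cut height %.2f on 1-|cor|; median cluster tightness %.3f\n",
              object@meta$cut_height, stats::median(object@tightness)))
  invisible(NULL)
})
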