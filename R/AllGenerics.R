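# Accessor generics for the S4 containers.

#' @rdname ICADecomposition-accessors
#' @param object an [ICADecomposition] (or, where noted, [StabilityReport]).
#' @export
setGeneric("mixingMatrix", function(object) standardGeneric("mixingMatrix"))

#' @rdname ICADecomposition-accessors
#' @export
setGeneric("icaSources", function(object) standardGeneric("icaSources"))

#' @rdname ICADecomposition-accessors
#' @export
setGeneric("residualMatrix", function(object) standardGeneric("residualMatrix"))

#' @rdname ICADecomposition-accessors
#' @export
setGeneric("nComponents", function(object) standardGeneric("nComponents"))

#' @rdname ICADecomposition-accessors
#' @export
setGeneric("indexMap", function(object) standardGeneric("indexMap"))

#' @rdname ICADecomposition-accessors
#' @export
setGeneric("icaMeta", function(object) standardGeneric("icaMeta"))

#' Canonicalize an ICA decomposition
#'
#' Resolves the scale/sign/order indeterminacy of ICA: every source row is
#' rescaled to unit sample variance (the compensating scale moves into the
#' mixing column), each component's sign is flipped so its largest-magnitude
#' loading is positive, and components are reordered by decreasing explained
#' variance (squared mixing-column norm, since sources then have unit
#' variance). The product `A S` is unchanged and the operation is idempotent.
#'
#' @param object an [ICADecomposition].
#' @return the canonicalized [ICADecomposition].
#' @export
setGeneric("canonicalize", function(object) standardGeneric("canonicalize"))

#' Reconstruct the data matrix from a decomposition
#'
#' @param object an [ICADecomposition].
#' @return `center + A %*% S`, the model part of the decomposition.
#' @export
setGeneric("reconstruct", function(object) standardGeneric("reconstruct"))
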