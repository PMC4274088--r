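# Accessors and show methods for the core containers.

#' @rdname FCNetwork-class
#' @param net An [FCNetwork-class] object.
#' @return `edgeWeights` returns the N x N weight matrix; `nodeLabels` the node
#'   names; `cerebellumMask` the logical cerebellar mask; `nNodes` and
#'   `nEdges` the node and edge counts.
#' @export
setGeneric("edgeWeights", function(net) standardGeneric("edgeWeights"))

#' @rdname FCNetwork-class
#' @export
setMethod("edgeWeights", "FCNetwork", function(net) net@weights)

#' @rdname FCNetwork-class
#' @export
setGeneric("nodeLabels", function(net) standardGeneric("nodeLabels"))

#' @rdname FCNetwork-class
#' @export
setMethod("nodeLabels", "FCNetwork", function(net) net@nodeLabels)

#' @rdname FCNetwork-class
#' @export
setGeneric("cerebellumMask", function(net) standardGeneric("cerebellumMask"))

#' @rdname FCNetwork-class
#' @export
setMethod("cerebellumMask", "FCNetwork", function(net) net@cerebellumMask)

#' @rdname FCNetwork-class
#' @export
setGeneric("nNodes", function(net) standardGeneric("nNodes"))

#' @rdname FCNetwork-class
#' @export
setMethod("nNodes", "FCNetwork", function(net) nrow(net@weights))

#' @rdname FCNetwork-class
#' @export
setGeneric("nEdges", function(net) standardGeneric("nEdges"))

#' @rdname FCNetwork-class
#' @export
setMethod("nEdges", "FCNetwork", function(net) sum(net@weights[upper.tri(net@weights)] > 0))

setMethod("show", "FCNetwork", function(object) {
  n <- nrow(object@weights)
  e <- sum(object@weights[upper.tri(object@weights)] > 0)
  cat(sprintf("FCNetwork: %d nodes, %d edges (density %.3f), %d cerebellar nodes\n",
              n, e, if (n > 1) e / (n * (n - 1) / 2) else 0,
              sum(object@cerebellumMask)))
})

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig\n")
  cat(sprintf("  groups: NC=%d TPD=%d NTPD=%d\n",
              object@nPerGroup[["NC"]], object@nPerGroup[["TPD"]],
              object@nPerGroup[["NTPD"]]))
  cat(sprintf("  %d ROIs in %d modules, %d volumes at TR=%.1fs\n",
              object@nRois, object@nModules, object@nVolumes, object@tr))
  cat(sprintf("  rWithin=%.2f rBetween=%.2f effectDelta=%s on %d nodes\n",
              object@rWithin, object@rBetween,
              paste(format(object@effectDelta), collapse = "/"),
              length(object@affectedNodes)))
  cat(sprintf("  %d cerebellar nodes, nuisance loading %.2f, seed %d\n",
              length(object@cerebellumNodes), object@nuisanceLoading,
              object@seed))
})

setMethod("show", "SimulatedSubject", function(object) {
  cat(sprintf("SimulatedSubject %s (%s, %s, %.0f y): %d volumes x %d ROIs\n",
              object@subjectId, object@group, object@gender, object@age,
              nrow(object@timeseries), ncol(object@timeseries)))
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf(
    "SelectionResult: %d/%d features selected at p < %g (%d permutations)\n",
    sum(object@selected), length(object@selected), object@alpha,
    object@nPermutations))
})

setMethod("show", "MldaModel", function(object) {
  cat(sprintf("MldaModel: %s vs %s, %d features (positive class %s)\n",
              object@classLabels[1], object@classLabels[2],
              length(object@discriminant), object@positiveClass))
})

#' @rdname SelectionResult-class
#' @param object A `SelectionResult`.
#' @return `selectedFeatures` returns the ids of the selected features;
#'   `pValues` the per-feature permutation p-values.
#' @export
setGeneric("selectedFeatures", function(object) standardGeneric("selectedFeatures"))

#' @rdname SelectionResult-class
#' @export
setMethod("selectedFeatures", "SelectionResult",
          function(object) object@featureIds[object@selected])

#' @rdname SelectionResult-class
#' @export
setGeneric("pValues", function(object) standardGeneric("pValues"))

#' @rdname SelectionResult-class
#' @export
setMethod("pValues", "SelectionResult",
          function(object) stats::setNames(object@pValues, object@featureIds))
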