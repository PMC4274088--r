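# Plain-text serialization of the pipeline's artifacts: delimited time
# series, subject metadata, network matrices and edge lists, NIfTI label
# volumes for parcellations.

#' Read/write regional time series as delimited text
#'
#' Tab-separated, one row per volume, header `ROI_0001...`.
#'
#' @param ts T x N matrix.
#' @param path File path.
#' @return `readTimeseries` returns the matrix.
#' @export
writeTimeseries <- function(ts, path) {
  utils::write.table(ts, path, sep = "\t", row.names = FALSE,
                     col.names = !is.null(colnames(ts)), quote = FALSE)
}

#' @rdname writeTimeseries
#' @export
readTimeseries <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                              check.names = FALSE))
}

#' Read/write subject metadata CSV
#'
#' Columns `subjectId,group,age,gender`.
#'
#' @param metadata data.frame as from [makeCohort()].
#' @param path File path.
#' @return `readMetadata` returns the data.frame.
#' @export
writeMetadata <- function(metadata, path) {
  utils::write.csv(metadata, path, row.names = FALSE, quote = FALSE)
}

#' @rdname writeMetadata
#' @export
readMetadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  rownames(df) <- df$subjectId
  df
}

#' Write a network as matrix and edge list
#'
#' The matrix form is N x N tab-separated with node labels as header; the
#' edge list has columns `nodeI`, `nodeJ`, `weight` for positive edges.
#'
#' @param net An [FCNetwork-class].
#' @param path Matrix file path.
#' @return `readNetworkMatrix` returns an [FCNetwork-class] (cerebellum mask
#'   all-FALSE unless supplied); `networkEdgeList` returns the edge-list
#'   data.frame.
#' @export
writeNetworkMatrix <- function(net, path) {
  stopifnot(is(net, "FCNetwork"))
  utils::write.table(net@weights, path, sep = "\t", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
}

#' @rdname writeNetworkMatrix
#' @param cerebellumMask Optional mask to attach on read.
#' @export
readNetworkMatrix <- function(path, cerebellumMask = NULL) {
  w <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   check.names = FALSE))
  fcNetwork(w, nodeLabels = colnames(w), cerebellumMask = cerebellumMask)
}

#' @rdname writeNetworkMatrix
#' @export
networkEdgeList <- function(net) {
  stopifnot(is(net, "FCNetwork"))
  idx <- which(upper.tri(net@weights) & net@weights > 0, arr.ind = TRUE)
  data.frame(nodeI = net@nodeLabels[idx[, 1]],
             nodeJ = net@nodeLabels[idx[, 2]],
             weight = net@weights[idx], stringsAsFactors = FALSE)
}

#' Read/write a parcellation as a NIfTI label volume
#'
#' @param pv A `ParcelVolume` from [generateParcellation()].
#' @param path NIfTI file path (`.nii`).
#' @return `readParcellation` returns a `ParcelVolume` (parcel-to-region
#'   mapping is not stored in the NIfTI and comes back as `NA`).
#' @export
writeParcellation <- function(pv, path) {
  stopifnot(inherits(pv, "ParcelVolume"))
  RNifti::writeNifti(RNifti::asNifti(pv$labels), path)
}

#' @rdname writeParcellation
#' @export
readParcellation <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.integer(round(img)), dim = dim(img))
  k <- max(arr)
  structure(list(labels = arr, nParcels = as.integer(k),
                 parcelRegion = rep(NA_integer_, k)),
            class = "ParcelVolume")
}
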