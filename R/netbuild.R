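# Weighted functional network construction: Pearson correlation of cleaned
# regional series, exact t-based p-values, Bonferroni thresholding over the
# N(N-1)/2 unordered pairs, positive-only edges, Fisher r-to-z weights.

#' Construct an FCNetwork from a weight matrix
#'
#' Low-level constructor; validity enforces symmetry, zero diagonal and
#' nonnegative weights.
#'
#' @param weights N x N symmetric nonnegative matrix with zero diagonal.
#' @param nodeLabels Node names (defaults to column names or ROI_0001...).
#' @param cerebellumMask Logical cerebellar membership per node.
#' @return An [FCNetwork-class].
#' @export
fcNetwork <- function(weights, nodeLabels = NULL, cerebellumMask = NULL) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (is.null(nodeLabels))
    nodeLabels <- colnames(weights)
  if (is.null(nodeLabels))
    nodeLabels <- sprintf("ROI_%04d", seq_len(n))
  if (is.null(cerebellumMask)) cerebellumMask <- rep(FALSE, n)
  dimnames(weights) <- list(nodeLabels, nodeLabels)
  new("FCNetwork", weights = weights, nodeLabels = nodeLabels,
      cerebellumMask = cerebellumMask)
}

#' Pairwise Pearson correlations with exact p-values
#'
#' Computes the full N x N Pearson correlation matrix of the columns of a
#' time-series matrix, with two-sided p-values from the exact t transform
#' `t = r sqrt((T-2)/(1-r^2))` on T - 2 degrees of freedom. The diagonal
#' p-values are 0 by convention.
#'
#' @param ts T x N numeric matrix, T >= 3, every column with nonzero variance.
#' @return A list with `r` (correlations), `p` (p-values) and `nSamples`.
#' @export
pearsonMatrix <- function(ts) {
  ts <- as.matrix(ts)
  Tn <- nrow(ts)
  if (Tn < 3L) stop("need at least 3 samples for correlation p-values")
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(ts)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("zero-variance column(s): ", paste(bad, collapse = ", "))
  }
  r <- stats::cor(ts)
  df <- Tn - 2L
  r2 <- pmin(r^2, 1)
  tstat <- abs(r) * sqrt(df / pmax(1 - r2, .Machine$double.eps))
  p <- 2 * stats::pt(tstat, df, lower.tail = FALSE)
  p[r2 >= 1] <- 0
  diag(p) <- 0
  list(r = r, p = p, nSamples = Tn)
}

#' Fisher r-to-z transformation
#'
#' The variance-stabilizing transform z = atanh(r) = 0.5 log((1+r)/(1-r)).
#' Odd and strictly increasing on (-1, 1).
#'
#' @param r Correlation value(s), strictly inside (-1, 1).
#' @return Transformed value(s).
#' @examples
#' fisherRtoZ(0.5)  # 0.5 * log(3)
#' @export
fisherRtoZ <- function(r) {
  if (any(abs(r) >= 1))
    stop("domain error: Fisher z requires |r| < 1")
  atanh(r)
}

#' Bonferroni-thresholded positive weighted network
#'
#' Keeps an edge between regions i and j iff its correlation p-value is below
#' `alpha / m`, where `m = N(N-1)/2` is the number of unordered pairs tested,
#' and (by default) the correlation is positive. Surviving edges are weighted
#' by the Fisher z of their correlation; everything else, including the
#' diagonal, is zero.
#'
#' @param corr Result of [pearsonMatrix()].
#' @param alpha Family-wise significance level, in (0, 1).
#' @param positiveOnly Drop negative correlations regardless of significance.
#' @param nodeLabels,cerebellumMask Passed to [fcNetwork()].
#' @return An [FCNetwork-class].
#' @export
bonferroniThreshold <- function(corr, alpha = 0.05, positiveOnly = TRUE,
                                nodeLabels = NULL, cerebellumMask = NULL) {
  if (alpha <= 0 || alpha >= 1)
    stop("invalid argument: alpha must lie in (0, 1)")
  r <- corr$r
  p <- corr$p
  n <- nrow(r)
  m <- n * (n - 1) / 2
  keep <- p < alpha / m
  if (positiveOnly) keep <- keep & r > 0
  diag(keep) <- FALSE
  w <- matrix(0, n, n)
  # with the sign rule off, surviving negative correlations enter by their
  # Fisher-z magnitude: the network container is nonnegative by contract
  w[keep] <- abs(fisherRtoZ(r[keep]))
  w <- (w + t(w)) / 2   # keep is symmetric; guards rounding asymmetry
  if (is.null(nodeLabels)) nodeLabels <- colnames(r)
  fcNetwork(w, nodeLabels = nodeLabels, cerebellumMask = cerebellumMask)
}

#' Build a subject's network from cleaned time series
#'
#' Convenience wrapper: [pearsonMatrix()] then [bonferroniThreshold()].
#'
#' @param ts Cleaned T x N time-series matrix.
#' @param alpha Family-wise significance level.
#' @param positiveOnly Keep positive correlations only.
#' @param cerebellumMask Logical cerebellar membership per node.
#' @return An [FCNetwork-class].
#' @export
buildNetwork <- function(ts, alpha = 0.05, positiveOnly = TRUE,
                         cerebellumMask = NULL) {
  bonferroniThreshold(pearsonMatrix(ts), alpha = alpha,
                      positiveOnly = positiveOnly,
                      cerebellumMask = cerebellumMask)
}

#' Drop the cerebellar nodes from a network's source time series
#'
#' Helper for the cerebellum-free analysis arm: removes the masked columns
#' before network construction so the Bonferroni test count reflects the
#' smaller node set.
#'
#' @param ts T x N matrix.
#' @param cerebellumMask Logical vector of length N.
#' @return The matrix restricted to non-cerebellar columns.
#' @export
excludeCerebellum <- function(ts, cerebellumMask) {
  stopifnot(ncol(ts) == length(cerebellumMask))
  ts[, !cerebellumMask, drop = FALSE]
}
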