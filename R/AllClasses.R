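#' @import methods
NULL

GROUP_LEVELS <- c("NC", "TPD", "NTPD")

#' Cohort simulation settings
#'
#' An S4 container for the generative settings of a synthetic resting-state
#' cohort: group sizes, the regional time-series dimensions, the modular
#' correlation structure, where and how strongly the patient groups differ,
#' which nodes are designated cerebellar, and how strongly shared nuisance
#' signal contaminates the regional series.
#'
#' @slot nPerGroup Named integer vector with entries `NC`, `TPD`, `NTPD`.
#' @slot nRois Number of regions (network nodes).
#' @slot nModules Number of correlation modules the regions are split into.
#' @slot nVolumes Number of acquired volumes per subject.
#' @slot tr Repetition time in seconds.
#' @slot rWithin Within-module correlation, in (0, 1).
#' @slot rBetween Between-module correlation, in [0, rWithin).
#' @slot affectedNodes 1-based indices of nodes carrying the group effect.
#' @slot effectDelta Correlation decrement applied to affected nodes'
#'   within-module correlations in the patient groups; a scalar (both patient
#'   groups) or a named vector with entries `TPD` and `NTPD`.
#' @slot cerebellumNodes 1-based indices of the designated cerebellar nodes.
#' @slot nuisanceLoading Nonnegative loading of the shared confound mixture
#'   added to every regional series.
#' @slot ageRange Length-2 increasing positive vector; ages are uniform on it.
#' @slot maleProb Probability that a simulated subject is male.
#' @slot seed Master seed for cohort generation.
#'
#' @seealso [cohortConfig()] for the user-facing constructor with defaults.
#' @exportClass CohortConfig
setClass("CohortConfig", slots = c(
  nPerGroup = "integer",
  nRois = "integer",
  nModules = "integer",
  nVolumes = "integer",
  tr = "numeric",
  rWithin = "numeric",
  rBetween = "numeric",
  affectedNodes = "integer",
  effectDelta = "numeric",
  cerebellumNodes = "integer",
  nuisanceLoading = "numeric",
  ageRange = "numeric",
  maleProb = "numeric",
  seed = "integer"
))

setValidity("CohortConfig", function(object) {
  msg <- character(0)
  if (!identical(sort(names(object@nPerGroup)), sort(GROUP_LEVELS)))
    msg <- c(msg, "nPerGroup must be named with NC, TPD, NTPD")
  if (any(object@nPerGroup < 0L))
    msg <- c(msg, "group counts must be nonnegative")
  if (object@nRois < 2L) msg <- c(msg, "nRois must be >= 2")
  if (object@nModules < 1L || object@nModules > object@nRois)
    msg <- c(msg, "nModules must be in [1, nRois]")
  if (object@nVolumes < 3L) msg <- c(msg, "nVolumes must be >= 3")
  if (object@tr <= 0) msg <- c(msg, "tr must be positive")
  if (object@rWithin <= 0 || object@rWithin >= 1)
    msg <- c(msg, "rWithin must lie in (0, 1)")
  if (object@rBetween < 0 || object@rBetween >= object@rWithin)
    msg <- c(msg, "rBetween must lie in [0, rWithin)")
  if (any(object@effectDelta < 0) || any(object@effectDelta >= object@rWithin))
    msg <- c(msg, "effectDelta must lie in [0, rWithin)")
  if (length(object@effectDelta) == 2L &&
      !identical(sort(names(object@effectDelta)), c("NTPD", "TPD")))
    msg <- c(msg, "a length-2 effectDelta must be named TPD and NTPD")
  if (!length(object@effectDelta) %in% c(1L, 2L))
    msg <- c(msg, "effectDelta must have length 1 or 2")
  idx <- c(object@affectedNodes, object@cerebellumNodes)
  if (length(idx) && (any(idx < 1L) || any(idx > object@nRois)))
    msg <- c(msg, "node index sets must be subsets of 1..nRois")
  if (length(object@ageRange) != 2L || object@ageRange[1] <= 0 ||
      diff(object@ageRange) <= 0)
    msg <- c(msg, "ageRange must be an increasing positive pair")
  if (object@maleProb < 0 || object@maleProb > 1)
    msg <- c(msg, "maleProb must lie in [0, 1]")
  if (object@nuisanceLoading < 0)
    msg <- c(msg, "nuisanceLoading must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' One simulated subject
#'
#' Holds a subject's metadata together with the simulated regional time series
#' (volumes by regions), the raw nuisance series (6 rigid-body motion
#' parameters plus mean white-matter and CSF signals), and the indices of the
#' nodes that truly carry the group effect (the recovery ground truth).
#'
#' @slot subjectId Character scalar.
#' @slot group One of `"NC"`, `"TPD"`, `"NTPD"`.
#' @slot age Age in years.
#' @slot gender `"M"` or `"F"`.
#' @slot timeseries T x N numeric matrix (volumes by regions).
#' @slot nuisance T x 8 numeric matrix, columns `mot1..mot6`, `wm`, `csf`.
#' @slot tr Repetition time in seconds.
#' @slot trueAffected Integer indices of the truly affected nodes.
#'
#' @exportClass SimulatedSubject
setClass("SimulatedSubject", slots = c(
  subjectId = "character",
  group = "character",
  age = "numeric",
  gender = "character",
  timeseries = "matrix",
  nuisance = "matrix",
  tr = "numeric",
  trueAffected = "integer"
))

setValidity("SimulatedSubject", function(object) {
  msg <- character(0)
  if (!object@group %in% GROUP_LEVELS)
    msg <- c(msg, "group must be one of NC, TPD, NTPD")
  if (object@age <= 0) msg <- c(msg, "age must be positive")
  if (!object@gender %in% c("M", "F")) msg <- c(msg, "gender must be M or F")
  if (nrow(object@timeseries) < 3L) msg <- c(msg, "need at least 3 volumes")
  if (anyNA(object@timeseries) || any(!is.finite(object@timeseries)))
    msg <- c(msg, "timeseries must be finite with no missing values")
  if (nrow(object@nuisance) != nrow(object@timeseries))
    msg <- c(msg, "nuisance rows must match timeseries rows")
  if (ncol(object@nuisance) != 8L)
    msg <- c(msg, "nuisance must have 8 columns (6 motion + wm + csf)")
  if (length(msg)) msg else TRUE
})

#' Weighted functional connectivity network
#'
#' A symmetric nonnegative weighted adjacency matrix over named nodes. Edge
#' weights are Fisher-z transformed correlations that survived significance
#' thresholding; a weight of exactly zero means "no edge". A logical mask
#' records which nodes belong to the designated cerebellar subset, so the
#' cerebellum-free analysis arm can drop them.
#'
#' @slot weights N x N symmetric numeric matrix, zero diagonal, all entries
#'   nonnegative.
#' @slot nodeLabels Character vector of length N.
#' @slot cerebellumMask Logical vector of length N.
#'
#' @seealso [fcNetwork()], [bonferroniThreshold()]
#' @exportClass FCNetwork
setClass("FCNetwork", slots = c(
  weights = "matrix",
  nodeLabels = "character",
  cerebellumMask = "logical"
))

setValidity("FCNetwork", function(object) {
  w <- object@weights
  msg <- character(0)
  if (nrow(w) != ncol(w)) msg <- c(msg, "weights must be square")
  if (length(object@nodeLabels) != nrow(w))
    msg <- c(msg, "nodeLabels length must match matrix order")
  if (length(object@cerebellumMask) != nrow(w))
    msg <- c(msg, "cerebellumMask length must match matrix order")
  if (anyNA(w)) msg <- c(msg, "weights must not contain NA")
  else {
    if (any(w < 0)) msg <- c(msg, "weights must be nonnegative")
    if (any(abs(diag(w)) > 0)) msg <- c(msg, "diagonal must be zero")
    if (max(abs(w - t(w))) > 1e-12) msg <- c(msg, "weights must be symmetric")
  }
  if (length(msg)) msg else TRUE
})

#' Permutation-test feature-selection result
#'
#' Per-feature observed two-sample t statistics, permutation p-values and the
#' selection mask at the chosen (uncorrected) significance level.
#'
#' @slot featureIds Character vector naming the features.
#' @slot tObserved Observed pooled-variance t statistic per feature.
#' @slot pValues Two-tailed permutation p-value per feature, in (0, 1].
#' @slot selected Logical mask, `pValues < alpha`.
#' @slot alpha Selection significance level.
#' @slot nPermutations Number of Monte-Carlo permutations drawn.
#' @slot seed Seed used for the permutation draw.
#'
#' @exportClass SelectionResult
setClass("SelectionResult", slots = c(
  featureIds = "character",
  tObserved = "numeric",
  pValues = "numeric",
  selected = "logical",
  alpha = "numeric",
  nPermutations = "integer",
  seed = "integer"
))

setValidity("SelectionResult", function(object) {
  msg <- character(0)
  n <- length(object@pValues)
  if (length(object@tObserved) != n || length(object@selected) != n ||
      length(object@featureIds) != n)
    msg <- c(msg, "featureIds, tObserved, pValues, selected must align")
  if (any(object@pValues <= 0) || any(object@pValues > 1))
    msg <- c(msg, "permutation p-values must lie in (0, 1]")
  if (!identical(object@selected, object@pValues < object@alpha))
    msg <- c(msg, "selected must equal pValues < alpha")
  if (length(msg)) msg else TRUE
})

#' Maximum-uncertainty LDA model
#'
#' A two-class linear discriminant whose pooled within-class covariance has
#' been regularized by raising every eigenvalue below the mean eigenvalue up
#' to the mean. The regularized covariance is positive-definite by
#' construction, so the model fits even when features outnumber samples.
#'
#' @slot classMeans 2 x F matrix of class means (rows named by class).
#' @slot covReg F x F regularized pooled covariance.
#' @slot discriminant Weight vector w = covReg^{-1} (mu1 - mu2).
#' @slot threshold Decision threshold w . (mu1 + mu2) / 2 (equal priors).
#' @slot classLabels Ordered pair of class labels; scores > 0 predict the
#'   first, scores < 0 the second.
#' @slot positiveClass The label ties (score exactly 0) are assigned to.
#'
#' @seealso [fitMlda()], [predictMlda()]
#' @exportClass MldaModel
setClass("MldaModel", slots = c(
  classMeans = "matrix",
  covReg = "matrix",
  discriminant = "numeric",
  threshold = "numeric",
  classLabels = "character",
  positiveClass = "character"
))

setValidity("MldaModel", function(object) {
  msg <- character(0)
  if (nrow(object@classMeans) != 2L) msg <- c(msg, "need exactly two classes")
  if (length(object@classLabels) != 2L) msg <- c(msg, "need two class labels")
  if (!object@positiveClass %in% object@classLabels)
    msg <- c(msg, "positiveClass must be one of classLabels")
  if (any(!is.finite(object@discriminant)))
    msg <- c(msg, "discriminant must be finite")
  if (length(msg)) msg else TRUE
})
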