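# Covariate residualization and nonparametric permutation feature selection
# on per-node network metrics. The feature container is a
# SummarizedExperiment: assay = features x subjects, colData = subject
# metadata (group, age, gender).

#' Assemble a feature table
#'
#' Packs per-subject per-node metric values into a
#' [SummarizedExperiment::SummarizedExperiment] with one assay (features in
#' rows, subjects in columns) and the subject metadata as column data.
#'
#' @param values Subjects x features numeric matrix (rownames = subject ids).
#' @param metadata data.frame with columns `subjectId`, `group`, `age`,
#'   `gender`, rows aligned with `values`.
#' @return A `SummarizedExperiment` with assay `"features"`.
#' @export
featureTable <- function(values, metadata) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == nrow(metadata))
  if (anyNA(values)) stop("feature values must be finite")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(values)),
    colData = S4Vectors::DataFrame(metadata, row.names = metadata$subjectId))
}

#' @rdname featureTable
#' @param se A feature table built by `featureTable`.
#' @return `featureMatrix` returns the subjects x features matrix.
#' @export
featureMatrix <- function(se) {
  t(SummarizedExperiment::assay(se, "features"))   # subjects x features
}

# Covariate design: intercept + age + coded gender; constant covariates are
# dropped with a warning.
.covariateDesign <- function(metadata, checkConstant = TRUE) {
  age <- as.numeric(metadata$age)
  gender <- as.numeric(factor(metadata$gender, levels = c("F", "M"))) - 1
  X <- cbind(`(intercept)` = 1, age = age, gender = gender)
  if (!checkConstant) return(X)
  keep <- c(TRUE, stats::sd(age) > 0, stats::sd(gender) > 0)
  if (!all(keep)) {
    warning("dropping constant covariate(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  X
}

#' Remove age and gender effects from features
#'
#' Replaces every feature by its residual from an ordinary least-squares fit
#' on an intercept, age and coded gender, fitted across all subjects in the
#' table. Residuals have zero mean and are orthogonal to both covariates.
#'
#' @param se Feature table from [featureTable()].
#' @return A `SummarizedExperiment` of residualized features.
#' @export
residualize <- function(se) {
  meta <- as.data.frame(SummarizedExperiment::colData(se))
  if (nrow(meta) < 4L)
    stop("need at least 4 subjects to residualize on two covariates")
  X <- .covariateDesign(meta)
  vals <- featureMatrix(se)
  res <- qr.resid(qr(X), vals)
  featureTable(res, meta)
}

# Fit the covariate model on training subjects only; returns a function that
# residualizes any aligned feature matrix (used by nested cross-validation).
fitResidualizer <- function(trainValues, trainMeta) {
  X <- .covariateDesign(trainMeta)
  beta <- qr.coef(qr(X), trainValues)
  beta[is.na(beta)] <- 0
  function(values, meta) {
    Xn <- .covariateDesign(meta, checkConstant = FALSE)
    common <- intersect(colnames(X), colnames(Xn))
    as.matrix(values) - Xn[, common, drop = FALSE] %*%
      beta[common, , drop = FALSE]
  }
}

#' Two-sample permutation t-test over many features
#'
#' For every feature, the observed pooled-variance two-sample t statistic is
#' compared with a Monte-Carlo null built by randomly reassigning subjects to
#' two groups of the original sizes and recomputing the statistic. Two-tailed
#' p-values use the add-one convention `p = (1 + #{|t*| >= |t|}) / (1 + P)`,
#' so the smallest attainable p is `1/(P+1)`. Constant-difference features
#' (zero pooled variance and zero mean difference) get t = 0 and p = 1.
#'
#' @param groupA,groupB Subjects x features matrices (>= 2 rows each).
#' @param nPermutations Number of Monte-Carlo permutations.
#' @param seed Integer seed; results are bitwise-reproducible under it.
#' @param alpha Selection level stored in the result.
#' @param featureIds Optional feature names.
#' @return A [SelectionResult-class].
#' @export
permutationTest <- function(groupA, groupB, nPermutations = 10000L,
                            seed = 1L, alpha = 0.05, featureIds = NULL) {
  groupA <- as.matrix(groupA)
  groupB <- as.matrix(groupB)
  nA <- nrow(groupA); nB <- nrow(groupB)
  if (nA < 2L || nB < 2L) stop("each group needs at least 2 subjects")
  stopifnot(ncol(groupA) == ncol(groupB))
  X <- rbind(groupA, groupB)
  n <- nA + nB
  f <- ncol(X)
  if (is.null(featureIds))
    featureIds <- colnames(X)
  if (is.null(featureIds))
    featureIds <- sprintf("f%04d", seq_len(f))

  X2 <- X^2
  S <- colSums(X); Q <- colSums(X2)
  tFrom <- function(S1, Q1) {
    mA <- S1 / nA
    mB <- (S - S1) / nB
    ssA <- Q1 - S1^2 / nA
    ssB <- (Q - Q1) - (S - S1)^2 / nB
    sp2 <- (ssA + ssB) / (n - 2)
    denom <- sqrt(sp2 * (1 / nA + 1 / nB))
    t <- (mA - mB) / denom
    t[denom == 0 & abs(mA - mB) < .Machine$double.eps^0.5] <- 0
    t
  }
  tObs <- tFrom(colSums(X[seq_len(nA), , drop = FALSE]),
                colSums(X2[seq_len(nA), , drop = FALSE]))

  set.seed(as.integer(seed))
  # n x P indicator matrix of the permuted group-A memberships; crossprod
  # turns the per-permutation column sums into two BLAS calls
  M <- matrix(0, n, nPermutations)
  for (b in seq_len(nPermutations))
    M[sample.int(n, nA), b] <- 1
  S1 <- crossprod(X, M)    # f x P
  Q1 <- crossprod(X2, M)
  mA <- S1 / nA
  mB <- (S - S1) / nB
  ssA <- Q1 - S1^2 / nA
  ssB <- (Q - Q1) - (S - S1)^2 / nB
  sp2 <- (ssA + ssB) / (n - 2)
  denom <- sqrt(sp2 * (1 / nA + 1 / nB))
  tPerm <- (mA - mB) / denom
  tPerm[denom == 0] <- 0
  exceed <- rowSums(abs(tPerm) >= abs(tObs) - 1e-12)
  p <- (1 + exceed) / (1 + nPermutations)

  new("SelectionResult", featureIds = as.character(featureIds),
      tObserved = as.numeric(tObs), pValues = as.numeric(p),
      selected = as.numeric(p) < alpha, alpha = alpha,
      nPermutations = as.integer(nPermutations), seed = as.integer(seed))
}

#' Re-threshold a selection result
#'
#' Updates the selection mask of a [SelectionResult-class] at a new
#' (uncorrected) significance level.
#'
#' @param result A [SelectionResult-class].
#' @param alpha New significance level (`alpha = 1` selects everything).
#' @return The updated [SelectionResult-class].
#' @export
selectFeatures <- function(result, alpha = 0.05) {
  stopifnot(is(result, "SelectionResult"))
  new("SelectionResult", featureIds = result@featureIds,
      tObserved = result@tObserved, pValues = result@pValues,
      selected = result@pValues < alpha, alpha = alpha,
      nPermutations = result@nPermutations, seed = result@seed)
}
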