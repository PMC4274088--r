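# Maximum-uncertainty linear discriminant analysis: classical two-class LDA
# whose pooled within-class covariance is regularized by raising every
# eigenvalue below the mean eigenvalue up to the mean. The regularized
# covariance is positive-definite whenever the pooled covariance is nonzero,
# so the discriminant exists even with more features than samples.

#' Fit a maximum-uncertainty LDA model
#'
#' Computes the pooled within-class covariance `Sp`, replaces every
#' eigenvalue of `Sp` below the mean eigenvalue by the mean, and uses the
#' reconstructed covariance to form the discriminant
#' `w = Sp*^{-1} (mu1 - mu2)` with midpoint threshold
#' `w . (mu1 + mu2) / 2` (equal priors). When all eigenvalues of `Sp` are
#' equal the model coincides with classical LDA.
#'
#' @param X Samples x features numeric matrix.
#' @param y Class labels, exactly two distinct values, each with >= 2
#'   samples.
#' @param positiveClass Label that tie scores (exactly 0) are assigned to;
#'   defaults to the second class (conventionally the patient group).
#' @return An [MldaModel-class].
#' @export
fitMlda <- function(X, y, positiveClass = NULL) {
  X <- as.matrix(X)
  if (ncol(X) == 0L) stop("no features to fit")
  y <- as.character(y)
  labs <- unique(y)
  if (length(labs) != 2L)
    stop("need exactly two classes, got ", length(labs))
  n1 <- sum(y == labs[1]); n2 <- sum(y == labs[2])
  if (n1 < 2L || n2 < 2L) stop("each class needs at least 2 samples")
  if (is.null(positiveClass)) positiveClass <- labs[2]
  X1 <- X[y == labs[1], , drop = FALSE]
  X2 <- X[y == labs[2], , drop = FALSE]
  mu1 <- colMeans(X1); mu2 <- colMeans(X2)
  C1 <- crossprod(sweep(X1, 2, mu1))
  C2 <- crossprod(sweep(X2, 2, mu2))
  Sp <- (C1 + C2) / (n1 + n2 - 2)
  e <- eigen(Sp, symmetric = TRUE)
  lbar <- mean(e$values)
  if (lbar <= 0) stop("pooled covariance is zero; features are constant")
  vals <- pmax(e$values, lbar)
  covReg <- e$vectors %*% (vals * t(e$vectors))
  w <- e$vectors %*% ((t(e$vectors) %*% (mu1 - mu2)) / vals)
  w <- as.numeric(w)
  means <- rbind(mu1, mu2)
  rownames(means) <- labs
  new("MldaModel", classMeans = means, covReg = covReg, discriminant = w,
      threshold = sum(w * (mu1 + mu2) / 2), classLabels = labs,
      positiveClass = positiveClass)
}

#' Predict with an MLDA model
#'
#' Scores are `w . x - threshold`; positive scores predict the first class,
#' negative the second, and exact ties go to the model's positive class.
#'
#' @param model An [MldaModel-class].
#' @param X Samples x features matrix with the model's feature count.
#' @return data.frame with columns `label` and `score`.
#' @export
predictMlda <- function(model, X) {
  stopifnot(is(model, "MldaModel"))
  X <- as.matrix(X)
  if (ncol(X) != length(model@discriminant))
    stop("feature dimension mismatch: model has ",
         length(model@discriminant), ", data has ", ncol(X))
  score <- as.numeric(X %*% model@discriminant) - model@threshold
  label <- ifelse(score > 0, model@classLabels[1],
           ifelse(score < 0, model@classLabels[2], model@positiveClass))
  data.frame(label = label, score = score, stringsAsFactors = FALSE)
}

# Stable per-subject hash for fold-level seeds, so leave-one-out results do
# not depend on subject ordering.
stableHash <- function(id) {
  codes <- utf8ToInt(id)
  h <- 0
  for (c in codes) h <- (h * 31 + c) %% 1048573
  as.integer(h)
}

#' Leave-one-out cross-validated discrimination
#'
#' Runs leave-one-out cross-validation of the MLDA classifier on a feature
#' table restricted to two groups. In `mode = "nested"` (the default,
#' methodologically sound), covariate residualization and permutation feature
#' selection are re-fit on each training fold and then applied to the
#' held-out subject. In `mode = "paper_faithful"`, residualization and
#' selection are performed once on all subjects before the loop, reproducing
#' the common but optimistically biased design in which feature selection
#' precedes cross-validation.
#'
#' @param se Feature table ([featureTable()]) containing exactly the
#'   subjects of the two groups being contrasted.
#' @param positiveClass The patient-group label (positive class for
#'   performance metrics and tie-breaking).
#' @param mode `"nested"` or `"paper_faithful"`.
#' @param nPermutations Permutations for per-fold (nested) or one-shot
#'   (paper_faithful) feature selection.
#' @param alpha Selection significance level (uncorrected).
#' @param seed Base seed; per-fold seeds derive from it and a stable hash of
#'   the held-out subject id, so results are invariant to subject order.
#' @return data.frame of fold predictions: `subjectId`, `trueLabel`,
#'   `predictedLabel`, `score`, `nSelected`.
#' @export
loocv <- function(se, positiveClass, mode = c("nested", "paper_faithful"),
                  nPermutations = 1000L, alpha = 0.05, seed = 1L) {
  mode <- match.arg(mode)
  meta <- as.data.frame(SummarizedExperiment::colData(se))
  vals <- featureMatrix(se)
  # canonical subject order: permutation draws and fold results then do not
  # depend on how the caller ordered the table
  ord <- order(meta$subjectId)
  meta <- meta[ord, , drop = FALSE]
  vals <- vals[ord, , drop = FALSE]
  y <- as.character(meta$group)
  labs <- sort(unique(y))   # stable contrast orientation, whatever the row order
  if (length(labs) != 2L) stop("feature table must hold exactly two groups")
  if (!positiveClass %in% labs) stop("positiveClass must be one of the groups")
  S <- nrow(vals)
  if (S < 4L) stop("need at least 4 subjects for leave-one-out validation")

  selectOn <- function(values, groups, foldSeed) {
    res <- permutationTest(values[groups == labs[1], , drop = FALSE],
                           values[groups == labs[2], , drop = FALSE],
                           nPermutations = nPermutations, seed = foldSeed,
                           alpha = alpha, featureIds = colnames(values))
    sel <- which(res@selected)
    if (!length(sel)) sel <- which.min(res@pValues)  # fallback: best feature
    sel
  }

  if (mode == "paper_faithful") {
    resid <- featureMatrix(residualize(se))
    selAll <- selectOn(resid, y, deriveSeed(seed, 7L))
  }

  preds <- vector("list", S)
  for (i in seq_len(S)) {
    trainIdx <- setdiff(seq_len(S), i)
    yTrain <- y[trainIdx]
    if (length(unique(yTrain)) != 2L || min(table(yTrain)) < 2L)
      stop("a training fold lost a class; groups are too small")
    foldSeed <- deriveSeed(seed, stableHash(meta$subjectId[i]))
    if (mode == "nested") {
      rz <- fitResidualizer(vals[trainIdx, , drop = FALSE], meta[trainIdx, ])
      trainR <- rz(vals[trainIdx, , drop = FALSE], meta[trainIdx, ])
      testR <- rz(vals[i, , drop = FALSE], meta[i, , drop = FALSE])
      sel <- selectOn(trainR, yTrain, foldSeed)
    } else {
      trainR <- resid[trainIdx, , drop = FALSE]
      testR <- resid[i, , drop = FALSE]
      sel <- selAll
    }
    model <- fitMlda(trainR[, sel, drop = FALSE], yTrain,
                     positiveClass = positiveClass)
    pr <- predictMlda(model, testR[, sel, drop = FALSE])
    preds[[i]] <- data.frame(subjectId = meta$subjectId[i], trueLabel = y[i],
                             predictedLabel = pr$label, score = pr$score,
                             nSelected = length(sel),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, preds)
  rownames(out) <- NULL
  out
}

#' Confusion counts and performance of fold predictions
#'
#' Summarizes leave-one-out predictions into confusion counts with the
#' patient group as the positive class, plus sensitivity `tp/(tp+fn)`,
#' specificity `tn/(tn+fp)` and accuracy `(tp+tn)/total`.
#'
#' @param preds Prediction data.frame from [loocv()].
#' @param positiveClass Positive (patient) class label.
#' @return One-row data.frame: `tp`, `tn`, `fp`, `fn`, `sensitivity`,
#'   `specificity`, `accuracy`.
#' @export
performanceMetrics <- function(preds, positiveClass) {
  stopifnot(nrow(preds) > 0)
  labs <- unique(c(preds$trueLabel, preds$predictedLabel))
  if (!positiveClass %in% labs)
    stop("unknown positive class: ", positiveClass)
  pos <- preds$trueLabel == positiveClass
  hit <- preds$predictedLabel == preds$trueLabel
  tp <- sum(pos & hit); fn <- sum(pos & !hit)
  tn <- sum(!pos & hit); fp <- sum(!pos & !hit)
  data.frame(tp = tp, tn = tn, fp = fp, fn = fn,
             sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
             specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
             accuracy = (tp + tn) / nrow(preds))
}
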