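twoClassData <- function(n1 = 20, n2 = 15, f = 6, sep = 0, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n1 * f), n1, f),
             matrix(rnorm(n2 * f), n2, f) + sep / sqrt(f))
  list(X = X, y = rep(c("NC", "TPD"), c(n1, n2)))
}

test_that("MLDA equals classical LDA when the pooled covariance is spherical", {
  # two features forced to have an exactly spherical pooled covariance:
  # whiten within classes so Sp = identity
  d <- twoClassData(f = 4, sep = 3, seed = 2)
  X <- d$X
  # whiten the pooled within-class covariance
  mu <- rowsum(X, d$y) / as.vector(table(d$y))
  Xc <- X - mu[d$y, ]
  Sp <- crossprod(Xc) / (nrow(X) - 2)
  X <- X %*% solve(chol(Sp))
  mu <- rowsum(X, d$y) / as.vector(table(d$y))
  model <- fitMlda(X, d$y)
  direction <- mu[1, ] - mu[2, ]   # classical LDA direction for identity Sp
  expect_lt(max(abs(model@discriminant - direction)), 1e-10)
  # and against MASS::lda's scaling direction (collinearity check)
  ld <- MASS::lda(X, grouping = factor(d$y))
  cosang <- abs(sum(model@discriminant * ld$scaling) /
                sqrt(sum(model@discriminant^2) * sum(ld$scaling^2)))
  expect_gt(cosang, 1 - 1e-8)
})

test_that("regularization floors eigenvalues at the mean and enables F > S fits", {
  d <- twoClassData(n1 = 8, n2 = 7, f = 40, sep = 4, seed = 3)  # F > S
  model <- fitMlda(d$X, d$y)
  expect_length(model@discriminant, 40L)
  # raw pooled covariance
  mu <- rowsum(d$X, d$y) / as.vector(table(d$y))
  Xc <- d$X - mu[d$y, ]
  Sp <- crossprod(Xc) / (nrow(d$X) - 2)
  lbar <- mean(eigen(Sp, symmetric = TRUE, only.values = TRUE)$values)
  evReg <- eigen(model@covReg, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(evReg), lbar - 1e-10)
  # eigenvalues above the mean are untouched
  evRaw <- eigen(Sp, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(evReg[evRaw > lbar], evRaw[evRaw > lbar], tolerance = 1e-10)

  # strong separation: perfect training accuracy
  d2 <- twoClassData(n1 = 20, n2 = 20, f = 5, sep = 10, seed = 4)
  m2 <- fitMlda(d2$X, d2$y)
  pr <- predictMlda(m2, d2$X)
  expect_equal(mean(pr$label == d2$y), 1.0)
  expect_error(fitMlda(d2$X, rep("NC", 40)), "two classes")
})

test_that("prediction uses the midpoint threshold with patient-favoring ties", {
  d <- twoClassData(f = 3, sep = 5, seed = 5)
  model <- fitMlda(d$X, d$y, positiveClass = "TPD")
  mu1 <- model@classMeans[1, ]; mu2 <- model@classMeans[2, ]
  expect_equal(predictMlda(model, rbind(mu1))$label, model@classLabels[1])
  expect_equal(predictMlda(model, rbind(mu2))$label, model@classLabels[2])
  mid <- predictMlda(model, rbind((mu1 + mu2) / 2))
  expect_equal(mid$score, 0, tolerance = 1e-10)
  expect_equal(mid$label, "TPD")

  # translation invariance
  shift <- rnorm(3)
  m2 <- fitMlda(sweep(d$X, 2, shift, "+"), d$y, positiveClass = "TPD")
  Xt <- matrix(rnorm(30), 10, 3)
  expect_equal(predictMlda(model, Xt)$label,
               predictMlda(m2, sweep(Xt, 2, shift, "+"))$label)
  expect_error(predictMlda(model, Xt[, 1:2]), "dimension mismatch")
})

test_that("confusion summaries follow the definitions", {
  preds <- data.frame(
    subjectId = sprintf("s%d", 1:10),
    trueLabel = c(rep("TPD", 4), rep("NC", 6)),
    predictedLabel = c("TPD", "TPD", "TPD", "NC",
                       "NC", "NC", "NC", "NC", "TPD", "TPD"),
    score = 0)
  pm <- performanceMetrics(preds, "TPD")
  expect_equal(pm$tp, 3); expect_equal(pm$fn, 1)
  expect_equal(pm$tn, 4); expect_equal(pm$fp, 2)
  expect_equal(pm$sensitivity, 0.75)
  expect_equal(pm$specificity, 2 / 3, tolerance = 1e-12)
  expect_equal(pm$accuracy, 0.7)

  allPos <- transform(preds, predictedLabel = "TPD")
  pmAll <- performanceMetrics(allPos, "TPD")
  expect_equal(pmAll$sensitivity, 1)
  expect_equal(pmAll$specificity, 0)

  allHit <- transform(preds, predictedLabel = trueLabel)
  pmHit <- performanceMetrics(allHit, "TPD")
  expect_equal(pmHit$sensitivity, 1)
  expect_equal(pmHit$specificity, 1)
  expect_equal(pmHit$accuracy, 1)
  expect_error(performanceMetrics(preds, "NTPD"), "unknown positive class")
})

test_that("LOOCV yields one prediction per subject and is order-invariant", {
  set.seed(6)
  n <- 16
  meta <- data.frame(subjectId = sprintf("s%02d", 1:n),
                     group = rep(c("NC", "TPD"), each = 8),
                     age = runif(n, 40, 80),
                     gender = sample(c("M", "F"), n, replace = TRUE))
  feat <- matrix(rnorm(n * 10), n, 10,
                 dimnames = list(meta$subjectId, sprintf("f%02d", 1:10)))
  feat[meta$group == "TPD", 1:3] <- feat[meta$group == "TPD", 1:3] + 2
  se <- featureTable(feat, meta)
  preds <- loocv(se, "TPD", nPermutations = 200L, seed = 11L)
  expect_equal(nrow(preds), n)
  expect_setequal(preds$subjectId, meta$subjectId)

  # shuffling the subjects changes nothing per subject
  perm <- sample(n)
  se2 <- featureTable(feat[perm, ], meta[perm, ])
  preds2 <- loocv(se2, "TPD", nPermutations = 200L, seed = 11L)
  ord <- match(preds$subjectId, preds2$subjectId)
  expect_equal(preds$predictedLabel, preds2$predictedLabel[ord])
  expect_equal(preds$score, preds2$score[ord], tolerance = 1e-10)

  # losing a class in training must error
  tiny <- featureTable(feat[c(1, 9:12), ], meta[c(1, 9:12), ])
  expect_error(loocv(tiny, "TPD", nPermutations = 50L, seed = 1L),
               "lost a class|at least")
})

test_that("paper_faithful selection-before-CV is optimistically biased on null data", {
  # pure feature-level nulls (no signal); both modes on the same data
  set.seed(31)
  nSim <- 12
  accN <- accP <- numeric(nSim)
  for (b in seq_len(nSim)) {
    n <- 24
    meta <- data.frame(subjectId = sprintf("s%02d", 1:n),
                       group = rep(c("NC", "TPD"), each = 12),
                       age = runif(n, 40, 80),
                       gender = sample(c("M", "F"), n, replace = TRUE))
    feat <- matrix(rnorm(n * 40), n, 40,
                   dimnames = list(meta$subjectId, sprintf("f%02d", 1:40)))
    se <- featureTable(feat, meta)
    accN[b] <- performanceMetrics(
      loocv(se, "TPD", mode = "nested", nPermutations = 100L,
            seed = 100L + b), "TPD")$accuracy
    accP[b] <- performanceMetrics(
      loocv(se, "TPD", mode = "paper_faithful", nPermutations = 100L,
            seed = 100L + b), "TPD")$accuracy
  }
  expect_gte(mean(accP), mean(accN))
})
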