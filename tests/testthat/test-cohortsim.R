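test_that("cohort records have the configured sizes, labels and determinism", {
  cfg <- cohortConfig(nRois = 16L, nModules = 2L, affectedNodes = 1:2,
                      cerebellumNodes = 15:16)
  rec <- makeCohort(cfg)
  expect_equal(nrow(rec), 45L)
  expect_equal(as.vector(table(rec$group)[c("NC", "TPD", "NTPD")]),
               c(20L, 15L, 10L))
  expect_true(all(rec$age > 0 & rec$age >= 40 & rec$age <= 80))
  expect_true(all(rec$gender %in% c("M", "F")))
  expect_identical(rec, makeCohort(cfg))

  empty <- cohortConfig(nPerGroup = c(NC = 0L, TPD = 0L, NTPD = 0L),
                        nRois = 16L, nModules = 2L, affectedNodes = 1:2,
                        cerebellumNodes = 15:16)
  expect_equal(nrow(makeCohort(empty)), 0L)
  expect_error(cohortConfig(nPerGroup = c(NC = -1L, TPD = 2L, NTPD = 2L),
                            nRois = 16L, nModules = 2L, affectedNodes = 1:2,
                            cerebellumNodes = 15:16),
               "nonnegative")
})

test_that("group correlation matrices have the modular block structure", {
  cfg <- cohortConfig(nRois = 12L, nModules = 3L, affectedNodes = 1:2,
                      cerebellumNodes = 11:12, rWithin = 0.4,
                      rBetween = 0.1, effectDelta = 0.25)
  Rnc <- buildGroupCorrelation(cfg, "NC", clip = FALSE)
  expect_true(isSymmetric(Rnc))
  expect_equal(diag(Rnc), rep(1, 12))
  expect_equal(Rnc[1, 2], 0.4)   # same module
  expect_equal(Rnc[1, 5], 0.1)   # different modules

  # difference to a patient group touches only affected rows/columns
  Rtpd <- buildGroupCorrelation(cfg, "TPD", clip = FALSE)
  dif <- Rnc - Rtpd
  touched <- unique(c(which(rowSums(abs(dif)) > 0)))
  expect_true(all(touched %in% 1:4))          # module 1 only
  expect_equal(dif[1, 3], 0.25)
  expect_equal(dif[5, 6], 0)

  # zero effect: groups identical
  cfg0 <- cohortConfig(nRois = 12L, nModules = 3L, affectedNodes = 1:2,
                       cerebellumNodes = 11:12, effectDelta = 0)
  expect_equal(buildGroupCorrelation(cfg0, "NC"),
               buildGroupCorrelation(cfg0, "TPD"))

  # single module: constant off-diagonal
  cfg1 <- cohortConfig(nRois = 6L, nModules = 1L, affectedNodes = integer(0),
                       cerebellumNodes = integer(0), rWithin = 0.4)
  R1 <- buildGroupCorrelation(cfg1, "NC", clip = FALSE)
  expect_true(all(R1[upper.tri(R1)] == 0.4))
})

test_that("clipped correlation matrices are positive-definite with unit diagonal", {
  for (g in c("NC", "TPD", "NTPD")) {
    R <- buildGroupCorrelation(tinyConfig(), g)
    expect_equal(diag(R), rep(1, 24))
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
})

test_that("simulated series converge to the target correlations", {
  # long single simulation, no nuisance: law of large numbers
  cfg <- cohortConfig(nPerGroup = c(NC = 1L, TPD = 1L, NTPD = 1L),
                      nRois = 16L, nModules = 2L, nVolumes = 20000L,
                      affectedNodes = 1:3, cerebellumNodes = 15:16,
                      rWithin = 0.4, nuisanceLoading = 0)
  rec <- list(subjectId = "NC_01", group = "NC", age = 60, gender = "M")
  s <- simulateSubject(rec, cfg, seed = 5L)
  r <- stats::cor(s@timeseries)
  mod <- rep(1:2, each = 8)
  within <- r[outer(mod, mod, "==") & upper.tri(r)]
  expect_lt(abs(mean(within) - 0.4), 0.02)

  # determinism
  s2 <- simulateSubject(rec, cfg, seed = 5L)
  expect_identical(s@timeseries, s2@timeseries)
  expect_identical(s@nuisance, s2@nuisance)

  # affected nodes show reduced within-module correlation for patients
  cfgE <- cohortConfig(nPerGroup = c(NC = 1L, TPD = 1L, NTPD = 1L),
                       nRois = 16L, nModules = 2L, nVolumes = 5000L,
                       affectedNodes = 1:3, cerebellumNodes = 15:16,
                       rWithin = 0.4, effectDelta = 0.25,
                       nuisanceLoading = 0)
  recT <- list(subjectId = "TPD_01", group = "TPD", age = 60, gender = "F")
  sT <- simulateSubject(recT, cfgE, seed = 6L)
  rT <- stats::cor(sT@timeseries)
  affPairs <- rT[1:3, 4:8]          # affected vs unaffected, module 1
  cleanPairs <- rT[4:8, 4:8][upper.tri(matrix(0, 5, 5))]
  expect_lt(mean(affPairs), mean(cleanPairs))
})

test_that("zero effect and zero nuisance make all groups generatively identical", {
  cfg <- tinyConfig(effectDelta = 0, nuisanceLoading = 0)
  Rs <- lapply(c("NC", "TPD", "NTPD"), buildGroupCorrelation, config = cfg)
  expect_equal(Rs[[1]], Rs[[2]])
  expect_equal(Rs[[1]], Rs[[3]])
})

test_that("cohort simulation is reproducible and carries ground truth", {
  cfg <- tinyConfig()
  subs <- simulateCohort(cfg)
  expect_length(subs, 15L)
  expect_identical(subs[[1]]@trueAffected, 1:4)
  subs2 <- simulateCohort(cfg)
  expect_identical(subs[[3]]@timeseries, subs2[[3]]@timeseries)
  expect_error(simulateSubject(list(subjectId = "x", group = "NC", age = 50,
                                    gender = "M"),
                               tinyConfig(nVolumes = 2L), seed = 1L))
})

test_that("parcellation partitions label volumes into contiguous balanced parcels", {
  vol <- array(0L, c(10, 10, 4))
  vol[2:9, 2:9, ] <- 1L

  # identity case
  pv1 <- generateParcellation(vol, k = 1, seed = 3L)
  expect_equal(which(pv1$labels == 1L), which(vol == 1L))

  pv <- generateParcellation(vol, k = 16, seed = 3L)
  expect_equal(sort(unique(pv$labels[pv$labels > 0])), 1:16)
  # partition: every input voxel assigned exactly once, background untouched
  expect_identical(pv$labels > 0, vol > 0)
  sizes <- table(pv$labels[pv$labels > 0])
  expect_true(all(sizes >= mean(sizes) / 3 & sizes <= mean(sizes) * 3))
  # each parcel is one 6-connected component
  for (p in 1:16) {
    lin <- which(pv$labels == p)
    comps <- brainNetDx:::connectedComponents3d(pv$labels == p, lin)
    expect_length(comps, 1L)
  }
  # determinism
  pv2 <- generateParcellation(vol, k = 16, seed = 3L)
  expect_identical(pv$labels, pv2$labels)
  expect_error(generateParcellation(vol, k = sum(vol) + 1L, seed = 1L),
               "exceeds")
})

test_that("a synthetic head mask splits into many contiguous parcels", {
  vol <- syntheticHeadMask(c(24L, 30L, 22L))
  expect_setequal(sort(unique(as.vector(vol[vol > 0]))), 1:3)
  k <- 96L
  pv <- generateParcellation(vol, k = k, seed = 11L)
  expect_identical(pv$labels > 0, vol > 0)
  expect_equal(sort(unique(pv$labels[pv$labels > 0])), seq_len(k))
  # parcels inherit their source region, so a cerebellar mask can be derived
  expect_equal(length(pv$parcelRegion), k)
  expect_true(all(pv$parcelRegion %in% 1:3))
  cerebParcels <- which(pv$parcelRegion == 3L)
  expect_true(length(cerebParcels) > 0)
  for (p in sample(seq_len(k), 8)) {
    lin <- which(pv$labels == p)
    expect_length(brainNetDx:::connectedComponents3d(pv$labels == p, lin), 1L)
    expect_true(all(vol[lin] == pv$parcelRegion[p]))
  }
})

test_that("parcellations round-trip through NIfTI", {
  vol <- array(0L, c(8, 8, 3)); vol[2:7, 2:7, ] <- 1L
  pv <- generateParcellation(vol, k = 5, seed = 2L)
  path <- tempfile(fileext = ".nii")
  writeParcellation(pv, path)
  back <- readParcellation(path)
  expect_identical(back$labels, pv$labels)
  unlink(path)
})
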