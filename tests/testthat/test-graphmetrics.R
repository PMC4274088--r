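test_that("path lengths follow the reciprocal-weight convention", {
  W <- unitPath3()
  d <- pathLengths(W)
  expect_equal(d[1, 3], 2)
  expect_equal(diag(d), rep(0, 3))
  expect_true(isSymmetric(d))

  # edge weight 2 -> length 0.5, checked against exhaustive enumeration
  W2 <- matrix(0, 2, 2); W2[1, 2] <- W2[2, 1] <- 2
  expect_equal(pathLengths(W2)[1, 2], 0.5)
  expect_equal(pathLengths(W2)[1, 2], brutePathLength(W2, 1, 2))

  # disconnected pair is Inf and contributes zero inverse distance
  W3 <- matrix(0, 3, 3); W3[1, 2] <- W3[2, 1] <- 1
  expect_equal(pathLengths(W3)[1, 3], Inf)
  expect_equal(globalEfficiency(W3), (1 / 1 + 1 / 1) / (3 * 2))

  # triangle inequality on a random graph
  set.seed(4)
  Wr <- randomWeightedGraph(7, 0.6)
  dr <- pathLengths(Wr)
  for (i in 1:7) for (j in 1:7) for (k in 1:7) {
    if (is.finite(dr[i, j]) && is.finite(dr[j, k]))
      expect_lte(dr[i, k], dr[i, j] + dr[j, k] + 1e-12)
  }
})

test_that("efficiencies reproduce closed-form cases", {
  expect_equal(globalEfficiency(unitComplete(5)), 1)
  expect_equal(globalEfficiency(unitPath3()), 5 / 6)
  expect_equal(globalEfficiency(matrix(0, 4, 4)), 0)

  star <- unitStar(3)
  eN <- nodalEfficiency(star)
  expect_equal(eN[1], 1)                        # hub reaches all at distance 1
  expect_equal(eN[2], (1 + 0.5 + 0.5) / 3)      # leaf
  expect_equal(nodalEfficiency(star, 2), 2 / 3)
  iso <- matrix(0, 4, 4); iso[1, 2] <- iso[2, 1] <- 1
  expect_equal(nodalEfficiency(iso)[4], 0)      # isolated node
  expect_error(nodalEfficiency(star, 9), "out of range")

  tri <- unitComplete(3)
  expect_equal(localEfficiency(tri)$eLocal, rep(1, 3))
  expect_equal(localEfficiency(unitPath3())$eLocal, rep(0, 3))
  expect_equal(localEfficiency(unitComplete(4))$eLocal, rep(1, 4))

  cp3 <- clusteringAndPath(tri)
  expect_equal(cp3$cp, 1)
  expect_equal(cp3$lp, 1)
  cpPath <- clusteringAndPath(unitPath3())
  expect_equal(cpPath$cp, 0)
  expect_equal(cpPath$lp, 4 / 3)
  cpStar <- clusteringAndPath(unitStar(3))
  expect_equal(cpStar$cp, 0)
  expect_equal(cpStar$cNode, rep(0, 4))
})

test_that("efficiencies match exhaustive path-enumeration oracles on random graphs", {
  set.seed(12)
  for (rep in 1:30) {
    n <- sample(4:7, 1)
    W <- randomWeightedGraph(n, stats::runif(1, 0.3, 0.8))
    expect_equal(globalEfficiency(W), bruteGlobalEfficiency(W),
                 tolerance = 1e-10)
    expect_equal(nodalEfficiency(W), bruteNodalEfficiency(W),
                 tolerance = 1e-10)
    expect_equal(localEfficiency(W)$eLocal, bruteLocalEfficiency(W),
                 tolerance = 1e-10)
    # mean-of-nodal equals global exactly
    expect_equal(mean(nodalEfficiency(W)), globalEfficiency(W),
                 tolerance = 1e-12)
  }
})

test_that("dense and igraph shortest-path backends agree", {
  set.seed(21)
  W <- randomWeightedGraph(60, 0.1)   # large enough to hit the igraph path
  dIg <- pathLengths(W)
  dFw <- brainNetDx:::.fwDist(ifelse(W > 0, 1 / W, Inf))
  expect_equal(dIg, dFw, tolerance = 1e-12)
})

test_that("adding an edge never decreases global efficiency", {
  set.seed(30)
  for (rep in 1:10) {
    W <- randomWeightedGraph(8, 0.3)
    off <- which(W == 0 & upper.tri(W), arr.ind = TRUE)
    if (nrow(off) == 0) next
    pick <- off[sample.int(nrow(off), 1), ]
    W2 <- W
    W2[pick[1], pick[2]] <- W2[pick[2], pick[1]] <- stats::runif(1, 0.2, 1.5)
    expect_gte(globalEfficiency(W2), globalEfficiency(W) - 1e-12)
  }
})

test_that("unit-weight graphs keep efficiencies and clustering in [0, 1]", {
  set.seed(33)
  for (rep in 1:8) {
    W <- randomWeightedGraph(8, stats::runif(1, 0.2, 0.9))
    W[W > 0] <- 1
    expect_true(globalEfficiency(W) >= 0 && globalEfficiency(W) <= 1)
    expect_true(all(localEfficiency(W)$eLocal >= 0 &
                    localEfficiency(W)$eLocal <= 1))
    cpl <- clusteringAndPath(W)
    expect_true(cpl$cp >= 0 && cpl$cp <= 1)
  }
  # weighted bound: e_glob cannot exceed the maximum edge weight
  set.seed(34)
  Wn <- randomWeightedGraph(10, 0.5)
  expect_lte(globalEfficiency(Wn), max(Wn))
})

test_that("degree-preserving nulls keep degrees and the weight multiset", {
  set.seed(40)
  W <- randomWeightedGraph(20, 0.25)
  ens <- degreePreservingNull(W, nNulls = 8L, seed = 5L, keepNulls = TRUE)
  degOrig <- rowSums(W > 0)
  wtsOrig <- sort(W[upper.tri(W) & W > 0])
  for (Wn in ens$nulls) {
    expect_equal(rowSums(Wn > 0), degOrig)
    expect_equal(sort(Wn[upper.tri(Wn) & Wn > 0]), wtsOrig)
  }
  ens2 <- degreePreservingNull(W, nNulls = 8L, seed = 5L)
  expect_equal(ens$meanEGlob, ens2$meanEGlob)
  expect_error(degreePreservingNull(matrix(0, 3, 3), nNulls = 2L, seed = 1L),
               "too few edges")
})

test_that("random graphs are close to their own degree-preserving null", {
  set.seed(55)
  g <- igraph::sample_gnp(60, 0.2)
  W <- igraph::as_adjacency_matrix(g, sparse = FALSE) * 1.0
  ens <- degreePreservingNull(W, nNulls = 20L, seed = 9L)
  eg <- globalEfficiency(W)
  expect_lt(abs(ens$meanEGlob - eg) / eg, 0.05)
})

test_that("small-world normalization is 1 against itself and detects lattices", {
  set.seed(60)
  W <- randomWeightedGraph(30, 0.2)
  eg <- globalEfficiency(W)
  el <- localEfficiency(W)$value
  self <- smallworldNormalize(eg, el, list(meanEGlob = eg, meanELoc = el))
  expect_equal(self$gamma, 1)
  expect_equal(self$lambda, 1)
  expect_equal(self$sigma, 1)
  expect_error(smallworldNormalize(eg, el, list(meanEGlob = 0, meanELoc = 1)),
               "positive")

  # Watts-Strogatz ring: sigma > 1
  set.seed(61)
  ws <- igraph::sample_smallworld(1, 100, 3, 0.1)
  Wws <- igraph::as_adjacency_matrix(ws, sparse = FALSE) * 1.0
  Wws[Wws > 1] <- 1
  ens <- degreePreservingNull(Wws, nNulls = 10L, seed = 4L)
  sw <- smallworldNormalize(globalEfficiency(Wws),
                            localEfficiency(Wws)$value, ens)
  expect_gt(sw$sigma, 1)
})

test_that("networkMetrics assembles aligned nodal and global tables", {
  cfg <- tinyConfig()
  s <- simulateCohort(cfg)[[1]]
  net <- buildNetwork(preprocessSubject(s))
  m <- networkMetrics(net, nNulls = 5L, seed = 2L)
  expect_equal(nrow(m$nodal), cfg@nRois)
  expect_named(m$nodal, c("node", "eNodal", "eLocal", "cNode", "lNode"))
  expect_equal(m$global$eGlob, globalEfficiency(net), tolerance = 1e-12)
  expect_equal(m$global$sigma, m$global$gamma / m$global$lambda,
               tolerance = 1e-12)
  expect_true(all(m$nodal$eNodal >= 0))
})
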