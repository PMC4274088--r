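# Independent oracles for graph metrics: exhaustive simple-path enumeration,
# deliberately separate from the package's shortest-path code paths.

# Minimum total length over all simple paths from i to j, where each edge
# contributes 1/weight. Depth-first enumeration; Inf if unreachable.
brutePathLength <- function(W, i, j) {
  n <- nrow(W)
  best <- Inf
  visit <- function(node, used, acc) {
    if (acc >= best) return()
    if (node == j) {
      best <<- acc
      return()
    }
    for (k in seq_len(n)) {
      if (!used[k] && W[node, k] > 0) {
        used[k] <- TRUE
        visit(k, used, acc + 1 / W[node, k])
        used[k] <- FALSE
      }
    }
  }
  used <- rep(FALSE, n)
  used[i] <- TRUE
  visit(i, used, 0)
  best
}

bruteDistMatrix <- function(W) {
  n <- nrow(W)
  d <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (i != j) d[i, j] <- brutePathLength(W, i, j)
  d
}

bruteGlobalEfficiency <- function(W) {
  n <- nrow(W)
  d <- bruteDistMatrix(W)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

bruteNodalEfficiency <- function(W) {
  n <- nrow(W)
  d <- bruteDistMatrix(W)
  inv <- 1 / d
  diag(inv) <- 0
  rowSums(inv) / (n - 1)
}

bruteLocalEfficiency <- function(W) {
  n <- nrow(W)
  sapply(seq_len(n), function(i) {
    nb <- which(W[i, ] > 0)
    if (length(nb) < 2) return(0)
    bruteGlobalEfficiency(W[nb, nb, drop = FALSE])
  })
}

# Random symmetric weighted graph on n nodes (weights in (0.2, 1.5)).
randomWeightedGraph <- function(n, density = 0.5) {
  W <- matrix(0, n, n)
  pairs <- which(upper.tri(W))
  on <- pairs[stats::runif(length(pairs)) < density]
  W[on] <- stats::runif(length(on), 0.2, 1.5)
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  W
}

# Tiny deterministic graphs used across tests
unitPath3 <- function() {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 1
  W[2, 3] <- W[3, 2] <- 1
  W
}

unitComplete <- function(n) {
  W <- matrix(1, n, n)
  diag(W) <- 0
  W
}

unitStar <- function(nLeaves) {
  n <- nLeaves + 1
  W <- matrix(0, n, n)
  W[1, 2:n] <- W[2:n, 1] <- 1
  W
}
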