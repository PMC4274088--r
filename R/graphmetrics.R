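# Weighted-graph efficiency and small-world metrics. Edge length is the
# reciprocal of edge weight (the standard convention for correlation-weighted
# connectomes); shortest paths on small graphs use a dense Floyd-Warshall,
# larger graphs go through igraph. Efficiency denominators always use the
# full node count, so isolated nodes dilute rather than vanish.

.asWeightMatrix <- function(net) {
  if (is(net, "FCNetwork")) net@weights else as.matrix(net)
}

# Dense Floyd-Warshall over a matrix of edge lengths (Inf = no edge).
.fwDist <- function(len) {
  d <- len
  diag(d) <- 0
  n <- nrow(d)
  for (k in seq_len(n)) {
    alt <- outer(d[, k], d[k, ], `+`)
    upd <- alt < d
    if (any(upd)) d[upd] <- alt[upd]
  }
  d
}

.igraphDist <- function(W, weighted = TRUE) {
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  wts <- if (weighted) 1 / igraph::E(g)$weight else NA
  d <- igraph::distances(g, weights = wts)
  dimnames(d) <- NULL
  d
}

#' Shortest-path length matrix
#'
#' All-pairs shortest paths where each kept edge contributes length
#' `1 / weight`; unreachable pairs are `Inf`, the diagonal 0.
#'
#' @param net An [FCNetwork-class] or a symmetric nonnegative weight matrix.
#' @return N x N symmetric matrix of path lengths.
#' @export
pathLengths <- function(net) {
  W <- .asWeightMatrix(net)
  n <- nrow(W)
  if (n <= 48L) {
    len <- ifelse(W > 0, 1 / W, Inf)
    .fwDist(len)
  } else {
    .igraphDist(W, weighted = TRUE)
  }
}

# Hop-count distances on the binarized topology.
.hopLengths <- function(W) {
  n <- nrow(W)
  if (n <= 48L) {
    len <- ifelse(W > 0, 1, Inf)
    .fwDist(len)
  } else {
    .igraphDist(W, weighted = FALSE)
  }
}

.efficiencyFromDist <- function(d) {
  n <- nrow(d)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Global efficiency
#'
#' Mean inverse shortest-path length over all ordered node pairs,
#' `E_glob = (1/(N(N-1))) sum_{i != j} 1/d_ij`, with `1/Inf = 0` for
#' unreachable pairs. Measures the network's capacity for parallel
#' information transfer.
#'
#' @param net An [FCNetwork-class] or weight matrix, N >= 2.
#' @return Scalar efficiency (in `[0, max weight]`).
#' @export
globalEfficiency <- function(net) {
  W <- .asWeightMatrix(net)
  if (nrow(W) < 2L) stop("invalid argument: need at least 2 nodes")
  .efficiencyFromDist(pathLengths(W))
}

#' Nodal efficiency
#'
#' Per-node mean inverse shortest-path length to all other nodes,
#' `E_nodal(i) = (1/(N-1)) sum_{j != i} 1/d_ij`. Averaging it over nodes
#' gives the global efficiency exactly.
#'
#' @param net An [FCNetwork-class] or weight matrix, N >= 2.
#' @param i Optional single node index; if `NULL`, the full vector.
#' @return Numeric vector of length N (or a scalar when `i` is given).
#' @export
nodalEfficiency <- function(net, i = NULL) {
  W <- .asWeightMatrix(net)
  n <- nrow(W)
  if (n < 2L) stop("invalid argument: need at least 2 nodes")
  d <- pathLengths(W)
  inv <- 1 / d
  diag(inv) <- 0
  e <- rowSums(inv) / (n - 1)
  if (is.null(i)) return(e)
  if (i < 1 || i > n) stop("node index out of range")
  e[[i]]
}

#' Local efficiency
#'
#' For each node, the global efficiency of the subgraph induced by its
#' neighbors (the node itself excluded, original weights kept); subgraphs
#' with fewer than two nodes score 0. The network-level local efficiency is
#' the mean over all nodes. Quantifies fault tolerance of communication in
#' each node's immediate neighborhood.
#'
#' @param net An [FCNetwork-class] or weight matrix.
#' @return A list with `eLocal` (per-node vector) and `value` (the mean).
#' @export
localEfficiency <- function(net) {
  W <- .asWeightMatrix(net)
  n <- nrow(W)
  e <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    if (length(nb) >= 2L) {
      sub <- W[nb, nb, drop = FALSE]
      e[i] <- .efficiencyFromDist(pathLengths(sub))
    }
  }
  list(eLocal = e, value = mean(e))
}

#' Clustering coefficient and characteristic path length
#'
#' Computed on the binarized topology (an edge wherever the weight is
#' positive). The clustering coefficient of node i is the number of edges
#' among its neighbors divided by `D_i (D_i - 1) / 2` (0 when the degree is
#' below 2); the network value is the mean over nodes. Path length uses
#' hop-count distances: `lNode[i]` is the mean distance from i to the nodes
#' it can reach (0 if none), and `lp` averages over all ordered reachable
#' pairs. The fraction of unreachable ordered pairs is reported alongside.
#'
#' @param net An [FCNetwork-class] or weight matrix, N >= 2.
#' @return List with `cp`, `lp`, `cNode`, `lNode`, `unreachableFraction`.
#' @export
clusteringAndPath <- function(net) {
  W <- .asWeightMatrix(net)
  n <- nrow(W)
  if (n < 2L) stop("invalid argument: need at least 2 nodes")
  A <- W > 0
  deg <- rowSums(A)
  cNode <- numeric(n)
  for (i in seq_len(n)) {
    if (deg[i] >= 2) {
      nb <- which(A[i, ])
      ei <- sum(A[nb, nb]) / 2
      cNode[i] <- ei / (deg[i] * (deg[i] - 1) / 2)
    }
  }
  d <- .hopLengths(W)
  diag(d) <- Inf          # exclude self-pairs from the means below
  finite <- is.finite(d)
  lNode <- numeric(n)
  for (i in seq_len(n)) {
    fi <- finite[i, ]
    lNode[i] <- if (any(fi)) mean(d[i, fi]) else 0
  }
  lp <- if (any(finite)) mean(d[finite]) else 0
  list(cp = mean(cNode), lp = lp, cNode = cNode, lNode = lNode,
       unreachableFraction = 1 - sum(finite) / (n * (n - 1)))
}

#' Degree-preserving random-network ensemble
#'
#' Builds `nNulls` surrogate networks that preserve the original degree
#' sequence exactly (double-edge-swap rewiring, 10 x edge-count attempted
#' swaps) and carry the original multiset of edge weights randomly permuted
#' onto the rewired edges. Returns the ensemble means of global efficiency,
#' local efficiency, clustering coefficient and path length, which serve as
#' the normalization denominators for the small-world coefficients.
#'
#' @param net An [FCNetwork-class] or weight matrix with at least 2 edges.
#' @param nNulls Number of surrogate networks.
#' @param seed Integer seed; the ensemble is deterministic under it.
#' @param keepNulls If `TRUE`, also return each null's weight matrix (used by
#'   tests; memory-heavy for large networks).
#' @return List with `nNulls`, `meanEGlob`, `meanELoc`, `meanCp`, `meanLp`,
#'   `seed`, and optionally `nulls`.
#' @export
degreePreservingNull <- function(net, nNulls = 100L, seed = 1L,
                                 keepNulls = FALSE) {
  W <- .asWeightMatrix(net)
  wts <- W[upper.tri(W)]
  wts <- wts[wts > 0]
  ec <- length(wts)
  if (ec < 2L) stop("too few edges to rewire (need at least 2)")
  g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected",
                                           diag = FALSE)
  set.seed(as.integer(seed))
  eg <- el <- cp <- lp <- numeric(nNulls)
  nulls <- if (keepNulls) vector("list", nNulls) else NULL
  for (b in seq_len(nNulls)) {
    gr <- igraph::rewire(g, igraph::keeping_degseq(niter = 10 * ec))
    Wn <- matrix(0, nrow(W), ncol(W))
    elist <- igraph::as_edgelist(gr, names = FALSE)
    wperm <- wts[sample.int(ec)]
    Wn[elist] <- wperm
    Wn[elist[, c(2, 1), drop = FALSE]] <- wperm
    eg[b] <- globalEfficiency(Wn)
    el[b] <- localEfficiency(Wn)$value
    cpl <- clusteringAndPath(Wn)
    cp[b] <- cpl$cp
    lp[b] <- cpl$lp
    if (keepNulls) nulls[[b]] <- Wn
  }
  out <- list(nNulls = as.integer(nNulls), meanEGlob = mean(eg),
              meanELoc = mean(el), meanCp = mean(cp), meanLp = mean(lp),
              seed = as.integer(seed))
  if (keepNulls) out$nulls <- nulls
  out
}

#' Small-world normalization
#'
#' Normalizes a network's efficiencies by the random-ensemble means:
#' `gamma = eLoc / meanELoc`, `lambda = eGlob / meanEGlob`,
#' `sigma = gamma / lambda`. A small-world network has gamma > 1 with
#' lambda close to 1, hence sigma > 1.
#'
#' @param eGlob,eLoc The network's global and local efficiency.
#' @param nulls Result of [degreePreservingNull()].
#' @return List with `gamma`, `lambda`, `sigma` (plus the inputs).
#' @export
smallworldNormalize <- function(eGlob, eLoc, nulls) {
  if (nulls$meanEGlob <= 0 || nulls$meanELoc <= 0)
    stop("null ensemble means must be positive for normalization")
  gamma <- eLoc / nulls$meanELoc
  lambda <- eGlob / nulls$meanEGlob
  list(eGlob = eGlob, eLoc = eLoc, gamma = gamma, lambda = lambda,
       sigma = gamma / lambda)
}

#' All per-node and global metrics of one network
#'
#' Computes nodal efficiency, local efficiency, clustering and path length
#' per node, their network-level values, and (when `nNulls > 0`) the
#' small-world coefficients against a degree-preserving null ensemble.
#'
#' @param net An [FCNetwork-class].
#' @param nNulls Null-ensemble size for normalization (0 skips it).
#' @param seed Seed for the null ensemble.
#' @return List with `nodal` (data.frame: node, eNodal, eLocal, cNode,
#'   lNode) and `global` (data.frame: eGlob, eLoc, cp, lp, gamma, lambda,
#'   sigma; the last three `NA` when `nNulls = 0`).
#' @export
networkMetrics <- function(net, nNulls = 0L, seed = 1L) {
  stopifnot(is(net, "FCNetwork"))
  W <- net@weights
  eNodal <- nodalEfficiency(W)
  le <- localEfficiency(W)
  cpl <- clusteringAndPath(W)
  eGlob <- mean(eNodal)
  gamma <- lambda <- sigma <- NA_real_
  if (nNulls > 0 && sum(W[upper.tri(W)] > 0) >= 2) {
    nulls <- degreePreservingNull(W, nNulls = nNulls, seed = seed)
    sw <- smallworldNormalize(eGlob, le$value, nulls)
    gamma <- sw$gamma; lambda <- sw$lambda; sigma <- sw$sigma
  }
  list(
    nodal = data.frame(node = net@nodeLabels, eNodal = eNodal,
                       eLocal = le$eLocal, cNode = cpl$cNode,
                       lNode = cpl$lNode, stringsAsFactors = FALSE),
    global = data.frame(eGlob = eGlob, eLoc = le$value, cp = cpl$cp,
                        lp = cpl$lp, gamma = gamma, lambda = lambda,
                        sigma = sigma)
  )
}
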