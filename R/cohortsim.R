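# Synthetic resting-state cohort generator: three groups, modular
# group-dependent covariance, localized group effects, shared nuisance
# contamination, and random contiguous parcellation of label volumes.

#' Create a cohort configuration
#'
#' Returns a validated [CohortConfig-class]. The defaults describe the study
#' conditions the rest of the package is calibrated against: 20 controls (NC),
#' 15 tremor-dominant (TPD) and 10 non-tremor-dominant (NTPD) subjects, 180
#' volumes at TR = 2 s, 128 regions in 8 equal correlation modules with
#' within-module correlation 0.4 and between-module correlation 0.1. Patient
#' groups differ from controls by a 0.25 decrement of the within-module
#' correlations incident to 10 known nodes; the last 16 nodes are designated
#' cerebellar so the cerebellum-free analysis arm can drop them.
#'
#' @param nPerGroup Named integer vector of group sizes (`NC`, `TPD`, `NTPD`).
#' @param nRois Number of regions; 128 is a desk-scale default, use 1024 to
#'   mirror a high-resolution random parcellation.
#' @param nModules Number of equal-size correlation modules.
#' @param nVolumes Acquired volumes per subject.
#' @param tr Repetition time, seconds.
#' @param rWithin,rBetween Within-/between-module correlations.
#' @param affectedNodes Indices (1-based) of the nodes carrying the group
#'   effect.
#' @param effectDelta Correlation decrement at affected nodes for the patient
#'   groups; scalar or named vector `c(TPD=, NTPD=)`.
#' @param cerebellumNodes Indices of the designated cerebellar nodes.
#' @param nuisanceLoading Loading of the shared confound mixture added to all
#'   regional series.
#' @param ageRange Uniform age range in years.
#' @param maleProb Probability of male gender.
#' @param seed Master seed; everything downstream is reproducible from it.
#' @return A [CohortConfig-class] object.
#' @examples
#' cfg <- cohortConfig(nRois = 32L, nModules = 4L)
#' cfg
#' @export
cohortConfig <- function(nPerGroup = c(NC = 20L, TPD = 15L, NTPD = 10L),
                         nRois = 128L,
                         nModules = 8L,
                         nVolumes = 180L,
                         tr = 2.0,
                         rWithin = 0.4,
                         rBetween = 0.1,
                         affectedNodes = 1:10,
                         effectDelta = 0.25,
                         cerebellumNodes = (nRois - 15L):nRois,
                         nuisanceLoading = 0.3,
                         ageRange = c(40, 80),
                         maleProb = 0.55,
                         seed = 1L) {
  if (any(nPerGroup < 0)) stop("group counts must be nonnegative")
  new("CohortConfig",
      nPerGroup = stats::setNames(as.integer(nPerGroup), names(nPerGroup)),
      nRois = as.integer(nRois), nModules = as.integer(nModules),
      nVolumes = as.integer(nVolumes), tr = as.numeric(tr),
      rWithin = rWithin, rBetween = rBetween,
      affectedNodes = as.integer(affectedNodes),
      effectDelta = effectDelta,
      cerebellumNodes = as.integer(cerebellumNodes),
      nuisanceLoading = nuisanceLoading,
      ageRange = as.numeric(ageRange), maleProb = maleProb,
      seed = as.integer(seed))
}

# Deterministic stage/subject seed derivation from one master seed.
# Affine step modulo the Mersenne prime 2^31 - 1 keeps seeds in int range.
deriveSeed <- function(master, offset) {
  as.integer((as.numeric(master) %% 2147483647 * 48271 + offset) %% 2147483647)
}

# Equal-size contiguous module labels for the nRois nodes.
moduleAssignment <- function(config) {
  sort(rep_len(seq_len(config@nModules), config@nRois))
}

effectDeltaFor <- function(config, group) {
  d <- config@effectDelta
  if (group == "NC") return(0)
  if (length(d) == 1L) unname(d) else unname(d[[group]])
}

#' Draw subject records for a cohort
#'
#' Generates one metadata record per subject: id, group, uniform age on the
#' configured range, Bernoulli gender. Deterministic under the config seed.
#'
#' @param config A [CohortConfig-class].
#' @return A data.frame with columns `subjectId`, `group`, `age`, `gender`,
#'   one row per subject, controls first.
#' @examples
#' table(makeCohort(cohortConfig(nRois = 16L, nModules = 2L))$group)
#' @export
makeCohort <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  counts <- config@nPerGroup[GROUP_LEVELS]
  groups <- rep(GROUP_LEVELS, times = counts)
  n <- length(groups)
  ids <- unlist(lapply(GROUP_LEVELS, function(g)
    sprintf("%s_%02d", g, seq_len(counts[[g]]))), use.names = FALSE)
  set.seed(deriveSeed(config@seed, 1L))
  age <- stats::runif(n, config@ageRange[1], config@ageRange[2])
  gender <- ifelse(stats::runif(n) < config@maleProb, "M", "F")
  df <- data.frame(subjectId = ids, group = groups, age = age,
                   gender = gender, stringsAsFactors = FALSE)
  rownames(df) <- df$subjectId
  df
}

#' Group-level ROI correlation matrix
#'
#' Builds the modular target correlation matrix of one group: `rWithin` inside
#' modules, `rBetween` across, unit diagonal. For patient groups, every
#' within-module correlation incident to an affected node is reduced by the
#' group's effect delta. The result is then projected to the nearest
#' positive-definite correlation matrix by eigenvalue clipping (floor 1e-6)
#' followed by rescaling to unit diagonal.
#'
#' @param config A [CohortConfig-class].
#' @param group `"NC"`, `"TPD"` or `"NTPD"`.
#' @param clip If `FALSE`, return the raw block construction before the
#'   positive-definite projection (useful for structural checks).
#' @return N x N correlation matrix.
#' @export
buildGroupCorrelation <- function(config, group, clip = TRUE) {
  stopifnot(is(config, "CohortConfig"), group %in% GROUP_LEVELS)
  n <- config@nRois
  mod <- moduleAssignment(config)
  same <- outer(mod, mod, "==")
  R <- matrix(config@rBetween, n, n)
  R[same] <- config@rWithin
  delta <- effectDeltaFor(config, group)
  if (delta > 0 && length(config@affectedNodes)) {
    aff <- logical(n)
    aff[config@affectedNodes] <- TRUE
    hit <- same & outer(aff, aff, "|")
    R[hit] <- R[hit] - delta
  }
  diag(R) <- 1
  if (!clip) return(R)
  R <- nearestPDCorrelation(R)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("group correlation matrix is not positive-definite after clipping")
  R
}

# Eigenvalue-clip a symmetric matrix to positive-definiteness, then rescale
# to unit diagonal so it remains a correlation matrix.
nearestPDCorrelation <- function(R, floor = 1e-6) {
  e <- eigen(R, symmetric = TRUE)
  v <- pmax(e$values, floor)
  S <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(S))
  S <- S / outer(d, d)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  S
}

#' Simulate one subject's regional time series
#'
#' Draws `nVolumes` i.i.d. multivariate-normal rows with the subject's group
#' correlation matrix (through its Cholesky factor), generates six AR(1)
#' rigid-body motion series (coefficient 0.9, unit innovations) plus AR(1)
#' white-matter and CSF confound series, and adds `nuisanceLoading` times a
#' shared standardized confound mixture (WM + CSF + first motion parameter) to
#' every regional series. The mixture lies in the span of the nuisance
#' regressors, so downstream nuisance regression can remove it exactly.
#'
#' @param record A one-row data.frame (or list) with `subjectId`, `group`,
#'   `age`, `gender`, as produced by [makeCohort()].
#' @param config A [CohortConfig-class].
#' @param seed Integer seed for this subject's draw.
#' @param cholFactor Optional pre-computed upper Cholesky factor of the
#'   group's correlation matrix (a speed-up when simulating whole cohorts).
#' @return A [SimulatedSubject-class].
#' @export
simulateSubject <- function(record, config, seed, cholFactor = NULL) {
  stopifnot(is(config, "CohortConfig"))
  Tn <- config@nVolumes
  if (Tn < 3L) stop("invalid config: need at least 3 volumes")
  N <- config@nRois
  if (is.null(cholFactor))
    cholFactor <- chol(buildGroupCorrelation(config, record$group))
  set.seed(as.integer(seed))
  X <- matrix(stats::rnorm(Tn * N), Tn, N) %*% cholFactor
  ar1 <- function(m) as.numeric(stats::filter(stats::rnorm(m), 0.9,
                                              method = "recursive"))
  motion <- sapply(seq_len(6L), function(i) ar1(Tn))
  wm <- ar1(Tn)
  csf <- ar1(Tn)
  nuis <- cbind(motion, wm, csf)
  colnames(nuis) <- c(paste0("mot", 1:6), "wm", "csf")
  if (config@nuisanceLoading > 0) {
    zs <- function(x) (x - mean(x)) / stats::sd(x)
    mixture <- (zs(wm) + zs(csf) + zs(motion[, 1])) / sqrt(3)
    X <- X + config@nuisanceLoading * mixture
  }
  colnames(X) <- sprintf("ROI_%04d", seq_len(N))
  new("SimulatedSubject",
      subjectId = as.character(record$subjectId),
      group = as.character(record$group),
      age = as.numeric(record$age),
      gender = as.character(record$gender),
      timeseries = X, nuisance = nuis, tr = config@tr,
      trueAffected = config@affectedNodes)
}

#' Simulate a whole cohort
#'
#' Draws the subject records with [makeCohort()] and simulates each subject's
#' time series with a per-subject seed derived from the config seed, so the
#' whole cohort is reproducible from one integer.
#'
#' @param config A [CohortConfig-class].
#' @return A list of [SimulatedSubject-class], in record order.
#' @export
simulateCohort <- function(config) {
  records <- makeCohort(config)
  chols <- lapply(stats::setNames(nm = GROUP_LEVELS), function(g)
    chol(buildGroupCorrelation(config, g)))
  lapply(seq_len(nrow(records)), function(i)
    simulateSubject(records[i, ], config,
                    seed = deriveSeed(config@seed, 100L + i),
                    cholFactor = chols[[records$group[i]]]))
}

# ---------------------------------------------------------------------------
# Random contiguous parcellation of integer label volumes
# ---------------------------------------------------------------------------

# 6-connected neighbor linear indices of voxel coordinates (matrix V x 3)
# within dims, returned as a list of index vectors aligned with the input.
.neighborOffsets <- matrix(c(-1, 0, 0, 1, 0, 0, 0, -1, 0, 0, 1, 0,
                             0, 0, -1, 0, 0, 1), ncol = 3, byrow = TRUE)

# Connected components (6-connectivity) of a logical 3D mask restricted to
# the voxels in `lin` (linear indices). Returns a list of linear-index sets.
connectedComponents3d <- function(mask, lin) {
  dims <- dim(mask)
  inset <- array(FALSE, dims)
  inset[lin] <- TRUE
  seen <- array(FALSE, dims)
  comps <- list()
  for (start in lin) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    members <- integer(0)
    while (length(queue)) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      members <- c(members, v)
      co <- arrayInd(v, dims)
      nb <- sweep(.neighborOffsets, 2, as.integer(co), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
            nb[, 2] >= 1 & nb[, 2] <= dims[2] &
            nb[, 3] >= 1 & nb[, 3] <= dims[3]
      if (any(ok)) {
        nl <- nb[ok, 1] + (nb[ok, 2] - 1) * dims[1] +
              (nb[ok, 3] - 1) * dims[1] * dims[2]
        nl <- nl[inset[nl] & !seen[nl]]
        if (length(nl)) {
          seen[nl] <- TRUE
          queue <- c(queue, nl)
        }
      }
    }
    comps[[length(comps) + 1L]] <- members
  }
  comps
}

# Largest-remainder allocation of k parcels across components, minimum 1 each.
.allocateParcels <- function(sizes, k) {
  m <- length(sizes)
  if (k < m)
    stop("k must be at least the number of connected regions (", m, ")")
  quota <- sizes / sum(sizes) * (k - m)
  base <- floor(quota)
  alloc <- 1L + as.integer(base)
  rem <- k - sum(alloc)
  if (rem > 0) {
    ord <- order(quota - base, decreasing = TRUE)
    alloc[ord[seq_len(rem)]] <- alloc[ord[seq_len(rem)]] + 1L
  }
  # a tiny component cannot hold more parcels than voxels; push excess to the
  # component with the most remaining room, one parcel at a time
  while (any(alloc > sizes)) {
    i <- which(alloc > sizes)[1]
    alloc[i] <- alloc[i] - 1L
    j <- which.max(sizes - alloc)
    alloc[j] <- alloc[j] + 1L
  }
  alloc
}

# sample() that never interprets a length-1 vector as 1:n
shuffle <- function(x) x[sample.int(length(x))]

# Balanced multi-source region growing: split one connected voxel set into
# m contiguous parcels of near-equal size. Round-robin growth: each parcel
# claims one frontier voxel per round while it can still grow.
.growParcels <- function(lin, m, dims) {
  nv <- length(lin)
  if (m == 1L) return(stats::setNames(rep(1L, nv), lin))
  assign_arr <- integer(prod(dims))        # 0 = unassigned / outside
  inset <- logical(prod(dims))
  inset[lin] <- TRUE
  co <- arrayInd(lin, dims)
  seeds <- lin[sample.int(nv, m)]
  stacks <- vector("list", m)
  nbrOf <- function(v) {
    x <- (v - 1L) %% dims[1] + 1L
    y <- ((v - 1L) %/% dims[1]) %% dims[2] + 1L
    z <- (v - 1L) %/% (dims[1] * dims[2]) + 1L
    nb <- integer(0)
    if (x > 1L) nb <- c(nb, v - 1L)
    if (x < dims[1]) nb <- c(nb, v + 1L)
    if (y > 1L) nb <- c(nb, v - dims[1])
    if (y < dims[2]) nb <- c(nb, v + dims[1])
    if (z > 1L) nb <- c(nb, v - dims[1] * dims[2])
    if (z < dims[3]) nb <- c(nb, v + dims[1] * dims[2])
    nb[inset[nb]]
  }
  for (p in seq_len(m)) {
    v <- seeds[p]
    assign_arr[v] <- p
    stacks[[p]] <- shuffle(nbrOf(v))
  }
  active <- seq_len(m)
  while (length(active)) {
    still <- integer(0)
    for (p in active) {
      st <- stacks[[p]]
      grown <- FALSE
      while (length(st)) {
        v <- st[length(st)]
        st <- st[-length(st)]
        if (assign_arr[v] == 0L) {
          assign_arr[v] <- p
          nb <- nbrOf(v)
          nb <- nb[assign_arr[nb] == 0L]
          if (length(nb)) st <- c(st, shuffle(nb))
          grown <- TRUE
          break
        }
      }
      stacks[[p]] <- st
      if (grown || length(st)) still <- c(still, p)
    }
    active <- still
  }
  stats::setNames(assign_arr[lin], lin)
}

#' Random contiguous parcellation of a label volume
#'
#' Splits each connected region of an integer 3D label volume into contiguous
#' parcels by seeded balanced region growing, until exactly `k` parcels exist
#' in total. Parcels are allocated to regions proportionally to region size
#' (at least one each) and grown round-robin from random seed voxels, which
#' keeps parcel sizes near the mean. 6-connectivity throughout. Deterministic
#' under the seed; if the size balance (all parcels within a factor 3 of the
#' mean) fails, growth is reseeded up to five times before a warning.
#'
#' @param labelVolume 3D integer array; 0 is background, positive labels are
#'   regions to subdivide.
#' @param k Total number of parcels (>= number of connected regions,
#'   <= number of nonzero voxels).
#' @param seed Integer seed.
#' @return An object of class `ParcelVolume`: a list with `labels` (3D
#'   integer array of parcel ids 1..k), `nParcels`, and `parcelRegion`
#'   (integer vector mapping each parcel id to its source region label).
#' @examples
#' vol <- array(0L, c(8, 8, 3)); vol[2:7, 2:7, ] <- 1L
#' pv <- generateParcellation(vol, k = 6, seed = 1)
#' table(pv$labels[pv$labels > 0])
#' @export
generateParcellation <- function(labelVolume, k, seed) {
  stopifnot(length(dim(labelVolume)) == 3L, k >= 1)
  dims <- dim(labelVolume)
  nz <- which(labelVolume > 0)
  if (k > length(nz))
    stop("invalid config: k exceeds the number of nonzero voxels")
  set.seed(as.integer(seed))
  comps <- list()
  regionOf <- integer(0)
  for (lab in sort(unique(labelVolume[nz]))) {
    cc <- connectedComponents3d(labelVolume == lab, which(labelVolume == lab))
    comps <- c(comps, cc)
    regionOf <- c(regionOf, rep(as.integer(lab), length(cc)))
  }
  alloc <- .allocateParcels(lengths(comps), k)
  out <- array(0L, dims)
  parcelRegion <- integer(k)
  nextId <- 0L
  meanSize <- length(nz) / k
  for (ci in seq_along(comps)) {
    m <- alloc[ci]
    lin <- comps[[ci]]
    best <- NULL
    for (attempt in 1:5) {
      a <- .growParcels(lin, m, dims)
      sizes <- tabulate(a, m)
      if (all(sizes >= meanSize / 3) && all(sizes <= meanSize * 3)) {
        best <- a
        break
      }
      if (is.null(best)) best <- a
    }
    sizes <- tabulate(best, m)
    if (any(sizes < meanSize / 3) || any(sizes > meanSize * 3))
      warning("parcel sizes outside a factor 3 of the mean in region ",
              regionOf[ci])
    out[lin] <- nextId + best
    parcelRegion[nextId + seq_len(m)] <- regionOf[ci]
    nextId <- nextId + m
  }
  structure(list(labels = out, nParcels = as.integer(k),
                 parcelRegion = parcelRegion),
            class = "ParcelVolume")
}

#' @export
print.ParcelVolume <- function(x, ...) {
  cat(sprintf("ParcelVolume: %d parcels over %d voxels (%s grid)\n",
              x$nParcels, sum(x$labels > 0),
              paste(dim(x$labels), collapse = "x")))
  invisible(x)
}

#' Synthetic head label volume
#'
#' Builds a small synthetic integer label volume with two cerebral hemisphere
#' ellipsoids (labels 1 and 2) and a posterior-inferior cerebellar ellipsoid
#' (label 3), for exercising random parcellation without any real atlas.
#'
#' @param dims Grid dimensions.
#' @return 3D integer array of labels (0 = background).
#' @export
syntheticHeadMask <- function(dims = c(36L, 44L, 32L)) {
  g <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                   z = seq_len(dims[3]))
  inEllipsoid <- function(cx, cy, cz, ax, ay, az)
    ((g$x - cx) / ax)^2 + ((g$y - cy) / ay)^2 + ((g$z - cz) / az)^2 <= 1
  cer <- inEllipsoid(dims[1] / 2 + 0.5, dims[2] * 0.55, dims[3] * 0.58,
                     dims[1] * 0.42, dims[2] * 0.36, dims[3] * 0.34)
  cbl <- inEllipsoid(dims[1] / 2 + 0.5, dims[2] * 0.22, dims[3] * 0.24,
                     dims[1] * 0.26, dims[2] * 0.15, dims[3] * 0.16)
  lab <- integer(nrow(g))
  lab[cer & g$x <= dims[1] / 2] <- 1L
  lab[cer & g$x > dims[1] / 2] <- 2L
  lab[cbl & lab == 0L] <- 3L
  array(lab, dims)
}
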