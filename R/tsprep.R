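# Temporal preprocessing of regional time series: volume dropping, linear
# detrending, ideal Fourier bandpass, 24-parameter motion expansion and
# nuisance regression. Spatial preprocessing is out of scope here; these
# operations act column-wise on a T x N matrix and commute with any
# permutation of the columns.

#' Discard initial volumes
#'
#' Removes the first `k` rows (volumes) of a regional time-series matrix,
#' the usual guard against scanner non-equilibrium at acquisition start.
#'
#' @param ts T x N numeric matrix (volumes by regions).
#' @param k Number of initial volumes to drop; must be < T.
#' @return The matrix with rows `(k+1):T`.
#' @examples
#' nrow(dropInitialVolumes(matrix(0, 180, 4), 5))  # 175
#' @export
dropInitialVolumes <- function(ts, k) {
  ts <- as.matrix(ts)
  if (k < 0 || k >= nrow(ts))
    stop("invalid argument: k must lie in [0, T)")
  if (k == 0) return(ts)
  ts[-seq_len(k), , drop = FALSE]
}

#' Remove linear trends
#'
#' Replaces every column by its residual from an ordinary least-squares fit on
#' an intercept and the volume index. Output columns have zero mean and zero
#' least-squares slope; the operation is idempotent.
#'
#' @param ts T x N numeric matrix, T >= 3.
#' @return Detrended matrix of the same shape.
#' @export
detrendLinear <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3L) stop("need at least 3 volumes to detrend")
  X <- cbind(1, seq_len(nrow(ts)))
  qr.resid(qr(X), ts)
}

#' Ideal Fourier bandpass filter
#'
#' Zeroes every discrete-Fourier coefficient whose frequency falls outside
#' `[lowHz, highHz]` and inverts the transform. The filter has an exactly
#' rectangular frequency response, so pure tones inside the band pass
#' unchanged and tones outside are fully suppressed (up to leakage of
#' non-bin-centered tones). No padding is applied.
#'
#' @param ts T x N numeric matrix.
#' @param lowHz,highHz Passband edges in Hz, `0 <= lowHz < highHz <= 1/(2 tr)`.
#' @param tr Repetition time in seconds (sampling interval).
#' @return Filtered real matrix of the same shape.
#' @export
bandpassFilter <- function(ts, lowHz = 0.01, highHz = 0.1, tr = 2.0) {
  ts <- as.matrix(ts)
  nyquist <- 1 / (2 * tr)
  if (lowHz < 0 || highHz <= lowHz || highHz > nyquist + 1e-12)
    stop("invalid argument: band must satisfy 0 <= low < high <= Nyquist (",
         format(nyquist), " Hz)")
  Tn <- nrow(ts)
  freq <- pmin(0:(Tn - 1), Tn - (0:(Tn - 1))) / (Tn * tr)
  keep <- freq >= lowHz - 1e-12 & freq <= highHz + 1e-12
  Fc <- stats::mvfft(ts)
  Fc[!keep, ] <- 0
  Re(stats::mvfft(Fc, inverse = TRUE)) / Tn
}

#' Expand 6 motion parameters to the 24-parameter set
#'
#' Builds the Friston 24-parameter motion regressor set from six rigid-body
#' parameters: the parameters themselves, their one-volume-lagged versions
#' (first row zero-padded), and the squares of both.
#'
#' @param motion6 T x 6 numeric matrix.
#' @return A list with `values` (T x 24 matrix) and `columnRoles` (character
#'   vector of `motion`, `motion_lag`, `motion_sq`, `motion_lag_sq`).
#' @export
expandMotion24 <- function(motion6) {
  motion6 <- as.matrix(motion6)
  if (ncol(motion6) != 6L)
    stop("invalid argument: expected exactly 6 motion columns")
  lagged <- rbind(0, motion6[-nrow(motion6), , drop = FALSE])
  values <- cbind(motion6, lagged, motion6^2, lagged^2)
  roles <- rep(c("motion", "motion_lag", "motion_sq", "motion_lag_sq"),
               each = 6L)
  colnames(values) <- paste0(roles, "_", rep(1:6, times = 4))
  list(values = values, columnRoles = roles)
}

#' Regress nuisance signals out of regional time series
#'
#' Returns the least-squares residuals of every regional column on the
#' nuisance design plus an intercept. Residuals are orthogonal to every
#' nuisance column and have zero mean.
#'
#' @param ts T x N numeric matrix.
#' @param nuisance T x P numeric matrix of nuisance regressors.
#' @return Residual matrix of the same shape as `ts`.
#' @export
regressNuisance <- function(ts, nuisance) {
  ts <- as.matrix(ts)
  nuisance <- as.matrix(nuisance)
  if (nrow(ts) != nrow(nuisance))
    stop("time series and nuisance matrices must have the same rows")
  X <- cbind(`(intercept)` = 1, nuisance)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
    stop("nuisance design is rank-deficient; linearly dependent columns: ",
         paste(dropped, collapse = ", "))
  }
  qr.resid(qrX, ts)
}

#' Full temporal preprocessing chain for one subject
#'
#' Applies the chain drop -> detrend -> bandpass -> nuisance regression to a
#' simulated subject, expanding the six motion parameters to 24 and appending
#' the WM and CSF signals (26 nuisance regressors plus intercept). The
#' nuisance series are row-dropped to stay aligned with the data but are not
#' themselves filtered.
#'
#' @param subject A [SimulatedSubject-class].
#' @param drop Number of initial volumes to discard.
#' @param lowHz,highHz Bandpass edges in Hz.
#' @return T' x N matrix of cleaned regional time series.
#' @export
preprocessSubject <- function(subject, drop = 5L, lowHz = 0.01, highHz = 0.1) {
  stopifnot(is(subject, "SimulatedSubject"))
  x <- dropInitialVolumes(subject@timeseries, drop)
  nuis <- dropInitialVolumes(subject@nuisance, drop)
  x <- detrendLinear(x)
  x <- bandpassFilter(x, lowHz, highHz, tr = subject@tr)
  m24 <- expandMotion24(nuis[, 1:6, drop = FALSE])
  design <- cbind(m24$values, wm = nuis[, "wm"], csf = nuis[, "csf"])
  regressNuisance(x, design)
}
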