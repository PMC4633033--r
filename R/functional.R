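# Functional connectivity: ROI time-series cleaning (nuisance regression,
# Fourier band-pass, run concatenation), Pearson/Fisher-z correlation
# matrices and region-level mean functional connectivity.

#' Construct an ROI time-series object
#'
#' @param subject_id Subject identifier.
#' @param values Numeric matrix, rows = time points, columns = regions
#'   (column names should be region ids or names). All values finite.
#' @param sampling_interval Sampling interval (TR) in seconds.
#' @return Object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(subject_id, values, sampling_interval = 0.72) {
  values <- as.matrix(values)
  if (!is.numeric(values) || any(!is.finite(values)))
    stop_invalid("time-series values must be a finite numeric matrix")
  check_scalar(sampling_interval, "sampling_interval",
               lo = .Machine$double.xmin)
  structure(list(subject_id = as.character(subject_id), values = values,
                 sampling_interval = sampling_interval),
            class = "roi_timeseries")
}

#' Regress nuisance signals out of every region's time series
#'
#' Replaces each region's series by its residual after least-squares
#' projection onto an intercept plus the supplied nuisance columns (e.g.
#' motion parameters, white-matter and CSF signals). With no nuisance
#' columns this is plain demeaning.
#'
#' @param ts A [roi_timeseries()].
#' @param nuisance Numeric matrix with one row per time point and one column
#'   per nuisance regressor, or `NULL` for intercept-only.
#' @return A `roi_timeseries` of residuals.
#' @export
regress_nuisance <- function(ts, nuisance = NULL) {
  stopifnot(inherits(ts, "roi_timeseries"))
  n_t <- nrow(ts$values)
  if (is.null(nuisance)) nuisance <- matrix(0, n_t, 0L)
  nuisance <- as.matrix(nuisance)
  if (nrow(nuisance) != n_t)
    stop_invalid("nuisance must have one row per time point")
  if (ncol(nuisance) + 1L >= n_t)
    stop_invalid("nuisance design has as many columns as time points; ",
                 "residuals would be identically zero")
  X <- cbind(1, nuisance)
  resid <- qr.resid(qr(X), ts$values)
  roi_timeseries(ts$subject_id, resid, ts$sampling_interval)
}

#' Band-pass filter ROI time series with a hard Fourier mask
#'
#' Discrete-Fourier-transform filter: coefficients at frequencies outside
#' `[f_lo, f_hi]` are zeroed (the DC component is always removed) and the
#' inverse transform is returned. This mirrors the Fourier-mask filtering
#' conventionally applied to resting-state data; the default band
#' 0.009-0.08 Hz isolates slow hemodynamic fluctuations.
#'
#' @param ts A [roi_timeseries()].
#' @param f_lo,f_hi Pass-band edges in Hz; `0 <= f_lo < f_hi <= ` Nyquist
#'   (`1 / (2 * sampling_interval)`).
#' @return A filtered `roi_timeseries`.
#' @export
bandpass <- function(ts, f_lo = 0.009, f_hi = 0.08) {
  stopifnot(inherits(ts, "roi_timeseries"))
  check_scalar(f_lo, "f_lo", lo = 0)
  check_scalar(f_hi, "f_hi", lo = 0)
  nyq <- 1 / (2 * ts$sampling_interval)
  if (f_lo >= f_hi) stop_invalid("f_lo must be strictly below f_hi")
  if (f_hi > nyq + 1e-12)
    stop_invalid(sprintf("f_hi = %g Hz exceeds the Nyquist frequency %g Hz",
                         f_hi, nyq))
  n_t <- nrow(ts$values)
  k <- 0:(n_t - 1L)
  freq <- pmin(k, n_t - k) / (n_t * ts$sampling_interval)
  keep <- freq >= f_lo & freq <= f_hi & k != 0L
  co <- stats::mvfft(ts$values)
  co[!keep, ] <- 0
  filtered <- Re(stats::mvfft(co, inverse = TRUE)) / n_t
  roi_timeseries(ts$subject_id, filtered, ts$sampling_interval)
}

#' Concatenate two runs of the same subject
#'
#' Each run is demeaned per region before stacking in time, so a constant
#' offset between acquisitions (e.g. two phase encodings) cannot masquerade
#' as shared signal.
#'
#' @param ts_a,ts_b Two [roi_timeseries()] with identical region sets and
#'   sampling interval.
#' @return The concatenated `roi_timeseries`.
#' @export
concatenate_runs <- function(ts_a, ts_b) {
  stopifnot(inherits(ts_a, "roi_timeseries"), inherits(ts_b, "roi_timeseries"))
  if (ncol(ts_a$values) != ncol(ts_b$values))
    stop_invalid("runs have different region counts and cannot be concatenated")
  if (!isTRUE(all.equal(ts_a$sampling_interval, ts_b$sampling_interval)))
    stop_invalid("runs have different sampling intervals")
  demean <- function(m) sweep(m, 2L, colMeans(m))
  roi_timeseries(ts_a$subject_id,
                 rbind(demean(ts_a$values), demean(ts_b$values)),
                 ts_a$sampling_interval)
}

#' Fisher r-to-z transform
#'
#' `z = atanh(r)`, the variance-stabilizing transform of a Pearson
#' correlation. Correlations of exactly +/-1 are clamped to
#' `+/-(1 - 1e-7)` before the transform so the result stays finite.
#'
#' @param r_value Correlation value(s) with `|r| <= 1`.
#' @return Transformed value(s).
#' @export
fisher_z <- function(r_value) {
  if (any(!is.finite(r_value)) || any(abs(r_value) > 1 + 1e-12))
    stop_invalid("fisher_z requires |r| <= 1")
  r <- pmin(pmax(r_value, -(1 - 1e-7)), 1 - 1e-7)
  atanh(r)
}

#' Build a subject's functional connectivity network
#'
#' Edge values are Pearson correlations between the (pre-processed) time
#' series of region pairs; the matrix is additionally Fisher r-to-z
#' transformed, and each region's mean functional connectivity -- the mean
#' of its z values to all other regions, a scaled degree centrality -- is
#' computed.
#'
#' @param ts A [roi_timeseries()]; every region must have nonzero variance.
#' @return Object of class `functional_network`: list with `subject_id`,
#'   `r` (correlation matrix, diagonal 1), `z` (Fisher-z matrix, diagonal 0)
#'   and `mean_fc` (per-region vector).
#' @export
correlation_matrix <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  sds <- apply(ts$values, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(ts$values)[sds == 0] %||% which(sds == 0)
    stop_invalid("zero-variance region(s): ",
                 paste(utils::head(bad, 5L), collapse = ", "))
  }
  r <- stats::cor(ts$values)
  z <- fisher_z(r)
  diag(z) <- 0
  n <- ncol(r)
  mean_fc <- if (n >= 2L) rowSums(z) / (n - 1L) else rep(NA_real_, n)
  structure(list(subject_id = ts$subject_id, r = r, z = z, mean_fc = mean_fc),
            class = "functional_network")
}

#' Mean functional connectivity of one region
#'
#' The mean of the region's Fisher-z correlations with all other regions
#' (self-correlation excluded) -- a scaled version of weighted degree
#' centrality, quantifying the region's importance for information flow.
#'
#' @param net A [correlation_matrix()] result.
#' @param region Region index (1-based) or name.
#' @return Scalar mean functional connectivity.
#' @export
mean_functional_connectivity <- function(net, region) {
  stopifnot(inherits(net, "functional_network"))
  n <- length(net$mean_fc)
  if (n < 2L) stop_invalid("mean functional connectivity needs >= 2 regions")
  if (is.character(region)) {
    idx <- match(region, rownames(net$z))
  } else {
    idx <- as.integer(region)
    if (is.na(idx) || idx < 1L || idx > n) idx <- NA_integer_
  }
  if (is.na(idx))
    stop_invalid(sprintf("unknown region '%s'", as.character(region)))
  net$mean_fc[[idx]]
}

#' @export
print.functional_network <- function(x, ...) {
  cat(sprintf("<functional_network> subject %s: %d regions, mean |r| = %.3f\n",
              x$subject_id, ncol(x$r),
              mean(abs(x$r[upper.tri(x$r)]))))
  invisible(x)
}
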