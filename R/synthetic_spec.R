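# Synthetic cohort specification: the statistical conditions the analysis
# assumes (group sizes, BMI distributions, planted edge effects,
# structure-function coupling, BMI signal fraction).

#' Default planted structural edges
#'
#' Ten edges, each joining a reward-system region (indices 1-8 in the
#' default atlas: bilateral thalamus, insula, putamen and superior
#' orbitofrontal cortex) to a partner region (indices 9-18), mirroring the
#' layout of reward-touching connections typically reported in obesity
#' connectomics. Requires an atlas of at least 18 regions; smaller atlases
#' default to no planted edges.
#'
#' @param n_regions Atlas size.
#' @param d Cohen's d of the planted group difference in fiber density.
#' @return Data frame with columns `u`, `v`, `d`.
#' @export
default_planted_edges <- function(n_regions, d = 1.2) {
  if (n_regions < 18L) return(data.frame(u = integer(0), v = integer(0),
                                         d = numeric(0)))
  data.frame(
    u = c(1L, 2L, 2L, 3L, 4L, 5L, 6L, 6L, 7L, 8L),
    v = c(9L, 10L, 11L, 12L, 13L, 14L, 10L, 15L, 16L, 17L),
    d = d
  )
}

#' Default structure-function coupling targets
#'
#' Six of the planted edges are coupled to the mean functional connectivity
#' of one endpoint region, with target correlations spanning the 0.26-0.52
#' range observed for fiber-density / degree-centrality coupling. One
#' region (right putamen, index 6) is the target of two edges, so the
#' deduplication bookkeeping downstream is exercised by default.
#'
#' @param n_regions Atlas size (>= 18 for the default set).
#' @return Data frame with columns `u`, `v`, `target_region`, `target_r`.
#' @export
default_coupling_edges <- function(n_regions) {
  if (n_regions < 18L)
    return(data.frame(u = integer(0), v = integer(0),
                      target_region = integer(0), target_r = numeric(0)))
  data.frame(
    u = c(2L, 4L, 6L, 6L, 7L, 8L),
    v = c(11L, 13L, 10L, 15L, 16L, 17L),
    target_region = c(2L, 4L, 6L, 6L, 7L, 8L),
    target_r = c(0.30, 0.26, 0.35, 0.33, 0.45, 0.44)
  )
}

#' Default BMI driver features
#'
#' BMI is driven by three structural edges and two functional (mean
#' connectivity) regions; coefficients are proportional to the square roots
#' of the single-feature R-squared magnitudes typical for these feature
#' classes, so the functional degree-centrality of the right thalamus
#' carries the largest weight.
#'
#' @return Data frame with columns `feature` (`"SC:u-v"` / `"FC:r"` ids)
#'   and `coefficient`.
#' @export
default_bmi_drivers <- function() {
  data.frame(
    feature = c("SC:2-11", "SC:6-15", "SC:7-16", "FC:8", "FC:2"),
    coefficient = c(0.244, 0.187, 0.176, 0.259, 0.453),
    stringsAsFactors = FALSE
  )
}

#' Build a synthetic cohort specification
#'
#' Captures the study conditions the generator emulates: two groups of 60
#' with BMI ~ Normal(22.53, 1.37^2) below and Normal(32.55, 3.60^2) at or
#' above the 25 kg/m^2 boundary, a 116-region parcellation, streamline
#' lengths on [20, 500] mm with truncated mean 26.2 mm, planted group
#' differences in a small reward-touching edge set, structure-function
#' coupling correlations in the 0.26-0.52 range, and a linear BMI link with
#' signal fraction 0.57.
#'
#' @param n_per_group Subjects per group (>= 2).
#' @param n_regions Atlas size (>= 4).
#' @param bmi_mean_hw,bmi_sd_hw,bmi_mean_nhw,bmi_sd_nhw Group BMI moments
#'   (kg/m^2).
#' @param planted_edges Data frame (`u`, `v`, `d`): edges whose fiber
#'   density differs between groups by Cohen's d. `NULL` = default set.
#' @param coupling_edges Data frame (`u`, `v`, `target_region`,
#'   `target_r`): edges whose density correlates across subjects with the
#'   target region's mean functional connectivity. `NULL` = default set.
#' @param bmi_driver_features Data frame (`feature`, `coefficient`); ids
#'   are `"SC:u-v"` or `"FC:r"`. `NULL` = default set.
#' @param bmi_signal_fraction Fraction of BMI-score variance carried by the
#'   driver features (noise supplies the rest); ignored when `noise_sd` is
#'   given.
#' @param noise_sd Optional explicit noise SD on the latent BMI score.
#' @param bmi_calibration `"group"` (match each group's mean/SD; default)
#'   or `"cohort"` (single affine map to the mixture mean/SD, preserving
#'   the whole-cohort signal fraction exactly).
#' @param fiber_length_log_mean,fiber_length_log_sd Lognormal parameters of
#'   streamline length before truncation to [20, 500] mm; defaults hit a
#'   truncated mean of 26.2 mm.
#' @param mean_fibers_per_edge Mean streamline count per connected pair.
#' @param edge_sparsity Fraction of region pairs with no fibers in any
#'   subject.
#' @param presence_dropout Per-subject probability that a connected pair
#'   has no fibers for that subject (drives the per-edge subject-exclusion
#'   rule downstream).
#' @param n_timepoints Time points per subject (>= 50).
#' @param sampling_interval Sampling interval in seconds (TR; default 0.72).
#' @param seed Root seed; all stage randomness derives from it through
#'   named substreams.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_group = 60L,
                           n_regions = 116L,
                           bmi_mean_hw = 22.53, bmi_sd_hw = 1.37,
                           bmi_mean_nhw = 32.55, bmi_sd_nhw = 3.60,
                           planted_edges = NULL,
                           coupling_edges = NULL,
                           bmi_driver_features = NULL,
                           bmi_signal_fraction = 0.57,
                           noise_sd = NULL,
                           bmi_calibration = c("group", "cohort"),
                           fiber_length_log_mean = 2.762889,
                           fiber_length_log_sd = 0.4,
                           mean_fibers_per_edge = 30,
                           edge_sparsity = 0.5,
                           presence_dropout = 0.05,
                           n_timepoints = 1200L,
                           sampling_interval = 0.72,
                           seed = 1L) {
  check_scalar(n_per_group, "n_per_group", lo = 2)
  check_scalar(n_regions, "n_regions", lo = 4)
  for (nm in c("bmi_sd_hw", "bmi_sd_nhw"))
    check_scalar(get(nm), nm, lo = .Machine$double.xmin)
  check_scalar(bmi_mean_hw, "bmi_mean_hw")
  check_scalar(bmi_mean_nhw, "bmi_mean_nhw")
  check_scalar(edge_sparsity, "edge_sparsity", lo = 0, hi = 1)
  check_scalar(presence_dropout, "presence_dropout", lo = 0, hi = 1)
  check_scalar(fiber_length_log_sd, "fiber_length_log_sd",
               lo = .Machine$double.xmin)
  check_scalar(mean_fibers_per_edge, "mean_fibers_per_edge",
               lo = .Machine$double.xmin)
  check_scalar(n_timepoints, "n_timepoints", lo = 50)
  check_scalar(sampling_interval, "sampling_interval",
               lo = .Machine$double.xmin)
  check_scalar(bmi_signal_fraction, "bmi_signal_fraction",
               lo = 1e-6, hi = 1)
  if (!is.null(noise_sd)) check_scalar(noise_sd, "noise_sd", lo = 0)

  if (is.null(planted_edges)) planted_edges <- default_planted_edges(n_regions)
  if (is.null(coupling_edges)) coupling_edges <- default_coupling_edges(n_regions)
  if (is.null(bmi_driver_features)) {
    bmi_driver_features <- if (n_regions >= 18L) default_bmi_drivers()
      else data.frame(feature = character(0), coefficient = numeric(0))
  }
  planted_edges <- as.data.frame(planted_edges)
  coupling_edges <- as.data.frame(coupling_edges)
  bmi_driver_features <- as.data.frame(bmi_driver_features)

  if (nrow(planted_edges)) {
    stopifnot(all(c("u", "v", "d") %in% names(planted_edges)))
    if (any(!is.finite(planted_edges$d)))
      stop_invalid("planted effect sizes must be finite")
    if (any(planted_edges$u == planted_edges$v) ||
        any(c(planted_edges$u, planted_edges$v) > n_regions) ||
        any(c(planted_edges$u, planted_edges$v) < 1))
      stop_invalid("planted edges reference invalid regions")
  }
  if (nrow(coupling_edges)) {
    stopifnot(all(c("u", "v", "target_region", "target_r") %in%
                    names(coupling_edges)))
    if (any(abs(coupling_edges$target_r) >= 1))
      stop_invalid("coupling target_r must lie in (-1, 1)")
    if (any(c(coupling_edges$u, coupling_edges$v,
              coupling_edges$target_region) > n_regions))
      stop_invalid("coupling edges reference invalid regions")
  }

  spec <- list(
    n_per_group = as.integer(n_per_group), n_regions = as.integer(n_regions),
    bmi_mean_hw = bmi_mean_hw, bmi_sd_hw = bmi_sd_hw,
    bmi_mean_nhw = bmi_mean_nhw, bmi_sd_nhw = bmi_sd_nhw,
    planted_edges = planted_edges, coupling_edges = coupling_edges,
    bmi_driver_features = bmi_driver_features,
    bmi_signal_fraction = bmi_signal_fraction, noise_sd = noise_sd,
    bmi_calibration = match.arg(bmi_calibration),
    fiber_length_log_mean = fiber_length_log_mean,
    fiber_length_log_sd = fiber_length_log_sd,
    mean_fibers_per_edge = mean_fibers_per_edge,
    edge_sparsity = edge_sparsity, presence_dropout = presence_dropout,
    n_timepoints = as.integer(n_timepoints),
    sampling_interval = sampling_interval,
    seed = as.integer(seed)
  )
  class(spec) <- "synthetic_spec"
  spec
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_spec> 2 x %d subjects, %d regions, ",
                     "%d planted edges, %d coupling edges, T = %d\n"),
              x$n_per_group, x$n_regions, nrow(x$planted_edges),
              nrow(x$coupling_edges), x$n_timepoints))
  invisible(x)
}

# Moments of 1/L under the truncated lognormal length distribution;
# used to calibrate planted count shifts to a target Cohen's d.
inv_length_moments <- function(spec) {
  ml <- spec$fiber_length_log_mean; sl <- spec$fiber_length_log_sd
  Z <- stats::plnorm(500, ml, sl) - stats::plnorm(20, ml, sl)
  if (Z <= 0) stop_invalid("length distribution has no mass in [20, 500] mm")
  mom <- function(k) {
    stats::integrate(function(x) x^(-k) * stats::dlnorm(x, ml, sl),
                     20, 500, rel.tol = 1e-10)$value / Z
  }
  c(m1 = mom(1), m2 = mom(2))
}
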