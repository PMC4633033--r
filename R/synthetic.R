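# Synthetic cohort generation: fiber records, ROI time series and BMI with
# planted group effects and structure-function coupling.

# Cohort-level wiring shared by all subjects: which region pairs are
# connected at all, and each connected pair's mean streamline count.
# Deterministic given the spec (substream "topology" of the root seed).
cohort_topology <- function(spec, atlas) {
  n <- nrow(atlas)
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  n_pairs <- nrow(ut)
  forced <- rep(FALSE, n_pairs)
  special <- rbind(
    if (nrow(spec$planted_edges)) spec$planted_edges[, c("u", "v")],
    if (nrow(spec$coupling_edges)) spec$coupling_edges[, c("u", "v")]
  )
  key <- pair_key(ut[, 1L], ut[, 2L], n)
  if (!is.null(special) && nrow(special))
    forced <- key %in% pair_key(special$u, special$v, n)

  withr::with_seed(derive_seed(spec$seed, "topology"), {
    connected <- stats::runif(n_pairs) >= spec$edge_sparsity
    # planted / coupling edges must exist, unless the spec says nothing
    # is connected at all
    if (spec$edge_sparsity < 1) connected <- connected | forced
    mu <- stats::rgamma(n_pairs, shape = 4,
                        rate = 4 / spec$mean_fibers_per_edge)
  })
  idx <- which(connected)
  list(u = ut[idx, 1L], v = ut[idx, 2L], mu = mu[idx],
       key = key[idx], n = n)
}

#' Simulate one subject's fiber records
#'
#' Streamline lengths are drawn from a lognormal truncated to [20, 500] mm
#' (defaults give mean 26.2 mm); per-pair streamline counts are Poisson
#' around the pair's cohort-level mean rate. For planted edges the non-HW
#' group's count rate is shifted so that the downstream fiber *density*
#' differs by the specified Cohen's d (the shift is calibrated through the
#' moments of 1/length). A spec-controlled fraction of pairs carries no
#' fibers at all, and each connected pair independently drops out per
#' subject with probability `presence_dropout`.
#'
#' @param atlas An [make_atlas()] table.
#' @param spec A [synthetic_spec()].
#' @param subject_effect Per-subject scalar multiplying the planted count
#'   shift: 0 for HW subjects, 1 for non-HW.
#' @param seed Integer seed for this subject's draws.
#' @param subject_id Subject identifier.
#' @return A [fiber_set()].
#' @export
simulate_fibers <- function(atlas, spec, subject_effect = 0, seed = 1L,
                            subject_id = "subj") {
  validate_atlas(atlas)
  stopifnot(inherits(spec, "synthetic_spec"))
  if (nrow(atlas) != spec$n_regions)
    stop_invalid("atlas size does not match the spec")
  topo <- cohort_topology(spec, atlas)

  mu <- topo$mu
  if (nrow(spec$planted_edges) && subject_effect != 0) {
    mom <- inv_length_moments(spec)
    a <- mom["m1"] / sqrt(mom["m2"])
    pe <- spec$planted_edges
    at <- match(pair_key(pe$u, pe$v, topo$n), topo$key)
    hit <- !is.na(at)
    if (any(hit)) {
      d <- pe$d[hit]; mu_e <- mu[at[hit]]
      # solve d = delta * a / sqrt(mu + delta / 2) for the count shift
      delta <- (d^2 / 2 + sqrt(d^4 / 4 + 4 * a^2 * d^2 * mu_e)) / (2 * a^2)
      mu[at[hit]] <- pmax(mu_e + subject_effect * delta, 0.01)
    }
  }

  withr::with_seed(as.integer(seed), {
    kept <- stats::runif(length(mu)) >= spec$presence_dropout
    counts <- stats::rpois(length(mu), mu) * kept
    total <- sum(counts)
    if (total > 0L) {
      plo <- stats::plnorm(20, spec$fiber_length_log_mean,
                           spec$fiber_length_log_sd)
      phi <- stats::plnorm(500, spec$fiber_length_log_mean,
                           spec$fiber_length_log_sd)
      lens <- stats::qlnorm(stats::runif(total, plo, phi),
                            spec$fiber_length_log_mean,
                            spec$fiber_length_log_sd)
    } else lens <- numeric(0)
  })
  fibers <- data.frame(region_u = rep(topo$u, counts),
                       region_v = rep(topo$v, counts),
                       length_mm = lens)
  fiber_set(subject_id, fibers)
}

# Band-limited unit-variance noise columns: white Gaussian spectrum masked
# to [f_lo, f_hi] Hz (DC removed), inverse-transformed and standardized.
band_limited_noise <- function(n_t, n_cols, dt, f_lo = 0.009, f_hi = 0.08) {
  k <- 0:(n_t - 1L)
  freq <- pmin(k, n_t - k) / (n_t * dt)
  keep <- freq >= f_lo & freq <= f_hi & k != 0L
  if (!any(keep))
    stop_invalid("no Fourier bin falls in the requested band; series too short")
  x <- matrix(stats::rnorm(n_t * n_cols), n_t, n_cols)
  co <- stats::mvfft(x)
  co[!keep, ] <- 0
  out <- Re(stats::mvfft(co, inverse = TRUE)) / n_t
  sweep(out, 2L, apply(out, 2L, stats::sd), `/`)
}

# Attenuation of the chain "shared-signal amplitude -> measured mean
# functional connectivity": the measured mean FC tracks the amplitude
# latent almost deterministically, shrunk slightly by correlation
# estimation noise at finite series length. Fixed design constant.
COUPLING_ATTENUATION <- 0.92

#' Simulate a cohort's ROI time series
#'
#' Latent-factor model: every region loads on one band-limited shared
#' signal (power confined to [f_lo, f_hi], default 0.009-0.08 Hz) plus
#' region-specific band-limited noise, so all correlations are positive and
#' moderate at baseline. For each coupling edge in the spec, the target
#' region's shared-signal amplitude is modulated across subjects by a
#' latent that mixes the edge's realized (standardized) fiber density with
#' fresh noise; the mixing weight is chosen so the across-subject
#' correlation between edge density and the target region's mean functional
#' connectivity comes out near `target_r`.
#'
#' @param atlas An [make_atlas()] table.
#' @param spec A [synthetic_spec()].
#' @param structural_edge_values Subjects x coupling-edges matrix of
#'   realized fiber densities (columns aligned with `spec$coupling_edges`
#'   rows), or `NULL` when the spec has no coupling edges.
#' @param seed Integer seed.
#' @param n_subjects Number of subjects (defaults to the matrix rows, or
#'   `2 * n_per_group`).
#' @param subject_ids Optional subject identifiers.
#' @return List of [roi_timeseries()], one per subject.
#' @export
simulate_timeseries <- function(atlas, spec, structural_edge_values = NULL,
                                seed = 1L, n_subjects = NULL,
                                subject_ids = NULL) {
  validate_atlas(atlas)
  stopifnot(inherits(spec, "synthetic_spec"))
  n_r <- nrow(atlas)
  n_cp <- nrow(spec$coupling_edges)
  if (n_cp > 0L) {
    if (is.null(structural_edge_values))
      stop_invalid("spec has coupling edges; structural_edge_values required")
    structural_edge_values <- as.matrix(structural_edge_values)
    if (ncol(structural_edge_values) != n_cp)
      stop_invalid("one structural_edge_values column per coupling edge required")
  }
  n_s <- n_subjects %||%
    (if (n_cp > 0L) nrow(structural_edge_values) else 2L * spec$n_per_group)
  subject_ids <- subject_ids %||% sprintf("subj%03d", seq_len(n_s))

  a0 <- 0.6     # baseline shared-signal amplitude
  s0 <- 0.8     # region-specific noise amplitude
  kappa <- 0.5  # amplitude modulation per unit coupling latent

  withr::with_seed(as.integer(seed), {
    # per-region amplitude modulation latents, one column per subject
    amp <- matrix(a0, n_r, n_s)
    if (n_cp > 0L) {
      v_edge <- matrix(0, n_s, n_cp)
      for (j in seq_len(n_cp)) {
        d <- structural_edge_values[, j]
        # standardize over subjects that actually carry the edge; subjects
        # with a dropped-out (zero-density) edge sit at the mean, so the
        # planted correlation lives in the present-subject set -- the set
        # the downstream coupling analysis is computed on
        dz <- rep(0, n_s)
        pres <- d > 0
        sdd <- stats::sd(d[pres])
        if (sum(pres) >= 2L && sdd > 0)
          dz[pres] <- (d[pres] - mean(d[pres])) / sdd
        rho <- max(-0.98, min(0.98, spec$coupling_edges$target_r[j] /
                                COUPLING_ATTENUATION))
        v_edge[, j] <- rho * dz + sqrt(1 - rho^2) * stats::rnorm(n_s)
      }
      for (r in unique(spec$coupling_edges$target_region)) {
        js <- which(spec$coupling_edges$target_region == r)
        v <- rowMeans(v_edge[, js, drop = FALSE])
        amp[r, ] <- a0 * pmax(1 + kappa * v, 0.05)
      }
    }
    lapply(seq_len(n_s), function(i) {
      g <- band_limited_noise(spec$n_timepoints, 1L, spec$sampling_interval)
      e <- band_limited_noise(spec$n_timepoints, n_r, spec$sampling_interval)
      values <- g %*% t(amp[, i]) + s0 * e
      colnames(values) <- atlas$name
      roi_timeseries(subject_ids[i], values, spec$sampling_interval)
    })
  })
}

#' Simulate BMI values and group labels from a feature matrix
#'
#' The latent BMI score is a linear combination of (standardized) driver
#' features plus Gaussian noise; the noise SD is either given explicitly or
#' derived from the spec's signal fraction (in-sample, so the generating
#' R-squared is exact). The score is then affinely calibrated:
#' \itemize{
#'   \item `"group"` (default): each pre-assigned group's scores are mapped
#'     to the spec's group mean/SD exactly, and values crossing the
#'     25 kg/m^2 boundary are reflected back, so labels and BMI stay
#'     consistent;
#'   \item `"cohort"`: one affine map to the mixture mean/SD, preserving
#'     the whole-cohort signal fraction.
#' }
#' Group labels are finally assigned by the 25 kg/m^2 threshold.
#'
#' @param features Subjects x features numeric matrix with column names
#'   matching the spec's driver feature ids.
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed.
#' @param groups Pre-assigned target groups (`"HW"` / `"nonHW"`) used by
#'   the `"group"` calibration; defaults to first half HW, second half
#'   non-HW.
#' @return List with `bmi` (kg/m^2), `group` (labels by the 25 threshold)
#'   and `signal` (the noiseless standardized driver combination).
#' @export
simulate_bmi <- function(features, spec, seed = 1L, groups = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  features <- as.matrix(features)
  n <- nrow(features)
  drv <- spec$bmi_driver_features
  missing_ids <- setdiff(drv$feature, colnames(features))
  if (length(missing_ids))
    stop_invalid("unknown BMI driver feature(s): ",
                 paste(missing_ids, collapse = ", "))
  if (is.null(groups))
    groups <- rep(c("HW", "nonHW"), c(ceiling(n / 2), floor(n / 2)))
  if (length(groups) != n) stop_invalid("one group per subject required")

  signal <- rep(0, n)
  for (i in seq_len(nrow(drv))) {
    x <- features[, drv$feature[i]]
    sdx <- stats::sd(x)
    if (sdx > 0) signal <- signal + drv$coefficient[i] * (x - mean(x)) / sdx
  }
  sd_sig <- stats::sd(signal)
  noise_sd <- spec$noise_sd %||% {
    f <- spec$bmi_signal_fraction
    if (sd_sig > 0) sd_sig * sqrt((1 - f) / f) else 1
  }
  raw <- signal + withr::with_seed(as.integer(seed),
                                   stats::rnorm(n, 0, noise_sd))

  rescale <- function(x, m, s) {
    sdx <- stats::sd(x)
    if (sdx > 0) m + s * (x - mean(x)) / sdx else rep(m, length(x))
  }
  if (spec$bmi_calibration == "group") {
    bmi <- numeric(n)
    hw <- groups == "HW"
    bmi[hw] <- rescale(raw[hw], spec$bmi_mean_hw, spec$bmi_sd_hw)
    bmi[!hw] <- rescale(raw[!hw], spec$bmi_mean_nhw, spec$bmi_sd_nhw)
    # reflect boundary crossers so labels stay consistent with the target
    # group assignment
    cross_hw <- hw & bmi >= 25
    bmi[cross_hw] <- pmin(50 - bmi[cross_hw], 25 - 1e-6)
    cross_nhw <- !hw & bmi < 25
    bmi[cross_nhw] <- 50 - bmi[cross_nhw]
  } else {
    m_mix <- (spec$bmi_mean_hw + spec$bmi_mean_nhw) / 2
    v_mix <- (spec$bmi_sd_hw^2 + spec$bmi_sd_nhw^2) / 2 +
      (spec$bmi_mean_nhw - spec$bmi_mean_hw)^2 / 4
    bmi <- rescale(raw, m_mix, sqrt(v_mix))
    bmi <- pmax(bmi, 12)  # physiological floor
  }
  list(bmi = bmi, group = ifelse(bmi < 25, "HW", "nonHW"), signal = signal)
}

# Fiber density of one region pair straight from a fiber set (length cutoff
# applied), without building the full matrix.
edge_density_from_fibers <- function(fs, atlas, u, v,
                                     min_len = 20, max_len = 500) {
  fib <- fs$fibers
  sel <- (pmin(fib$region_u, fib$region_v) == min(u, v)) &
    (pmax(fib$region_u, fib$region_v) == max(u, v)) &
    fib$length_mm >= min_len & fib$length_mm <= max_len
  fiber_density(fib$length_mm[sel], atlas$surface_area[u],
                atlas$surface_area[v])
}

#' Generate a complete synthetic cohort
#'
#' Composes the atlas, fiber, time-series and BMI simulators: subjects are
#' pre-assigned to two groups of `n_per_group`; planted edges shift the
#' non-HW group's fiber densities; coupling edges tie the target regions'
#' shared-signal amplitudes to the realized densities; BMI is generated
#' from the driver features. Deterministic given the spec (all randomness
#' flows from `spec$seed` through named substreams).
#'
#' @param spec A [synthetic_spec()].
#' @return Object of class `cohort`: list with `atlas`, `subjects` (data
#'   frame: `subject_id`, `group`, `bmi`), `fiber_sets`, `timeseries`,
#'   `features` (subjects x features matrix of all planted-edge densities
#'   and coupling-target mean-FC values) and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  atlas <- make_atlas(spec$n_regions, seed = derive_seed(spec$seed, "atlas"))
  n <- 2L * spec$n_per_group
  ids <- sprintf("subj%03d", seq_len(n))
  groups <- rep(c("HW", "nonHW"), each = spec$n_per_group)

  fiber_sets <- lapply(seq_len(n), function(i) {
    simulate_fibers(atlas, spec,
                    subject_effect = as.numeric(groups[i] == "nonHW"),
                    seed = derive_seed(spec$seed, "fibers", i),
                    subject_id = ids[i])
  })

  cp <- spec$coupling_edges
  D <- NULL
  if (nrow(cp)) {
    D <- vapply(fiber_sets, function(fs) {
      vapply(seq_len(nrow(cp)), function(j) {
        edge_density_from_fibers(fs, atlas, cp$u[j], cp$v[j])
      }, numeric(1L))
    }, numeric(nrow(cp)))
    D <- t(matrix(D, nrow = nrow(cp)))
  }

  timeseries <- simulate_timeseries(atlas, spec, structural_edge_values = D,
                                    seed = derive_seed(spec$seed, "timeseries"),
                                    n_subjects = n, subject_ids = ids)

  feat_edges <- unique(rbind(
    if (nrow(spec$planted_edges)) spec$planted_edges[, c("u", "v")],
    if (nrow(cp)) cp[, c("u", "v")]
  )) %||% data.frame(u = integer(0), v = integer(0))
  feat_regions <- unique(cp$target_region)
  features <- cohort_features(atlas, fiber_sets, timeseries,
                              edges = feat_edges, regions = feat_regions)

  bm <- simulate_bmi(features, spec, seed = derive_seed(spec$seed, "bmi"),
                     groups = groups)
  structure(list(
    atlas = atlas,
    subjects = data.frame(subject_id = ids, group = bm$group, bmi = bm$bmi,
                          stringsAsFactors = FALSE),
    fiber_sets = fiber_sets,
    timeseries = timeseries,
    features = features,
    spec = spec
  ), class = "cohort")
}

#' Extract a named feature matrix from cohort data
#'
#' Builds columns `SC:u-v` (edge fiber densities, zero when absent) and
#' `FC:r` (region mean functional connectivity) for the requested edges and
#' regions.
#'
#' @param atlas Atlas table.
#' @param fiber_sets List of [fiber_set()].
#' @param timeseries List of [roi_timeseries()], aligned with `fiber_sets`.
#' @param edges Data frame with columns `u`, `v`.
#' @param regions Integer region ids.
#' @return Subjects x features numeric matrix.
#' @export
cohort_features <- function(atlas, fiber_sets, timeseries, edges, regions) {
  n <- length(fiber_sets)
  cols <- list()
  for (j in seq_len(nrow(edges))) {
    u <- edges$u[j]; v <- edges$v[j]
    cols[[sprintf("SC:%d-%d", u, v)]] <- vapply(fiber_sets, function(fs) {
      edge_density_from_fibers(fs, atlas, u, v)
    }, numeric(1L))
  }
  if (length(regions)) {
    mfc <- vapply(timeseries, function(ts) {
      correlation_matrix(ts)$mean_fc[regions]
    }, numeric(length(regions)))
    mfc <- t(matrix(mfc, nrow = length(regions)))
    for (k in seq_along(regions))
      cols[[sprintf("FC:%d", regions[k])]] <- mfc[, k]
  }
  X <- do.call(cbind, cols)
  if (is.null(X)) X <- matrix(numeric(0), nrow = n, ncol = 0L)
  rownames(X) <- vapply(fiber_sets, `[[`, "", "subject_id")
  X
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects (%d HW / %d nonHW), %d regions\n",
              nrow(x$subjects), sum(x$subjects$group == "HW"),
              sum(x$subjects$group == "nonHW"), nrow(x$atlas)))
  invisible(x)
}
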