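# Synthetic cohort generator: atlas, fibers, time series, BMI.

test_that("atlas generation is deterministic with configured reward flags", {
  a1 <- make_atlas(116, seed = 9)
  expect_equal(nrow(a1), 116)
  expect_equal(anyDuplicated(a1$region), 0L)
  expect_identical(a1, make_atlas(116, seed = 9))
  expect_equal(sum(make_atlas(10, seed = 1, n_reward = 4)$reward), 4L)
  expect_true(all(a1$surface_area > 0))
  expect_error(make_atlas(3), "n_regions")
})

test_that("fiber lengths respect the truncation bounds and target mean", {
  spec <- structural_spec(2, n_regions = 10, seed = 21,
                          mean_fibers_per_edge = 300)
  atlas <- make_atlas(10, derive_seed(spec$seed, "atlas"))
  fs <- simulate_fibers(atlas, spec, seed = 31)
  lens <- fs$fibers$length_mm
  expect_gt(length(lens), 1e4)
  expect_true(all(lens >= 20 & lens <= 500))
  expect_lt(abs(mean(lens) - 26.2), 1)
  # full sparsity: no fibers at all
  spec0 <- structural_spec(2, n_regions = 6, seed = 3, edge_sparsity = 1)
  expect_equal(nrow(simulate_fibers(make_atlas(6, derive_seed(3, "atlas")),
                                    spec0, seed = 1)$fibers), 0L)
})

test_that("fiber simulation is deterministic and sparsity removes pairs cohort-wide", {
  spec <- structural_spec(2, n_regions = 12, seed = 5, edge_sparsity = 0.6,
                          presence_dropout = 0)
  atlas <- make_atlas(12, derive_seed(spec$seed, "atlas"))
  f1 <- simulate_fibers(atlas, spec, seed = 7)
  expect_identical(f1, simulate_fibers(atlas, spec, seed = 7))
  pairs_of <- function(fs) unique(paste(pmin(fs$fibers$region_u, fs$fibers$region_v),
                                        pmax(fs$fibers$region_u, fs$fibers$region_v)))
  f2 <- simulate_fibers(atlas, spec, seed = 8)
  # with no per-subject dropout, both subjects draw from the same topology
  expect_setequal(pairs_of(f1), pairs_of(f2))
  expect_lt(length(pairs_of(f1)), choose(12, 2))
})

test_that("planted density effects are recovered near the target Cohen's d", {
  reps <- 30
  ds <- vapply(seq_len(reps), function(k) {
    spec <- structural_spec(30, n_regions = 6, seed = 400 + k,
                            planted_edges = data.frame(u = 1L, v = 5L, d = 1.2))
    atlas <- make_atlas(6, derive_seed(spec$seed, "atlas"))
    g <- rep(0:1, each = 30)
    D <- vapply(seq_len(60), function(i) {
      fs <- simulate_fibers(atlas, spec, g[i],
                            derive_seed(spec$seed, "fibers", i))
      bmiconn:::edge_density_from_fibers(fs, atlas, 1, 5)
    }, numeric(1))
    a <- D[g == 0 & D > 0]; b <- D[g == 1 & D > 0]
    (mean(b) - mean(a)) /
      sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
             (length(a) + length(b) - 2))
  }, numeric(1))
  expect_lt(abs(mean(ds) - 1.2), 0.2)
})

test_that("time series are deterministic, band-limited, and uncoupled without coupling edges", {
  spec <- synthetic_spec(n_per_group = 10, n_regions = 8, n_timepoints = 256,
                         planted_edges = no_edges(),
                         coupling_edges = no_coupling(),
                         bmi_driver_features = no_drivers(), seed = 17)
  atlas <- make_atlas(8, derive_seed(spec$seed, "atlas"))
  ts1 <- simulate_timeseries(atlas, spec, seed = 2, n_subjects = 4)
  ts2 <- simulate_timeseries(atlas, spec, seed = 2, n_subjects = 4)
  expect_identical(ts1[[3]]$values, ts2[[3]]$values)

  # >= 90% of spectral power inside 0.009-0.08 Hz
  x <- ts1[[1]]$values[, 1]
  n <- length(x); k <- 0:(n - 1)
  fr <- pmin(k, n - k) / (n * spec$sampling_interval)
  pw <- Mod(stats::fft(x))^2
  frac <- sum(pw[fr >= 0.009 & fr <= 0.08 & k != 0]) / sum(pw[k != 0])
  expect_gt(frac, 0.9)

  # no planted coupling: across-subject correlation between an arbitrary
  # "edge value" and any region's mean FC is near zero on average
  rs <- vapply(1:40, function(k) {
    tss <- simulate_timeseries(atlas, spec, seed = 100 + k, n_subjects = 30)
    mfc <- vapply(tss, function(t) correlation_matrix(t)$mean_fc[2], numeric(1))
    fake_edge <- withr::with_seed(k, rnorm(30))
    cor(fake_edge, mfc)
  }, numeric(1))
  expect_lt(abs(mean(rs)), 3 / sqrt(40 * 30))
})

test_that("planted coupling yields across-subject correlation near target_r", {
  rs <- vapply(1:25, function(k) {
    spec <- synthetic_spec(n_per_group = 60, n_regions = 16, n_timepoints = 400,
                           planted_edges = no_edges(),
                           coupling_edges = data.frame(u = 7L, v = 12L,
                                                       target_region = 7L,
                                                       target_r = 0.45),
                           bmi_driver_features = no_drivers(),
                           seed = 900 + k)
    atlas <- make_atlas(16, derive_seed(spec$seed, "atlas"))
    D <- vapply(seq_len(120), function(i) {
      fs <- simulate_fibers(atlas, spec, 0, derive_seed(spec$seed, "fibers", i))
      bmiconn:::edge_density_from_fibers(fs, atlas, 7, 12)
    }, numeric(1))
    tss <- simulate_timeseries(atlas, spec, matrix(D, ncol = 1),
                               derive_seed(spec$seed, "timeseries"))
    mfc <- vapply(tss, function(t) correlation_matrix(t)$mean_fc[7], numeric(1))
    cor(D, mfc)
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.45), 0.15)
})

test_that("BMI calibration hits group moments and the 25 kg/m^2 boundary rule", {
  spec <- synthetic_spec(n_per_group = 60, n_regions = 6, n_timepoints = 64,
                         planted_edges = no_edges(),
                         coupling_edges = no_coupling(),
                         bmi_driver_features =
                           data.frame(feature = "x", coefficient = 1),
                         seed = 5)
  X <- matrix(withr::with_seed(6, rnorm(120)), ncol = 1,
              dimnames = list(NULL, "x"))
  bm <- simulate_bmi(X, spec, seed = 8)
  hw <- bm$group == "HW"
  expect_true(all((bm$bmi < 25) == hw))
  expect_lt(abs(mean(bm$bmi[hw]) - 22.53), 0.5)
  expect_lt(abs(mean(bm$bmi[!hw]) - 32.55), 0.5)
  # noiseless single-driver link is exactly monotone within groups
  spec0 <- synthetic_spec(n_per_group = 20, n_regions = 6, n_timepoints = 64,
                          planted_edges = no_edges(),
                          coupling_edges = no_coupling(),
                          bmi_driver_features =
                            data.frame(feature = "x", coefficient = 1),
                          noise_sd = 0, seed = 5)
  X0 <- matrix(withr::with_seed(7, rnorm(40)), ncol = 1,
               dimnames = list(NULL, "x"))
  grp <- rep(c("HW", "nonHW"), each = 20)
  bm0 <- simulate_bmi(X0, spec0, seed = 9, groups = grp)
  sub <- grp == "HW" & bm0$bmi < 24.9  # unreflected region
  expect_equal(cor(X0[sub, 1], bm0$bmi[sub]), 1)
  expect_error(simulate_bmi(X0, synthetic_spec(
    n_per_group = 20, n_regions = 6, n_timepoints = 64,
    planted_edges = no_edges(), coupling_edges = no_coupling(),
    bmi_driver_features = data.frame(feature = "nope", coefficient = 1)),
    seed = 1), "unknown BMI driver")
})

test_that("cohort-mode calibration fixes the in-sample signal fraction", {
  ev <- vapply(1:10, function(k) {
    spec <- synthetic_spec(n_per_group = 50, n_regions = 6, n_timepoints = 64,
                           planted_edges = no_edges(),
                           coupling_edges = no_coupling(),
                           bmi_driver_features =
                             data.frame(feature = "x", coefficient = 1),
                           bmi_signal_fraction = 0.57,
                           bmi_calibration = "cohort", seed = k)
    X <- matrix(withr::with_seed(50 + k, rnorm(100)), ncol = 1,
                dimnames = list(NULL, "x"))
    bm <- simulate_bmi(X, spec, seed = 70 + k)
    summary(lm(bm$bmi ~ X[, 1]))$r.squared
  }, numeric(1))
  expect_lt(abs(mean(ev) - 0.57), 0.06)
})

test_that("whole cohorts are reproducible and internally consistent", {
  spec <- synthetic_spec(n_per_group = 3, n_regions = 20, n_timepoints = 80,
                         seed = 33)
  co <- generate_cohort(spec)
  expect_equal(nrow(co$subjects), 6)
  expect_identical(co$subjects, generate_cohort(spec)$subjects)
  expect_true(all((co$subjects$bmi < 25) == (co$subjects$group == "HW")))
  expect_equal(anyDuplicated(co$subjects$subject_id), 0L)
  expect_equal(nrow(co$features), 6)
})
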