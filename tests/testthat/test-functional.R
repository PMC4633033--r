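# Time-series cleaning and functional network construction.

test_that("nuisance regression projects out the supplied columns", {
  withr::with_seed(1, {
    n_t <- 120
    nuis <- cbind(sin(seq_len(n_t) / 9), rnorm(n_t))
    vals <- cbind(a = rnorm(n_t), b = 3 * nuis[, 1] + rnorm(n_t, sd = 0.1))
    ts <- roi_timeseries("s1", vals)
    out <- regress_nuisance(ts, nuis)
    # residuals orthogonal to intercept and every nuisance column
    expect_lt(max(abs(crossprod(cbind(1, nuis), out$values))), 1e-8)
    # a series equal to a nuisance column vanishes
    ts2 <- roi_timeseries("s1", cbind(x = nuis[, 2]))
    expect_lt(max(abs(regress_nuisance(ts2, nuis)$values)), 1e-10)
    # k = 0 reduces to demeaning
    demeaned <- regress_nuisance(ts)
    expect_equal(demeaned$values, scale(vals, scale = FALSE),
                 ignore_attr = TRUE)
  })
  tiny <- roi_timeseries("s", matrix(rnorm(8), 4, 2))
  expect_error(regress_nuisance(tiny, matrix(rnorm(16), 4, 4)), "columns")
})

test_that("Fourier band-pass keeps in-band tones and kills out-of-band ones", {
  dt <- 0.72; n_t <- 1200
  tt <- (seq_len(n_t) - 1) * dt
  inband <- sin(2 * pi * 0.05 * tt)
  outband <- sin(2 * pi * 0.2 * tt)
  const <- rep(5, n_t)
  ts <- roi_timeseries("s", cbind(inband, outband, const))
  out <- bandpass(ts, 0.009, 0.08)
  rms <- function(x) sqrt(mean(x^2))
  expect_gt(rms(out$values[, 1]) / rms(inband), 0.98)
  expect_lt(rms(out$values[, 2]) / rms(outband), 0.02)
  expect_lt(max(abs(out$values[, 3])), 1e-10)  # DC removed
  expect_error(bandpass(ts, 0.01, 1.0), "Nyquist")
})

test_that("run concatenation demeans per run and preserves correlations", {
  withr::with_seed(2, {
    vals <- matrix(rnorm(600 * 3), 600, 3)
    run <- roi_timeseries("s", vals, 0.72)
    both <- concatenate_runs(run, run)
    expect_equal(nrow(both$values), 1200)
    expect_equal(correlation_matrix(both)$r, correlation_matrix(run)$r)
    # an offset between runs must not create artificial signal
    run2 <- roi_timeseries("s", vals + 100, 0.72)
    expect_equal(correlation_matrix(concatenate_runs(run, run2))$r,
                 correlation_matrix(both)$r)
  })
  a <- roi_timeseries("s", matrix(rnorm(60), 20, 3))
  b <- roi_timeseries("s", matrix(rnorm(80), 20, 4))
  expect_error(concatenate_runs(a, b), "region counts")
})

test_that("correlation matrix matches a direct two-column computation", {
  withr::with_seed(3, {
    vals <- matrix(rnorm(200 * 4), 200, 4)
    vals[, 2] <- -vals[, 1]
    net <- correlation_matrix(roi_timeseries("s", vals))
    expect_equal(net$r[1, 2], -1)
    expect_equal(diag(net$r), rep(1, 4), ignore_attr = TRUE)
    # oracle: covariance over sigma-sigma for one pair
    cc <- function(x, y) mean((x - mean(x)) * (y - mean(y))) /
      (sd(x) * sd(y)) * length(x) / (length(x) - 1)
    expect_equal(net$r[3, 4], cc(vals[, 3], vals[, 4]), tolerance = 1e-12)
    # independent noise at large n has small correlation
    big <- matrix(rnorm(1e4 * 2), 1e4, 2)
    expect_lt(abs(correlation_matrix(roi_timeseries("s", big))$r[1, 2]), 0.05)
  })
  flat <- cbind(a = rep(1, 60), b = rnorm(60))
  expect_error(correlation_matrix(roi_timeseries("s", flat)),
               "zero-variance.*a")
})

test_that("Fisher transform is atanh with clamping at |r| = 1", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), atanh(0.5))
  r <- seq(-0.95, 0.95, by = 0.19)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_equal(fisher_z(1), atanh(1 - 1e-7))
  expect_error(fisher_z(1.5), "<= 1")
})

test_that("mean functional connectivity averages z over the other regions", {
  z <- matrix(0, 3, 3)
  z[1, 2] <- z[2, 1] <- 0.2
  z[1, 3] <- z[3, 1] <- 0.4
  r <- tanh(z); diag(r) <- 1
  net <- structure(list(subject_id = "s", r = r, z = z,
                        mean_fc = rowSums(z) / 2),
                   class = "functional_network")
  expect_equal(mean_functional_connectivity(net, 1), 0.3)
  expect_error(mean_functional_connectivity(net, 9), "unknown region")
  # all-zero off-diagonal
  withr::with_seed(4, {
    vals <- matrix(rnorm(5000 * 3), 5000, 3)
    net2 <- correlation_matrix(roi_timeseries("s", vals))
    expect_lt(max(abs(net2$mean_fc)), 0.05)
  })
})

test_that("cleaning pipeline is deterministic and r stays positive semidefinite", {
  withr::with_seed(5, {
    vals <- matrix(rnorm(300 * 6), 300, 6)
    ts <- roi_timeseries("s", vals)
    run <- function() {
      correlation_matrix(bandpass(regress_nuisance(ts), 0.009, 0.08))
    }
    n1 <- run(); n2 <- run()
    expect_identical(n1$r, n2$r)
    expect_gt(min(eigen(n1$r, symmetric = TRUE, only.values = TRUE)$values),
              -1e-8)
    expect_true(all(is.finite(n1$mean_fc)))
  })
})
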