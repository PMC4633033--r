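# PLS1 regression, PRESS model selection, LOOCV and error metrics.

rand_design <- function(n, p, seed, signal = TRUE, noise_sd = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
    beta <- if (signal) rnorm(p) else rep(0, p)
    y <- 30 + drop(X %*% beta) + rnorm(n, sd = noise_sd)
    list(X = X, y = y)
  })
}

test_that("PLS1 at full rank reproduces OLS; one predictor reduces to the
           simple regression line", {
  d <- rand_design(40, 6, seed = 1)
  fit <- fit_plsr(d$X, d$y, n_lv = 6)
  ols <- lm.fit(cbind(1, d$X), d$y)
  expect_lt(max(abs(fit$fitted - ols$fitted.values)), 1e-6)
  expect_equal(fit$explained_variance_y,
               1 - sum(ols$residuals^2) / sum((d$y - mean(d$y))^2),
               tolerance = 1e-8)

  x1 <- d$X[, 1, drop = FALSE]
  f1 <- fit_plsr(x1, d$y, 1)
  sl <- lm.fit(cbind(1, x1), d$y)
  expect_lt(max(abs(f1$fitted - sl$fitted.values)), 1e-8)

  # exact linear response is recovered perfectly
  y_lin <- drop(d$X %*% seq_len(6))
  f_lin <- fit_plsr(d$X, y_lin, 6)
  expect_lt(max(abs(f_lin$fitted - y_lin)), 1e-8)
  expect_equal(f_lin$explained_variance_y, 1, tolerance = 1e-10)
})

test_that("fit and predict agree with the naive NIPALS oracle at every k", {
  d <- rand_design(30, 5, seed = 2)
  new <- rand_design(4, 5, seed = 3)$X
  for (k in 1:5) {
    fit <- fit_plsr(d$X, d$y, k)
    expect_lt(max(abs(predict(fit, new) -
                        naive_pls1_predict(d$X, d$y, new, k))), 1e-8)
  }
})

test_that("prediction applies stored parameters without refitting", {
  d <- rand_design(25, 4, seed = 4)
  fit <- fit_plsr(d$X, d$y, 3)
  expect_equal(predict(fit, d$X), fit$fitted)
  # a row at the training means predicts the training mean response
  expect_equal(predict(fit, matrix(fit$x_mean, 1)), mean(d$y))
  # batch equals row-by-row
  rowwise <- vapply(1:4, function(i) predict(fit, d$X[i, , drop = FALSE]),
                    numeric(1))
  expect_equal(unname(predict(fit, d$X[1:4, ])), rowwise)
  expect_error(predict(fit, d$X[, 1:2]), "features")
  expect_error(fit_plsr(d$X, d$y, 10), "n_lv")
  Xc <- d$X; Xc[, 2] <- 7
  expect_error(fit_plsr(Xc, d$y, 2), "constant.*f2")
})

test_that("PRESS equals the brute-force refit-per-subject loop", {
  d <- rand_design(20, 4, seed = 5)
  pc <- press_curve(d$X, d$y, 4)
  for (k in 1:4) {
    expect_equal(pc[k], naive_press(d$X, d$y, k), tolerance = 1e-10)
    expect_equal(press(d$X, d$y, k), pc[k])
  }
  # noiseless linear response: PRESS at full rank is numerically zero
  y_lin <- drop(d$X %*% c(1, -2, 0.5, 3))
  expect_lt(press(d$X, y_lin, 4), 1e-10 * sum((y_lin - mean(y_lin))^2))
})

test_that("latent-variable selection stops at the first PRESS non-improvement", {
  # sequence {10, 8, 9, ...} -> k = 2; verified through a crafted response
  # by checking select_n_lv against the press curve it is defined over
  d <- rand_design(30, 6, seed = 6, noise_sd = 3)
  pc <- press_curve(d$X, d$y, 5)
  k <- select_n_lv(d$X, d$y, 5)
  if (any(diff(pc) >= 0)) {
    expect_equal(k, which(diff(pc) >= 0)[1])
  } else {
    expect_equal(k, 5L)
  }
  expect_equal(select_n_lv(d$X, d$y, 5, method = "min"), which.min(pc))
  # strictly decreasing curve -> max_lv (noiseless response)
  y_lin <- drop(d$X %*% rep(1, 6))
  expect_equal(select_n_lv(d$X, y_lin, 3), 3L)
})

test_that("training explained variance grows with k while PRESS need not", {
  d <- rand_design(35, 6, seed = 7, signal = FALSE)  # pure noise response
  ev <- vapply(1:6, function(k) fit_plsr(d$X, d$y, k)$explained_variance_y,
               numeric(1))
  expect_true(all(diff(ev) >= -1e-12))
  pc <- press_curve(d$X, d$y, 6)
  expect_true(any(diff(pc) > 0))  # overfitting shows up in PRESS
})

test_that("single-feature R^2 and p-value match closed forms", {
  r <- simple_feature_r2(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(r$r_squared, 0.36)          # Pearson r = 3/5
  y <- c(3, 5, 7, 9, 11)
  expect_equal(simple_feature_r2(1:5, y)$r_squared, 1)
  expect_equal(simple_feature_r2(1:5, y)$p_value, 0)
  # orthogonal construction gives R^2 = 0
  expect_equal(simple_feature_r2(c(-1, 1, -1, 1), c(1, 1, -1, -1))$r_squared, 0)
  # cross-check p against lm's F test
  d <- rand_design(20, 1, seed = 8)
  ours <- simple_feature_r2(d$X[, 1], d$y)
  lmp <- summary(lm(d$y ~ d$X[, 1]))
  expect_equal(ours$r_squared, lmp$r.squared)
  expect_equal(ours$p_value, unname(stats::pf(lmp$fstatistic[1],
                                              1, 18, lower.tail = FALSE)))
  expect_error(simple_feature_r2(rep(2, 10), rnorm(10)), "constant")
})

test_that("error metrics match hand arithmetic and reject nonpositive actuals", {
  m <- error_metrics(c(20, 30), c(22, 27))
  expect_equal(m$rms_error, sqrt((4 + 9) / 2))
  expect_equal(m$percent_error, 10)
  expect_equal(error_metrics(c(25, 28), c(25, 28)),
               list(rms_error = 0, percent_error = 0))
  sh <- withr::with_seed(9, sample(5))
  a <- c(21, 34, 27, 30, 25); p <- a + rnorm(5)
  expect_equal(error_metrics(a, p)$rms_error,
               error_metrics(a[sh], p[sh])$rms_error)
  expect_error(error_metrics(c(-1, 20), c(1, 20)), "positive")
})

test_that("LOOCV predicts noiseless responses almost perfectly and reports
           one fold per subject", {
  withr::with_seed(10, {
    X <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(NULL, paste0("f", 1:4)))
    y <- 28 + drop(X %*% c(2, -1, 0.5, 1))
  })
  rep <- loocv_predict(X, y, max_lv = 4)
  expect_equal(nrow(rep$predictions), 30)
  expect_equal(length(rep$per_fold_n_lv), 30)
  expect_lt(rep$percent_error, 0.1)
  expect_gt(rep$pearson_r, 0.999)
})

test_that("the held-out subject cannot leak into its fold's model", {
  d <- rand_design(25, 5, seed = 11)
  y <- d$y - min(d$y) + 20  # keep positive for percent error
  i <- 7
  # fold i's selection and fit depend only on the other subjects
  k_clean <- select_n_lv(d$X[-i, ], y[-i], 4)
  fit_clean <- fit_plsr(d$X[-i, ], y[-i], k_clean)
  X_corrupt <- d$X
  X_corrupt[i, ] <- X_corrupt[i, ] * 50 + 1000
  k_corrupt <- select_n_lv(X_corrupt[-i, ], y[-i], 4)
  fit_corrupt <- fit_plsr(X_corrupt[-i, ], y[-i], k_corrupt)
  expect_identical(k_clean, k_corrupt)
  expect_identical(fit_clean$coef_path, fit_corrupt$coef_path)
  # and the full report flags the corrupted subject with the same fold k
  r1 <- loocv_predict(d$X, y, max_lv = 4)
  r2 <- loocv_predict(X_corrupt, y, max_lv = 4)
  expect_identical(r1$per_fold_n_lv[i], r2$per_fold_n_lv[i])
})
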