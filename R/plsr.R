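# BMI prediction: PLS1 regression with PRESS-based latent-variable
# selection, per-feature simple regressions, leave-one-subject-out
# cross-validation and error metrics.

check_design <- function(X, y, min_subjects = 3L) {
  X <- as.matrix(X)
  if (!is.numeric(X) || anyNA(X)) stop_invalid("X must be numeric with no missing entries")
  if (anyNA(y) || !is.numeric(y)) stop_invalid("y must be numeric with no missing entries")
  if (nrow(X) != length(y)) stop_invalid("nrow(X) must equal length(y)")
  if (nrow(X) < min_subjects)
    stop_invalid(sprintf("need >= %d subjects", min_subjects))
  sds <- apply(X, 2L, stats::sd)
  if (any(sds < 1e-12)) {
    bad <- colnames(X)[sds < 1e-12] %||% which(sds < 1e-12)
    stop_invalid("constant feature column(s): ",
                 paste(utils::head(bad, 5L), collapse = ", "))
  }
  X
}

#' Fit a PLS1 regression model
#'
#' Partial least-squares regression with a single response, the standard
#' choice when predictors are many and collinear (here: fiber densities and
#' mean functional connectivity values on mixed scales). Feature columns are
#' standardized to zero mean and unit variance and the response is centered;
#' latent variables are extracted by the NIPALS scheme with deflation.
#'
#' @param X Subjects x features numeric matrix (no missing entries).
#' @param y Response vector (BMI in kg/m^2).
#' @param n_lv Number of latent variables, `1 <= n_lv <= min(n - 1, p)`.
#' @return Object of class `plsr_fit`: centering/scaling parameters, the
#'   coefficient path for `1..n_lv` components (standardized scale),
#'   training fitted values and `explained_variance_y` (training
#'   `1 - RSS/TSS`).
#' @export
fit_plsr <- function(X, y, n_lv) {
  X <- check_design(X, y)
  n <- nrow(X); p <- ncol(X)
  check_scalar(n_lv, "n_lv", lo = 1)
  n_lv <- as.integer(n_lv)
  if (n_lv > min(n - 1L, p))
    stop_invalid(sprintf("n_lv = %d exceeds min(n - 1, p) = %d",
                         n_lv, min(n - 1L, p)))
  coef_path <- .cpp_pls1_path(X, y, n_lv)
  rownames(coef_path) <- colnames(X)
  model <- structure(list(
    n_lv = n_lv,
    x_mean = colMeans(X),
    x_scale = apply(X, 2L, stats::sd),
    y_mean = mean(y),
    coef_path = coef_path,
    feature_names = colnames(X)
  ), class = "plsr_fit")
  fitted <- predict(model, X)
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  model$fitted <- fitted
  model$explained_variance_y <- 1 - rss / tss
  model
}

#' Predict from a fitted PLS1 model
#'
#' Applies the stored centering/scaling and the coefficient vector at
#' `n_lv` components; no refitting touches the new data.
#'
#' @param object A [fit_plsr()] model.
#' @param newdata Matrix (or vector for one subject) with the model's
#'   feature count.
#' @param n_lv Component count to predict at (defaults to the fitted
#'   `n_lv`; must not exceed it).
#' @param ... Unused.
#' @return Predicted response vector.
#' @export
predict.plsr_fit <- function(object, newdata, n_lv = object$n_lv, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_mean))
    stop_invalid(sprintf("newdata has %d features; model expects %d",
                         ncol(newdata), length(object$x_mean)))
  n_lv <- as.integer(n_lv)
  if (n_lv < 1L || n_lv > object$n_lv)
    stop_invalid("n_lv out of the fitted range")
  Xs <- sweep(sweep(newdata, 2L, object$x_mean), 2L, object$x_scale, `/`)
  drop(object$y_mean + Xs %*% object$coef_path[, n_lv])
}

#' @export
print.plsr_fit <- function(x, ...) {
  cat(sprintf("<plsr_fit> %d features, %d latent variables, training R^2 = %.4f\n",
              length(x$x_mean), x$n_lv, x$explained_variance_y))
  invisible(x)
}

#' Leave-one-out PRESS of a k-component PLS1 model
#'
#' `PRESS(k) = sum_i (y_i - yhat_{-i,k})^2`, where `yhat_{-i,k}` is the
#' prediction for subject i from a k-component model fit (including
#' re-standardization) without subject i.
#'
#' @inheritParams fit_plsr
#' @param n_lv Component count k.
#' @return The PRESS value (scalar).
#' @export
press <- function(X, y, n_lv) {
  press_curve(X, y, n_lv)[n_lv]
}

#' Leave-one-out PRESS for all component counts up to `max_lv`
#'
#' @inheritParams fit_plsr
#' @param max_lv Largest component count.
#' @return Numeric vector `PRESS(1..max_lv)`.
#' @export
press_curve <- function(X, y, max_lv) {
  X <- check_design(X, y, min_subjects = 4L)
  check_scalar(max_lv, "max_lv", lo = 1)
  max_lv <- as.integer(max_lv)
  if (max_lv > min(nrow(X) - 2L, ncol(X)))
    stop_invalid("max_lv exceeds min(n - 2, p) (inner folds drop one subject)")
  drop(.cpp_press_curve(X, y, max_lv))
}

#' Choose the latent-variable count from the PRESS curve
#'
#' Components are added until PRESS no longer improves: the selected count
#' is the smallest k with `PRESS(k + 1) >= PRESS(k)`, or `max_lv` when the
#' curve is strictly decreasing throughout. `method = "min"` instead takes
#' the global PRESS minimizer.
#'
#' @inheritParams press_curve
#' @param method `"first"` (first non-improvement; default) or `"min"`.
#' @return Selected component count.
#' @export
select_n_lv <- function(X, y, max_lv, method = c("first", "min")) {
  method <- match.arg(method)
  pc <- press_curve(X, y, max_lv)
  if (method == "min") return(which.min(pc))
  if (length(pc) > 1L) {
    worse <- which(diff(pc) >= 0)
    if (length(worse)) return(worse[1L])
  }
  length(pc)
}

#' Simple one-predictor regression R-squared
#'
#' Quantifies a single feature's contribution to the response: R^2 is the
#' squared Pearson correlation and the two-sided p-value comes from the
#' regression F test (equivalently the t test on the slope).
#'
#' @param x Feature vector (nonconstant).
#' @param y Response vector.
#' @return List with `r_squared` and `p_value`.
#' @export
simple_feature_r2 <- function(x, y) {
  if (length(x) != length(y)) stop_invalid("x and y lengths differ")
  n <- length(x)
  if (n < 4L) stop_invalid("need >= 4 subjects")
  if (stats::sd(x) < 1e-12) stop_invalid("constant feature")
  r <- stats::cor(x, y)
  r2 <- r^2
  if (1 - r2 < 1e-15) {
    p <- 0
  } else {
    tval <- r * sqrt((n - 2) / (1 - r2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(r_squared = r2, p_value = p)
}

#' RMS and percent error between actual and predicted values
#'
#' `rms = sqrt(mean((a - p)^2))`; `percent = mean(|a - p| / a) * 100`
#' (actual value in the denominator).
#'
#' @param actual Actual response values (all > 0).
#' @param predicted Predicted values, same length.
#' @return List with `rms_error` and `percent_error`.
#' @export
error_metrics <- function(actual, predicted) {
  if (length(actual) != length(predicted))
    stop_invalid("actual and predicted lengths differ")
  if (any(!is.finite(actual)) || any(actual <= 0))
    stop_invalid("actual values must be positive (percent error divides by them)")
  list(rms_error = sqrt(mean((actual - predicted)^2)),
       percent_error = mean(abs(actual - predicted) / actual) * 100)
}

#' Leave-one-subject-out cross-validated prediction
#'
#' For each subject: the latent-variable count is chosen by inner
#' leave-one-out PRESS on the remaining n - 1 subjects, a PLS1 model is fit
#' on those subjects, and the held-out subject is predicted. Selection and
#' fitting never see the held-out row, so the reported errors are honest
#' out-of-sample estimates.
#'
#' @inheritParams fit_plsr
#' @param max_lv Largest component count considered per fold (capped at
#'   `min(n - 3, p)` so the inner folds stay feasible).
#' @param method Passed to [select_n_lv()].
#' @return Object of class `prediction_report`: `predictions` data frame
#'   (`subject`, `actual`, `predicted`, `n_lv`), `rms_error`,
#'   `percent_error`, `pearson_r`, `per_fold_n_lv`.
#' @export
loocv_predict <- function(X, y, max_lv = 10L, method = "first") {
  X <- check_design(X, y, min_subjects = 5L)
  n <- nrow(X)
  max_lv <- min(as.integer(max_lv), n - 3L, ncol(X))
  if (max_lv < 1L) stop_invalid("max_lv must allow at least one component")
  predicted <- numeric(n)
  k_used <- integer(n)
  for (i in seq_len(n)) {
    Xt <- X[-i, , drop = FALSE]
    yt <- y[-i]
    k <- select_n_lv(Xt, yt, max_lv, method = method)
    fit <- fit_plsr(Xt, yt, k)
    predicted[i] <- predict(fit, X[i, , drop = FALSE])
    k_used[i] <- k
  }
  subj <- rownames(X) %||% as.character(seq_len(n))
  err <- error_metrics(y, predicted)
  structure(list(
    predictions = data.frame(subject = subj, actual = y,
                             predicted = predicted, n_lv = k_used,
                             stringsAsFactors = FALSE),
    rms_error = err$rms_error,
    percent_error = err$percent_error,
    pearson_r = stats::cor(y, predicted),
    per_fold_n_lv = k_used
  ), class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf(paste0("<prediction_report> n = %d: RMS error %.3f, percent ",
                     "error %.2f%%, r(actual, predicted) = %.4f, modal n_lv = %d\n"),
              nrow(x$predictions), x$rms_error, x$percent_error, x$pearson_r,
              as.integer(names(sort(table(x$per_fold_n_lv),
                                    decreasing = TRUE))[1L])))
  invisible(x)
}
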