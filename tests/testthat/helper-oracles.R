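# Independent oracle implementations, deliberately naive: used only to
# cross-check the package's vectorized/compiled routines.

# Brute-force structural matrix: double loop over all region pairs,
# re-filtering and re-summing from scratch.
naive_structural_matrix <- function(fs, atlas, min_len = 20, max_len = 500) {
  n <- nrow(atlas)
  fib <- fs$fibers
  fib <- fib[fib$length_mm >= min_len & fib$length_mm <= max_len, , drop = FALSE]
  dens <- matrix(0, n, n)
  for (u in seq_len(n - 1L)) {
    for (v in (u + 1L):n) {
      sel <- (pmin(fib$region_u, fib$region_v) == u) &
        (pmax(fib$region_u, fib$region_v) == v)
      lens <- fib$length_mm[sel]
      if (length(lens)) {
        d <- 2 / (atlas$surface_area[u] + atlas$surface_area[v]) * sum(1 / lens)
        dens[u, v] <- dens[v, u] <- d
      }
    }
  }
  dens
}

# Naive NIPALS PLS1: standardize, extract k components, predict new rows.
naive_pls1_predict <- function(Xtr, ytr, Xte, k) {
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2L, sd)
  Xd <- sweep(sweep(Xtr, 2L, mu), 2L, sdv, `/`)
  ym <- mean(ytr)
  yd <- ytr - ym
  p <- ncol(Xtr)
  W <- P <- matrix(0, p, k)
  q <- numeric(k)
  for (a in seq_len(k)) {
    w <- drop(crossprod(Xd, yd))
    w <- w / sqrt(sum(w^2))
    tt <- drop(Xd %*% w)
    t2 <- sum(tt^2)
    P[, a] <- drop(crossprod(Xd, tt)) / t2
    q[a] <- sum(yd * tt) / t2
    Xd <- Xd - tt %*% t(P[, a])
    yd <- yd - q[a] * tt
    W[, a] <- w
  }
  B <- W %*% solve(crossprod(P, W), q)
  if (is.null(dim(Xte))) Xte <- matrix(Xte, nrow = 1L)
  Xts <- sweep(sweep(Xte, 2L, mu), 2L, sdv, `/`)
  drop(ym + Xts %*% B)
}

# PRESS by refitting from scratch for every held-out subject, through the
# public fit/predict interface.
naive_press <- function(X, y, k) {
  sum(vapply(seq_len(nrow(X)), function(i) {
    fit <- fit_plsr(X[-i, , drop = FALSE], y[-i], k)
    (y[i] - predict(fit, X[i, , drop = FALSE]))^2
  }, numeric(1L)))
}

# Structural-network object with a prescribed density matrix (for crafting
# exact coupling configurations).
craft_network <- function(subject_id, density) {
  structure(list(subject_id = subject_id, density = density,
                 present = density > 0),
            class = "structural_network")
}
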