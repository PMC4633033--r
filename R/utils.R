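# Internal helpers: seed substreams, argument checks.

#' Derive a reproducible sub-seed from a root seed
#'
#' All randomness in the package flows from one root seed through named
#' substreams (e.g. `derive_seed(seed, "fibers", subject_id)`), so each
#' simulation stage can be regenerated independently without replaying the
#' others.
#'
#' @param seed Integer root seed.
#' @param ... Character or numeric labels naming the substream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  parts <- vapply(list(...), function(x) paste(as.character(x), collapse = ","),
                  character(1L))
  # 31-multiplier string hash folded into a Mersenne-prime modulus; doubles
  # stay below 2^53 so the arithmetic is exact.
  h <- abs(as.double(seed)) %% 2147483647
  for (p in parts) {
    h <- (h * 31 + 7) %% 2147483647
    for (cc in utf8ToInt(p)) h <- (h * 31 + cc) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(..., call. = FALSE)

check_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    stop_invalid(sprintf("`%s` must be a finite scalar in [%s, %s]", name,
                         format(lo), format(hi)))
  invisible(x)
}

# unordered pair -> single integer key (u < v, 1-based)
pair_key <- function(u, v, n) {
  a <- pmin(u, v); b <- pmax(u, v)
  (a - 1) * n + b
}
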