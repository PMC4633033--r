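# Structural connectivity: fiber-density networks built from per-subject
# fiber records (endpoint region pair + streamline length in mm).

#' Construct a fiber set
#'
#' @param subject_id Subject identifier.
#' @param fibers Data frame with columns `region_u`, `region_v` (region ids)
#'   and `length_mm` (> 0). Self-loops are forbidden; pairs are unordered.
#' @return Object of class `fiber_set`.
#' @export
fiber_set <- function(subject_id, fibers) {
  fibers <- as.data.frame(fibers)
  if (!all(c("region_u", "region_v", "length_mm") %in% names(fibers)))
    stop_invalid("fibers must have columns region_u, region_v, length_mm")
  if (nrow(fibers) > 0L) {
    if (any(!is.finite(fibers$length_mm)) || any(fibers$length_mm <= 0))
      stop_invalid("fiber lengths must be positive and finite")
    if (any(fibers$region_u == fibers$region_v))
      stop_invalid("self-loop fibers (region_u == region_v) are not allowed")
  }
  structure(list(subject_id = as.character(subject_id), fibers = fibers),
            class = "fiber_set")
}

#' Filter fibers by streamline length
#'
#' Keeps fibers whose length lies in `[min_len, max_len]` (bounds inclusive),
#' the conventional tract-length cutoff used when building fiber-density
#' networks; defaults are 20 and 500 mm. Order is preserved.
#'
#' @param fs A [fiber_set()].
#' @param min_len,max_len Length bounds in mm, `0 < min_len < max_len`.
#' @return A `fiber_set` with the surviving fibers.
#' @export
filter_fibers <- function(fs, min_len = 20, max_len = 500) {
  stopifnot(inherits(fs, "fiber_set"))
  check_scalar(min_len, "min_len", lo = .Machine$double.xmin)
  check_scalar(max_len, "max_len")
  if (min_len >= max_len)
    stop_invalid("min_len must be strictly less than max_len")
  keep <- fs$fibers$length_mm >= min_len & fs$fibers$length_mm <= max_len
  fiber_set(fs$subject_id, fs$fibers[keep, , drop = FALSE])
}

#' Fiber density between two regions
#'
#' The edge weight is the number of fiber tracks per unit surface,
#' `2 / (s_u + s_v) * sum_f 1 / l(f)`: each streamline contributes the
#' inverse of its length, normalized by the mean cortical surface area of the
#' two endpoint regions. An empty fiber list gives density 0.
#'
#' @param lengths Streamline lengths in mm (all > 0); may be empty.
#' @param s_u,s_v Endpoint cortical surface areas in mm^2 (> 0).
#' @return Fiber density (1/mm^3).
#' @export
fiber_density <- function(lengths, s_u, s_v) {
  check_scalar(s_u, "s_u", lo = .Machine$double.xmin)
  check_scalar(s_v, "s_v", lo = .Machine$double.xmin)
  if (length(lengths) == 0L) return(0)
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop_invalid("all fiber lengths must be positive and finite")
  2 / (s_u + s_v) * sum(1 / lengths)
}

#' Build a subject's structural connectivity matrix
#'
#' Applies the length cutoff, groups the surviving fibers by unordered region
#' pair, and fills a symmetric fiber-density matrix (zero diagonal). Region
#' pairs connected by no surviving fiber get density 0 and are marked absent
#' in the companion presence mask -- "no fiber" must stay distinguishable
#' from "tiny density" because downstream subject-exclusion logic depends on
#' edge presence, not magnitude.
#'
#' @param fs A [fiber_set()]; every endpoint id must exist in `atlas`.
#' @param atlas An [make_atlas()] table supplying surface areas.
#' @param min_len,max_len Length cutoff in mm (inclusive), default 20-500.
#' @return Object of class `structural_network`: list with `subject_id`,
#'   `density` (n x n symmetric matrix) and `present` (logical matrix,
#'   `present[u, v]` iff >= 1 surviving fiber joins u and v).
#' @export
build_structural_matrix <- function(fs, atlas, min_len = 20, max_len = 500) {
  stopifnot(inherits(fs, "fiber_set"))
  validate_atlas(atlas)
  n <- nrow(atlas)
  fib <- fs$fibers
  if (nrow(fib) > 0L) {
    bad <- !(fib$region_u %in% atlas$region) | !(fib$region_v %in% atlas$region)
    if (any(bad))
      stop_invalid(sprintf("fiber set '%s' references unknown region ids: %s",
                           fs$subject_id,
                           paste(unique(c(fib$region_u[bad], fib$region_v[bad])),
                                 collapse = ", ")))
  }
  fib <- filter_fibers(fs, min_len, max_len)$fibers

  density <- matrix(0, n, n)
  present <- matrix(FALSE, n, n)
  if (nrow(fib) > 0L) {
    u <- pmin(fib$region_u, fib$region_v)
    v <- pmax(fib$region_u, fib$region_v)
    inv <- rowsum(1 / fib$length_mm, group = pair_key(u, v, n))
    key <- as.numeric(rownames(inv))
    pu <- (key - 1) %/% n + 1
    pv <- key - (pu - 1) * n
    dens <- 2 / (atlas$surface_area[pu] + atlas$surface_area[pv]) * inv[, 1L]
    density[cbind(pu, pv)] <- dens
    density[cbind(pv, pu)] <- dens
    present[cbind(pu, pv)] <- TRUE
    present[cbind(pv, pu)] <- TRUE
  }
  dimnames(density) <- dimnames(present) <- list(atlas$name, atlas$name)
  structure(list(subject_id = fs$subject_id, density = density,
                 present = present),
            class = "structural_network")
}

#' @export
print.structural_network <- function(x, ...) {
  cat(sprintf("<structural_network> subject %s: %d regions, %d present edges\n",
              x$subject_id, nrow(x$density), sum(x$present[upper.tri(x$present)])))
  invisible(x)
}
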