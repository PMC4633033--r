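# Edge-wise group comparison of structural networks: pooled-t statistics,
# max-statistic permutation FWE correction, per-edge subject exclusion and
# reward-system filtering.

GROUP_LEVELS <- c("HW", "nonHW")

#' Collect per-edge density samples across subjects
#'
#' Builds, for every unordered region pair connected in at least one subject,
#' the vector of fiber densities over subjects in which the edge is present.
#' Subjects without the edge are excluded from that edge's test; an edge is
#' eligible for testing only when the excluded fraction is below
#' `max_excluded` (default 20%) and each group retains at least two
#' subjects, so removal bias stays bounded.
#'
#' @param networks List of [build_structural_matrix()] results, one per
#'   subject, all on the same atlas.
#' @param labels Group labels, one per network, values `"HW"` / `"nonHW"`.
#' @param max_excluded Maximum tolerated excluded-subject fraction.
#' @return Object of class `edge_samples`: list with `edges` (data frame:
#'   `u`, `v`, `n_present`, `excluded_fraction`, `n_hw`, `n_nhw`,
#'   `eligible`), `values` and `present` (edges x subjects matrices),
#'   `labels`, `subject_ids`.
#' @export
collect_edge_samples <- function(networks, labels, max_excluded = 0.20) {
  if (!length(networks)) stop_invalid("no networks supplied")
  labels <- as.character(labels)
  if (length(labels) != length(networks))
    stop_invalid("one group label per network is required")
  if (!all(labels %in% GROUP_LEVELS))
    stop_invalid("labels must be 'HW' or 'nonHW'")
  if (min(table(factor(labels, GROUP_LEVELS))) < 2L)
    stop_invalid("need at least 2 subjects per group")
  check_scalar(max_excluded, "max_excluded", lo = 0, hi = 1)

  n <- nrow(networks[[1L]]$density)
  s <- length(networks)
  ut <- upper.tri(matrix(0, n, n))
  uv <- which(ut, arr.ind = TRUE)  # col 1 = row (u), col 2 = col (v), u < v

  values <- vapply(networks, function(net) {
    if (nrow(net$density) != n)
      stop_invalid("networks are not all on the same atlas")
    net$density[ut]
  }, numeric(sum(ut)))
  present <- vapply(networks, function(net) net$present[ut], logical(sum(ut)))

  any_present <- rowSums(present) > 0L
  values <- values[any_present, , drop = FALSE]
  present <- present[any_present, , drop = FALSE]
  uv <- uv[any_present, , drop = FALSE]

  is_hw <- labels == "HW"
  n_present <- rowSums(present)
  n_hw <- rowSums(present[, is_hw, drop = FALSE])
  n_nhw <- n_present - n_hw
  excluded_fraction <- 1 - n_present / s
  eligible <- excluded_fraction < max_excluded & n_hw >= 2L & n_nhw >= 2L

  edges <- data.frame(u = uv[, 1L], v = uv[, 2L], n_present = n_present,
                      excluded_fraction = excluded_fraction,
                      n_hw = n_hw, n_nhw = n_nhw, eligible = eligible)
  structure(list(edges = edges,
                 values = values * present,  # zero where absent
                 present = present,
                 labels = labels,
                 subject_ids = vapply(networks, `[[`, "", "subject_id")),
            class = "edge_samples")
}

#' @export
print.edge_samples <- function(x, ...) {
  cat(sprintf("<edge_samples> %d edges (%d eligible) x %d subjects\n",
              nrow(x$edges), sum(x$edges$eligible), ncol(x$values)))
  invisible(x)
}

#' Pooled two-sample t statistic
#'
#' Classic equal-variance two-sample t with orientation `a - b`; the
#' permutation machinery uses its absolute value, so the test is two-sided.
#'
#' @param values_a,values_b Numeric samples, each of length >= 2.
#' @return The t value.
#' @export
edge_statistic <- function(values_a, values_b) {
  na <- length(values_a); nb <- length(values_b)
  if (na < 2L || nb < 2L) stop_invalid("need >= 2 values per group")
  sp2 <- (sum((values_a - mean(values_a))^2) +
            sum((values_b - mean(values_b))^2)) / (na + nb - 2L)
  if (sp2 <= 0) stop_invalid("zero pooled variance; t statistic undefined")
  (mean(values_a) - mean(values_b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# Vectorized pooled t for all edges under a matrix of 0/1 group-A indicator
# columns (one column per labelling). V = values (0 where absent), P =
# presence, both edges x subjects. Returns edges x labellings matrix;
# degenerate cells (a group < 2 present subjects, or zero pooled variance)
# are NA.
edge_t_matrix <- function(V, P, G) {
  Pn <- P * 1
  V2 <- V * V
  nA <- Pn %*% G
  nB <- rowSums(Pn) - nA
  sA <- V %*% G
  sB <- rowSums(V) - sA
  qA <- V2 %*% G
  qB <- rowSums(V2) - qA
  ok <- nA >= 2 & nB >= 2
  nA[!ok] <- NA
  mA <- sA / nA; mB <- sB / nB
  ssA <- pmax(qA - sA^2 / nA, 0)
  ssB <- pmax(qB - sB^2 / nB, 0)
  sp2 <- (ssA + ssB) / (nA + nB - 2)
  t <- (mA - mB) / sqrt(sp2 * (1 / nA + 1 / nB))
  t[!is.finite(t)] <- NA
  t
}

#' Edge-wise permutation test with max-statistic FWE correction
#'
#' For each of `n_perm` permutations the subject group labels are shuffled
#' once globally (shared by all edges, as required for a valid max-statistic
#' family-wise correction) and every eligible edge's pooled t is recomputed
#' on that edge's own present-subject set -- presence is a property of the
#' subject's anatomy and is never permuted. P-values use the add-one
#' permutation estimator, so the smallest reportable p is
#' `1 / (n_perm + 1)`:
#' \itemize{
#'   \item `p_uncorrected = (1 + #\{|t_perm| >= |t_obs|\}) / (n_perm + 1)`
#'     per edge;
#'   \item `p_corrected = (1 + #\{max_edges |t_perm| >= |t_obs|\}) /
#'     (n_perm + 1)` (single-step max-statistic FWE).
#' }
#'
#' @param samples An [collect_edge_samples()] object; only eligible edges
#'   are tested.
#' @param n_perm Number of permutations (>= 100; 5000 by default, the usual
#'   choice for connectome-wide edge screening).
#' @param seed Integer seed; results are deterministic given the seed.
#' @param block_size Permutations processed per matrix block (memory knob).
#' @return Data frame of class `edge_test_result` with columns `u`, `v`,
#'   `t_stat`, `p_uncorrected`, `p_corrected`, `excluded_fraction`,
#'   `eligible`. Empty (with a warning) if no edge is eligible.
#' @export
permutation_test <- function(samples, n_perm = 5000L, seed = 1L,
                             block_size = 1000L) {
  stopifnot(inherits(samples, "edge_samples"))
  check_scalar(n_perm, "n_perm", lo = 100)
  n_perm <- as.integer(n_perm)

  keep <- samples$edges$eligible
  if (!any(keep)) {
    warning("no eligible edges; permutation test returns an empty result")
    res <- cbind(samples$edges[0L, c("u", "v")],
                 data.frame(t_stat = numeric(0), p_uncorrected = numeric(0),
                            p_corrected = numeric(0),
                            excluded_fraction = numeric(0),
                            eligible = logical(0)))
    class(res) <- c("edge_test_result", "data.frame")
    return(res)
  }
  V <- samples$values[keep, , drop = FALSE]
  P <- samples$present[keep, , drop = FALSE]
  g_obs <- matrix(as.numeric(samples$labels == "HW"), ncol = 1L)
  t_obs <- edge_t_matrix(V, P, g_obs)[, 1L]
  if (anyNA(t_obs))
    stop_invalid("degenerate eligible edge (zero pooled variance) in observed data")
  abs_obs <- abs(t_obs)

  n_ge_edge <- numeric(length(t_obs))
  n_ge_max <- numeric(length(t_obs))
  withr::with_seed(as.integer(seed), {
    done <- 0L
    while (done < n_perm) {
      b <- min(block_size, n_perm - done)
      G <- vapply(seq_len(b),
                  function(i) as.numeric(sample(samples$labels) == "HW"),
                  numeric(length(samples$labels)))
      Tp <- abs(edge_t_matrix(V, P, G))
      n_ge_edge <- n_ge_edge + rowSums(Tp >= abs_obs, na.rm = TRUE)
      maxs <- apply(Tp, 2L, max, na.rm = TRUE)
      n_ge_max <- n_ge_max + vapply(abs_obs, function(a) sum(maxs >= a), 0)
      done <- done + b
    }
  })

  res <- cbind(samples$edges[keep, c("u", "v")],
               data.frame(t_stat = t_obs,
                          p_uncorrected = (1 + n_ge_edge) / (n_perm + 1),
                          p_corrected = (1 + n_ge_max) / (n_perm + 1),
                          excluded_fraction =
                            samples$edges$excluded_fraction[keep],
                          eligible = TRUE))
  rownames(res) <- NULL
  class(res) <- c("edge_test_result", "data.frame")
  res
}

#' Keep significant edges touching the reward system
#'
#' Retains edges with corrected p below `alpha` whose endpoints include at
#' least one reward-flagged region (thalamus, insula, putamen or
#' orbitofrontal cortex in the default atlas), the reward-system focus used
#' when relating structural differences to obesity.
#'
#' @param results An [permutation_test()] result.
#' @param atlas The atlas the networks were built on.
#' @param alpha Significance level for the corrected p-value, in (0, 1).
#' @return The filtered `edge_test_result` with added columns `reward_hit`,
#'   `name_u`, `name_v`.
#' @export
filter_reward_edges <- function(results, atlas, alpha = 0.05) {
  stopifnot(inherits(results, "edge_test_result"))
  validate_atlas(atlas)
  check_scalar(alpha, "alpha", lo = 1e-12, hi = 1 - 1e-12)
  hit <- atlas$reward[results$u] | atlas$reward[results$v]
  out <- results[results$p_corrected < alpha & hit, , drop = FALSE]
  out$reward_hit <- rep(TRUE, nrow(out))
  out$name_u <- atlas$name[out$u]
  out$name_v <- atlas$name[out$v]
  rownames(out) <- NULL
  class(out) <- c("edge_test_result", "data.frame")
  out
}
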