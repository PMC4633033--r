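# Cross-modal coupling: retain significant structural edges whose fiber
# density correlates with the mean functional connectivity of either
# endpoint, then assemble the deduplicated multimodal feature set.

#' Correlate a structural edge with its endpoints' mean functional
#' connectivity
#'
#' Pearson correlation (with two-sided p) between the edge's per-subject
#' fiber density and each endpoint region's mean functional connectivity,
#' computed over the subjects in which the edge is present. The edge is
#' retained when either endpoint's correlation is significant at `alpha`;
#' these coupling p-values are deliberately not multiplicity-corrected (the
#' edge set was already screened with a family-wise-corrected test).
#'
#' @param edge_densities Per-subject fiber densities of the edge.
#' @param mean_fc_u,mean_fc_v Per-subject mean functional connectivity of
#'   the two endpoint regions, aligned with `edge_densities`.
#' @param alpha Significance level, in (0, 1).
#' @param present Optional logical vector selecting the subjects in which
#'   the edge is present; defaults to all subjects.
#' @return Object of class `coupling_record`: list with `r1`, `p1`, `r2`,
#'   `p2`, `n`, `retained`.
#' @export
couple_edge <- function(edge_densities, mean_fc_u, mean_fc_v, alpha = 0.05,
                        present = NULL) {
  check_scalar(alpha, "alpha", lo = 1e-12, hi = 1 - 1e-12)
  if (length(mean_fc_u) != length(edge_densities) ||
      length(mean_fc_v) != length(edge_densities))
    stop_invalid("edge densities and mean-FC vectors must be subject-aligned")
  if (is.null(present)) present <- rep(TRUE, length(edge_densities))
  d <- edge_densities[present]
  fu <- mean_fc_u[present]
  fv <- mean_fc_v[present]
  if (length(d) < 4L)
    stop_invalid("coupling needs >= 4 paired observations")
  ct1 <- stats::cor.test(d, fu)
  ct2 <- stats::cor.test(d, fv)
  rec <- list(r1 = unname(ct1$estimate), p1 = ct1$p.value,
              r2 = unname(ct2$estimate), p2 = ct2$p.value,
              n = length(d),
              retained = ct1$p.value < alpha || ct2$p.value < alpha)
  class(rec) <- "coupling_record"
  rec
}

#' Couple every significant edge to functional connectivity
#'
#' Applies [couple_edge()] to each edge in a (typically reward-filtered)
#' permutation-test result, using the per-edge present-subject sets.
#'
#' @param results An `edge_test_result` (rows = edges to couple).
#' @param samples The [collect_edge_samples()] object the test was run on.
#' @param mean_fc_matrix Subjects x regions matrix of mean functional
#'   connectivity values.
#' @param atlas Atlas table (for edge names).
#' @param alpha Coupling significance level.
#' @return Data frame of class `coupling_table` with one row per edge:
#'   `u`, `v`, `name_u`, `name_v`, `r1`, `p1`, `r2`, `p2`, `n`, `retained`.
#' @export
couple_edges <- function(results, samples, mean_fc_matrix, atlas,
                         alpha = 0.05) {
  stopifnot(inherits(results, "edge_test_result"),
            inherits(samples, "edge_samples"))
  validate_atlas(atlas)
  if (nrow(mean_fc_matrix) != ncol(samples$values))
    stop_invalid("mean_fc_matrix must have one row per subject")
  rows <- lapply(seq_len(nrow(results)), function(i) {
    u <- results$u[i]; v <- results$v[i]
    e <- which(samples$edges$u == u & samples$edges$v == v)
    if (length(e) != 1L)
      stop_invalid(sprintf("edge (%d, %d) not found in samples", u, v))
    rec <- couple_edge(samples$values[e, ], mean_fc_matrix[, u],
                       mean_fc_matrix[, v], alpha = alpha,
                       present = samples$present[e, ])
    data.frame(u = u, v = v, name_u = atlas$name[u], name_v = atlas$name[v],
               r1 = rec$r1, p1 = rec$p1, r2 = rec$r2, p2 = rec$p2,
               n = rec$n, retained = rec$retained)
  })
  out <- do.call(rbind, rows) %||% data.frame()
  if (!nrow(out))
    out <- data.frame(u = integer(0), v = integer(0), name_u = character(0),
                      name_v = character(0), r1 = numeric(0), p1 = numeric(0),
                      r2 = numeric(0), p2 = numeric(0), n = integer(0),
                      retained = logical(0))
  class(out) <- c("coupling_table", "data.frame")
  out
}

#' Assemble the multimodal feature set
#'
#' One structural feature per retained edge (per-subject fiber density, with
#' 0 for subjects lacking the edge, so the regression design has no holes)
#' and one functional feature per distinct region whose side-specific
#' coupling was significant -- a region shared by several retained edges
#' appears once, and an endpoint whose own coupling failed significance
#' contributes no functional feature. This is the bookkeeping that turns
#' 2 x (number of retained edges) candidate regions into the final
#' functional feature list.
#'
#' @param coupling A [couple_edges()] table.
#' @param samples The [collect_edge_samples()] object (structural densities).
#' @param mean_fc_matrix Subjects x regions mean-FC matrix.
#' @param atlas Atlas table.
#' @param alpha Side-specific coupling significance level (same value used
#'   in [couple_edges()]).
#' @return Object of class `feature_set`: list with `X` (subjects x features
#'   numeric matrix; columns named `SC:<regionA>-<regionB>` and
#'   `FC:<region>`), `structural` (data frame of retained edges),
#'   `functional_regions` (integer region ids) and `provenance` (the
#'   coupling table).
#' @export
assemble_features <- function(coupling, samples, mean_fc_matrix, atlas,
                              alpha = 0.05) {
  stopifnot(inherits(coupling, "coupling_table"))
  validate_atlas(atlas)
  kept <- coupling[coupling$retained, , drop = FALSE]
  n_subj <- nrow(mean_fc_matrix)

  sc_cols <- list(); fc_regions <- integer(0)
  for (i in seq_len(nrow(kept))) {
    u <- kept$u[i]; v <- kept$v[i]
    e <- which(samples$edges$u == u & samples$edges$v == v)
    if (length(e) != 1L)
      stop_invalid(sprintf("edge (%d, %d) not found in samples", u, v))
    sc_cols[[sprintf("SC:%s-%s", atlas$name[u], atlas$name[v])]] <-
      samples$values[e, ]
    if (kept$p1[i] < alpha) fc_regions <- c(fc_regions, u)
    if (kept$p2[i] < alpha) fc_regions <- c(fc_regions, v)
  }
  fc_regions <- fc_regions[!duplicated(fc_regions)]

  X <- matrix(numeric(0), nrow = n_subj, ncol = 0L)
  if (length(sc_cols)) X <- do.call(cbind, sc_cols)
  if (length(fc_regions)) {
    fc <- mean_fc_matrix[, fc_regions, drop = FALSE]
    colnames(fc) <- sprintf("FC:%s", atlas$name[fc_regions])
    X <- cbind(X, fc)
  }
  rownames(X) <- rownames(mean_fc_matrix)
  structure(list(X = X,
                 structural = kept,
                 functional_regions = fc_regions,
                 provenance = coupling),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d structural + %d functional features, %d subjects\n",
              nrow(x$structural), length(x$functional_regions), nrow(x$X)))
  invisible(x)
}
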