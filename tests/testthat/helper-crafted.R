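# Craft a 120-subject configuration with 6 significant edges whose
# densities we control exactly, mirroring the bookkeeping of a reward-system
# connectivity analysis: 12 endpoint couplings, one side non-significant,
# one region shared by two edges.
crafted_coupling_setup <- function(seed = 101) {
  atlas <- make_atlas(20, seed = 2)
  n_subj <- 120
  edges <- data.frame(u = c(6L, 6L, 2L, 4L, 7L, 8L),
                      v = c(10L, 15L, 11L, 13L, 16L, 17L))
  withr::with_seed(seed, {
    D <- matrix(abs(rnorm(n_subj * 6)) + 0.5, n_subj, 6)
    noise <- rnorm(n_subj)
  })
  nets <- lapply(seq_len(n_subj), function(i) {
    d <- matrix(0, 20, 20)
    for (j in seq_len(6)) {
      d[edges$u[j], edges$v[j]] <- d[edges$v[j], edges$u[j]] <- D[i, j]
    }
    craft_network(sprintf("s%03d", i), d)
  })
  mfc <- matrix(0, n_subj, 20)
  # every endpoint's mean FC copies its edge's density (r = 1) except:
  # region 6 (shared by edges 1 and 2) sums both, and region 11 is made
  # exactly orthogonal to its edge's density (r = 0, p = 1)
  mfc[, 10] <- D[, 1]; mfc[, 15] <- D[, 2]
  mfc[, 6] <- D[, 1] + D[, 2]
  mfc[, 2] <- D[, 3]; mfc[, 11] <- stats::resid(stats::lm(noise ~ D[, 3]))
  mfc[, 4] <- D[, 4]; mfc[, 13] <- D[, 4]^2 + D[, 4]
  mfc[, 7] <- D[, 5]; mfc[, 16] <- D[, 5]
  mfc[, 8] <- D[, 6]; mfc[, 17] <- D[, 6]
  rownames(mfc) <- sprintf("s%03d", seq_len(n_subj))
  samples <- collect_edge_samples(nets, rep(c("HW", "nonHW"), 60))
  results <- data.frame(u = edges$u, v = edges$v, t_stat = 5,
                        p_uncorrected = 1e-3, p_corrected = 1e-2,
                        excluded_fraction = 0, eligible = TRUE)
  class(results) <- c("edge_test_result", "data.frame")
  list(atlas = atlas, samples = samples, results = results, mfc = mfc, D = D)
}
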