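# Edge-wise permutation testing with FWE correction and subject exclusion.

test_that("edge eligibility follows the excluded-fraction rule", {
  n_subj <- 120
  dens <- matrix(0, 4, 4)
  nets <- lapply(seq_len(n_subj), function(i) {
    d <- matrix(0, 4, 4)
    d[1, 2] <- d[2, 1] <- abs(rnorm(1)) + 0.1          # always present
    if (i <= 90) d[1, 3] <- d[3, 1] <- abs(rnorm(1)) + 0.1  # 90 / 120
    craft_network(sprintf("s%d", i), d)
  })
  labels <- rep(c("HW", "nonHW"), 60)
  samp <- collect_edge_samples(nets, labels, max_excluded = 0.20)
  e12 <- samp$edges[samp$edges$u == 1 & samp$edges$v == 2, ]
  e13 <- samp$edges[samp$edges$u == 1 & samp$edges$v == 3, ]
  expect_equal(e12$excluded_fraction, 0)
  expect_true(e12$eligible)
  expect_equal(e13$excluded_fraction, 0.25)
  expect_false(e13$eligible)            # 0.25 >= 0.20
  # edges absent everywhere are not emitted
  expect_equal(nrow(samp$edges), 2L)
})

test_that("pooled t matches hand computation and is antisymmetric", {
  expect_equal(edge_statistic(c(1, 2, 3), c(4, 5, 6)), -3.674,
               tolerance = 1e-3)
  expect_equal(edge_statistic(c(4, 5, 6), c(1, 2, 3)),
               -edge_statistic(c(1, 2, 3), c(4, 5, 6)))
  # mirrored samples: identical means and spread give t = 0
  expect_equal(edge_statistic(c(1, 2, 3), c(3, 1, 2)), 0)
  expect_error(edge_statistic(c(1), c(2, 3)), ">= 2")
  expect_error(edge_statistic(c(1, 1), c(1, 1)), "pooled variance")
})

test_that("permutation p-values are valid, ordered and deterministic", {
  co <- make_structural_cohort(structural_spec(
    15, n_regions = 6, seed = 77,
    planted_edges = data.frame(u = 1L, v = 4L, d = 1.5)))
  samp <- collect_edge_samples(co$networks, co$groups)
  res <- permutation_test(samp, n_perm = 300, seed = 4)
  expect_true(all(res$p_corrected >= res$p_uncorrected))
  expect_true(all(res$p_uncorrected >= 1 / 301))
  expect_true(all(res$p_corrected <= 1))
  expect_identical(res, permutation_test(samp, n_perm = 300, seed = 4))
  expect_false(identical(res$p_uncorrected,
                         permutation_test(samp, n_perm = 300,
                                          seed = 5)$p_uncorrected))
})

test_that("complete separation attains the minimum reportable p", {
  # shift of 5 pooled SDs at n = 20/20: the observed |t| dominates every
  # label shuffle, so corrected p is exactly 1/(n_perm + 1)
  withr::with_seed(11, {
    base <- rnorm(40)
    vals <- base + rep(c(0, 5), each = 20)
  })
  nets <- lapply(seq_len(40), function(i) {
    d <- matrix(0, 3, 3)
    d[1, 2] <- d[2, 1] <- vals[i] + 10  # keep densities positive
    craft_network(sprintf("s%d", i), d)
  })
  labels <- rep(c("HW", "nonHW"), each = 20)
  res <- permutation_test(collect_edge_samples(nets, labels),
                          n_perm = 1000, seed = 2)
  expect_equal(res$p_corrected, 1 / 1001)
  expect_equal(res$p_uncorrected, 1 / 1001)
})

test_that("reward filtering keeps only significant reward-touching edges", {
  atlas <- make_atlas(8, seed = 1, n_reward = 2)  # regions 1, 2 reward
  res <- data.frame(u = c(1L, 3L, 2L), v = c(5L, 4L, 6L),
                    t_stat = c(4, 5, 1),
                    p_uncorrected = c(0.001, 0.001, 0.4),
                    p_corrected = c(0.01, 0.01, 0.9),
                    excluded_fraction = 0, eligible = TRUE)
  class(res) <- c("edge_test_result", "data.frame")
  out <- filter_reward_edges(res, atlas, alpha = 0.05)
  # (3,4) significant but touches no reward region; (2,6) reward but not
  # significant
  expect_equal(nrow(out), 1L)
  expect_equal(out$u, 1L)
  expect_true(out$reward_hit)
  expect_equal(out$name_u, "Thalamus_L")
  # nothing significant -> empty
  res$p_corrected <- 0.5
  expect_equal(nrow(filter_reward_edges(res, atlas)), 0L)
})

test_that("a cohort with no eligible edges returns an empty result with a warning", {
  nets <- lapply(1:10, function(i) {
    d <- matrix(0, 3, 3)
    if (i <= 3) d[1, 2] <- d[2, 1] <- 1  # 70% excluded -> ineligible
    craft_network(sprintf("s%d", i), d)
  })
  samp <- collect_edge_samples(nets, rep(c("HW", "nonHW"), 5))
  expect_warning(res <- permutation_test(samp, n_perm = 100, seed = 1),
                 "no eligible")
  expect_equal(nrow(res), 0L)
})
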