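# Shared cohort configurations for tests. Sizes are kept small; the
# statistical conditions (group BMI moments, length distribution, effect
# sizes) are the generator defaults.

no_edges <- function() data.frame(u = integer(0), v = integer(0), d = numeric(0))
no_coupling <- function() data.frame(u = integer(0), v = integer(0),
                                     target_region = integer(0),
                                     target_r = numeric(0))
no_drivers <- function() data.frame(feature = character(0),
                                    coefficient = numeric(0))

# Structural-only spec: no coupling, no BMI drivers; cheap to generate.
structural_spec <- function(n_per_group, n_regions = 7L, seed = 1L,
                            planted_edges = no_edges(), edge_sparsity = 0, ...) {
  synthetic_spec(n_per_group = n_per_group, n_regions = n_regions,
                 n_timepoints = 64L, edge_sparsity = edge_sparsity,
                 planted_edges = planted_edges,
                 coupling_edges = no_coupling(),
                 bmi_driver_features = no_drivers(),
                 seed = seed, ...)
}

# Fiber sets + group labels for a two-group structural cohort.
make_structural_cohort <- function(spec) {
  atlas <- make_atlas(spec$n_regions, derive_seed(spec$seed, "atlas"))
  n <- 2L * spec$n_per_group
  groups <- rep(c("HW", "nonHW"), each = spec$n_per_group)
  nets <- lapply(seq_len(n), function(i) {
    fs <- simulate_fibers(atlas, spec,
                          subject_effect = as.numeric(groups[i] == "nonHW"),
                          seed = derive_seed(spec$seed, "fibers", i),
                          subject_id = sprintf("s%03d", i))
    build_structural_matrix(fs, atlas)
  })
  list(atlas = atlas, networks = nets, groups = groups)
}
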