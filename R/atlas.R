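# Synthetic parcellation atlas: region labels, cortical surface areas and
# reward-system flags.

REWARD_REGION_NAMES <- c(
  "Thalamus_L", "Thalamus_R", "Insula_L", "Insula_R",
  "Putamen_L", "Putamen_R", "Frontal_Sup_Orb_L", "Frontal_Sup_Orb_R"
)

PARTNER_REGION_NAMES <- c(
  "Lingual_L", "Hippocampus_R", "Caudate_R", "Postcentral_L", "Olfactory_R",
  "Pallidum_L", "Heschl_R", "Amygdala_L", "ParaHippocampal_R", "Precuneus_L"
)

#' Build a synthetic parcellation atlas
#'
#' Emulates a whole-brain parcellation (116 regions by default, the size of
#' the AAL atlas commonly used for connectome construction). Each region gets
#' a positive cortical surface area drawn from a lognormal distribution, and
#' a configurable number of regions are flagged as belonging to the reward
#' system (thalamus, insula, putamen and orbitofrontal cortex, left and
#' right). Region names are synthetic stand-ins, not a real AAL ordering.
#'
#' @param n_regions Number of regions (>= 4).
#' @param seed Integer seed; the same seed always yields the same atlas.
#' @param n_reward Number of reward-flagged regions; defaults to 8 (four
#'   bilateral reward structures) capped at half the atlas.
#' @param surface_log_mean,surface_log_sd Lognormal parameters (log mm^2) for
#'   region surface areas. Defaults give a median area of about 25 cm^2.
#' @return A data frame of class `atlas` with columns `region` (1-based id),
#'   `name`, `surface_area` (mm^2) and `reward` (logical).
#' @export
make_atlas <- function(n_regions, seed = 1L,
                       n_reward = min(8L, n_regions %/% 2L),
                       surface_log_mean = log(2500), surface_log_sd = 0.5) {
  check_scalar(n_regions, "n_regions", lo = 4)
  check_scalar(n_reward, "n_reward", lo = 0, hi = n_regions)
  n_regions <- as.integer(n_regions)
  n_reward <- as.integer(n_reward)

  nm <- character(n_regions)
  k_named <- min(n_regions, length(REWARD_REGION_NAMES))
  nm[seq_len(k_named)] <- REWARD_REGION_NAMES[seq_len(k_named)]
  if (n_regions > 8L) {
    k2 <- min(n_regions - 8L, length(PARTNER_REGION_NAMES))
    nm[8L + seq_len(k2)] <- PARTNER_REGION_NAMES[seq_len(k2)]
  }
  rest <- which(nm == "")
  nm[rest] <- sprintf("Region_%03d", rest)

  areas <- withr::with_seed(
    derive_seed(seed, "atlas-areas"),
    stats::rlnorm(n_regions, meanlog = surface_log_mean, sdlog = surface_log_sd)
  )

  atlas <- data.frame(
    region = seq_len(n_regions),
    name = nm,
    surface_area = areas,
    reward = seq_len(n_regions) <= n_reward,
    stringsAsFactors = FALSE
  )
  class(atlas) <- c("atlas", "data.frame")
  atlas
}

validate_atlas <- function(atlas) {
  if (!all(c("region", "name", "surface_area", "reward") %in% names(atlas)))
    stop_invalid("atlas must have columns region, name, surface_area, reward")
  if (anyDuplicated(atlas$region) || !identical(as.integer(atlas$region),
                                                seq_len(nrow(atlas))))
    stop_invalid("atlas region ids must be unique and contiguous from 1")
  if (any(atlas$surface_area <= 0))
    stop_invalid("atlas surface areas must be positive")
  invisible(atlas)
}

#' @export
print.atlas <- function(x, ...) {
  cat(sprintf("<atlas> %d regions, %d reward-flagged\n",
              nrow(x), sum(x$reward)))
  print.data.frame(utils::head(x, 8L))
  if (nrow(x) > 8L) cat(sprintf("  ... %d more regions\n", nrow(x) - 8L))
  invisible(x)
}
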