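# End-to-end orchestration: config validation, stage execution, output
# tables and a reproducibility manifest with per-stage checksums.

PIPELINE_DEFAULTS <- list(
  min_len = 20, max_len = 500,
  f_lo = 0.009, f_hi = 0.08,
  sampling_interval = 0.72,
  n_perm = 5000L,
  alpha_edge = 0.05, alpha_coupling = 0.05,
  max_excluded = 0.20,
  max_lv = 10L,
  modality = "combined",
  seed = 1L,
  write_networks = FALSE
)

#' Build and validate a pipeline configuration
#'
#' @param cohort_dir Directory holding `atlas.tsv`, `subjects.csv`,
#'   `fibers.tsv` and `ts/<subject>.csv` (see [write_cohort()]).
#' @param output_dir Directory for stage outputs and the manifest.
#' @param ... Parameter overrides; defaults are the conventional analysis
#'   values: length cutoff 20-500 mm, band 0.009-0.08 Hz, 5000
#'   permutations, alpha 0.05 for both the corrected edge test and the
#'   coupling rule, 20% maximum excluded-subject fraction.
#'   `modality` is one of `"combined"`, `"dti_only"`, `"fmri_only"` and
#'   restricts only the regression design matrix (feature selection stays
#'   multimodal).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort_dir, output_dir, ...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(PIPELINE_DEFAULTS))
  if (length(unknown))
    stop_invalid("unknown pipeline parameter(s): ",
                 paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(PIPELINE_DEFAULTS, over)
  cfg$cohort_dir <- cohort_dir
  cfg$output_dir <- output_dir
  if (!cfg$modality %in% c("combined", "dti_only", "fmri_only"))
    stop_invalid("modality must be combined, dti_only or fmri_only")
  for (nm in c("alpha_edge", "alpha_coupling"))
    check_scalar(cfg[[nm]], nm, lo = 1e-12, hi = 1 - 1e-12)
  check_scalar(cfg$max_excluded, "max_excluded", lo = 0, hi = 1)
  check_scalar(cfg$n_perm, "n_perm", lo = 100)
  check_scalar(cfg$max_lv, "max_lv", lo = 1)
  if (cfg$min_len >= cfg$max_len) stop_invalid("min_len must be < max_len")
  if (cfg$f_lo >= cfg$f_hi) stop_invalid("f_lo must be < f_hi")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Strict: unknown keys are an error. `cohort_dir` and `output_dir` are
#' required.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$cohort_dir) || is.null(y$output_dir))
    stop_invalid(path, ": cohort_dir and output_dir are required")
  args <- y[setdiff(names(y), c("cohort_dir", "output_dir"))]
  do.call(pipeline_config,
          c(list(cohort_dir = y$cohort_dir, output_dir = y$output_dir), args))
}

restrict_modality <- function(X, modality) {
  keep <- switch(modality,
                 combined = rep(TRUE, ncol(X)),
                 dti_only = startsWith(colnames(X), "SC:"),
                 fmri_only = startsWith(colnames(X), "FC:"))
  X[, keep, drop = FALSE]
}

#' Run the full multimodal analysis pipeline
#'
#' Executes, in order: structural network construction, functional network
#' construction, edge-wise permutation testing with reward filtering,
#' cross-modal coupling and feature assembly, and PLSR BMI prediction under
#' leave-one-subject-out cross-validation. All stage tables are written
#' under the configured output directory, followed by a manifest
#' (`manifest.json`) recording the configuration, per-stage row counts,
#' wall-clock times and the md5 checksum of every output file; re-running
#' with the same inputs and seed reproduces the checksums bit for bit.
#'
#' An empty significant-edge set short-circuits the run: the manifest gets
#' `status = "no_significant_edges"` and downstream stages are skipped.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = unclass(config), counts = list(),
                   timings = list(), status = "ok")
  outputs <- character(0)
  t_stage <- function(expr) {
    t0 <- Sys.time()
    res <- force(expr)
    list(res = res, secs = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }

  data <- read_cohort(config$cohort_dir, config$sampling_interval)
  atlas <- data$atlas
  subjects <- data$subjects
  manifest$counts$subjects <- nrow(subjects)
  manifest$counts$regions <- nrow(atlas)

  ## structural networks
  st <- t_stage({
    lapply(data$fiber_sets, build_structural_matrix, atlas = atlas,
           min_len = config$min_len, max_len = config$max_len)
  })
  networks <- st$res
  manifest$timings$structural <- st$secs
  if (isTRUE(config$write_networks)) {
    dir.create(file.path(out, "structural"), showWarnings = FALSE)
    for (net in networks) {
      p <- file.path(out, "structural", paste0(net$subject_id, ".csv"))
      write_matrix_csv(net$density, p)
      outputs <- c(outputs, p)
      p2 <- file.path(out, "structural", paste0(net$subject_id, "_present.csv"))
      write_matrix_csv(net$present * 1L, p2)
      outputs <- c(outputs, p2)
    }
  }

  ## functional networks (clean -> correlate -> mean FC)
  fn <- t_stage({
    nets <- lapply(data$timeseries, function(ts) {
      correlation_matrix(bandpass(regress_nuisance(ts),
                                  config$f_lo, config$f_hi))
    })
    mfc <- t(vapply(nets, `[[`, numeric(nrow(atlas)), "mean_fc"))
    rownames(mfc) <- subjects$subject_id
    colnames(mfc) <- atlas$name
    mfc
  })
  mean_fc_matrix <- fn$res
  manifest$timings$functional <- fn$secs
  p <- file.path(out, "mean_fc.csv")
  write_matrix_csv(mean_fc_matrix, p)
  outputs <- c(outputs, p)

  ## edge-wise permutation test + reward filter
  gt <- t_stage({
    samples <- collect_edge_samples(networks, subjects$group,
                                    config$max_excluded)
    results <- permutation_test(samples, n_perm = config$n_perm,
                                seed = config$seed)
    sig <- filter_reward_edges(results, atlas, config$alpha_edge)
    list(samples = samples, results = results, sig = sig)
  })
  manifest$timings$edge_test <- gt$secs
  manifest$counts$edges_tested <- nrow(gt$res$results)
  manifest$counts$edges_significant <- nrow(gt$res$sig)
  sig_tab <- gt$res$sig
  sig_out <- data.frame(
    region_u_name = sig_tab$name_u, region_v_name = sig_tab$name_v,
    t_stat = sig_tab$t_stat, p_uncorrected = sig_tab$p_uncorrected,
    p_corrected = sig_tab$p_corrected, eligible = sig_tab$eligible,
    reward_hit = sig_tab$reward_hit)
  p <- file.path(out, "significant_edges.tsv")
  data.table::fwrite(sig_out, p, sep = "\t")
  outputs <- c(outputs, p)

  if (nrow(sig_tab) == 0L) {
    manifest$status <- "no_significant_edges"
    manifest$checksums <- as.list(tools::md5sum(outputs))
    names(manifest$checksums) <- basename(outputs)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    message("no significant edges survive correction; pipeline stopped early")
    return(invisible(manifest))
  }

  ## cross-modal coupling + feature assembly
  cm <- t_stage({
    coupling <- couple_edges(sig_tab, gt$res$samples, mean_fc_matrix, atlas,
                             alpha = config$alpha_coupling)
    fset <- assemble_features(coupling, gt$res$samples, mean_fc_matrix,
                              atlas, alpha = config$alpha_coupling)
    list(coupling = coupling, fset = fset)
  })
  manifest$timings$cross_modal <- cm$secs
  coupling <- cm$res$coupling
  fset <- cm$res$fset
  manifest$counts$edges_retained <- sum(coupling$retained)
  manifest$counts$structural_features <- nrow(fset$structural)
  manifest$counts$functional_features <- length(fset$functional_regions)
  p <- file.path(out, "coupling.tsv")
  data.table::fwrite(coupling, p, sep = "\t")
  outputs <- c(outputs, p)
  p <- file.path(out, "features.csv")
  write_matrix_csv(fset$X, p)
  outputs <- c(outputs, p)

  if (ncol(fset$X) < 2L) {
    manifest$status <- "too_few_features"
    manifest$checksums <- as.list(tools::md5sum(outputs))
    names(manifest$checksums) <- basename(outputs)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    message("fewer than 2 features retained; pipeline stopped early")
    return(invisible(manifest))
  }

  ## per-feature contribution + PLSR LOOCV
  pr <- t_stage({
    contrib <- do.call(rbind, lapply(colnames(fset$X), function(f) {
      r <- simple_feature_r2(fset$X[, f], subjects$bmi)
      data.frame(feature = f, r_squared = r$r_squared, p_value = r$p_value)
    }))
    Xm <- restrict_modality(fset$X, config$modality)
    if (ncol(Xm) < 1L)
      stop_invalid("modality restriction left no features")
    report <- loocv_predict(Xm, subjects$bmi,
                            max_lv = min(config$max_lv, ncol(Xm)))
    modal_k <- as.integer(names(sort(table(report$per_fold_n_lv),
                                     decreasing = TRUE))[1L])
    final_fit <- fit_plsr(Xm, subjects$bmi, modal_k)
    list(contrib = contrib, report = report, modal_k = modal_k,
         explained_variance = final_fit$explained_variance_y)
  })
  manifest$timings$plsr <- pr$secs
  p <- file.path(out, "feature_contributions.tsv")
  data.table::fwrite(pr$res$contrib, p, sep = "\t")
  outputs <- c(outputs, p)
  pred <- cbind(pr$res$report$predictions,
                group = subjects$group[match(pr$res$report$predictions$subject,
                                             subjects$subject_id)])
  p <- file.path(out, "predictions.csv")
  data.table::fwrite(pred, p, sep = ",")
  outputs <- c(outputs, p)

  summary <- list(
    modality = config$modality,
    n_subjects = nrow(subjects),
    rms_error = pr$res$report$rms_error,
    percent_error = pr$res$report$percent_error,
    pearson_r = pr$res$report$pearson_r,
    modal_n_lv = pr$res$modal_k,
    explained_variance = pr$res$explained_variance
  )
  p <- file.path(out, "summary.json")
  jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  outputs <- c(outputs, p)

  manifest$checksums <- as.list(tools::md5sum(outputs))
  names(manifest$checksums) <- basename(outputs)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
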