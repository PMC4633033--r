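# Plain-text I/O: atlas TSV, fiber TSV, time-series CSV, subject CSV,
# matrix CSV, results TSV and summary JSON. Everything round-trips
# losslessly up to float formatting.

fread_checked <- function(path, required, sep) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          data.table = FALSE)
  miss <- setdiff(required, names(dt))
  if (length(miss))
    stop_invalid(sprintf("%s: missing column(s) %s", path,
                         paste(miss, collapse = ", ")))
  dt
}

#' @rdname cohort_io
#' @export
write_atlas <- function(atlas, path) {
  validate_atlas(atlas)
  data.table::fwrite(data.frame(region_id = atlas$region, name = atlas$name,
                                surface_area_mm2 = atlas$surface_area,
                                reward = as.integer(atlas$reward)),
                     path, sep = "\t")
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_atlas <- function(path) {
  dt <- fread_checked(path, c("region_id", "name", "surface_area_mm2",
                              "reward"), sep = "\t")
  atlas <- data.frame(region = as.integer(dt$region_id), name = dt$name,
                      surface_area = dt$surface_area_mm2,
                      reward = as.logical(dt$reward),
                      stringsAsFactors = FALSE)
  class(atlas) <- c("atlas", "data.frame")
  validate_atlas(atlas)
  atlas
}

#' @rdname cohort_io
#' @export
write_fibers <- function(fiber_sets, path) {
  if (inherits(fiber_sets, "fiber_set")) fiber_sets <- list(fiber_sets)
  tabs <- lapply(fiber_sets, function(fs) {
    if (nrow(fs$fibers) == 0L) return(NULL)
    cbind(subject_id = fs$subject_id, fs$fibers)
  })
  out <- do.call(rbind, tabs) %||%
    data.frame(subject_id = character(0), region_u = integer(0),
               region_v = integer(0), length_mm = numeric(0))
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_fibers <- function(path) {
  dt <- fread_checked(path, c("subject_id", "region_u", "region_v",
                              "length_mm"), sep = "\t")
  bad <- which(!is.finite(dt$length_mm) | dt$length_mm <= 0)
  if (length(bad))
    stop_invalid(sprintf("%s: non-positive fiber length at data line %d",
                         path, bad[1L]))
  split_idx <- split(seq_len(nrow(dt)), dt$subject_id)
  lapply(names(split_idx), function(id) {
    fiber_set(id, dt[split_idx[[id]], c("region_u", "region_v", "length_mm")])
  })
}

#' @rdname cohort_io
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "roi_timeseries"))
  data.table::fwrite(as.data.frame(ts$values), path, sep = ",")
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_timeseries <- function(path, subject_id, sampling_interval = 0.72) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  dt <- data.table::fread(path, sep = ",", header = TRUE, data.table = FALSE)
  roi_timeseries(subject_id, as.matrix(dt), sampling_interval)
}

#' @rdname cohort_io
#' @export
write_subjects <- function(subjects, path) {
  stopifnot(all(c("subject_id", "group", "bmi") %in% names(subjects)))
  data.table::fwrite(subjects[, c("subject_id", "group", "bmi")], path,
                     sep = ",")
  invisible(path)
}

#' Cohort file formats
#'
#' Readers and writers for the pipeline's plain-text formats: atlas TSV
#' (`region_id`, `name`, `surface_area_mm2`, `reward`), fiber TSV
#' (`subject_id`, `region_u`, `region_v`, `length_mm`), per-subject ROI
#' time-series CSV (columns = regions), subject CSV (`subject_id`,
#' `group`, `bmi`) and numeric matrix CSV. `read_subjects` enforces the
#' group rule: BMI below 25 kg/m^2 is HW, 25 or above is non-HW.
#'
#' @param path File path.
#' @param atlas,fiber_sets,ts,subjects,m Objects to write.
#' @param subject_id Subject id for a time-series file.
#' @param sampling_interval Sampling interval (s) of the stored series.
#' @name cohort_io
#' @export
read_subjects <- function(path) {
  dt <- fread_checked(path, c("subject_id", "group", "bmi"), sep = ",")
  if (anyDuplicated(dt$subject_id))
    stop_invalid(path, ": duplicate subject ids")
  if (any(!is.finite(dt$bmi) | dt$bmi <= 0))
    stop_invalid(path, ": BMI values must be positive")
  expect_grp <- ifelse(dt$bmi < 25, "HW", "nonHW")
  bad <- which(dt$group != expect_grp)
  if (length(bad))
    stop_invalid(sprintf(
      "%s: subject %s has BMI %.2f but group '%s' (boundary: BMI >= 25 is nonHW)",
      path, dt$subject_id[bad[1L]], dt$bmi[bad[1L]], dt$group[bad[1L]]))
  dt
}

#' @rdname cohort_io
#' @export
write_matrix_csv <- function(m, path) {
  if (ncol(m) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  df <- as.data.frame(m)
  names(df) <- colnames(m) %||% sprintf("V%d", seq_len(ncol(m)))
  data.table::fwrite(df, path, sep = ",")
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_matrix_csv <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  as.matrix(data.table::fread(path, sep = ",", header = TRUE,
                              data.table = FALSE))
}

#' Write a cohort to a directory of plain-text files
#'
#' Produces `atlas.tsv`, `subjects.csv`, `fibers.tsv`, `features.csv` and
#' one `ts/<subject_id>.csv` per subject -- the same formats the pipeline
#' reads back.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "ts"), showWarnings = FALSE)
  write_atlas(cohort$atlas, file.path(dir, "atlas.tsv"))
  write_subjects(cohort$subjects, file.path(dir, "subjects.csv"))
  write_fibers(cohort$fiber_sets, file.path(dir, "fibers.tsv"))
  write_matrix_csv(cohort$features, file.path(dir, "features.csv"))
  for (ts in cohort$timeseries)
    write_timeseries(ts, file.path(dir, "ts", paste0(ts$subject_id, ".csv")))
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @param sampling_interval Sampling interval (s) of the stored series.
#' @return A list with `atlas`, `subjects`, `fiber_sets`, `timeseries`.
#' @export
read_cohort <- function(dir, sampling_interval = 0.72) {
  atlas <- read_atlas(file.path(dir, "atlas.tsv"))
  subjects <- read_subjects(file.path(dir, "subjects.csv"))
  fiber_sets <- read_fibers(file.path(dir, "fibers.tsv"))
  # keep subject order; subjects with zero fibers get empty sets
  fs_ids <- vapply(fiber_sets, `[[`, "", "subject_id")
  fiber_sets <- lapply(subjects$subject_id, function(id) {
    i <- match(id, fs_ids)
    if (is.na(i))
      fiber_set(id, data.frame(region_u = integer(0), region_v = integer(0),
                               length_mm = numeric(0)))
    else fiber_sets[[i]]
  })
  timeseries <- lapply(subjects$subject_id, function(id) {
    read_timeseries(file.path(dir, "ts", paste0(id, ".csv")), id,
                    sampling_interval)
  })
  list(atlas = atlas, subjects = subjects, fiber_sets = fiber_sets,
       timeseries = timeseries)
}
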