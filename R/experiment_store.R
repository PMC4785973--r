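# Experiment metadata, head-eversion time alignment and the relational
# store. The onset of head eversion (HE) is the temporal reference point:
# all series are expressed in signed hours aHE and compared on a canonical
# 13-point analysis grid.

#' Experiment metadata
#'
#' @param sample_id sample identifier.
#' @param genotype genotype label (e.g. `"control"`, `"TOR_shRNA"`).
#' @param pixel_size microns per pixel.
#' @param frame_interval minutes between frames (> 0).
#' @param he_frame frame index (0-based) of head-eversion onset (>= 0).
#' @param frame_hours optional explicit hours-aHE per frame for acquisitions
#'   on a non-uniform time grid.
#' @param temperature optional free-text temperature note.
#' @return an `experiment_meta`.
#' @export
experiment_meta <- function(sample_id, genotype, pixel_size = 1.25,
                            frame_interval = 30, he_frame = 24L,
                            frame_hours = NULL, temperature = NULL) {
  stopifnot(frame_interval > 0, he_frame >= 0)
  structure(list(sample_id = sample_id, genotype = genotype,
                 pixel_size = pixel_size, frame_interval = frame_interval,
                 he_frame = as.integer(he_frame), frame_hours = frame_hours,
                 temperature = temperature),
            class = "experiment_meta")
}

#' Convert frame indices to hours after head eversion
#'
#' `(frame - he_frame) * frame_interval / 60`; negative before HE. When the
#' metadata carries explicit `frame_hours`, those are looked up instead.
#'
#' @param frame_index 0-based frame index (vectorised).
#' @param meta an [experiment_meta()].
#' @return signed hours aHE.
#' @export
frame_to_hours_aHE <- function(frame_index, meta) {
  stopifnot(inherits(meta, "experiment_meta"))
  if (!is.null(meta$frame_hours)) return(meta$frame_hours[frame_index + 1L])
  (frame_index - meta$he_frame) * meta$frame_interval / 60
}

#' Inverse of [frame_to_hours_aHE()] on the uniform frame grid
#' @param hours signed hours aHE.
#' @param meta an [experiment_meta()].
#' @export
hours_aHE_to_frame <- function(hours, meta) {
  stopifnot(inherits(meta, "experiment_meta"), is.null(meta$frame_hours))
  hours * 60 / meta$frame_interval + meta$he_frame
}

#' The canonical 13-point analysis grid (hours aHE)
#'
#' @return `c(5, 10, 15, 20, 25, 30, 40, 50, 60, 70, 80, 90, 100)`.
#' @export
canonical_grid <- function() {
  c(5, 10, 15, 20, 25, 30, 40, 50, 60, 70, 80, 90, 100)
}

#' Expected frame count of an acquisition
#'
#' @param duration_days acquisition duration in days (> 0).
#' @param interval_min frame interval in minutes (> 0).
#' @return `floor(duration_days * 24 * 60 / interval_min)`.
#' @export
expected_frame_count <- function(duration_days, interval_min) {
  if (duration_days <= 0 || interval_min <= 0)
    stop("duration and interval must be positive")
  as.integer(floor(duration_days * 24 * 60 / interval_min))
}

#' Snap an aligned series onto the canonical grid
#'
#' For each grid time the nearest observed time point within `tolerance_h`
#' is assigned; slots with no observation in tolerance stay absent. Values
#' are never interpolated or otherwise fabricated.
#'
#' @param series data.frame with a `hours_aHE` column (strictly increasing)
#'   plus any value columns.
#' @param tolerance_h matching tolerance in hours (default 0.25 = half the
#'   standard 30-min acquisition interval, which guarantees a unique
#'   nearest frame).
#' @param grid grid times in hours aHE.
#' @return the matching rows of `series` with `hours_aHE` replaced by a
#'   `grid_time` column (original hours kept as `observed_hours`).
#' @export
snap_to_grid <- function(series, tolerance_h = 0.25, grid = canonical_grid()) {
  stopifnot(is.data.frame(series), "hours_aHE" %in% names(series),
            nrow(series) >= 1L)
  rows <- lapply(grid, function(g) {
    d <- abs(series$hours_aHE - g)
    i <- which.min(d)
    if (d[i] <= tolerance_h) {
      out <- series[i, , drop = FALSE]
      out$observed_hours <- out$hours_aHE
      out$grid_time <- g
      out
    } else NULL
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    out <- series[0, , drop = FALSE]
    out$observed_hours <- numeric(0); out$grid_time <- numeric(0)
    return(out)
  }
  out <- do.call(rbind, rows)
  out$hours_aHE <- NULL
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# Relational store: experiments / rois / features / nuclei tables with key
# constraints, held in an environment and persisted as a directory of CSVs.
# ---------------------------------------------------------------------------

empty_feature_table <- function() {
  data.frame(sample_id = character(0), genotype = character(0),
             muscle_id = character(0), frame_index = integer(0),
             hours_aHE = numeric(0), area_um2 = numeric(0),
             length_um = numeric(0), mean_diameter_um = numeric(0),
             stringsAsFactors = FALSE)
}

#' Create an experiment store
#'
#' A small relational database: tables `experiments`, `features` and
#' `nuclei` with enforced key constraints (features may only be added for
#' registered experiments; one feature row per (sample, muscle, frame)).
#'
#' @return a `muscle_store`.
#' @export
muscle_store <- function() {
  e <- new.env(parent = emptyenv())
  e$experiments <- data.frame(sample_id = character(0), genotype = character(0),
                              pixel_size = numeric(0), frame_interval = numeric(0),
                              he_frame = integer(0), temperature = character(0),
                              stringsAsFactors = FALSE)
  e$features <- empty_feature_table()
  e$nuclei <- data.frame(sample_id = character(0), muscle_id = character(0),
                         frame_index = integer(0), hours_aHE = numeric(0),
                         x = numeric(0), y = numeric(0), axial_u = numeric(0),
                         lateral_d_um = numeric(0), local_radius_um = numeric(0),
                         stringsAsFactors = FALSE)
  class(e) <- "muscle_store"
  e
}

#' @export
print.muscle_store <- function(x, ...) {
  cat(sprintf("muscle_store: %d experiments, %d feature rows, %d nuclei rows\n",
              nrow(x$experiments), nrow(x$features), nrow(x$nuclei)))
  invisible(x)
}

#' Register an experiment
#' @param store a [muscle_store()].
#' @param meta an [experiment_meta()].
#' @export
store_add_experiment <- function(store, meta) {
  stopifnot(inherits(store, "muscle_store"), inherits(meta, "experiment_meta"))
  if (meta$sample_id %in% store$experiments$sample_id)
    stop("sample_id '", meta$sample_id, "' already registered")
  store$experiments <- rbind(store$experiments, data.frame(
    sample_id = meta$sample_id, genotype = meta$genotype,
    pixel_size = meta$pixel_size, frame_interval = meta$frame_interval,
    he_frame = meta$he_frame,
    temperature = meta$temperature %||% NA_character_,
    stringsAsFactors = FALSE))
  invisible(store)
}

#' Insert feature rows
#'
#' @param store a [muscle_store()].
#' @param features data.frame shaped like the morphometry export (columns
#'   `sample_id`, `muscle_id`, `frame_index`, `hours_aHE`, `area_um2`,
#'   `length_um`, `mean_diameter_um`; `genotype` is filled in from the
#'   experiments table).
#' @export
store_add_features <- function(store, features) {
  stopifnot(inherits(store, "muscle_store"), is.data.frame(features))
  need <- c("sample_id", "muscle_id", "frame_index", "hours_aHE",
            "area_um2", "length_um", "mean_diameter_um")
  miss <- setdiff(need, names(features))
  if (length(miss)) stop("feature table lacks columns: ", paste(miss, collapse = ", "))
  unknown <- setdiff(unique(features$sample_id), store$experiments$sample_id)
  if (length(unknown))
    stop("features reference unregistered sample(s): ", paste(unknown, collapse = ", "))
  features$genotype <- store$experiments$genotype[
    match(features$sample_id, store$experiments$sample_id)]
  new <- rbind(store$features, features[, names(empty_feature_table())])
  key <- paste(new$sample_id, new$muscle_id, new$frame_index)
  if (anyDuplicated(key))
    stop("duplicate (sample, muscle, frame) feature row: ", key[duplicated(key)][1L])
  store$features <- new
  invisible(store)
}

#' Insert nuclei observation rows
#' @param store a [muscle_store()].
#' @param nuclei data.frame with the nuclei-export columns.
#' @export
store_add_nuclei <- function(store, nuclei) {
  stopifnot(inherits(store, "muscle_store"), is.data.frame(nuclei))
  unknown <- setdiff(unique(nuclei$sample_id), store$experiments$sample_id)
  if (length(unknown))
    stop("nuclei reference unregistered sample(s): ", paste(unknown, collapse = ", "))
  keep <- intersect(names(store$nuclei), names(nuclei))
  row <- nuclei[, keep]
  for (col in setdiff(names(store$nuclei), keep)) row[[col]] <- NA
  store$nuclei <- rbind(store$nuclei, row[, names(store$nuclei)])
  invisible(store)
}

#' Query feature rows
#'
#' @param store a [muscle_store()].
#' @param genotype,muscle_id optional equality filters.
#' @param grid_time optional hours-aHE filter: rows are snapped per muscle
#'   to the canonical grid and only the requested grid time is returned.
#' @param tolerance_h snapping tolerance (hours).
#' @return data.frame of matching feature rows.
#' @export
store_query <- function(store, genotype = NULL, muscle_id = NULL,
                        grid_time = NULL, tolerance_h = 0.25) {
  stopifnot(inherits(store, "muscle_store"))
  f <- store$features
  if (!is.null(genotype)) f <- f[f$genotype %in% genotype, , drop = FALSE]
  if (!is.null(muscle_id)) f <- f[f$muscle_id %in% muscle_id, , drop = FALSE]
  if (is.null(grid_time) || !nrow(f)) { rownames(f) <- NULL; return(f) }
  per <- split(f, paste(f$sample_id, f$muscle_id))
  out <- lapply(per, function(s) {
    s <- s[order(s$hours_aHE), , drop = FALSE]
    snap_to_grid(s, tolerance_h = tolerance_h, grid = grid_time)
  })
  out <- do.call(rbind, Filter(function(x) nrow(x) > 0, out))
  if (is.null(out)) return(f[0, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Persist / load a store as a directory of CSV files
#'
#' @param store a [muscle_store()].
#' @param dir directory path.
#' @return `store_write`: `dir` invisibly; `store_read`: a [muscle_store()]
#'   whose tables round-trip the written values exactly.
#' @export
store_write <- function(store, dir) {
  stopifnot(inherits(store, "muscle_store"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(store$experiments, file.path(dir, "experiments.csv"), row.names = FALSE)
  write.csv(store$features, file.path(dir, "features.csv"), row.names = FALSE)
  write.csv(store$nuclei, file.path(dir, "nuclei.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname store_write
#' @export
store_read <- function(dir) {
  store <- muscle_store()
  store$experiments <- read.csv(file.path(dir, "experiments.csv"),
                                colClasses = c(sample_id = "character",
                                               genotype = "character",
                                               temperature = "character"))
  store$features <- read.csv(file.path(dir, "features.csv"),
                             colClasses = c(sample_id = "character",
                                            genotype = "character",
                                            muscle_id = "character"))
  store$nuclei <- read.csv(file.path(dir, "nuclei.csv"),
                           colClasses = c(sample_id = "character",
                                          muscle_id = "character"))
  store
}

#' Ingest a generated cohort into a store
#'
#' Registers one experiment per sample and measures every ROI with the
#' morphometry core (this is the measurement path; ground truth is not
#' copied into the store).
#'
#' @param store a [muscle_store()].
#' @param cohort result of [generate_cohort()].
#' @param pixel_size,step_px morphometry settings.
#' @return the store, invisibly.
#' @export
store_ingest_cohort <- function(store, cohort, pixel_size = 1.25, step_px = 5) {
  for (i in seq_len(nrow(cohort$manifest))) {
    store_add_experiment(store, experiment_meta(
      sample_id = cohort$manifest$sample_id[i],
      genotype = cohort$manifest$genotype[i],
      pixel_size = pixel_size))
  }
  feats <- measure_rois(cohort$rois, pixel_size = pixel_size, step_px = step_px)
  store_add_features(store, feats)
  invisible(store)
}
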