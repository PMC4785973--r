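# One-command orchestration: simulate -> measure -> align -> compare ->
# nuclei -> report, every stage re-runnable from its inputs and the whole
# run reproducible from the seed in the config.

#' Build a pipeline run configuration
#'
#' Captures every tunable default of the pipeline; round-trips losslessly
#' through a YAML file via [write_run_config()] / [read_run_config()].
#'
#' @param preset_a,preset_b genotype presets to simulate and compare.
#' @param n_per_group pupae per cohort.
#' @param profile `"fast"` or `"full"` (see [generate_cohort()]).
#' @param feature feature compared (`"area_um2"`, `"length_um"`,
#'   `"mean_diameter_um"`).
#' @param tail MWU tail for A vs B.
#' @param pixel_size,step_px morphometry settings.
#' @param tolerance_h grid snapping tolerance (hours).
#' @param min_n minimum group size per grid time.
#' @param alpha significance threshold.
#' @param thresholds nuclear-pattern classifier thresholds.
#' @param write_images also write the synthetic TIFF stacks.
#' @param seed integer master seed.
#' @param out_dir output directory.
#' @return a `run_config` list.
#' @export
run_config <- function(preset_a = "control", preset_b = "TOR_shRNA",
                       n_per_group = 15L, profile = "fast",
                       feature = "area_um2", tail = "left",
                       pixel_size = 1.25, step_px = 5,
                       tolerance_h = 0.25, min_n = 5L, alpha = 0.05,
                       thresholds = pattern_thresholds(),
                       write_images = FALSE, seed = 1L,
                       out_dir = tempfile("myomorph_run_")) {
  structure(list(preset_a = preset_a, preset_b = preset_b,
                 n_per_group = as.integer(n_per_group), profile = profile,
                 feature = feature, tail = tail, pixel_size = pixel_size,
                 step_px = step_px, tolerance_h = tolerance_h,
                 min_n = as.integer(min_n), alpha = alpha,
                 thresholds = thresholds,
                 write_images = isTRUE(write_images),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

config_hash <- function(config) {
  s <- yaml::as.yaml(unclass(config))
  sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 97 + 1)) %% 1e9
}

#' Run the full pipeline
#'
#' Simulates the two cohorts, measures every ROI with the morphometry core,
#' aligns the series on the canonical grid inside the experiment store,
#' compares the genotypes per grid time, quantifies the myonuclear
#' distributions and phase timelines, and writes a machine-readable summary
#' (fold changes, per-grid p-values, phase transitions). Identical seed,
#' identical summary.
#'
#' @param config a [run_config()].
#' @return the summary list, invisibly; files are written under
#'   `config$out_dir` (`features.csv`, `comparison.csv`, `comparison.png`,
#'   `nuclei_metrics.csv`, `phase_transitions.csv`, `summary.json`,
#'   `run_config.yaml`).
#' @export
run_all <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(stage, ...) {
    message(sprintf("[myomorph %s] seed=%d cfg=%d %s", stage, config$seed,
                    config_hash(config), sprintf(...)))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           " (partial outputs kept in ", config$out_dir, ")", call. = FALSE)
    })
  }

  # distinct genotype labels even when both groups use the same preset
  labels <- c(a = config$preset_a,
              b = if (identical(config$preset_a, config$preset_b))
                paste0(config$preset_b, "_B") else config$preset_b)
  cohorts <- stage("simulate", {
    out <- lapply(c("a", "b"), function(g) {
      p <- if (g == "a") config$preset_a else config$preset_b
      sub <- if (config$write_images)
        file.path(config$out_dir, paste0("cohort_", labels[[g]])) else NULL
      generate_cohort(p, config$n_per_group,
                      seed = mix_seed(config$seed, utf8ToInt(g), nchar(p)),
                      profile = config$profile, out_dir = sub,
                      render = config$write_images,
                      genotype = labels[[g]])
    })
    names(out) <- c("a", "b")
    log_stage("simulate", "%d + %d samples (%s vs %s)", config$n_per_group,
              config$n_per_group, config$preset_a, config$preset_b)
    out
  })

  features <- stage("measure", {
    f <- do.call(rbind, lapply(cohorts, function(co)
      measure_rois(co$rois, pixel_size = config$pixel_size,
                   step_px = config$step_px)))
    write.csv(f, file.path(config$out_dir, "features.csv"), row.names = FALSE)
    log_stage("measure", "%d feature rows", nrow(f))
    f
  })

  store <- stage("align", {
    st <- muscle_store()
    for (co in cohorts) store_ingest_cohort(st, co, pixel_size = config$pixel_size,
                                            step_px = config$step_px)
    log_stage("align", "store holds %d experiments", nrow(st$experiments))
    st
  })

  comparison <- stage("compare", {
    cmp <- compare_genotypes(store, config$feature, labels[["a"]],
                             labels[["b"]], tail = config$tail,
                             min_n = config$min_n, alpha = config$alpha,
                             tolerance_h = config$tolerance_h)
    write_comparison_csv(cmp, file.path(config$out_dir, "comparison.csv"))
    png(file.path(config$out_dir, "comparison.png"), width = 900, height = 700)
    plot(cmp)
    dev.off()
    log_stage("compare", "%d grid times, %d significant", nrow(cmp),
              sum(cmp$significant))
    cmp
  })

  nuclei <- stage("nuclei", {
    res <- lapply(names(cohorts), function(which) {
      co <- cohorts[[which]]
      if (is.null(co$nuclei) || !nrow(co$nuclei)) return(NULL)
      keys <- unique(co$nuclei[, c("sample_id", "muscle_id", "frame_index", "hours_aHE")])
      rows <- lapply(seq_len(nrow(keys)), function(i) {
        k <- keys[i, ]
        nuc <- co$nuclei[co$nuclei$sample_id == k$sample_id &
                         co$nuclei$muscle_id == k$muscle_id &
                         co$nuclei$frame_index == k$frame_index, ]
        tr <- co$truth[co$truth$sample_id == k$sample_id &
                       co$truth$muscle_id == k$muscle_id &
                       co$truth$frame_index == k$frame_index, ]
        m <- distribution_metrics(truth_observations(nuc, tr$diameter_um[1L]),
                                  thresholds = config$thresholds)
        data.frame(genotype = co$manifest$genotype[1L], sample_id = k$sample_id,
                   muscle_id = k$muscle_id, frame_index = k$frame_index,
                   hours_aHE = k$hours_aHE, n_nuclei = m$n_nuclei,
                   axial_sd = m$axial_sd, central_fraction = m$central_fraction,
                   midline_score = m$midline_score, pattern = m$pattern,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    })
    metrics <- do.call(rbind, Filter(Negate(is.null), res))
    write.csv(metrics, file.path(config$out_dir, "nuclei_metrics.csv"),
              row.names = FALSE)
    trans <- lapply(split(metrics, paste(metrics$genotype, metrics$sample_id,
                                         metrics$muscle_id)), function(mm) {
      if (nrow(mm) < 2L) return(NULL)
      tl <- phase_timeline(mm)
      if (!nrow(tl$transitions)) return(NULL)
      cbind(genotype = mm$genotype[1L], sample_id = mm$sample_id[1L],
            muscle_id = mm$muscle_id[1L], tl$transitions)
    })
    trans <- do.call(rbind, Filter(Negate(is.null), trans))
    if (is.null(trans))
      trans <- data.frame(genotype = character(0), sample_id = character(0),
                          muscle_id = character(0), hours_aHE = numeric(0),
                          from = character(0), to = character(0))
    write.csv(trans, file.path(config$out_dir, "phase_transitions.csv"),
              row.names = FALSE)
    log_stage("nuclei", "%d metric rows, %d transitions", nrow(metrics), nrow(trans))
    list(metrics = metrics, transitions = trans)
  })

  summary <- stage("report", {
    med_at <- function(geno, g) {
      cmpg <- features[features$genotype == geno, ]
      per <- split(cmpg, paste(cmpg$sample_id, cmpg$muscle_id))
      v <- vapply(per, function(s) {
        d <- abs(s$hours_aHE - g); i <- which.min(d)
        if (length(i) && d[i] <= config$tolerance_h) s[[config$feature]][i] else NA_real_
      }, numeric(1))
      median(v, na.rm = TRUE)
    }
    fold_a <- list(
      decline_5_50 = as.numeric(fold_change(med_at(labels[["a"]], 5),
                                            med_at(labels[["a"]], 50),
                                            direction = "decline")),
      regrowth_50_100 = as.numeric(fold_change(med_at(labels[["a"]], 50),
                                               med_at(labels[["a"]], 100),
                                               direction = "increase")))
    s <- list(config = unclass(config)[setdiff(names(config), "out_dir")],
              feature = config$feature,
              folds_group_a = fold_a,
              grid = comparison$grid_time,
              p_values = comparison$p,
              tested = comparison$tested,
              significant = comparison$significant,
              n_transitions = nrow(nuclei$transitions))
    jsonlite::write_json(s, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    write_run_config(config, file.path(config$out_dir, "run_config.yaml"))
    log_stage("report", "summary written")
    s
  })
  invisible(summary)
}
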