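# Myonuclear distribution quantification. Nuclear centroids (detected in
# the nuclear channel, or taken from ground truth) are decomposed into an
# axial coordinate along the medial axis (normalized arc position u in
# [0, 1]) and a lateral offset from the axis (in microns, plus a signed
# variant used by the pattern classifier). Patterns: uniform basal spread,
# central cluster, midline single row, scattered.

#' Detect nuclear centroids in a nuclear-channel image
#'
#' Global Otsu threshold computed from the intensities inside the ROI,
#' connected-component labelling, minimum-size filter, intensity-weighted
#' centroids. Zero detections is a valid result.
#'
#' @param img intensity matrix (rows = y, columns = x, 0-based coordinate
#'   convention).
#' @param roi_contour optional [contour()]; detection is restricted to
#'   pixels inside it.
#' @param min_size minimum component size in pixels.
#' @param max_intensity intensity scale (255 for 8-bit data).
#' @return data.frame with columns `x`, `y` (0-based, sub-pixel), `size`,
#'   `intensity`.
#' @export
detect_nuclei <- function(img, roi_contour = NULL, min_size = 4L,
                          max_intensity = 255) {
  stopifnot(is.matrix(img))
  h <- nrow(img); w <- ncol(img)
  mask <- matrix(TRUE, h, w)
  if (!is.null(roi_contour)) {
    if (!inherits(roi_contour, "contour")) roi_contour <- contour(roi_contour)
    xs <- rep(0:(w - 1L), each = h)
    ys <- rep(0:(h - 1L), times = w)
    mask <- matrix(pracma::inpolygon(xs, ys, roi_contour[, 1L], roi_contour[, 2L],
                                     boundary = TRUE), h, w)
  }
  vals <- img[mask]
  empty <- data.frame(x = numeric(0), y = numeric(0),
                      size = integer(0), intensity = numeric(0))
  if (!length(vals) || diff(range(vals)) == 0) return(empty)
  th <- EBImage::otsu(EBImage::Image(matrix(vals, ncol = 1L)),
                      range = c(0, max_intensity), levels = 256L)
  bw <- (img > th) & mask
  if (!any(bw)) return(empty)
  lbl <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bw * 1)))
  ids <- sort(unique(lbl[lbl > 0]))
  rows <- lapply(ids, function(id) {
    idx <- which(lbl == id, arr.ind = TRUE)
    if (nrow(idx) < min_size) return(NULL)
    wgt <- img[idx]
    data.frame(x = sum((idx[, 2L] - 1) * wgt) / sum(wgt),
               y = sum((idx[, 1L] - 1) * wgt) / sum(wgt),
               size = nrow(idx), intensity = sum(wgt))
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# nearest point on a polyline: arc position, distance, and the side of the
# axis the query point falls on (sign of the cross product with the local
# tangent)
nearest_on_polyline <- function(axis, p) {
  n <- nrow(axis)
  arcs <- cum_arc(axis)
  best <- list(d2 = Inf, arc = 0, side = 1)
  for (i in seq_len(n - 1L)) {
    a <- axis[i, ]; b <- axis[i + 1L, ]
    v <- b - a; vv <- sum(v^2)
    t <- if (vv > 0) min(max(sum((p - a) * v) / vv, 0), 1) else 0
    q <- a + t * v
    d2 <- sum((p - q)^2)
    if (d2 < best$d2) {
      cross <- v[1L] * (p[2L] - q[2L]) - v[2L] * (p[1L] - q[1L])
      best <- list(d2 = d2, arc = arcs[i] + t * sqrt(vv),
                   side = if (cross >= 0) 1 else -1)
    }
  }
  best
}

#' Localize nuclear centroids relative to a muscle ROI
#'
#' Decomposes each centroid into `axial_u` (arc position of the nearest
#' medial-axis point divided by the axis length), `lateral_d_um` (unsigned
#' distance to the axis), `lateral_signed_um` (signed by the side of the
#' axis) and `local_radius_um` (half the chord at the nearest profile
#' sample). Centroids outside the contour are excluded with a warning.
#'
#' @param centroids data.frame with `x`, `y` (pixel coordinates).
#' @param roi a [muscle_roi()].
#' @param chord_profile optional precomputed profile from
#'   [diameter_profile()]; computed on the fly when absent.
#' @param pixel_size microns per pixel.
#' @param step_px chord sampling step when the profile must be computed.
#' @return data.frame of nucleus observations (one row per retained
#'   centroid): `muscle_id`, `frame_index`, `x`, `y`, `axial_u`,
#'   `lateral_d_um`, `lateral_signed_um`, `local_radius_um`.
#' @export
localize_nuclei <- function(centroids, roi, chord_profile = NULL,
                            pixel_size = 1.25, step_px = 5) {
  stopifnot(inherits(roi, "muscle_roi"), is.data.frame(centroids))
  if (is.null(chord_profile))
    chord_profile <- diameter_profile(roi$contour, roi$axis, step_px = step_px,
                                      pixel_size = pixel_size)$chord_profile
  total <- polyline_length(roi$axis, 1)
  inside <- pracma::inpolygon(centroids$x, centroids$y,
                              roi$contour[, 1L], roi$contour[, 2L],
                              boundary = TRUE)
  if (any(!inside))
    warning(sum(!inside), " centroid(s) outside the contour of '",
            roi$muscle_id, "' excluded")
  centroids <- centroids[inside, , drop = FALSE]
  rows <- lapply(seq_len(nrow(centroids)), function(i) {
    p <- c(centroids$x[i], centroids$y[i])
    np <- nearest_on_polyline(unclass(roi$axis), p)
    arc_um <- np$arc * pixel_size
    j <- which.min(abs(chord_profile$arc_um - arc_um))
    data.frame(muscle_id = roi$muscle_id, frame_index = roi$frame_index,
               x = p[1L], y = p[2L],
               axial_u = if (total > 0) np$arc / total else 0,
               lateral_d_um = sqrt(np$d2) * pixel_size,
               lateral_signed_um = np$side * sqrt(np$d2) * pixel_size,
               local_radius_um = chord_profile$chord_um[j] / 2,
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(muscle_id = character(0), frame_index = integer(0),
                      x = numeric(0), y = numeric(0), axial_u = numeric(0),
                      lateral_d_um = numeric(0), lateral_signed_um = numeric(0),
                      local_radius_um = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default thresholds of the nuclear-pattern classifier
#'
#' `axial_sd_cluster`: population SD of `axial_u` below which the nuclei
#' form a central cluster. `midline_max`: midline score (median
#' `lateral_d / local_radius`) below which an axially spread configuration
#' counts as a midline row. `side_frac_min` and `lateral_sd_max`: a
#' laterally offset configuration counts as uniform (basal) rather than
#' scattered when at least this fraction of nuclei sits on one side of the
#' axis and the signed lateral spread stays below this value (in units of
#' the local radius). `axial_sd_uniform`: minimum axial spread for the
#' uniform pattern.
#'
#' @export
pattern_thresholds <- function(axial_sd_cluster = 0.15, midline_max = 0.25,
                               side_frac_min = 0.75, lateral_sd_max = 0.25,
                               axial_sd_uniform = 0.2) {
  list(axial_sd_cluster = axial_sd_cluster, midline_max = midline_max,
       side_frac_min = side_frac_min, lateral_sd_max = lateral_sd_max,
       axial_sd_uniform = axial_sd_uniform)
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Distribution metrics and pattern call for one muscle at one time point
#'
#' @param observations data.frame from [localize_nuclei()] (or ground-truth
#'   centroids routed through it).
#' @param thresholds classifier thresholds, see [pattern_thresholds()].
#' @return a `distribution_metrics` list: `n_nuclei`, `axial_sd`
#'   (population SD of `axial_u`; `NA` with `axial_sd_defined = FALSE` when
#'   n < 2), `central_fraction` (fraction with `|axial_u - 0.5| < 0.15`),
#'   `midline_score` (median `lateral_d / local_radius`), `side_fraction`,
#'   `lateral_sd_ratio`, `pattern`.
#' @export
distribution_metrics <- function(observations, thresholds = pattern_thresholds()) {
  n <- nrow(observations)
  if (n == 0L)
    return(structure(list(n_nuclei = 0L, axial_sd = NA_real_,
                          axial_sd_defined = FALSE, central_fraction = NA_real_,
                          midline_score = NA_real_, side_fraction = NA_real_,
                          lateral_sd_ratio = NA_real_, pattern = NA_character_),
                     class = "distribution_metrics"))
  u <- observations$axial_u
  ratio <- observations$lateral_d_um / pmax(observations$local_radius_um, 1e-9)
  signed <- observations$lateral_signed_um / pmax(observations$local_radius_um, 1e-9)
  axial_sd <- if (n >= 2L) pop_sd(u) else NA_real_
  central_fraction <- mean(abs(u - 0.5) < 0.15)
  midline_score <- median(ratio)
  side_fraction <- max(mean(signed >= 0), mean(signed < 0))
  lateral_sd_ratio <- if (n >= 2L) pop_sd(signed) else NA_real_
  pattern <- if (n < 2L) NA_character_
  else if (axial_sd < thresholds$axial_sd_cluster) "central_cluster"
  else if (midline_score < thresholds$midline_max) "midline_row"
  else if (side_fraction >= thresholds$side_frac_min &&
           lateral_sd_ratio < thresholds$lateral_sd_max &&
           axial_sd >= thresholds$axial_sd_uniform) "uniform"
  else "scattered"
  structure(list(n_nuclei = n, axial_sd = axial_sd,
                 axial_sd_defined = n >= 2L,
                 central_fraction = central_fraction,
                 midline_score = midline_score,
                 side_fraction = side_fraction,
                 lateral_sd_ratio = lateral_sd_ratio,
                 pattern = pattern),
            class = "distribution_metrics")
}

#' @export
print.distribution_metrics <- function(x, ...) {
  cat(sprintf("distribution_metrics: n=%d, axial_sd=%.3f, central=%.2f, midline=%.3f -> %s\n",
              x$n_nuclei, x$axial_sd, x$central_fraction, x$midline_score,
              x$pattern %||% "NA"))
  invisible(x)
}

#' Localization pattern timeline of one muscle
#'
#' Majority-smooths the per-time-point pattern sequence (window of 3, ties
#' keep the centre value) and reports the transition times.
#'
#' @param metrics data.frame with `hours_aHE` and `pattern` columns (one
#'   row per time point, sorted or not).
#' @param window smoothing window (odd).
#' @return list with `timeline` (data.frame `hours_aHE`, `pattern`,
#'   `smoothed`) and `transitions` (data.frame `hours_aHE`, `from`, `to` —
#'   the first time each new pattern is in force).
#' @export
phase_timeline <- function(metrics, window = 3L) {
  stopifnot(is.data.frame(metrics), all(c("hours_aHE", "pattern") %in% names(metrics)),
            nrow(metrics) >= 2L, window %% 2L == 1L)
  m <- metrics[order(metrics$hours_aHE), , drop = FALSE]
  pat <- m$pattern
  half <- window %/% 2L
  smoothed <- vapply(seq_along(pat), function(i) {
    w <- pat[max(1L, i - half):min(length(pat), i + half)]
    tab <- table(w)
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1L) top else pat[i]
  }, character(1))
  ch <- which(smoothed[-1L] != smoothed[-length(smoothed)])
  transitions <- if (length(ch)) {
    data.frame(hours_aHE = m$hours_aHE[ch + 1L],
               from = smoothed[ch], to = smoothed[ch + 1L],
               stringsAsFactors = FALSE)
  } else {
    data.frame(hours_aHE = numeric(0), from = character(0), to = character(0))
  }
  list(timeline = data.frame(hours_aHE = m$hours_aHE, pattern = pat,
                             smoothed = smoothed, stringsAsFactors = FALSE),
       transitions = transitions)
}

#' Ground-truth bypass: nucleus observations from generator truth
#'
#' Converts the exact nuclei table of a synthetic cohort into the same
#' observation schema [localize_nuclei()] produces, so the distribution
#' metrics and classifier can be assessed independently of detector
#' quality.
#'
#' @param nuclei_truth nuclei truth rows of one muscle at one time point
#'   (columns `axial_u`, `lateral_um`, plus diameter context).
#' @param diameter_um true muscle diameter (microns).
#' @return observation data.frame for [distribution_metrics()].
#' @export
truth_observations <- function(nuclei_truth, diameter_um) {
  data.frame(muscle_id = nuclei_truth$muscle_id,
             frame_index = nuclei_truth$frame_index,
             x = nuclei_truth$x, y = nuclei_truth$y,
             axial_u = nuclei_truth$axial_u,
             lateral_d_um = abs(nuclei_truth$lateral_um),
             lateral_signed_um = nuclei_truth$lateral_um,
             local_radius_um = diameter_um / 2,
             stringsAsFactors = FALSE)
}
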