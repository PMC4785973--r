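# ---------------------------------------------------------------------------
# Geometry conventions (used throughout the package):
#   * coordinates are 0-based pixel indices, x rightward, y downward;
#   * a pixel's centre sits at its integer coordinate;
#   * contours are n x 2 matrices (columns x, y), implicitly closed, sub-pixel
#     vertices allowed; medial axes are open n x 2 polylines.
# ---------------------------------------------------------------------------

as_coord_matrix <- function(p, what = "coordinates") {
  if (is.data.frame(p)) p <- as.matrix(p)
  if (is.list(p) && !is.matrix(p)) p <- do.call(rbind, lapply(p, as.numeric))
  if (!is.matrix(p) || ncol(p) != 2L || !is.numeric(p))
    stop(what, " must be an n x 2 numeric matrix of (x, y) positions")
  if (anyNA(p)) stop(what, " contain missing values")
  unname(p)
}

#' Construct a closed muscle contour
#'
#' @param vertices n x 2 matrix of (x, y) pixel coordinates (sub-pixel
#'   allowed). The polygon is implicitly closed; do not repeat the first
#'   vertex.
#' @param check if `TRUE` (default), reject self-intersecting polygons.
#' @return a `contour` object (n x 2 matrix).
#' @export
contour <- function(vertices, check = TRUE) {
  v <- as_coord_matrix(vertices, "contour vertices")
  if (nrow(v) >= 2L && isTRUE(all.equal(v[1L, ], v[nrow(v), ]))) {
    v <- v[-nrow(v), , drop = FALSE]
  }
  if (nrow(v) < 3L) stop("a contour needs at least 3 vertices")
  if (check && !is_simple_polygon(v)) stop("contour is self-intersecting")
  structure(v, class = c("contour", "matrix"))
}

#' Construct a medial-axis polyline
#'
#' @param vertices n x 2 matrix of (x, y) pixel coordinates, ordered along
#'   the axis; the polyline is open.
#' @return a `medial_axis` object.
#' @export
medial_axis <- function(vertices) {
  v <- as_coord_matrix(vertices, "medial-axis vertices")
  if (nrow(v) < 2L) stop("a medial axis needs at least 2 vertices")
  structure(v, class = c("medial_axis", "matrix"))
}

#' A muscle region of interest at one time point
#'
#' Bundles a contour, its medial axis and the identity used for tracking
#' (e.g. `"DIOM 3L"`). When `check = TRUE` every axis vertex must lie
#' strictly inside the contour.
#'
#' @param muscle_id non-empty identity string.
#' @param frame_index 0-based frame index.
#' @param contour a [contour()] (or coercible matrix).
#' @param axis a [medial_axis()] (or coercible matrix).
#' @param check validate that the axis lies inside the contour.
#' @return a `muscle_roi` object.
#' @export
muscle_roi <- function(muscle_id, frame_index, contour, axis, check = TRUE) {
  if (!is.character(muscle_id) || length(muscle_id) != 1L || !nzchar(muscle_id))
    stop("muscle_id must be a non-empty string")
  if (!inherits(contour, "contour")) contour <- contour(contour)
  if (!inherits(axis, "medial_axis")) axis <- medial_axis(axis)
  if (check) {
    inside <- pracma::inpolygon(axis[, 1L], axis[, 2L],
                                contour[, 1L], contour[, 2L],
                                boundary = FALSE)
    if (!all(inside))
      stop("medial axis of '", muscle_id, "' has vertices outside its contour")
  }
  structure(list(muscle_id = muscle_id,
                 frame_index = as.integer(frame_index),
                 contour = contour, axis = axis),
            class = "muscle_roi")
}

# O(n^2) simplicity check: no two non-adjacent edges may cross.
is_simple_polygon <- function(v) {
  n <- nrow(v)
  a <- v
  b <- v[c(2:n, 1L), , drop = FALSE]
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      adjacent <- (j == i + 1L) || (i == 1L && j == n)
      if (adjacent) next
      if (segments_cross(a[i, ], b[i, ], a[j, ], b[j, ])) return(FALSE)
    }
  }
  TRUE
}

segments_cross <- function(p1, p2, q1, q2) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(q1, q2, p1); d2 <- d(q1, q2, p2)
  d3 <- d(p1, p2, q1); d4 <- d(p1, p2, q2)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
   ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

#' Polygon area of a contour
#'
#' Shoelace area of the exact (sub-pixel) polygon, scaled to square microns.
#' Orientation independent.
#'
#' @param contour a [contour()] or n x 2 matrix.
#' @param pixel_size pixel edge length in microns.
#' @return area in square microns.
#' @export
polygon_area <- function(contour, pixel_size = 1) {
  if (!inherits(contour, "contour")) contour <- contour(contour)
  stopifnot(pixel_size > 0)
  x <- contour[, 1L]; y <- contour[, 2L]
  n <- length(x)
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2 * pixel_size^2
}

#' Arc length of a medial axis
#'
#' @param axis a [medial_axis()] or n x 2 matrix.
#' @param pixel_size pixel edge length in microns.
#' @return length in microns.
#' @export
polyline_length <- function(axis, pixel_size = 1) {
  if (!inherits(axis, "medial_axis")) axis <- medial_axis(axis)
  stopifnot(pixel_size > 0)
  d <- diff(axis)
  sum(sqrt(rowSums(d^2))) * pixel_size
}

# cumulative arc length (pixels) at each polyline vertex, starting at 0
cum_arc <- function(axis) {
  d <- diff(axis)
  c(0, cumsum(sqrt(rowSums(d^2))))
}

# point on the arc-length-parameterised polyline at arc position s (pixels)
point_at_arc <- function(axis, arcs, s) {
  s <- min(max(s, 0), arcs[length(arcs)])
  i <- findInterval(s, arcs, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(axis) - 1L)
  seg <- arcs[i + 1L] - arcs[i]
  f <- if (seg > 0) (s - arcs[i]) / seg else 0
  axis[i, ] + f * (axis[i + 1L, ] - axis[i, ])
}

# unit tangent at arc position s by central difference (one-sided at the ends)
tangent_at_arc <- function(axis, arcs, s, h = 0.5) {
  total <- arcs[length(arcs)]
  h <- min(h, total / 2)
  p1 <- point_at_arc(axis, arcs, s - h)
  p2 <- point_at_arc(axis, arcs, s + h)
  v <- p2 - p1
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("degenerate medial axis: zero tangent")
  v / nv
}

# nearest intersection distance of ray (origin p, unit direction d) with the
# closed polygon; returns Inf when the ray misses every edge
ray_polygon_distance <- function(p, d, poly, tol = 1e-9) {
  n <- nrow(poly)
  a <- poly
  b <- poly[c(2:n, 1L), , drop = FALSE]
  ex <- b[, 1L] - a[, 1L]; ey <- b[, 2L] - a[, 2L]
  # solve p + t d = a + u e  for each edge
  den <- d[1L] * (-ey) - d[2L] * (-ex)
  wx <- a[, 1L] - p[1L]; wy <- a[, 2L] - p[2L]
  t <- (wx * (-ey) - wy * (-ex)) / den
  u <- (d[1L] * wy - d[2L] * wx) / den
  ok <- is.finite(t) & t > tol & u >= -tol & u <= 1 + tol
  if (!any(ok)) return(Inf)
  min(t[ok])
}

#' Chord-diameter profile along the medial axis
#'
#' Samples equidistant points along the medial axis (every `step_px` pixels
#' of arc length, starting at arc position 0) and, at each sample, casts rays
#' in both directions orthogonal to the local tangent. The chord is the sum
#' of the distances to the nearest contour intersection on each side; the
#' average diameter of the muscle is the arithmetic mean of the chords.
#'
#' @param contour a [contour()].
#' @param axis a [medial_axis()] lying inside the contour.
#' @param step_px arc-length sampling step in pixels (default 5).
#' @param pixel_size pixel edge length in microns.
#' @return list with `chord_profile` (data.frame `arc_um`, `chord_um`) and
#'   `mean_diameter` (microns).
#' @export
diameter_profile <- function(contour, axis, step_px = 5, pixel_size = 1) {
  if (!inherits(contour, "contour")) contour <- contour(contour)
  if (!inherits(axis, "medial_axis")) axis <- medial_axis(axis)
  stopifnot(step_px > 0, pixel_size > 0)
  arcs <- cum_arc(axis)
  total <- arcs[length(arcs)]
  samples <- seq(0, total, by = step_px)
  chords <- numeric(length(samples))
  for (k in seq_along(samples)) {
    s <- samples[k]
    p <- point_at_arc(axis, arcs, s)
    tg <- tangent_at_arc(axis, arcs, s)
    nrm <- c(-tg[2L], tg[1L])
    d1 <- ray_polygon_distance(p, nrm, contour)
    d2 <- ray_polygon_distance(p, -nrm, contour)
    if (!is.finite(d1) || !is.finite(d2))
      stop(sprintf(
        "orthogonal ray at arc position %.2f px (sample %d) does not hit the contour; is the medial axis inside the contour?",
        s, k))
    chords[k] <- (d1 + d2) * pixel_size
  }
  list(chord_profile = data.frame(arc_um = samples * pixel_size,
                                  chord_um = chords),
       mean_diameter = mean(chords))
}

#' Extract the three shape features of a muscle ROI
#'
#' Area (shoelace polygon area), length (medial-axis arc length) and average
#' diameter (mean orthogonal chord along the medial axis), all in micron
#' units, plus the per-sample-point chord profile.
#'
#' @param roi a [muscle_roi()].
#' @param pixel_size pixel edge length in microns.
#' @param step_px chord sampling step in pixels.
#' @return a `feature_record`: list with `area`, `length`, `mean_diameter`,
#'   `chord_profile`.
#' @export
extract_features <- function(roi, pixel_size = 1, step_px = 5) {
  stopifnot(inherits(roi, "muscle_roi"))
  prof <- diameter_profile(roi$contour, roi$axis, step_px = step_px,
                           pixel_size = pixel_size)
  structure(list(area = polygon_area(roi$contour, pixel_size),
                 length = polyline_length(roi$axis, pixel_size),
                 mean_diameter = prof$mean_diameter,
                 chord_profile = prof$chord_profile),
            class = "feature_record")
}

#' @export
print.feature_record <- function(x, ...) {
  cat(sprintf("feature_record: area %.1f um^2, length %.1f um, mean diameter %.2f um (%d chords)\n",
              x$area, x$length, x$mean_diameter, nrow(x$chord_profile)))
  invisible(x)
}

#' Group ROIs into per-identity, frame-sorted series
#'
#' @param rois list of [muscle_roi()] objects spanning several frames.
#' @return named list (one element per muscle id) of frame-sorted ROI lists;
#'   frames where an id was not annotated are simply absent (gaps are never
#'   interpolated).
#' @export
track <- function(rois) {
  stopifnot(is.list(rois), length(rois) > 0)
  ids <- vapply(rois, function(r) r$muscle_id, character(1))
  frames <- vapply(rois, function(r) r$frame_index, integer(1))
  key <- paste(ids, frames, sep = "@")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("duplicate (muscle_id, frame) pair: ", dup)
  }
  out <- split(rois, ids)
  lapply(out, function(series) {
    series[order(vapply(series, function(r) r$frame_index, integer(1)))]
  })
}

#' Measure a set of annotated ROIs
#'
#' Convenience wrapper running [extract_features()] over an ROI list and
#' returning a tidy feature table (one row per ROI).
#'
#' @param rois list of [muscle_roi()] objects; elements may carry optional
#'   `sample_id`, `genotype` and `hours_aHE` attributes which are copied into
#'   the table.
#' @param pixel_size,step_px see [extract_features()].
#' @return data.frame with columns `sample_id`, `genotype`, `muscle_id`,
#'   `frame_index`, `hours_aHE`, `area_um2`, `length_um`, `mean_diameter_um`.
#' @export
measure_rois <- function(rois, pixel_size = 1, step_px = 5) {
  rows <- lapply(rois, function(r) {
    f <- extract_features(r, pixel_size = pixel_size, step_px = step_px)
    data.frame(
      sample_id = attr(r, "sample_id") %||% NA_character_,
      genotype = attr(r, "genotype") %||% NA_character_,
      muscle_id = r$muscle_id,
      frame_index = r$frame_index,
      hours_aHE = attr(r, "hours_aHE") %||% NA_real_,
      area_um2 = f$area,
      length_um = f$length,
      mean_diameter_um = f$mean_diameter,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write ROI annotation files
#'
#' One JSON document per sample: a list of objects
#' `{muscle_id, frame_index, contour: [[x, y], ...], axis: [[x, y], ...]}`
#' with optional `sample_id`, `genotype` and `hours_aHE` fields.
#'
#' @param path JSON file path.
#' @return `read_rois_json`: list of [muscle_roi()] objects.
#' @export
read_rois_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(doc, function(e) {
    r <- muscle_roi(e$muscle_id, e$frame_index,
                    contour(do.call(rbind, lapply(e$contour, unlist)),
                            check = FALSE),
                    medial_axis(do.call(rbind, lapply(e$axis, unlist))),
                    check = FALSE)
    attr(r, "sample_id") <- e$sample_id %||% NULL
    attr(r, "genotype") <- e$genotype %||% NULL
    attr(r, "hours_aHE") <- e$hours_aHE %||% NULL
    r
  })
}

#' @rdname read_rois_json
#' @param rois list of [muscle_roi()] objects.
#' @export
write_rois_json <- function(rois, path) {
  doc <- lapply(rois, function(r) {
    e <- list(muscle_id = r$muscle_id,
              frame_index = r$frame_index,
              contour = apply(unclass(r$contour), 1L, function(v) as.list(unname(v)), simplify = FALSE),
              axis = apply(unclass(r$axis), 1L, function(v) as.list(unname(v)), simplify = FALSE))
    for (f in c("sample_id", "genotype", "hours_aHE"))
      if (!is.null(attr(r, f))) e[[f]] <- attr(r, f)
    e
  })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
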