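# Time-lapse containers.
#
# A TimeLapseVolume is a 5-D intensity array indexed (t, channel, z, y, x);
# a ProjectedSeries is the 4-D (t, channel, y, x) result of projecting the
# z axis away. Intensities are stored on the native integer scale (0..255
# for 8-bit data). Spacing is (z, y, x) in microns.

#' Construct a time-lapse volume
#'
#' @param voxels 5-D numeric array, dimensions (t, channel, z, y, x).
#' @param spacing voxel spacing `c(z, y, x)` in microns.
#' @param frame_interval acquisition interval in minutes.
#' @return a `time_lapse_volume`.
#' @export
time_lapse_volume <- function(voxels, spacing = c(13.2, 1.25, 1.25),
                              frame_interval = 30) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 5L)
  if (any(dim(voxels) < 1L)) stop("all dimensions must be >= 1")
  if (length(spacing) != 3L || any(spacing <= 0)) stop("spacing must be 3 positive values (z, y, x)")
  if (frame_interval <= 0) stop("frame_interval must be positive")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 frame_interval = frame_interval),
            class = "time_lapse_volume")
}

#' Construct a projected (2-D) time-lapse series
#'
#' @param frames 4-D numeric array, dimensions (t, channel, y, x).
#' @param pixel_size pixel size in microns.
#' @param frame_interval acquisition interval in minutes.
#' @param provenance free-form description of how the frames were obtained.
#' @return a `projected_series`.
#' @export
projected_series <- function(frames, pixel_size = 1.25, frame_interval = 30,
                             provenance = "direct") {
  stopifnot(is.array(frames), length(dim(frames)) == 4L)
  if (any(dim(frames) < 1L)) stop("all dimensions must be >= 1")
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval, provenance = provenance),
            class = "projected_series")
}

#' @export
print.time_lapse_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("time_lapse_volume: %d frames x %d channels x %d z x %d y x %d x; spacing %.2f/%.2f/%.2f um\n",
              d[1], d[2], d[3], d[4], d[5],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' @export
print.projected_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("projected_series (%s): %d frames x %d channels x %d y x %d x; %.2f um/px\n",
              x$provenance, d[1], d[2], d[3], d[4], x$pixel_size))
  invisible(x)
}

#' Concatenate acquisitions along the time axis
#'
#' All stacks must agree in channel/z/y/x dimensions and spacing; the output
#' holds the frames of each input in the order given.
#'
#' @param stacks list of [time_lapse_volume()] objects.
#' @return a single [time_lapse_volume()].
#' @export
concatenate_volumes <- function(stacks) {
  stopifnot(is.list(stacks), length(stacks) >= 1L)
  for (s in stacks) stopifnot(inherits(s, "time_lapse_volume"))
  ref <- dim(stacks[[1L]]$voxels)[-1L]
  for (i in seq_along(stacks)) {
    di <- dim(stacks[[i]]$voxels)[-1L]
    if (!identical(di, ref))
      stop("stack ", i, " has channel/z/y/x dimensions (",
           paste(di, collapse = "x"), ") differing from stack 1 (",
           paste(ref, collapse = "x"), ")")
    if (!isTRUE(all.equal(stacks[[i]]$spacing, stacks[[1L]]$spacing)))
      stop("stack ", i, " has a different voxel spacing than stack 1")
  }
  nt <- sum(vapply(stacks, function(s) dim(s$voxels)[1L], integer(1)))
  out <- array(vector(typeof(stacks[[1L]]$voxels), 1L), dim = c(nt, ref))
  at <- 1L
  for (s in stacks) {
    n <- dim(s$voxels)[1L]
    out[at:(at + n - 1L), , , , ] <- s$voxels
    at <- at + n
  }
  time_lapse_volume(out, stacks[[1L]]$spacing, stacks[[1L]]$frame_interval)
}

#' Maximum-intensity projection
#'
#' Projects the z axis away: each output pixel is the maximum over all
#' z slices. Applying it to a single-slice volume returns that slice, so the
#' operation is idempotent on already-projected data.
#'
#' @param volume a [time_lapse_volume()].
#' @param axis projection axis; only `"z"` is supported.
#' @return a [projected_series()].
#' @export
max_project <- function(volume, axis = "z") {
  stopifnot(inherits(volume, "time_lapse_volume"))
  if (!identical(axis, "z")) stop("only z-axis projection is supported")
  d <- dim(volume$voxels)
  out <- array(-Inf, dim = d[c(1L, 2L, 4L, 5L)])
  for (z in seq_len(d[3L])) out <- pmax(out, volume$voxels[, , z, , , drop = FALSE][, , 1L, , ])
  projected_series(out, pixel_size = volume$spacing[3L],
                   frame_interval = volume$frame_interval,
                   provenance = "max_project(z)")
}

#' Orthogonal reslice along a polyline
#'
#' Samples the volume on the curtain-like surface through an x-y polyline
#' extended along z, at one-pixel arc steps (nearest-neighbour lookup), and
#' measures per column the z extent of signal above half of the column
#' maximum, in microns.
#'
#' @param volume a [time_lapse_volume()].
#' @param polyline n x 2 matrix of (x, y) pixel coordinates.
#' @param frame 0-based frame index.
#' @param channel 1-based channel index.
#' @return list with `section` (matrix z x arc samples), `depth_profile_um`
#'   (per-column depth) and `arc_px` (arc position of each column).
#' @export
orthogonal_reslice <- function(volume, polyline, frame = 0, channel = 1) {
  stopifnot(inherits(volume, "time_lapse_volume"))
  poly <- as_coord_matrix(polyline, "reslice polyline")
  d <- dim(volume$voxels)
  if (frame < 0 || frame >= d[1L]) stop("frame index out of range")
  if (any(poly[, 1L] < 0) || any(poly[, 1L] > d[5L] - 1L) ||
      any(poly[, 2L] < 0) || any(poly[, 2L] > d[4L] - 1L))
    stop("reslice polyline lies outside the image bounds")
  arcs <- cum_arc(poly)
  total <- arcs[length(arcs)]
  samples <- seq(0, total, by = 1)
  nz <- d[3L]
  section <- matrix(0, nrow = nz, ncol = length(samples))
  for (k in seq_along(samples)) {
    p <- point_at_arc(poly, arcs, samples[k])
    xi <- min(max(round(p[1L]), 0L), d[5L] - 1L) + 1L
    yi <- min(max(round(p[2L]), 0L), d[4L] - 1L) + 1L
    section[, k] <- volume$voxels[frame + 1L, channel, , yi, xi]
  }
  depth <- apply(section, 2L, function(col) {
    m <- max(col)
    if (m <= 0) return(0)
    above <- which(col >= m / 2)
    (above[length(above)] - above[1L] + 1L) * volume$spacing[1L]
  })
  list(section = section, depth_profile_um = depth, arc_px = samples)
}

# ---------------------------------------------------------------------------
# Multi-page TIFF I/O. Pages are ordered time-major with interleaved
# channels: (t0 c0, t0 c1, t1 c0, ...); for volumetric data the z slices of
# one (t, channel) pair are consecutive: (t0 c0 z0, t0 c0 z1, ...). The page
# dialect and acquisition metadata live in a YAML sidecar next to the TIFF.
# ---------------------------------------------------------------------------

sidecar_path <- function(path) paste0(path, ".yaml")

#' Write a projected series (or volume) as a multi-page 8/16-bit TIFF
#'
#' @param x a [projected_series()] or [time_lapse_volume()].
#' @param path output TIFF path; a YAML metadata sidecar is written to
#'   `<path>.yaml`.
#' @param bits 8 or 16.
#' @param metadata extra fields merged into the sidecar (e.g. `he_frame`,
#'   `genotype`).
#' @return `path`, invisibly.
#' @export
write_tiff_series <- function(x, path, bits = 8, metadata = list()) {
  stopifnot(bits %in% c(8L, 16L))
  maxval <- 2^bits - 1
  if (inherits(x, "projected_series")) {
    d <- dim(x$frames); nz <- 1L
    get_page <- function(t, c, z) x$frames[t, c, , ]
    spacing <- c(NA, x$pixel_size, x$pixel_size)
    interval <- x$frame_interval
  } else if (inherits(x, "time_lapse_volume")) {
    d <- dim(x$voxels)[c(1L, 2L, 4L, 5L)]; nz <- dim(x$voxels)[3L]
    get_page <- function(t, c, z) x$voxels[t, c, z, , ]
    spacing <- x$spacing
    interval <- x$frame_interval
  } else stop("x must be a projected_series or time_lapse_volume")
  pages <- vector("list", d[1L] * d[2L] * nz)
  k <- 1L
  for (t in seq_len(d[1L])) for (ci in seq_len(d[2L])) for (z in seq_len(nz)) {
    pages[[k]] <- pmin(pmax(get_page(t, ci, z), 0), maxval) / maxval
    k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  meta <- c(list(n_frames = d[1L], n_channels = d[2L], n_z = nz,
                 height = d[3L], width = d[4L], bits = bits,
                 pixel_size_um = spacing[3L], z_spacing_um = spacing[1L],
                 frame_interval_min = interval,
                 page_order = "t,channel,z"),
            metadata)
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

#' Read a multi-page TIFF written by [write_tiff_series()]
#'
#' @param path TIFF path; the sidecar `<path>.yaml` declares the page
#'   dialect. Without a sidecar, pages are assumed to be a two-channel
#'   interleaved 2-D series.
#' @return a [projected_series()] (when `n_z == 1`) or
#'   [time_lapse_volume()]; the sidecar metadata is attached as attribute
#'   `"metadata"`.
#' @export
read_tiff_series <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- if (file.exists(sidecar_path(path))) yaml::read_yaml(sidecar_path(path))
          else list(n_channels = 2L, n_z = 1L, bits = 8L,
                    pixel_size_um = 1.25, frame_interval_min = 30,
                    z_spacing_um = NA)
  bits <- meta$bits %||% 8L
  maxval <- 2^bits - 1
  nc <- meta$n_channels; nz <- meta$n_z %||% 1L
  nt <- length(pages) / (nc * nz)
  if (nt != floor(nt)) stop("page count is not a multiple of channels x z")
  h <- nrow(pages[[1L]]); w <- ncol(pages[[1L]])
  if (nz == 1L) {
    out <- array(0, dim = c(nt, nc, h, w))
    k <- 1L
    for (t in seq_len(nt)) for (ci in seq_len(nc)) {
      out[t, ci, , ] <- round(pages[[k]] * maxval); k <- k + 1L
    }
    res <- projected_series(out, pixel_size = meta$pixel_size_um,
                            frame_interval = meta$frame_interval_min,
                            provenance = paste0("tiff:", basename(path)))
  } else {
    out <- array(0, dim = c(nt, nc, nz, h, w))
    k <- 1L
    for (t in seq_len(nt)) for (ci in seq_len(nc)) for (z in seq_len(nz)) {
      out[t, ci, z, , ] <- round(pages[[k]] * maxval); k <- k + 1L
    }
    res <- time_lapse_volume(out, spacing = c(meta$z_spacing_um,
                                              meta$pixel_size_um,
                                              meta$pixel_size_um),
                             frame_interval = meta$frame_interval_min)
  }
  attr(res, "metadata") <- meta
  res
}
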