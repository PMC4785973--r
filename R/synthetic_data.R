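# Seeded synthetic two-channel time-lapse generator with exact ground truth.
#
# Muscles are rendered as capsules (a rectangular shaft with semicircular
# caps): irregular real fibres have no closed-form features, capsules do —
# area = shaft_length * diameter + pi * (diameter/2)^2, length = shaft
# length (the medial axis), diameter = capsule width — which is what makes
# every downstream measurement testable against analytic truth.

# -- deterministic seeding -------------------------------------------------

mix_seed <- function(...) {
  parts <- as.numeric(c(...))
  s <- 11
  for (p in parts) s <- (s * 69069 + (p %% 2147483647) + 7) %% 2147483629
  as.integer(s)
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# -- spec constructors -----------------------------------------------------

#' Image-noise description for the synthetic renderer
#'
#' @param background_level constant background intensity.
#' @param gaussian_sd standard deviation of additive Gaussian read noise.
#' @param poisson_scaling photon-counting scale (0 disables shot noise;
#'   larger values mean more photons and relatively less noise).
#' @param bit_depth output bit depth (intensities clipped to `2^bit_depth-1`).
#' @return a `noise_spec`.
#' @export
noise_spec <- function(background_level = 6, gaussian_sd = 2,
                       poisson_scaling = 0.5, bit_depth = 8) {
  stopifnot(background_level >= 0, gaussian_sd >= 0,
            poisson_scaling >= 0, bit_depth >= 1)
  structure(list(background_level = background_level,
                 gaussian_sd = gaussian_sd,
                 poisson_scaling = poisson_scaling,
                 bit_depth = as.integer(bit_depth)),
            class = "noise_spec")
}

#' Myonuclear localization program
#'
#' Phases describe the positional pattern of the nuclei as a function of
#' hours after head eversion (aHE): `uniform_basal` (evenly spread along the
#' axis, offset to one side), `central_cluster` (tight cluster at the fibre
#' centre), `midline_row` (spread along the axis on the medial axis),
#' `scattered` (random axial and lateral positions away from the midline)
#' and `frozen` (retain the positions of the preceding phase). Between
#' consecutive phases, nuclei move by linear interpolation of their target
#' positions over `transition_h` hours.
#'
#' @param n_nuclei number of nuclei.
#' @param phases list of `list(start = <hours aHE>, pattern = <name>)`,
#'   start times strictly increasing.
#' @param lateral_jitter extra lateral placement noise (microns).
#' @param nucleus_radius rendered nucleus radius (microns).
#' @param transition_h duration of the movement between phases (hours).
#' @return a `nuclei_program`.
#' @export
nuclei_program <- function(n_nuclei = 10,
                           phases = list(list(start = -12, pattern = "uniform_basal")),
                           lateral_jitter = 1, nucleus_radius = 5,
                           transition_h = 10) {
  stopifnot(n_nuclei >= 0, lateral_jitter >= 0, nucleus_radius > 0)
  pats <- vapply(phases, function(p) p$pattern, character(1))
  starts <- vapply(phases, function(p) as.numeric(p$start), numeric(1))
  valid <- c("uniform_basal", "central_cluster", "midline_row", "scattered", "frozen")
  if (!all(pats %in% valid))
    stop("unknown nuclei pattern(s): ", paste(setdiff(pats, valid), collapse = ", "))
  if (length(starts) > 1L && any(diff(starts) <= 0))
    stop("phase start times must be strictly increasing")
  structure(list(n_nuclei = as.integer(n_nuclei), phases = phases,
                 lateral_jitter = lateral_jitter,
                 nucleus_radius = nucleus_radius,
                 transition_h = transition_h),
            class = "nuclei_program")
}

check_keyframes <- function(kf, name, positive = TRUE) {
  kf <- as.matrix(kf)
  if (ncol(kf) < 2L) stop(name, " keyframes need (hours, value) columns")
  if (nrow(kf) > 1L && any(diff(kf[, 1L]) <= 0))
    stop(name, " keyframe times must be strictly increasing")
  if (positive && any(kf[, 2L] <= 0)) stop(name, " keyframe values must be > 0")
  unname(kf)
}

#' One synthetic muscle
#'
#' Feature trajectories are piecewise-linear in hours aHE; the shaft length
#' is derived from area and diameter via the capsule identity so the three
#' features stay mutually consistent. Before head eversion the shaft is
#' longer by `1 / he_contraction_factor` (head eversion contracts the fibre
#' over a single frame).
#'
#' @param muscle_id identity string, e.g. `"DIOM 3L"`.
#' @param area_keyframes matrix of (hours aHE, um^2).
#' @param diameter_keyframes matrix of (hours aHE, um).
#' @param orientation_keyframes matrix of (hours aHE, degrees).
#' @param centroid_keyframes matrix of (hours aHE, x px, y px).
#' @param he_contraction_factor shaft-length multiplier applied at head
#'   eversion, in (0, 1].
#' @param nuclei a [nuclei_program()].
#' @param death_time optional hours aHE after which the muscle is gone.
#' @return a `muscle_spec`.
#' @export
muscle_spec <- function(muscle_id, area_keyframes, diameter_keyframes,
                        orientation_keyframes = cbind(0, 0),
                        centroid_keyframes = cbind(0, 128, 128),
                        he_contraction_factor = 0.53,
                        nuclei = nuclei_program(),
                        death_time = NULL) {
  stopifnot(nzchar(muscle_id),
            he_contraction_factor > 0, he_contraction_factor <= 1)
  structure(list(
    muscle_id = muscle_id,
    area_keyframes = check_keyframes(area_keyframes, "area"),
    diameter_keyframes = check_keyframes(diameter_keyframes, "diameter"),
    orientation_keyframes = check_keyframes(orientation_keyframes, "orientation", positive = FALSE),
    centroid_keyframes = check_keyframes(centroid_keyframes, "centroid", positive = FALSE),
    he_contraction_factor = he_contraction_factor,
    nuclei = nuclei, death_time = death_time),
    class = "muscle_spec")
}

#' Scene description for one synthetic pupa
#'
#' @param muscles list of [muscle_spec()] objects.
#' @param image_size `c(width, height)` in pixels.
#' @param pixel_size microns per pixel.
#' @param frame_interval minutes between frames.
#' @param n_frames number of frames.
#' @param he_frame frame index (0-based) of head-eversion onset.
#' @param frame_hours optional explicit hours-aHE per frame (overrides the
#'   uniform `frame_interval` grid; used by the fast profile which renders
#'   only the 13 canonical analysis time points).
#' @param noise a [noise_spec()].
#' @param seed integer seed; identical (spec, seed) produce bit-identical
#'   renders.
#' @param z_stack if `TRUE`, frames are emitted as small z-stacks whose
#'   depth equals the local capsule diameter (for orthogonal reslicing).
#' @return a `scene_spec`.
#' @export
scene_spec <- function(muscles, image_size = c(1024L, 1024L),
                       pixel_size = 1.25, frame_interval = 30,
                       n_frames = 240L, he_frame = 24L,
                       frame_hours = NULL, noise = noise_spec(),
                       seed = 1L, z_stack = FALSE) {
  stopifnot(is.list(muscles), length(muscles) >= 1L,
            pixel_size > 0, frame_interval > 0)
  for (m in muscles) stopifnot(inherits(m, "muscle_spec"))
  if (!is.null(frame_hours)) n_frames <- length(frame_hours)
  if (n_frames < 1L) stop("n_frames must be >= 1")
  if (is.null(frame_hours) && (he_frame < 0L || he_frame >= n_frames))
    stop("he_frame must lie in [0, n_frames)")
  structure(list(muscles = muscles, image_size = as.integer(image_size),
                 pixel_size = pixel_size, frame_interval = frame_interval,
                 n_frames = as.integer(n_frames), he_frame = as.integer(he_frame),
                 frame_hours = frame_hours, noise = noise,
                 seed = as.integer(seed), z_stack = isTRUE(z_stack)),
            class = "scene_spec")
}

#' Hours aHE of every frame in a scene
#' @param spec a [scene_spec()].
#' @export
scene_frame_hours <- function(spec) {
  if (!is.null(spec$frame_hours)) return(spec$frame_hours)
  (seq_len(spec$n_frames) - 1L - spec$he_frame) * spec$frame_interval / 60
}

# -- capsule geometry ------------------------------------------------------

#' Analytic area of a capsule
#'
#' @param shaft_length_um shaft (medial axis) length in microns.
#' @param diameter_um capsule width in microns.
#' @return area in square microns: `shaft * diameter + pi * (diameter/2)^2`.
#' @export
capsule_area <- function(shaft_length_um, diameter_um) {
  shaft_length_um * diameter_um + pi * (diameter_um / 2)^2
}

# shaft length consistent with a given capsule area and diameter
capsule_shaft_from_area <- function(area_um2, diameter_um) {
  pmax((area_um2 - pi * (diameter_um / 2)^2) / diameter_um, 2)
}

#' Capsule outline polygon and medial axis (pixel coordinates)
#'
#' @param centre_px capsule centre `c(x, y)` in pixels.
#' @param theta_deg orientation of the long axis, degrees.
#' @param shaft_length_um,diameter_um capsule dimensions in microns.
#' @param pixel_size microns per pixel.
#' @param n_cap vertices per semicircular cap.
#' @return `capsule_polygon`: a [contour()]; `capsule_axis`: a
#'   [medial_axis()] with `n_axis` equally spaced vertices on the shaft.
#' @export
capsule_polygon <- function(centre_px, theta_deg, shaft_length_um,
                            diameter_um, pixel_size = 1.25, n_cap = 24L) {
  th <- theta_deg * pi / 180
  u <- c(cos(th), sin(th)); v <- c(-sin(th), cos(th))
  hl <- shaft_length_um / 2 / pixel_size
  r <- diameter_um / 2 / pixel_size
  e1 <- centre_px + hl * u
  e2 <- centre_px - hl * u
  ang <- seq(-pi / 2, pi / 2, length.out = n_cap)
  cap1 <- t(e1 + r * (outer(u, cos(ang)) + outer(v, sin(ang))))
  cap2 <- t(e2 - r * (outer(u, cos(ang)) + outer(v, sin(ang))))
  contour(rbind(cap1, cap2), check = FALSE)
}

#' @rdname capsule_polygon
#' @export
capsule_axis <- function(centre_px, theta_deg, shaft_length_um,
                         pixel_size = 1.25, n_axis = 5L) {
  th <- theta_deg * pi / 180
  u <- c(cos(th), sin(th))
  hl <- shaft_length_um / 2 / pixel_size
  f <- seq(-1, 1, length.out = max(n_axis, 2L))
  medial_axis(t(vapply(f, function(s) centre_px + s * hl * u, numeric(2))))
}

# interpolate a keyframe track at given hours (constant extrapolation)
kf_interp <- function(kf, hours, col = 2L) {
  if (nrow(kf) == 1L) return(rep(kf[1L, col], length(hours)))
  approx(kf[, 1L], kf[, col], xout = hours, rule = 2)$y
}

# full geometric state of one muscle at a given time
muscle_state <- function(m, hours) {
  D <- kf_interp(m$diameter_keyframes, hours)
  A <- kf_interp(m$area_keyframes, hours)
  L <- capsule_shaft_from_area(A, D)
  if (hours < 0) L <- L / m$he_contraction_factor
  list(diameter = D, shaft = L, area = capsule_area(L, D),
       theta = kf_interp(m$orientation_keyframes, hours),
       centre = c(kf_interp(m$centroid_keyframes, hours, 2L),
                  kf_interp(m$centroid_keyframes, hours, 3L)),
       alive = is.null(m$death_time) || hours < m$death_time)
}

# -- nuclei placement ------------------------------------------------------

# target (axial u, lateral ratio) positions for one pattern; rng state is
# the caller's responsibility
pattern_targets <- function(pattern, n) {
  strata <- (sample.int(n) - 0.5) / n
  switch(pattern,
    uniform_basal = list(
      u = pmin(pmax(strata + runif(n, -0.3, 0.3) / n, 0.03), 0.97),
      lat = pmin(pmax(0.6 + rnorm(n, 0, 0.05), 0.4), 0.8)),
    central_cluster = list(
      u = 0.5 + pmin(pmax(rnorm(n, 0, 0.045), -0.09), 0.09),
      lat = pmin(pmax(rnorm(n, 0, 0.1), -0.3), 0.3)),
    midline_row = list(
      u = pmin(pmax(strata + runif(n, -0.3, 0.3) / n, 0.03), 0.97),
      lat = pmin(pmax(rnorm(n, 0, 0.06), -0.2), 0.2)),
    scattered = list(
      u = pmin(pmax(strata + runif(n, -0.45, 0.45) / n, 0.03), 0.97),
      lat = sample(c(-1, 1), n, replace = TRUE) * runif(n, 0.15, 0.85)),
    stop("no direct targets for pattern '", pattern, "'"))
}

#' Draw one pure nuclear-pattern configuration
#'
#' Samples the (axial position, lateral offset ratio) targets of a single
#' localization pattern, exactly as the scene renderer places nuclei. Useful
#' for assessing the pattern classifier independently of image synthesis.
#'
#' @param pattern one of `"uniform_basal"`, `"central_cluster"`,
#'   `"midline_row"`, `"scattered"`.
#' @param n_nuclei number of nuclei.
#' @param seed integer seed.
#' @return data.frame with `axial_u` (in `[0, 1]`) and `lateral_ratio`
#'   (signed offset in units of the local half-width; the renderer scales it
#'   by 0.9 of the capsule radius).
#' @export
sample_nuclei_pattern <- function(pattern, n_nuclei = 10L, seed = 1L) {
  tl <- with_seed(seed, pattern_targets(pattern, n_nuclei))
  data.frame(axial_u = tl$u, lateral_ratio = tl$lat)
}

# resolve per-phase targets for a muscle (frozen phases inherit the previous
# phase's targets); deterministic given (scene_seed, muscle_index)
muscle_phase_targets <- function(prog, scene_seed, muscle_index) {
  n <- prog$n_nuclei
  targets <- vector("list", length(prog$phases))
  for (i in seq_along(prog$phases)) {
    pat <- prog$phases[[i]]$pattern
    if (pat == "frozen") {
      if (i == 1L) stop("the first phase cannot be 'frozen'")
      targets[[i]] <- targets[[i - 1L]]
    } else {
      targets[[i]] <- with_seed(mix_seed(scene_seed, muscle_index, i, 977),
                                pattern_targets(pat, n))
    }
  }
  targets
}

# (u, lat) of all nuclei of one muscle at a given time
nuclei_at_hours <- function(prog, targets, hours) {
  starts <- vapply(prog$phases, function(p) as.numeric(p$start), numeric(1))
  i <- findInterval(hours, starts)
  if (i < 1L) i <- 1L
  cur <- targets[[i]]
  frozen <- prog$phases[[i]]$pattern == "frozen"
  if (i > 1L && !frozen && hours < starts[i] + prog$transition_h) {
    f <- (hours - starts[i]) / prog$transition_h
    prev <- targets[[i - 1L]]
    cur <- list(u = (1 - f) * prev$u + f * cur$u,
                lat = (1 - f) * prev$lat + f * cur$lat)
  }
  cur
}

# pixel positions of nuclei given the muscle state
nuclei_pixel_positions <- function(st, prog, targets, hours, pixel_size) {
  if (prog$n_nuclei == 0L)
    return(data.frame(nucleus = integer(0), x = numeric(0), y = numeric(0),
                      axial_u = numeric(0), lateral_um = numeric(0),
                      lateral_ratio = numeric(0)))
  tl <- nuclei_at_hours(prog, targets, hours)
  th <- st$theta * pi / 180
  u <- c(cos(th), sin(th)); v <- c(-sin(th), cos(th))
  hl <- st$shaft / 2 / pixel_size
  lat_um <- tl$lat * (st$diameter / 2) * 0.9
  px <- t(vapply(seq_along(tl$u), function(i) {
    st$centre + (tl$u[i] - 0.5) * 2 * hl * u + (lat_um[i] / pixel_size) * v
  }, numeric(2)))
  data.frame(nucleus = seq_along(tl$u), x = px[, 1L], y = px[, 2L],
             axial_u = tl$u, lateral_um = lat_um, lateral_ratio = tl$lat)
}

# -- rendering -------------------------------------------------------------

# add a filled capsule (possibly z-thinned) into an intensity matrix
paint_capsule <- function(img, centre, theta_deg, shaft_px, radius_px, level) {
  h <- nrow(img); w <- ncol(img)
  th <- theta_deg * pi / 180
  u <- c(cos(th), sin(th))
  p1 <- centre - (shaft_px / 2) * u
  p2 <- centre + (shaft_px / 2) * u
  x0 <- max(floor(min(p1[1], p2[1]) - radius_px - 1), 0)
  x1 <- min(ceiling(max(p1[1], p2[1]) + radius_px + 1), w - 1)
  y0 <- max(floor(min(p1[2], p2[2]) - radius_px - 1), 0)
  y1 <- min(ceiling(max(p1[2], p2[2]) + radius_px + 1), h - 1)
  if (x1 < x0 || y1 < y0) return(img)
  xs <- x0:x1; ys <- y0:y1
  X <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  Y <- matrix(ys, nrow = length(ys), ncol = length(xs))
  vx <- p2[1] - p1[1]; vy <- p2[2] - p1[2]
  vv <- vx^2 + vy^2
  t <- if (vv > 0) pmin(pmax(((X - p1[1]) * vx + (Y - p1[2]) * vy) / vv, 0), 1) else 0
  dx <- X - (p1[1] + t * vx); dy <- Y - (p1[2] + t * vy)
  # anti-aliased edge: one-pixel linear coverage ramp, so the integrated
  # intensity is an unbiased estimate of the true capsule area
  cov <- pmin(pmax(radius_px - sqrt(dx^2 + dy^2) + 0.5, 0), 1)
  sub <- img[ys + 1L, xs + 1L, drop = FALSE]
  img[ys + 1L, xs + 1L] <- pmax(sub, level * cov)
  img
}

# add Gaussian nuclear spots
paint_spots <- function(img, pos, sigma_px, amp) {
  h <- nrow(img); w <- ncol(img)
  half <- ceiling(4 * sigma_px)
  for (i in seq_len(nrow(pos))) {
    cx <- pos$x[i]; cy <- pos$y[i]
    x0 <- max(floor(cx - half), 0); x1 <- min(ceiling(cx + half), w - 1)
    y0 <- max(floor(cy - half), 0); y1 <- min(ceiling(cy + half), h - 1)
    if (x1 < x0 || y1 < y0) next
    xs <- x0:x1; ys <- y0:y1
    g <- amp * exp(-outer((ys - cy)^2, (xs - cx)^2, "+") / (2 * sigma_px^2))
    img[ys + 1L, xs + 1L] <- img[ys + 1L, xs + 1L] + g
  }
  img
}

apply_noise <- function(img, noise, frame_seed, channel) {
  maxval <- 2^noise$bit_depth - 1
  img <- img + noise$background_level
  with_seed(mix_seed(frame_seed, channel, 555), {
    if (noise$poisson_scaling > 0) {
      img[] <- rpois(length(img), pmax(img, 0) * noise$poisson_scaling) /
        noise$poisson_scaling
    }
    if (noise$gaussian_sd > 0)
      img <- img + rnorm(length(img), 0, noise$gaussian_sd)
  })
  matrix(pmin(pmax(round(img), 0), maxval), nrow = nrow(img))
}

#' Render one frame of a synthetic scene
#'
#' Channel 1 holds the filled muscle bodies (cytoplasmic reporter), channel
#' 2 Gaussian nuclear spots at the programmed centroids. The returned ground
#' truth records the analytic capsule features, the true contour/axis
#' annotations and the exact nuclei positions of every living muscle.
#'
#' @param spec a [scene_spec()].
#' @param frame_index 0-based frame index.
#' @return list with `channels` (list of two intensity matrices, or of two
#'   z-stack arrays `(z, y, x)` when `spec$z_stack`), `truth` (data.frame,
#'   one row per living muscle), `nuclei` (data.frame of true centroids) and
#'   `rois` (list of ground-truth [muscle_roi()] annotations).
#' @export
render_frame <- function(spec, frame_index) {
  stopifnot(inherits(spec, "scene_spec"))
  if (frame_index < 0 || frame_index >= spec$n_frames)
    stop("frame_index out of range [0, ", spec$n_frames - 1L, "]")
  hours <- scene_frame_hours(spec)[frame_index + 1L]
  w <- spec$image_size[1L]; h <- spec$image_size[2L]
  px <- spec$pixel_size
  frame_seed <- mix_seed(spec$seed, frame_index, 131)
  fg_level <- 170; nuc_amp <- 220
  z_spacing <- 13.2

  n_z <- if (spec$z_stack) {
    dmax <- max(vapply(spec$muscles, function(m) max(m$diameter_keyframes[, 2L]), numeric(1)))
    2L * ceiling(dmax / 2 / z_spacing) + 3L
  } else 1L
  ch1 <- lapply(seq_len(n_z), function(z) matrix(0, h, w))
  ch2 <- lapply(seq_len(n_z), function(z) matrix(0, h, w))
  z_centre <- (n_z + 1) / 2

  truth <- list(); nuclei <- list(); rois <- list()
  for (mi in seq_along(spec$muscles)) {
    m <- spec$muscles[[mi]]
    st <- muscle_state(m, hours)
    if (!st$alive) next
    shaft_px <- st$shaft / px
    r_px <- st$diameter / 2 / px
    th <- st$theta * pi / 180
    ends <- rbind(st$centre + (shaft_px / 2) * c(cos(th), sin(th)),
                  st$centre - (shaft_px / 2) * c(cos(th), sin(th)))
    if (min(ends) - r_px < 0 || max(ends[, 1L]) + r_px > w - 1 ||
        max(ends[, 2L]) + r_px > h - 1)
      stop("muscle '", m$muscle_id, "' extends outside the ", w, "x", h,
           " image at frame ", frame_index)
    for (z in seq_len(n_z)) {
      dz_um <- (z - z_centre) * z_spacing
      r_eff2 <- (st$diameter / 2)^2 - dz_um^2
      if (r_eff2 <= 0) next
      ch1[[z]] <- paint_capsule(ch1[[z]], st$centre, st$theta, shaft_px,
                                sqrt(r_eff2) / px, fg_level)
    }
    targets <- muscle_phase_targets(m$nuclei, spec$seed, mi)
    pos <- nuclei_pixel_positions(st, m$nuclei, targets, hours, px)
    if (m$nuclei$lateral_jitter > 0 && nrow(pos) > 0) {
      jit <- with_seed(mix_seed(spec$seed, mi, round(hours * 60), 421),
                       matrix(rnorm(2L * nrow(pos), 0, m$nuclei$lateral_jitter / px), ncol = 2L))
      pos$x <- pos$x + jit[, 1L]; pos$y <- pos$y + jit[, 2L]
    }
    zc <- round(z_centre)
    if (nrow(pos) > 0)
      ch2[[zc]] <- paint_spots(ch2[[zc]], pos, m$nuclei$nucleus_radius / px * 0.6, nuc_amp)
    truth[[length(truth) + 1L]] <- data.frame(
      frame_index = frame_index, hours_aHE = hours, muscle_id = m$muscle_id,
      area_um2 = st$area, length_um = st$shaft, diameter_um = st$diameter,
      centre_x = st$centre[1L], centre_y = st$centre[2L],
      theta_deg = st$theta, alive = TRUE, stringsAsFactors = FALSE)
    if (nrow(pos) > 0) {
      pos$muscle_id <- m$muscle_id; pos$frame_index <- frame_index
      pos$hours_aHE <- hours
      nuclei[[length(nuclei) + 1L]] <- pos
    }
    roi <- muscle_roi(m$muscle_id, frame_index,
                      capsule_polygon(st$centre, st$theta, st$shaft, st$diameter, px),
                      capsule_axis(st$centre, st$theta, st$shaft, px),
                      check = FALSE)
    attr(roi, "hours_aHE") <- hours
    rois[[length(rois) + 1L]] <- roi
  }
  channels <- if (spec$z_stack) {
    list(simplify2array_zyx(ch1), simplify2array_zyx(ch2))
  } else list(ch1[[1L]], ch2[[1L]])
  channels <- lapply(seq_along(channels), function(ci) {
    x <- channels[[ci]]
    if (is.matrix(x)) apply_noise(x, spec$noise, frame_seed, ci)
    else {
      for (z in seq_len(dim(x)[1L]))
        x[z, , ] <- apply_noise(x[z, , ], spec$noise, mix_seed(frame_seed, z), ci)
      x
    }
  })
  list(channels = channels,
       truth = if (length(truth)) do.call(rbind, truth) else NULL,
       nuclei = if (length(nuclei)) do.call(rbind, nuclei) else NULL,
       rois = rois)
}

simplify2array_zyx <- function(slices) {
  out <- array(0, dim = c(length(slices), nrow(slices[[1L]]), ncol(slices[[1L]])))
  for (z in seq_along(slices)) out[z, , ] <- slices[[z]]
  out
}

#' Render a whole scene into a projected series (or volume)
#'
#' @param spec a [scene_spec()].
#' @return list with `series` (a [projected_series()] or, for z-stack
#'   scenes, a [time_lapse_volume()]), plus pooled `truth`, `nuclei` and
#'   `rois` across frames.
#' @export
render_scene <- function(spec) {
  frames <- lapply(seq_len(spec$n_frames) - 1L, function(f) render_frame(spec, f))
  if (spec$z_stack) {
    d <- dim(frames[[1L]]$channels[[1L]])
    vox <- array(0, dim = c(spec$n_frames, 2L, d[1L], d[2L], d[3L]))
    for (t in seq_len(spec$n_frames)) for (ci in 1:2)
      vox[t, ci, , , ] <- frames[[t]]$channels[[ci]]
    series <- time_lapse_volume(vox, spacing = c(13.2, spec$pixel_size, spec$pixel_size),
                                frame_interval = spec$frame_interval)
  } else {
    d <- dim(frames[[1L]]$channels[[1L]])
    arr <- array(0, dim = c(spec$n_frames, 2L, d[1L], d[2L]))
    for (t in seq_len(spec$n_frames)) for (ci in 1:2)
      arr[t, ci, , ] <- frames[[t]]$channels[[ci]]
    series <- projected_series(arr, pixel_size = spec$pixel_size,
                               frame_interval = spec$frame_interval,
                               provenance = "synthetic")
  }
  list(series = series,
       truth = do.call(rbind, lapply(frames, `[[`, "truth")),
       nuclei = do.call(rbind, Filter(Negate(is.null), lapply(frames, `[[`, "nuclei"))),
       rois = do.call(c, lapply(frames, `[[`, "rois")))
}

# -- genotype presets ------------------------------------------------------

# Preset trajectories. The control is pinned to the published medians
# (area 17925 -> 6038 -> 15719 um^2 at +5/+50/+100 h; diameter 84.4 ->
# 24.4 um with recovery to ~71% of the +5 h value); perturbation presets
# encode the direction and rough magnitude of each phenotype. Nuclei
# programs follow the observed phases: uniform basal until ~+40 h,
# anti-polar migration to a central cluster, then polar migration onto the
# midline over the next 10 h.
genotype_presets <- function() {
  ctrl_nuclei <- list(list(start = -12, pattern = "uniform_basal"),
                      list(start = 40, pattern = "central_cluster"),
                      list(start = 50, pattern = "midline_row"))
  list(
    control = list(
      area = cbind(c(5, 50, 100), c(17925, 6038, 15719)),
      diameter = cbind(c(5, 50, 100), c(84.4, 24.4, 59.9)),
      he_contraction_factor = 0.53,
      nuclei_phases = ctrl_nuclei),
    TOR_shRNA = list(
      area = cbind(c(5, 50, 100), c(14000, 2800, 4480)),
      diameter = cbind(c(5, 50, 100), c(70, 21, 28)),
      he_contraction_factor = 0.53,
      nuclei_phases = ctrl_nuclei),
    Rheb_shRNA = list(
      area = cbind(c(5, 50, 100), c(14500, 3045, 5655)),
      diameter = cbind(c(5, 50, 100), c(72, 23, 30)),
      he_contraction_factor = 0.53,
      nuclei_phases = ctrl_nuclei),
    Tsc2_1_shRNA = list(
      area = cbind(c(5, 50, 100), c(17925, 11500, 16000)),
      diameter = cbind(c(5, 50, 100), c(84.4, 62, 72)),
      he_contraction_factor = 0.53,
      nuclei_phases = ctrl_nuclei),
    Atg_shRNA = list(
      area = cbind(c(5, 50, 100), c(17925, 9299, 15719)),
      diameter = cbind(c(5, 50, 100), c(84.4, 44.4, 59.9)),
      he_contraction_factor = 0.53,
      nuclei_phases = list(list(start = -12, pattern = "uniform_basal"),
                           list(start = 40, pattern = "central_cluster"),
                           list(start = 50, pattern = "scattered"))),
    yki_shRNA = list(
      area = cbind(c(5, 50, 60, 100), c(17925, 6038, 7000, 11000)),
      diameter = cbind(c(5, 50, 60, 100), c(77, 22, 25, 40)),
      he_contraction_factor = 0.578,
      nuclei_phases = ctrl_nuclei),
    Cp1_shRNA = list(
      area = cbind(c(5, 50, 100), c(17925, 6038, 15719)),
      diameter = cbind(c(5, 50, 100), c(84.4, 24.4, 59.9)),
      he_contraction_factor = 0.53,
      nuclei_phases = list(list(start = -12, pattern = "uniform_basal")),
      death_fraction = 2 / 3, death_mean = 55.3, death_sd = 13.4))
}

#' Keyframes of a genotype preset
#' @param preset preset name, one of `names(genotype_presets())`.
#' @export
preset_keyframes <- function(preset) {
  presets <- genotype_presets()
  if (!preset %in% names(presets))
    stop("unknown preset '", preset, "'; valid presets: ",
         paste(names(presets), collapse = ", "))
  presets[[preset]]
}

#' Generate a synthetic cohort for one genotype preset
#'
#' Each sample is one pupa carrying a single remodelled muscle ("DIOM 3L")
#' whose area and diameter keyframes are scaled by a per-sample log-normal
#' size multiplier (sigma = 0.1 on the log scale, constant across the whole
#' trajectory). Multipliers are drawn by seeded stratified (Latin-hypercube)
#' sampling, which pins the cohort median trajectory to the preset keyframes
#' by construction while keeping log-normal marginal spread.
#'
#' @param preset genotype preset name (see [genotype_presets()]).
#' @param n_samples number of pupae.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @param profile `"fast"` (256 x 256 px, only the 13 canonical analysis
#'   time points) or `"full"` (1024 x 1024 px, 240 frames at 30-min
#'   intervals, head eversion at frame 24).
#' @param out_dir if non-`NULL`, per-sample two-channel TIFFs (+ YAML
#'   sidecars), per-sample ROI JSON annotations, a ground-truth CSV, a
#'   nuclei-truth CSV, a cohort manifest CSV and the generator configuration
#'   are written there.
#' @param render render pixel data (`FALSE` skips image synthesis and
#'   returns annotations/truth only; forced `TRUE` when `out_dir` is set).
#' @param genotype genotype label stored with the cohort (defaults to the
#'   preset name; override when comparing two cohorts of the same preset).
#' @param id_prefix prefix of the generated sample ids.
#' @return list with `truth`, `nuclei`, `rois` (ROIs carry `sample_id`,
#'   `genotype`, `hours_aHE` attributes), `manifest`, `scenes`, and `files`
#'   (paths written, if any).
#' @export
generate_cohort <- function(preset, n_samples, seed = 1L,
                            profile = c("fast", "full"),
                            out_dir = NULL, render = !is.null(out_dir),
                            genotype = preset, id_prefix = genotype) {
  profile <- match.arg(profile)
  stopifnot(n_samples >= 1L)
  pk <- preset_keyframes(preset)
  if (!is.null(out_dir)) { dir.create(out_dir, recursive = TRUE, showWarnings = FALSE); render <- TRUE }

  z <- with_seed(mix_seed(seed, 101), {
    strata <- qnorm((seq_len(n_samples) - 0.5) / n_samples)
    pmin(pmax(strata[sample.int(n_samples)], -2), 2)
  })
  mult <- exp(0.1 * z)

  death_times <- rep(NA_real_, n_samples)
  if (!is.null(pk$death_fraction)) {
    k <- round(pk$death_fraction * n_samples)
    idx <- with_seed(mix_seed(seed, 303), sample.int(n_samples, k))
    death_times[idx] <- with_seed(mix_seed(seed, 304),
      pmin(pmax(rnorm(k, pk$death_mean, pk$death_sd), 35), 95))
  }

  geom <- if (profile == "fast") {
    list(image_size = c(256L, 256L), frame_hours = canonical_grid(),
         centroid = c(127.5, 127.5), he_frame = 0L)
  } else {
    list(image_size = c(1024L, 1024L), frame_hours = NULL,
         centroid = c(511.5, 511.5), he_frame = 24L)
  }

  scenes <- vector("list", n_samples)
  truth <- list(); nuclei <- list(); rois <- list(); files <- character(0)
  sample_ids <- sprintf("%s_s%02d", id_prefix, seq_len(n_samples))
  for (i in seq_len(n_samples)) {
    area_kf <- pk$area; area_kf[, 2L] <- area_kf[, 2L] * mult[i]
    diam_kf <- pk$diameter; diam_kf[, 2L] <- diam_kf[, 2L] * mult[i]
    m <- muscle_spec(
      "DIOM 3L", area_kf, diam_kf,
      orientation_keyframes = cbind(c(-12, 5, 25, 100), c(25, 25, 0, 0)),
      centroid_keyframes = cbind(0, geom$centroid[1L], geom$centroid[2L]),
      he_contraction_factor = pk$he_contraction_factor,
      nuclei = nuclei_program(phases = pk$nuclei_phases),
      death_time = if (is.na(death_times[i])) NULL else death_times[i])
    spec <- scene_spec(list(m), image_size = geom$image_size,
                       frame_hours = geom$frame_hours,
                       he_frame = geom$he_frame,
                       n_frames = if (profile == "full") 240L else 13L,
                       seed = mix_seed(seed, 1000 + i))
    scenes[[i]] <- spec
    if (render) {
      sc <- render_scene(spec)
      s_truth <- sc$truth; s_nuclei <- sc$nuclei; s_rois <- sc$rois
      if (!is.null(out_dir)) {
        tif <- file.path(out_dir, paste0(sample_ids[i], ".tif"))
        write_tiff_series(sc$series, tif,
                          metadata = list(sample_id = sample_ids[i],
                                          genotype = genotype,
                                          he_frame = geom$he_frame,
                                          frame_hours = geom$frame_hours))
        files <- c(files, tif)
      }
    } else {
      hrs <- scene_frame_hours(spec)
      per_frame <- lapply(seq_len(spec$n_frames) - 1L, function(f) {
        st <- muscle_state(m, hrs[f + 1L])
        if (!st$alive) return(NULL)
        targets <- muscle_phase_targets(m$nuclei, spec$seed, 1L)
        pos <- nuclei_pixel_positions(st, m$nuclei, targets, hrs[f + 1L], spec$pixel_size)
        pos$muscle_id <- m$muscle_id; pos$frame_index <- f; pos$hours_aHE <- hrs[f + 1L]
        roi <- muscle_roi(m$muscle_id, f,
                          capsule_polygon(st$centre, st$theta, st$shaft, st$diameter, spec$pixel_size),
                          capsule_axis(st$centre, st$theta, st$shaft, spec$pixel_size),
                          check = FALSE)
        attr(roi, "hours_aHE") <- hrs[f + 1L]
        list(truth = data.frame(frame_index = f, hours_aHE = hrs[f + 1L],
                                muscle_id = m$muscle_id, area_um2 = st$area,
                                length_um = st$shaft, diameter_um = st$diameter,
                                centre_x = st$centre[1L], centre_y = st$centre[2L],
                                theta_deg = st$theta, alive = TRUE,
                                stringsAsFactors = FALSE),
             nuclei = pos, rois = list(roi))
      })
      per_frame <- Filter(Negate(is.null), per_frame)
      s_truth <- do.call(rbind, lapply(per_frame, `[[`, "truth"))
      s_nuclei <- do.call(rbind, lapply(per_frame, `[[`, "nuclei"))
      s_rois <- do.call(c, lapply(per_frame, `[[`, "rois"))
    }
    s_truth$sample_id <- sample_ids[i]; s_truth$genotype <- genotype
    if (!is.null(s_nuclei) && nrow(s_nuclei)) {
      s_nuclei$sample_id <- sample_ids[i]; s_nuclei$genotype <- genotype
    }
    s_rois <- lapply(s_rois, function(r) {
      attr(r, "sample_id") <- sample_ids[i]; attr(r, "genotype") <- genotype; r
    })
    if (!is.null(out_dir)) {
      rj <- file.path(out_dir, paste0(sample_ids[i], "_rois.json"))
      write_rois_json(s_rois, rj)
      files <- c(files, rj)
    }
    truth[[i]] <- s_truth; nuclei[[i]] <- s_nuclei; rois <- c(rois, s_rois)
  }
  truth <- do.call(rbind, truth)
  nuclei <- do.call(rbind, Filter(Negate(is.null), nuclei))
  manifest <- data.frame(sample_id = sample_ids, genotype = genotype,
                         size_multiplier = mult, death_time = death_times,
                         stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    tpath <- file.path(out_dir, "ground_truth.csv")
    npath <- file.path(out_dir, "nuclei_truth.csv")
    mpath <- file.path(out_dir, "manifest.csv")
    cpath <- file.path(out_dir, "cohort_config.yaml")
    write.csv(truth, tpath, row.names = FALSE)
    write.csv(nuclei, npath, row.names = FALSE)
    write.csv(manifest, mpath, row.names = FALSE)
    yaml::write_yaml(list(preset = preset, n_samples = n_samples, seed = seed,
                          profile = profile, pixel_size_um = 1.25,
                          sigma_log = 0.1), cpath)
    files <- c(files, tpath, npath, mpath, cpath)
  }
  list(preset = preset, n_samples = n_samples, seed = seed, profile = profile,
       truth = truth, nuclei = nuclei, rois = rois, manifest = manifest,
       scenes = scenes, files = files)
}
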