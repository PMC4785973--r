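# Shared fixtures and independent oracles.

# axis-aligned rectangle ROI: w x h pixels, medial axis along the mid line
rect_roi <- function(w = 100, h = 20, id = "rect", frame = 0L) {
  muscle_roi(id, frame,
             contour(rbind(c(0, 0), c(w, 0), c(w, h), c(0, h)), check = FALSE),
             medial_axis(rbind(c(0, h / 2), c(w, h / 2))),
             check = FALSE)
}

# random star-shaped (hence simple) polygon around a centre
random_star_polygon <- function(n = 12, r_range = c(10, 40), centre = c(50, 50)) {
  ang <- sort(runif(n, 0, 2 * pi))
  r <- runif(n, r_range[1], r_range[2])
  cbind(centre[1] + r * cos(ang), centre[2] + r * sin(ang))
}

# Monte-Carlo point-in-polygon area oracle (independent of the shoelace path)
mc_polygon_area <- function(poly, n = 2e5, pixel_size = 1) {
  x0 <- min(poly[, 1]); x1 <- max(poly[, 1])
  y0 <- min(poly[, 2]); y1 <- max(poly[, 2])
  xs <- runif(n, x0, x1); ys <- runif(n, y0, y1)
  frac <- mean(pracma::inpolygon(xs, ys, poly[, 1], poly[, 2], boundary = TRUE))
  frac * (x1 - x0) * (y1 - y0) * pixel_size^2
}

# exact Mann-Whitney p by enumeration of all C(m+n, m) group assignments
# of the pooled ranks (tie-free samples only)
mwu_enum_oracle <- function(a, b, tail) {
  m <- length(a); n <- length(b)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  ranks <- rank(pooled)
  u_obs <- sum(ranks[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(m + n, m)
  u_all <- apply(combos, 2, function(idx) sum(rank(pooled)[idx]) - m * (m + 1) / 2)
  switch(tail,
         left = mean(u_all <= u_obs),
         right = mean(u_all >= u_obs),
         two = min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))))
}

# single-muscle scene used across tests: control-preset trajectory, centred
demo_scene <- function(seed = 7, noise = noise_spec(), image_size = c(256, 256),
                       frame_hours = canonical_grid(), nuclei = nuclei_program(),
                       z_stack = FALSE) {
  m <- muscle_spec("DIOM 3L",
                   cbind(c(5, 50, 100), c(17925, 6038, 15719)),
                   cbind(c(5, 50, 100), c(84.4, 24.4, 59.9)),
                   centroid_keyframes = cbind(0, (image_size[1] - 1) / 2,
                                              (image_size[2] - 1) / 2),
                   nuclei = nuclei)
  scene_spec(list(m), image_size = image_size, frame_hours = frame_hours,
             n_frames = length(frame_hours), seed = seed, noise = noise,
             z_stack = z_stack)
}

# per-muscle pattern-classifier call on generator truth at one time point
truth_pattern <- function(cohort, sample_id, hours) {
  nuc <- cohort$nuclei[cohort$nuclei$sample_id == sample_id &
                       cohort$nuclei$hours_aHE == hours, ]
  tr <- cohort$truth[cohort$truth$sample_id == sample_id &
                     cohort$truth$hours_aHE == hours, ]
  distribution_metrics(truth_observations(nuc, tr$diameter_um[1]))$pattern
}
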