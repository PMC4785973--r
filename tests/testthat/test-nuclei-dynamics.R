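test_that("detection recovers programmed spots on a noiseless render", {
  sc <- demo_scene(seed = 7, noise = noise_spec(0, 0, 0))
  fr <- render_frame(sc, 0)
  det <- detect_nuclei(fr$channels[[2]], fr$rois[[1]]$contour)
  expect_equal(nrow(det), nrow(fr$nuclei))
  for (i in seq_len(nrow(det))) {
    d <- min(sqrt((fr$nuclei$x - det$x[i])^2 + (fr$nuclei$y - det$y[i])^2))
    expect_lt(d, 1)
  }
})

test_that("a blank nuclear channel yields zero detections", {
  blank <- matrix(0, 64, 64)
  expect_equal(nrow(detect_nuclei(blank)), 0)
  flat <- matrix(7, 64, 64)
  expect_equal(nrow(detect_nuclei(flat)), 0)
})

test_that("two spots merged below resolution are never over-split", {
  img <- matrix(0, 64, 64)
  for (cx in c(30, 33)) {
    xs <- 0:63
    img <- img + 200 * exp(-outer((xs - 32)^2, (xs - cx)^2, "+") / (2 * 2.5^2))
  }
  img <- pmin(round(img), 255)
  det <- detect_nuclei(img)
  expect_lte(nrow(det), 2)
  expect_gte(nrow(det), 1)
})

test_that("localization decomposes positions into axial and lateral parts", {
  roi <- rect_roi(100, 20)  # axis from (0,10) to (100,10)
  cent <- data.frame(x = c(0, 50, 75), y = c(10, 10, 16))
  obs <- localize_nuclei(cent, roi, pixel_size = 1.25)
  expect_equal(obs$axial_u, c(0, 0.5, 0.75))
  expect_equal(obs$lateral_d_um, c(0, 0, 6 * 1.25))
  expect_equal(obs$local_radius_um, rep(12.5, 3))
  # signed offsets distinguish the two sides
  both <- localize_nuclei(data.frame(x = c(50, 50), y = c(4, 16)), roi,
                          pixel_size = 1)
  expect_equal(abs(both$lateral_signed_um), c(6, 6))
  expect_equal(prod(sign(both$lateral_signed_um)), -1)
})

test_that("centroids outside the contour are excluded with a warning", {
  roi <- rect_roi(100, 20)
  expect_warning(obs <- localize_nuclei(data.frame(x = c(50, 200), y = c(10, 10)),
                                        roi, pixel_size = 1),
                 "outside")
  expect_equal(nrow(obs), 1)
})

test_that("lateral distance matches a brute-force point-to-polyline oracle", {
  set.seed(31)
  axis_pts <- cbind(c(10, 40, 70, 95), c(20, 35, 30, 50))
  poly <- capsule_polygon(c(50, 35), 15, 100, 40, pixel_size = 1)
  roi <- muscle_roi("m", 0L, poly, medial_axis(axis_pts), check = FALSE)
  pts <- data.frame(x = runif(20, 20, 80), y = runif(20, 25, 45))
  keep <- pracma::inpolygon(pts$x, pts$y, poly[, 1], poly[, 2], boundary = TRUE)
  pts <- pts[keep, ]
  obs <- localize_nuclei(pts, roi, pixel_size = 1)
  # oracle: continuous minimization of the distance on every segment
  for (i in seq_len(nrow(pts))) {
    dmin <- Inf
    for (s in 1:(nrow(axis_pts) - 1)) {
      f <- function(t) {
        q <- axis_pts[s, ] + t * (axis_pts[s + 1, ] - axis_pts[s, ])
        sum((c(pts$x[i], pts$y[i]) - q)^2)
      }
      o <- optimize(f, c(0, 1), tol = 1e-12)
      dmin <- min(dmin, sqrt(min(o$objective, f(0), f(1))))
    }
    expect_equal(obs$lateral_d_um[i], dmin, tolerance = 1e-6)
  }
})

test_that("distribution metrics hit their closed-form anchors", {
  mk_obs <- function(u, lat, radius = 1) {
    data.frame(muscle_id = "m", frame_index = 0L, x = 0, y = 0,
               axial_u = u, lateral_d_um = abs(lat), lateral_signed_um = lat,
               local_radius_um = radius)
  }
  centred <- distribution_metrics(mk_obs(rep(0.5, 8), rep(0, 8)))
  expect_equal(centred$axial_sd, 0)
  expect_equal(centred$central_fraction, 1)
  expect_equal(centred$midline_score, 0)
  expect_equal(centred$pattern, "central_cluster")
  # equally spaced nuclei on the axis: SD approaches 1/sqrt(12)
  row <- distribution_metrics(mk_obs(seq(0, 1, length.out = 101), rep(0, 101)))
  expect_equal(row$axial_sd, 1 / sqrt(12), tolerance = 0.01)
  expect_equal(row$pattern, "midline_row")
  single <- distribution_metrics(mk_obs(0.3, 0.1))
  expect_false(single$axial_sd_defined)
  expect_true(is.na(single$pattern))
  # midline score is zero when every nucleus sits on the axis, and grows
  # once the typical nucleus leaves it
  on_axis <- distribution_metrics(mk_obs(seq(0, 1, length.out = 9), rep(0, 9)))
  expect_equal(on_axis$midline_score, 0)
  off <- distribution_metrics(mk_obs(seq(0, 1, length.out = 9),
                                     c(rep(0, 3), rep(0.5, 6))))
  expect_gt(off$midline_score, 0)
})

test_that("the pattern classifier reaches 90% recall on pure generated patterns", {
  patterns <- c("uniform_basal", "central_cluster", "midline_row", "scattered")
  expected <- c(uniform_basal = "uniform", central_cluster = "central_cluster",
                midline_row = "midline_row", scattered = "scattered")
  for (p in patterns) {
    calls <- vapply(1:12, function(i) {
      tgt <- sample_nuclei_pattern(p, 10, seed = 1000 * match(p, patterns) + i)
      obs <- data.frame(muscle_id = "m", frame_index = 0L, x = 0, y = 0,
                        axial_u = tgt$axial_u,
                        lateral_d_um = abs(tgt$lateral_ratio) * 0.9,
                        lateral_signed_um = tgt$lateral_ratio * 0.9,
                        local_radius_um = 1)
      distribution_metrics(obs)$pattern
    }, character(1))
    expect_gte(mean(calls == expected[[p]]), 0.9)
  }
})

test_that("axial spread is invariant to axis reversal and rigid motion", {
  co <- generate_cohort("control", 1, seed = 6, profile = "fast", render = FALSE)
  roi <- co$rois[[1]]
  nuc <- co$nuclei[co$nuclei$frame_index == 0, ]
  obs <- localize_nuclei(nuc[, c("x", "y")], roi, pixel_size = 1.25)
  roi_rev <- muscle_roi(roi$muscle_id, roi$frame_index, roi$contour,
                        medial_axis(unclass(roi$axis)[nrow(roi$axis):1, ]),
                        check = FALSE)
  obs_rev <- localize_nuclei(nuc[, c("x", "y")], roi_rev, pixel_size = 1.25)
  m1 <- distribution_metrics(obs)
  m2 <- distribution_metrics(obs_rev)
  expect_equal(obs_rev$axial_u, 1 - obs$axial_u, tolerance = 1e-9)
  expect_equal(m2$axial_sd, m1$axial_sd, tolerance = 1e-9)
  expect_equal(m2$midline_score, m1$midline_score, tolerance = 1e-9)
})

test_that("control muscles transit uniform -> central cluster -> midline row", {
  co <- generate_cohort("control", 3, seed = 15, profile = "fast", render = FALSE)
  for (s in unique(co$truth$sample_id)) {
    met <- do.call(rbind, lapply(canonical_grid(), function(h) {
      nuc <- co$nuclei[co$nuclei$sample_id == s & co$nuclei$hours_aHE == h, ]
      tr <- co$truth[co$truth$sample_id == s & co$truth$hours_aHE == h, ]
      m <- distribution_metrics(truth_observations(nuc, tr$diameter_um[1]))
      data.frame(hours_aHE = h, pattern = m$pattern)
    }))
    tl <- phase_timeline(met)
    to_cluster <- tl$transitions[tl$transitions$to == "central_cluster", ]
    to_midline <- tl$transitions[tl$transitions$to == "midline_row", ]
    expect_equal(nrow(to_cluster), 1)
    expect_true(to_cluster$hours_aHE >= 35 && to_cluster$hours_aHE <= 55)
    expect_equal(nrow(to_midline), 1)
    expect_true(to_midline$hours_aHE >= 45 && to_midline$hours_aHE <= 65)
  }
})

test_that("Cp1 muscles show no nuclear phase transition; Atg ends scattered", {
  cp <- generate_cohort("Cp1_shRNA", 4, seed = 20, profile = "fast", render = FALSE)
  for (s in unique(cp$truth$sample_id)) {
    hrs <- sort(unique(cp$truth$hours_aHE[cp$truth$sample_id == s]))
    if (length(hrs) < 2) next
    met <- do.call(rbind, lapply(hrs, function(h)
      data.frame(hours_aHE = h, pattern = truth_pattern(cp, s, h))))
    expect_equal(nrow(phase_timeline(met)$transitions), 0)
  }
  atg <- generate_cohort("Atg_shRNA", 12, seed = 21, profile = "fast", render = FALSE)
  calls <- vapply(unique(atg$truth$sample_id), function(s)
    truth_pattern(atg, s, 70), character(1))
  expect_gte(mean(calls == "scattered"), 0.9)
})

test_that("constant metrics give a single phase without transitions", {
  met <- data.frame(hours_aHE = c(5, 10, 15, 20),
                    pattern = rep("uniform", 4))
  tl <- phase_timeline(met)
  expect_equal(nrow(tl$transitions), 0)
  expect_equal(unique(tl$timeline$smoothed), "uniform")
})
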