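test_that("polygon area is exact on rectangles and orientation-independent", {
  sq <- contour(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  expect_equal(polygon_area(sq, 1), 1)
  rect <- rbind(c(0, 0), c(100, 0), c(100, 20), c(0, 20))
  expect_equal(polygon_area(rect, 1.25), 100 * 20 * 1.25^2)
  expect_equal(polygon_area(rect[4:1, ], 1.25), 3125)  # reversed winding
})

test_that("invalid polygons are rejected", {
  expect_error(contour(rbind(c(0, 0), c(1, 1))), "3 vertices")
  bowtie <- rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10))
  expect_error(contour(bowtie), "self-intersecting")
  expect_error(polygon_area(bowtie), "self-intersecting")
})

test_that("polygon area agrees with a Monte-Carlo rasterization oracle", {
  set.seed(42)
  for (i in 1:3) {
    poly <- random_star_polygon()
    a_exact <- polygon_area(contour(poly), 1.25)
    a_mc <- mc_polygon_area(poly, n = 2e5, pixel_size = 1.25)
    expect_lt(abs(a_exact - a_mc) / a_mc, 0.01)
  }
})

test_that("polyline length: scaling, subdivision invariance, accumulation oracle", {
  expect_equal(polyline_length(rbind(c(0, 0), c(100, 0)), 1.25), 125)
  # 10 collinear vertices describe the same segment
  sub <- cbind(seq(0, 100, length.out = 10), 0)
  expect_equal(polyline_length(sub, 1.25), 125)
  set.seed(1)
  p <- cbind(cumsum(runif(20)), cumsum(rnorm(20)))
  acc <- 0
  for (i in 2:20) acc <- acc + sqrt(sum((p[i, ] - p[i - 1, ])^2))
  expect_equal(polyline_length(p, 1), acc, tolerance = 1e-9)
})

test_that("diameter profile is exact on a constant-width rectangle", {
  roi <- rect_roi(100, 20)
  prof <- diameter_profile(roi$contour, roi$axis, step_px = 5, pixel_size = 1.25)
  expect_equal(nrow(prof$chord_profile), 21)           # arcs 0, 5, ..., 100
  expect_true(all(abs(prof$chord_profile$chord_um - 25) < 1e-9))
  expect_equal(prof$mean_diameter, 25)
})

test_that("diameter profile recovers a linearly varying width on a trapezoid", {
  # symmetric trapezoid, width 10 px at x = 0 growing to 30 px at x = 100,
  # horizontal medial axis: the chord at arc x equals the local width
  tz <- contour(rbind(c(0, -5), c(100, -15), c(100, 15), c(0, 5)), check = FALSE)
  ax <- medial_axis(rbind(c(0, 0), c(100, 0)))
  prof <- diameter_profile(tz, ax, step_px = 5, pixel_size = 1)
  xs <- seq(0, 100, by = 5)
  expect_equal(prof$chord_profile$chord_um, 10 + 0.2 * xs, tolerance = 1e-9)
  expect_equal(prof$mean_diameter, mean(10 + 0.2 * xs), tolerance = 1e-9)
})

test_that("a ray that cannot reach the contour is reported with its sample point", {
  roi <- rect_roi(100, 20)
  bad_axis <- medial_axis(rbind(c(0, 10), c(200, 10)))  # leaves the contour
  expect_error(diameter_profile(roi$contour, bad_axis),
               "does not hit the contour")
})

test_that("feature extraction composes the three measures", {
  f <- extract_features(rect_roi(), pixel_size = 1.25, step_px = 5)
  expect_equal(f$area, 3125)
  expect_equal(f$length, 125)
  expect_equal(f$mean_diameter, 25)
  expect_gte(nrow(f$chord_profile), 1)  # at least the arc-0 sample
})

test_that("capsule ROIs recover generator ground truth", {
  # shaft 150 um >= 5x the cap radius, so chords see mostly the parallel sides
  poly <- capsule_polygon(c(127.5, 127.5), 20, 150, 25, pixel_size = 1.25)
  ax <- capsule_axis(c(127.5, 127.5), 20, 150, pixel_size = 1.25)
  roi <- muscle_roi("cap", 0L, poly, ax)
  f <- extract_features(roi, pixel_size = 1.25, step_px = 5)
  expect_equal(f$length, 150, tolerance = 1e-9)
  expect_lt(abs(f$area - capsule_area(150, 25)) / capsule_area(150, 25), 0.02)
  expect_lt(abs(f$mean_diameter - 25) / 25, 0.05)
})

test_that("features are invariant under rigid transforms", {
  roi <- muscle_roi("cap", 0L,
                    capsule_polygon(c(100, 100), 10, 120, 30, 1.25),
                    capsule_axis(c(100, 100), 10, 120, 1.25))
  th <- 33 * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  tr <- function(m) sweep(unclass(m) %*% t(rot), 2, c(40, -15), "+")
  roi2 <- muscle_roi("cap", 0L, contour(tr(roi$contour), check = FALSE),
                     medial_axis(tr(roi$axis)), check = FALSE)
  f1 <- extract_features(roi, 1.25)
  f2 <- extract_features(roi2, 1.25)
  expect_equal(f2$area, f1$area, tolerance = 1e-3)
  expect_equal(f2$length, f1$length, tolerance = 1e-3)
  expect_equal(f2$mean_diameter, f1$mean_diameter, tolerance = 1e-3)
})

test_that("chord sampling step refinement is stable on capsules", {
  poly <- capsule_polygon(c(127.5, 127.5), -15, 140, 28, 1.25)
  ax <- capsule_axis(c(127.5, 127.5), -15, 140, 1.25)
  d5 <- diameter_profile(poly, ax, step_px = 5, pixel_size = 1.25)$mean_diameter
  d1 <- diameter_profile(poly, ax, step_px = 1, pixel_size = 1.25)$mean_diameter
  expect_lt(abs(d5 - d1) / d1, 0.02)
})

test_that("track groups by identity, keeps gaps, is order-independent and rejects duplicates", {
  mk <- function(id, fr) rect_roi(id = id, frame = fr)
  rois <- list(mk("A", 0L), mk("A", 1L), mk("A", 3L),
               mk("B", 0L), mk("B", 1L), mk("B", 2L))
  tr <- track(rois)
  expect_named(tr, c("A", "B"))
  expect_equal(vapply(tr$A, `[[`, integer(1), "frame_index"), c(0L, 1L, 3L))
  expect_length(tr$B, 3)
  # shuffled input gives the identical grouping
  set.seed(9)
  tr2 <- track(sample(rois))
  expect_equal(lapply(tr2$A, `[[`, "frame_index"),
               lapply(tr$A, `[[`, "frame_index"))
  expect_error(track(c(rois, list(mk("A", 0L)))), "duplicate")
})

test_that("ROI JSON annotations round-trip", {
  rois <- list(rect_roi(id = "DIOM 3L", frame = 2L),
               rect_roi(80, 15, id = "DIOM 3R", frame = 2L))
  attr(rois[[1]], "sample_id") <- "s01"
  attr(rois[[1]], "hours_aHE") <- 5
  path <- tempfile(fileext = ".json")
  write_rois_json(rois, path)
  back <- read_rois_json(path)
  expect_length(back, 2)
  expect_equal(back[[1]]$muscle_id, "DIOM 3L")
  expect_equal(unclass(back[[1]]$contour), unclass(rois[[1]]$contour))
  expect_equal(unclass(back[[2]]$axis), unclass(rois[[2]]$axis))
  expect_equal(attr(back[[1]], "hours_aHE"), 5)
})

test_that("a medial axis outside its contour is rejected at construction", {
  expect_error(
    muscle_roi("bad", 0L, rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)),
               rbind(c(5, 5), c(15, 5))),
    "outside")
})
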