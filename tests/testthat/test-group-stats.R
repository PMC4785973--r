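test_that("median and quartiles use linear interpolation of order statistics", {
  expect_equal(median_iqr(c(1, 2, 3, 4, 5)), c(median = 3, q25 = 2, q75 = 4))
  expect_equal(median_iqr(7), c(median = 7, q25 = 7, q75 = 7))
  expect_error(median_iqr(numeric(0)), "at least one")
  # independent sort-and-interpolate oracle
  set.seed(77)
  x <- runif(1000)
  s <- sort(x)
  oracle <- function(p) {
    h <- (length(s) - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
  }
  m <- median_iqr(x)
  expect_equal(m[["median"]], oracle(0.5), tolerance = 1e-12)
  expect_equal(m[["q25"]], oracle(0.25), tolerance = 1e-12)
  expect_equal(m[["q75"]], oracle(0.75), tolerance = 1e-12)
})

test_that("MWU reproduces exact enumeration for separated small samples", {
  r <- mwu_test(1:5, 6:10, tail = "left")
  expect_equal(r$p, 1 / 252, tolerance = 1e-12)
  expect_true(r$exact)
  # complete separation the other way: the whole mass is below
  expect_equal(mwu_test(6:10, 1:5, tail = "left")$p, 1)
})

test_that("MWU agrees with the enumeration oracle across tails", {
  set.seed(5)
  for (i in 1:4) {
    a <- sample(seq(0.1, 50, by = 0.1), 6)
    b <- sample(setdiff(seq(0.05, 50, by = 0.1), a), 7)
    for (tail in c("left", "right", "two")) {
      got <- mwu_test(a, b, tail = tail)
      expect_true(got$exact)
      expect_equal(got$p_raw, mwu_enum_oracle(a, b, tail), tolerance = 1e-10,
                   label = paste("tail", tail, "rep", i))
    }
  }
})

test_that("MWU enforces the documented minimum group size and p floor", {
  expect_error(mwu_test(1:4, 1:10), "minimum sample size of 5")
  expect_error(mwu_test(1:10, 1:3), "minimum sample size of 5")
  # 50 widely separated values per group: raw p underflows the floor
  a <- seq(1, 50); b <- seq(1001, 1050)
  r <- mwu_test(a, b, tail = "left")
  expect_equal(r$p, 1e-4)
  expect_lt(r$p_raw, 1e-4)
  expect_lte(mwu_test(b, a, tail = "left")$p, 1)
})

test_that("MWU left/right duality holds exactly, including with ties", {
  set.seed(8)
  for (i in 1:3) {
    a <- sample(1:20, 8, replace = TRUE)  # ties likely
    b <- sample(1:20, 9, replace = TRUE)
    pl <- mwu_test(a, b, tail = "left")$p_raw
    pr <- mwu_test(b, a, tail = "right")$p_raw
    expect_equal(pl, pr, tolerance = 1e-12)
    expect_gte(mwu_test(a, b, tail = "left")$p_raw +
               mwu_test(a, b, tail = "right")$p_raw, 1 - 1e-12)
  }
})

test_that("normal approximation stays within 0.01 of the exact p for small samples", {
  set.seed(13)
  for (i in 1:5) {
    a <- sample(seq(0.1, 99.9, by = 0.1), 9)
    b <- sample(setdiff(seq(0.05, 99.9, by = 0.1), a), 10)
    exact <- mwu_test(a, b, tail = "left")$p_raw
    approx_p <- suppressWarnings(
      wilcox.test(a, b, alternative = "less", exact = FALSE, correct = TRUE)$p.value)
    expect_lt(abs(exact - approx_p), 0.01)
  }
})

test_that("normalization is 100% at the reference and scale-invariant", {
  s <- data.frame(hours_aHE = c(5, 50, 100), value = c(17925, 6038, 15719))
  n1 <- normalize_to_reference(s, 5)
  expect_equal(n1$pct[1], 100)
  expect_equal(n1$pct[2], 100 * 6038 / 17925)
  halved <- data.frame(hours_aHE = c(5, 50), value = c(200, 100))
  expect_equal(normalize_to_reference(halved, 5)$pct, c(100, 50))
  s2 <- transform(s, value = value * 3.7)
  expect_equal(normalize_to_reference(s2, 5)$pct, n1$pct)
  expect_warning(out <- normalize_to_reference(s, 33), "no observation")
  expect_null(out)
})

test_that("fold changes reproduce the published worked examples", {
  expect_equal(as.numeric(fold_change(17925, 6038, "decline", digits = 0)), 3)
  expect_equal(as.numeric(fold_change(6038, 15719, "increase", digits = 1)), 2.6)
  expect_equal(as.numeric(fold_change(8755, 3596, "decline", digits = 1)), 2.4)
  expect_equal(as.numeric(fold_change(14643, 2697, "decline", digits = 1)), 5.4)
  f <- fold_change(10, 10)
  expect_equal(as.numeric(f), 1)
  expect_error(fold_change(0, 5), "positive")
})

test_that("trajectory correlation matches the covariance formula", {
  x <- c(1, 4, 2, 8, 5)
  expect_equal(trajectory_correlation(x, x), 1)
  expect_equal(trajectory_correlation(x, -x), -1)
  set.seed(3)
  a <- rnorm(13); b <- rnorm(13)
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(trajectory_correlation(a, b), oracle, tolerance = 1e-12)
  expect_warning(r <- trajectory_correlation(rep(2, 5), a[1:5]), "zero variance")
  expect_true(is.na(r))
  expect_error(trajectory_correlation(1:2, 2:3), "at least 3")
})

test_that("the weighted-mean eclosion time reproduces the published total", {
  tab <- eclosion_table()
  tab <- tab[!is.na(tab$n_eclosed) & tab$n_eclosed > 0 &
             nzchar(tab$eclosion_mean_hmin), ]
  expect_equal(sum(tab$n_eclosed), 37)
  wm <- weighted_mean_time(tab$eclosion_mean_hmin, tab$n_eclosed)
  expect_equal(as.numeric(wm), 107.04)
  expect_equal(as.numeric(weighted_mean_time("103.30", 4)), 103.30)
  expect_equal(as.numeric(weighted_mean_time(c("100.00", "101.00"), c(1, 1))), 100.30)
  expect_error(weighted_mean_time("100.75", 1), "minutes")
  expect_error(weighted_mean_time("abc", 1), "malformed")
})

test_that("identical cohorts show no significant grid time; small groups stay untested", {
  co <- generate_cohort("control", 8, seed = 44, profile = "fast", render = FALSE)
  feats <- measure_rois(co$rois, pixel_size = 1.25, step_px = 5)
  # same measurements under two genotype labels
  fa <- transform(feats, genotype = "A")
  fb <- transform(feats, genotype = "B", sample_id = paste0("b_", sample_id))
  cmp <- compare_genotypes(rbind(fa, fb), "area_um2", "A", "B", tail = "two")
  expect_true(all(cmp$tested))
  expect_false(any(cmp$significant))
  expect_true(all(cmp$p == 1))
  # drop group A to n = 4 at one grid time
  fa2 <- fa[!(fa$hours_aHE == 50 & fa$sample_id %in% unique(fa$sample_id)[1:4]), ]
  cmp2 <- compare_genotypes(rbind(fa2, fb), "area_um2", "A", "B", tail = "two")
  row50 <- cmp2[cmp2$grid_time == 50, ]
  expect_false(row50$tested)
  expect_true(is.na(row50$p))
  expect_equal(row50$n_a, 4)
})

test_that("normalized control cohorts reproduce the relative atrophy depth", {
  co <- generate_cohort("control", 15, seed = 2, profile = "fast", render = FALSE)
  feats <- measure_rois(co$rois, pixel_size = 1.25, step_px = 5)
  per <- split(feats, feats$sample_id)
  at50 <- vapply(per, function(s) {
    n <- normalize_to_reference(
      data.frame(hours_aHE = s$hours_aHE, value = s$area_um2), 5)
    n$pct[n$hours_aHE == 50]
  }, numeric(1))
  # published control series decline to 34% of the +5 h value at +50 h
  expect_lt(abs(median(at50) - 34) , 3)
})
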