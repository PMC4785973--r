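# Statistical surface of the time-series analysis: per-timepoint medians
# with 25/75 percentiles, per-muscle normalization to a reference time,
# fold changes, tail-specific Mann-Whitney U with a documented p floor and
# minimum group size, trajectory correlation and the weighted-mean eclosion
# summary.

#' Median with 25/75 percentiles
#'
#' Percentiles use linear interpolation between order statistics
#' (`quantile` type 7).
#'
#' @param values numeric vector, length >= 1 (NAs dropped).
#' @return named numeric `c(median, q25, q75)`.
#' @export
median_iqr <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("median_iqr needs at least one value")
  q <- quantile(values, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  c(median = q[1L], q25 = q[2L], q75 = q[3L])
}

#' Tail-specific Mann-Whitney U test with documented floor and minimum n
#'
#' Rank-sum test with midranks for ties. Both groups must have at least 5
#' observations. For tie-free samples with `length(a) + length(b) <= 20`
#' the p-value comes from exact enumeration of the rank distribution;
#' otherwise from the normal approximation with continuity and tie
#' correction. The returned p-value is clipped to `[0.0001, 1]`.
#'
#' Tails: `"left"` tests the alternative A < B, `"right"` tests A > B,
#' `"two"` is two-sided.
#'
#' @param a,b numeric value vectors.
#' @param tail `"two"`, `"left"` or `"right"`.
#' @return list with `p` (clipped), `p_raw`, `U` (rank-sum statistic of
#'   group A), `tail`, `exact` (whether the exact distribution was used).
#' @export
mwu_test <- function(a, b, tail = c("two", "left", "right")) {
  tail <- match.arg(tail)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 5L || length(b) < 5L)
    stop("mwu_test requires a minimum sample size of 5 per group (got ",
         length(a), " and ", length(b), ")")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties && (length(a) + length(b) <= 20L)
  alternative <- switch(tail, two = "two.sided", left = "less", right = "greater")
  ht <- suppressWarnings(wilcox.test(a, b, alternative = alternative,
                                     exact = exact, correct = TRUE))
  p_raw <- ht$p.value
  list(p = min(max(p_raw, 1e-4), 1), p_raw = p_raw,
       U = unname(ht$statistic), tail = tail, exact = exact)
}

#' Normalize a feature series to a reference time point
#'
#' Expresses every point of one muscle's trajectory as a percentage of its
#' own value at the reference time (so 100% at the reference), computed per
#' muscle before any group aggregation.
#'
#' @param series data.frame with `hours_aHE` and a value column.
#' @param ref_time reference hours aHE.
#' @param value_col name of the value column.
#' @param tolerance_h tolerance when matching the reference time.
#' @return data.frame `hours_aHE`, `pct`; `NULL` (with a warning) when the
#'   series has no observation at the reference time.
#' @export
normalize_to_reference <- function(series, ref_time, value_col = "value",
                                   tolerance_h = 0.25) {
  stopifnot(is.data.frame(series), value_col %in% names(series))
  d <- abs(series$hours_aHE - ref_time)
  i <- which.min(d)
  if (!length(i) || d[i] > tolerance_h) {
    warning("series has no observation at the reference time ", ref_time,
            " h aHE; excluded from normalization")
    return(NULL)
  }
  ref <- series[[value_col]][i]
  if (!is.finite(ref) || ref <= 0) {
    warning("non-positive reference value; series excluded")
    return(NULL)
  }
  data.frame(hours_aHE = series$hours_aHE,
             pct = 100 * series[[value_col]] / ref)
}

#' Fold change between two values
#'
#' @param v_from,v_to positive values.
#' @param direction `"increase"` reports `v_to / v_from`, `"decline"`
#'   reports `v_from / v_to`; `"auto"` picks whichever is >= 1.
#' @param digits optional rounding of the reported fold.
#' @return the fold, with the direction as attribute `"direction"`.
#' @export
fold_change <- function(v_from, v_to, direction = c("auto", "increase", "decline"),
                        digits = NULL) {
  direction <- match.arg(direction)
  if (v_from <= 0 || v_to <= 0) stop("fold_change needs positive values")
  if (direction == "auto")
    direction <- if (v_to >= v_from) "increase" else "decline"
  f <- switch(direction, increase = v_to / v_from, decline = v_from / v_to)
  if (!is.null(digits)) f <- round(f, digits)
  structure(f, direction = direction)
}

#' Pearson correlation between two median trajectories
#'
#' @param medians_a,medians_b numeric vectors over the same grid (>= 3
#'   shared finite pairs).
#' @return Pearson r; `NA` with attribute `"degenerate" = TRUE` (and a
#'   warning) when either trajectory has zero variance.
#' @export
trajectory_correlation <- function(medians_a, medians_b) {
  stopifnot(length(medians_a) == length(medians_b))
  ok <- is.finite(medians_a) & is.finite(medians_b)
  if (sum(ok) < 3L) stop("need at least 3 shared grid points")
  a <- medians_a[ok]; b <- medians_b[ok]
  if (sd(a) == 0 || sd(b) == 0) {
    warning("zero variance in a trajectory; correlation undefined")
    return(structure(NA_real_, degenerate = TRUE))
  }
  cor(a, b)
}

# parse "h.min" notation (e.g. "107.04" = 107 h 04 min) to minutes
parse_hmin <- function(x) {
  s <- if (is.numeric(x)) sprintf("%.2f", x) else as.character(x)
  parts <- strsplit(s, ".", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) != 2L || is.na(suppressWarnings(as.numeric(p[1L]))))
      stop("malformed h.min value: ", paste(p, collapse = "."))
    hrs <- as.numeric(p[1L]); mins <- as.numeric(p[2L])
    if (is.na(mins) || mins >= 60) stop("minutes must be < 60 in h.min value")
    hrs * 60 + mins
  }, numeric(1))
}

format_hmin <- function(minutes) {
  minutes <- round(minutes)
  sprintf("%d.%02d", minutes %/% 60, minutes %% 60)
}

#' Sample-size-weighted mean of times in h.min notation
#'
#' Used for eclosion-time summaries: per-genotype mean eclosion times (in
#' hours.minutes notation, minutes < 60) are converted to minutes, weighted
#' by the number of eclosed pupae, averaged, rounded to the nearest minute
#' and re-expressed in h.min notation.
#'
#' @param mean_hmin character (or numeric) vector of h.min values.
#' @param n positive integer weights.
#' @return numeric h.min value (e.g. `107.04` = 107 h 04 min), with the
#'   exact weighted mean in minutes as attribute `"minutes"`.
#' @export
weighted_mean_time <- function(mean_hmin, n) {
  stopifnot(length(mean_hmin) == length(n), all(n >= 1))
  minutes <- parse_hmin(mean_hmin)
  wm <- sum(minutes * n) / sum(n)
  structure(as.numeric(format_hmin(wm)), minutes = wm)
}

#' Per-grid-time comparison of two genotypes
#'
#' For every canonical grid time with at least `min_n` muscles in both
#' groups: group medians with 25/75 percentiles and the tail-specific
#' Mann-Whitney U p-value; grid times failing the minimum-n rule are
#' reported as untested (`tested = FALSE`, `p = NA`), never as p = 1. No
#' multiple-testing correction is applied (raw per-timepoint p-values with
#' a 0.05 significance line, as is conventional for these time-resolved
#' comparisons).
#'
#' @param x a [muscle_store()] or a feature data.frame with columns
#'   `sample_id`, `genotype`, `muscle_id`, `hours_aHE` and the feature.
#' @param feature feature column: `"area_um2"`, `"length_um"` or
#'   `"mean_diameter_um"`.
#' @param genotype_a,genotype_b group labels; the tail refers to A vs B
#'   (`"left"`: A < B).
#' @param tail `"two"`, `"left"` or `"right"`.
#' @param grid grid times (hours aHE).
#' @param min_n minimum group size per grid time (default 5).
#' @param alpha significance threshold for the `significant` flag.
#' @param tolerance_h grid snapping tolerance.
#' @return a `genotype_comparison`: data.frame with one row per grid time
#'   (`grid_time`, `n_a`, `median_a`, `q25_a`, `q75_a`, `n_b`, ...,
#'   `tail`, `tested`, `p`, `significant`) plus attributes `feature`,
#'   `genotype_a`, `genotype_b`.
#' @export
compare_genotypes <- function(x, feature, genotype_a, genotype_b,
                              tail = c("two", "left", "right"),
                              grid = canonical_grid(), min_n = 5L,
                              alpha = 0.05, tolerance_h = 0.25) {
  tail <- match.arg(tail)
  df <- if (inherits(x, "muscle_store")) x$features else x
  stopifnot(is.data.frame(df), feature %in% names(df))
  value_at_grid <- function(geno, g) {
    sub <- df[df$genotype == geno, , drop = FALSE]
    per <- split(sub, paste(sub$sample_id, sub$muscle_id))
    v <- vapply(per, function(s) {
      d <- abs(s$hours_aHE - g)
      i <- which.min(d)
      if (length(i) && d[i] <= tolerance_h) s[[feature]][i] else NA_real_
    }, numeric(1))
    v[!is.na(v)]
  }
  rows <- lapply(grid, function(g) {
    va <- value_at_grid(genotype_a, g)
    vb <- value_at_grid(genotype_b, g)
    tested <- length(va) >= min_n && length(vb) >= min_n
    sa <- if (length(va)) median_iqr(va) else c(median = NA, q25 = NA, q75 = NA)
    sb <- if (length(vb)) median_iqr(vb) else c(median = NA, q25 = NA, q75 = NA)
    p <- if (tested) mwu_test(va, vb, tail = tail)$p else NA_real_
    data.frame(grid_time = g, n_a = length(va), median_a = sa[["median"]],
               q25_a = sa[["q25"]], q75_a = sa[["q75"]],
               n_b = length(vb), median_b = sb[["median"]],
               q25_b = sb[["q25"]], q75_b = sb[["q75"]],
               tail = tail, tested = tested, p = p,
               significant = tested && !is.na(p) && p < alpha)
  })
  out <- do.call(rbind, rows)
  structure(out, feature = feature, genotype_a = genotype_a,
            genotype_b = genotype_b, alpha = alpha,
            class = c("genotype_comparison", "data.frame"))
}

#' @export
print.genotype_comparison <- function(x, ...) {
  cat(sprintf("Comparison of %s: %s vs %s (%s-tailed MWU)\n",
              attr(x, "feature"), attr(x, "genotype_a"),
              attr(x, "genotype_b"), x$tail[1L]))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Two-panel comparison plot (median +/- IQR over time; log10 p)
#'
#' @param x a `genotype_comparison`.
#' @param ... unused.
#' @export
plot.genotype_comparison <- function(x, ...) {
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  ylim <- range(c(x$q25_a, x$q75_a, x$q25_b, x$q75_b), na.rm = TRUE)
  plot(x$grid_time, x$median_a, type = "b", pch = 16, ylim = ylim,
       xlab = "hours aHE", ylab = attr(x, "feature"),
       main = paste(attr(x, "genotype_a"), "vs", attr(x, "genotype_b")))
  segments(x$grid_time, x$q25_a, x$grid_time, x$q75_a)
  lines(x$grid_time, x$median_b, type = "b", pch = 1, col = 2)
  segments(x$grid_time, x$q25_b, x$grid_time, x$q75_b, col = 2)
  legend("topright", legend = c(attr(x, "genotype_a"), attr(x, "genotype_b")),
         pch = c(16, 1), col = c(1, 2), bty = "n")
  ok <- x$tested & !is.na(x$p)
  plot(x$grid_time[ok], log10(x$p[ok]), type = "b", pch = 16,
       xlab = "hours aHE", ylab = "log10 p (MWU)", xlim = range(x$grid_time))
  abline(h = log10(attr(x, "alpha")), lty = 2)
  invisible(x)
}

#' Export a comparison table as CSV
#' @param x a `genotype_comparison`.
#' @param path output CSV path.
#' @export
write_comparison_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Eclosion-time summary table
#'
#' The per-genotype eclosion summaries (number of pupae imaged, number
#' eclosed, mean eclosion time in h.min notation, eclosion rate) that feed
#' [weighted_mean_time()]; shipped as a plain-text table in `extdata`.
#'
#' @return data.frame with one row per genotype.
#' @export
eclosion_table <- function() {
  read.csv(system.file("extdata", "eclosion_times.csv", package = "myomorph"),
           colClasses = c(genotype = "character",
                          eclosion_mean_hmin = "character"))
}
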