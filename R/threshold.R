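# Amplitude-cutoff curve and break-point detection for choosing the final
# fold-change threshold.

#' Up/down percentage curve over amplitude cut-offs
#'
#' At cut-off `c`, counts the called coding genes with `fc >= c` (up) and
#' `fc <= 1/c` (down), expressed as percentages of the protein-coding pool.
#'
#' @param diff a called `diff_table`.
#' @param grid amplitude cut-offs (ratios >= 1); default 1.0 to 4.0 by 0.05.
#' @param n_coding size of the coding-gene reference pool (> 0).
#' @param coding_ids optional character vector restricting the counted genes
#'   to coding ones; default: all genes in `diff`.
#' @return object of class `cutoff_curve`: data.frame `cutoff`, `up_pct`,
#'   `down_pct` ordered by increasing cutoff, with attribute
#'   `n_coding_reference`.
#' @export
cutoff_curve <- function(diff, grid = seq(1, 4, by = 0.05), n_coding,
                         coding_ids = NULL) {
  assert_that(n_coding > 0, "n_coding reference pool must be positive")
  assert_that(all(grid >= 1), "amplitude cut-offs must be >= 1")
  assert_that("called" %in% names(diff), "run call_differential() first")
  d <- diff[diff$called & !is.na(diff$fc), ]
  if (!is.null(coding_ids)) d <- d[d$id %in% coding_ids, ]
  grid <- sort(grid)
  up <- vapply(grid, function(c) sum(d$fc >= c), 0L)
  dn <- vapply(grid, function(c) sum(d$fc <= 1 / c), 0L)
  structure(data.frame(cutoff = grid, up_pct = 100 * up / n_coding,
                       down_pct = 100 * dn / n_coding),
            n_coding_reference = n_coding,
            class = c("cutoff_curve", "data.frame"))
}

#' Detect the slope break point of the up-vs-down curve
#'
#' Fits `up_pct` against `down_pct` (points ordered by cutoff, the plane of
#' the published comparison plot) with a continuous two-segment
#' least-squares model; the knot is found by exhaustive search over interior
#' curve points with at least 3 points per segment. A break is reported only
#' when the two-segment fit improves the single-line residual sum of squares
#' by at least `improvement_min` (relative), guarding against over-fitting
#' an essentially straight curve.
#'
#' @param curve a [cutoff_curve()] with at least 6 points.
#' @param improvement_min minimum relative RSS improvement (default 0.05).
#' @return object of class `breakpoint_result`: list with `cutoff_at_break`
#'   (`NA` when no credible break), `segment_slopes` (`slope_low` on the
#'   low-cutoff side of the knot, `slope_high` above it, in the
#'   (down%, up%) plane), `rss_single`, `rss_two_segment`, `improvement`.
#' @export
detect_breakpoint <- function(curve, improvement_min = 0.05) {
  n <- nrow(curve)
  if (n < 6) stop("break-point detection needs at least 6 curve points",
                  call. = FALSE)
  x <- curve$down_pct
  y <- curve$up_pct
  fit1 <- stats::lm.fit(cbind(1, x), y)
  rss1 <- sum(fit1$residuals^2)
  ks <- 3:(n - 2)
  rss_k <- vapply(ks, function(k) {
    sum(stats::lm.fit(cbind(1, x, pmax(x - x[k], 0)), y)$residuals^2)
  }, 0)
  rss_min <- min(rss_k)
  # knots whose RSS is within 30% of the minimum are equivalent: plateaus
  # arise where the curve is locally flat in x (cut-offs above the knee
  # barely move down_pct), and the knee is the onset of the plateau, so the
  # smallest such cutoff is reported
  plateau <- ks[rss_k <= rss_min * 1.3]
  k_best <- plateau[which.min(curve$cutoff[plateau])]
  fitb <- stats::lm.fit(cbind(1, x, pmax(x - x[k_best], 0)), y)
  best <- list(rss = sum(fitb$residuals^2), k = k_best,
               coefs = fitb$coefficients)
  improvement <- if (rss1 > 1e-12) (rss1 - rss_min) / rss1 else 0
  b <- best$coefs
  b[is.na(b)] <- 0
  # points are ordered by cutoff: low cutoffs have large down_pct (x above
  # the knot), high cutoffs small down_pct
  slopes <- c(slope_low = unname(b[2] + b[3]), slope_high = unname(b[2]))
  structure(list(
    cutoff_at_break = if (improvement >= improvement_min)
      curve$cutoff[best$k] else NA_real_,
    segment_slopes = slopes,
    rss_single = rss1, rss_two_segment = best$rss,
    improvement = improvement),
    class = "breakpoint_result")
}

#' Final up/down gene sets at an amplitude threshold
#'
#' @param diff a called `diff_table`.
#' @param amplitude_min minimum amplitude (default 1.6); boundaries are
#'   inclusive: `fc >= amplitude_min` is up, `fc <= 1/amplitude_min` is
#'   down.
#' @return list with character vectors `up` and `down`.
#' @export
final_gene_sets <- function(diff, amplitude_min = 1.6) {
  assert_that("called" %in% names(diff), "run call_differential() first")
  d <- diff[diff$called & !is.na(diff$fc), ]
  list(up = d$id[d$fc >= amplitude_min],
       down = d$id[d$fc <= 1 / amplitude_min])
}
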