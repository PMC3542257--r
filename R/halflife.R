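# mRNA half-life estimation from rifampicin-chase decay series.

#' Fit an mRNA half-life from a decay series
#'
#' Ordinary least squares of `ln(intensity)` on time; for a decaying series
#' `t_half = ln(2) / (-slope)`. Slopes shallower than `-slope_min` yield the
#' `not_measurable` sentinel (flat or rising series). The pre-arrest `t = 0`
#' point is included by default.
#'
#' @param series a [decay_series()] (or data.frame `time`, `intensity`),
#'   >= 3 points, all intensities > 0.
#' @param slope_min minimum decay rate (natural-log units per minute,
#'   default 1e-4) below which the half-life is not measurable.
#' @param include_t0 include the `t = 0` point (default `TRUE`).
#' @return object of class `halflife_result`: list with `t_half` (minutes,
#'   `NA` when not measurable), `status` (`"ok"`/`"not_measurable"`),
#'   `slope` (per minute, natural-log scale), `r_squared`, `n_points`.
#' @export
fit_halflife <- function(series, slope_min = 1e-4, include_t0 = TRUE) {
  s <- as.data.frame(series)
  if (!include_t0) s <- s[s$time > 0, ]
  assert_that(nrow(s) >= 3, "half-life fitting needs at least 3 points")
  if (any(s$intensity <= 0))
    stop("non-positive intensity in decay series (log-linear fit undefined)",
         call. = FALSE)
  fit <- lm(log(intensity) ~ time, data = s)
  slope <- unname(coef(fit)[2])
  tss <- sum((log(s$intensity) - mean(log(s$intensity)))^2)
  r2 <- if (tss > 0) 1 - sum(fit$residuals^2) / tss else 0
  measurable <- slope < -slope_min
  structure(list(t_half = if (measurable) log(2) / (-slope) else NA_real_,
                 status = if (measurable) "ok" else "not_measurable",
                 slope = slope, r_squared = r2, n_points = nrow(s),
                 transcript_id = attr(series, "transcript_id"),
                 condition = attr(series, "condition")),
            class = "halflife_result")
}

#' A one-sided bound on a half-life or a stabilization fold
#'
#' Used when a quantity could not be measured but is bounded, e.g. a
#' wild-type half-life reported as "< 2 min".
#'
#' @param value the bound (minutes or fold); `NA` for an unquantified bound.
#' @param side `"upper"` (quantity < value) or `"lower"` (quantity > value).
#' @return object of class `halflife_bound`.
#' @export
halflife_bound <- function(value, side = c("upper", "lower")) {
  side <- match.arg(side)
  structure(list(value = value, side = side), class = "halflife_bound")
}

#' @export
format.halflife_bound <- function(x, ...) {
  if (is.na(x$value)) return(if (x$side == "lower") "> (unquantified)" else "< (unquantified)")
  sprintf("%s %.2f", if (x$side == "lower") ">=" else "<=", x$value)
}

#' @export
print.halflife_bound <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' @export
print.halflife_result <- function(x, ...) {
  if (x$status == "ok")
    cat(sprintf("half-life: %.2f min (slope %.4f /min, r^2 %.3f, n = %d)\n",
                x$t_half, x$slope, x$r_squared, x$n_points))
  else
    cat(sprintf("half-life: not measurable (slope %.4f /min, n = %d)\n",
                x$slope, x$n_points))
  invisible(x)
}

#' Fold-stabilization between depletion and reference conditions
#'
#' `ratio = t_half(depleted) / t_half(induced)`. When the reference
#' half-life is only an upper bound (or not measurable), the result is a
#' lower-bound object, never a plain number.
#'
#' @param depleted a numeric half-life, or an `"ok"` `halflife_result`.
#' @param induced a numeric half-life, an `"ok"` `halflife_result`, a
#'   [halflife_bound()] (upper), or a `not_measurable` result.
#' @return numeric fold, or a `halflife_bound` (side `"lower"`).
#' @export
stabilization_ratio <- function(depleted, induced) {
  t_dep <- if (inherits(depleted, "halflife_result")) depleted$t_half else depleted
  assert_that(is.numeric(t_dep) && length(t_dep) == 1 && !is.na(t_dep) &&
                t_dep > 0,
              "depleted half-life must be a measurable positive number")
  if (inherits(induced, "halflife_bound")) {
    assert_that(induced$side == "upper",
                "reference half-life bound must be an upper bound")
    if (is.na(induced$value)) return(halflife_bound(NA_real_, "lower"))
    return(halflife_bound(t_dep / induced$value, "lower"))
  }
  if (inherits(induced, "halflife_result")) {
    if (induced$status == "not_measurable")
      return(halflife_bound(NA_real_, "lower"))
    induced <- induced$t_half
  }
  if (!is.numeric(induced) || is.na(induced))
    stop("both half-lives non-numeric: stabilization undefined", call. = FALSE)
  t_dep / induced
}

#' Format a stabilization fold the way it is reported
#'
#' @param ratio numeric fold or a `halflife_bound`.
#' @return character, e.g. `"≈7-fold"` for 6.86.
#' @export
format_fold <- function(ratio) {
  if (inherits(ratio, "halflife_bound"))
    return(sprintf("%s-fold", format(ratio)))
  sprintf("≈%d-fold", round(ratio))
}
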