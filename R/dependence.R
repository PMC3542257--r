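# Expression-level dependence of the detected regulation: kernel-density
# profiles by regulation class, fraction curves, and the aggregate
# direct/indirect projection.

#' Scaled kernel-density profiles of expression level by regulation class
#'
#' Gaussian kernel with standard deviation equal to `bandwidth` (the `bw`
#' argument of `stats::density`); each class density is scaled by the class
#' fraction so the scaled curves sum to the total density at every grid
#' point. Classes with fewer than 10 genes are merged into `"other"` with a
#' warning.
#'
#' @param reference_expression named numeric: per-gene log2 expression in
#'   the reference (induced) condition.
#' @param class_labels character of the same length: `"up"`, `"down"` or
#'   `"other"`.
#' @param bandwidth kernel sd in log2 units (default 0.5).
#' @param n_grid number of evaluation points (default 512) spanning the data
#'   range plus/minus 3 bandwidths.
#' @return object of class `density_profile`: list with `grid`, `scaled`
#'   (grid x class matrix), `total`, `class_fractions`, `bandwidth`.
#' @export
density_profiles <- function(reference_expression, class_labels,
                             bandwidth = 0.5, n_grid = 512) {
  keep <- !is.na(reference_expression) & !is.na(class_labels)
  x <- reference_expression[keep]
  cl <- class_labels[keep]
  if (length(x) == 0) stop("no expression values to profile", call. = FALSE)
  small <- names(which(table(cl) < 10))
  small <- setdiff(small, "other")
  if (length(small) > 0) {
    warning("classes with fewer than 10 genes merged into 'other': ",
            paste(small, collapse = ", "))
    cl[cl %in% small] <- "other"
  }
  classes <- unique(cl)
  lo <- min(x) - 3 * bandwidth
  hi <- max(x) + 3 * bandwidth
  scaled <- vapply(classes, function(cc) {
    xs <- x[cl == cc]
    d <- density(xs, bw = bandwidth, kernel = "gaussian",
                 from = lo, to = hi, n = n_grid)
    d$y * (length(xs) / length(x))
  }, numeric(n_grid))
  grid <- density(x[cl == classes[1]], bw = bandwidth, from = lo, to = hi,
                  n = n_grid)$x
  structure(list(grid = grid, scaled = scaled, total = rowSums(scaled),
                 class_fractions = table(cl)[classes] / length(x),
                 bandwidth = bandwidth),
            class = "density_profile")
}

#' Per-class fraction curves from a density profile
#'
#' `fraction_c(x) = scaled_c(x) / total(x)`, evaluated only where the total
#' density exceeds 1% of its maximum (a guard against blow-up in empty
#' tails). Fractions sum to 1 at every retained grid point.
#'
#' @param profile a [density_profiles()] result.
#' @return data.frame: `grid` plus one fraction column per class.
#' @export
fraction_curves <- function(profile) {
  keep <- profile$total >= 0.01 * max(profile$total)
  fr <- profile$scaled[keep, , drop = FALSE] / profile$total[keep]
  out <- data.frame(grid = profile$grid[keep])
  for (cc in colnames(fr)) out[[cc]] <- fr[, cc]
  out
}

#' Aggregate projection of direct versus indirect regulation
#'
#' Under the working assumptions that indirect effects cause equal amounts
#' of up- and down-regulation and that all downward effects are indirect,
#' the down-fraction at the expression level where the up-fraction peaks
#' estimates the indirect share of the up-calls, and the difference
#' estimates the direct target repertoire.
#'
#' @param up_max_pct maximum up-regulated percentage (> 0).
#' @param down_pct_at_same_x down-regulated percentage at the same
#'   expression level (<= `up_max_pct`).
#' @return list with `indirect_share_pct` (= 100 * down/up) and
#'   `direct_repertoire_pct` (= up - down).
#' @export
direct_indirect_projection <- function(up_max_pct, down_pct_at_same_x) {
  assert_that(up_max_pct > 0, "up-fraction maximum must be positive")
  assert_that(down_pct_at_same_x <= up_max_pct,
              "down percentage cannot exceed the up percentage here")
  list(indirect_share_pct = 100 * down_pct_at_same_x / up_max_pct,
       direct_repertoire_pct = up_max_pct - down_pct_at_same_x)
}

#' Locate the up-fraction maximum and project direct/indirect shares
#'
#' @param profile a [density_profiles()] result whose classes include
#'   `"up"` and `"down"`.
#' @return object of class `projection_result`: list with `x_star` (log2
#'   expression at the up-fraction maximum), `up_max_pct`,
#'   `down_pct_at_x_star`, `indirect_share_pct`, `direct_repertoire_pct`.
#' @export
project_from_profile <- function(profile) {
  fr <- fraction_curves(profile)
  assert_that(all(c("up", "down") %in% names(fr)),
              "profile must contain 'up' and 'down' classes")
  i <- which.max(fr$up)
  up <- 100 * fr$up[i]
  dn <- 100 * fr$down[i]
  dn <- min(dn, up)  # projection is defined for down <= up
  pr <- direct_indirect_projection(up, dn)
  structure(list(x_star = fr$grid[i], up_max_pct = up,
                 down_pct_at_x_star = dn,
                 indirect_share_pct = pr$indirect_share_pct,
                 direct_repertoire_pct = pr$direct_repertoire_pct),
            class = "projection_result")
}
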