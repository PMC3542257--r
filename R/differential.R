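# Per-gene two-condition testing: fold-changes, pooled-variance t-tests,
# Grenander-based local FDR estimation, and the lfdr <= 0.1 calling rule.

#' Per-gene log2 fold-changes between depleted and induced arrays
#'
#' `delta = mean(log2 depleted) - mean(log2 induced)`; the linear ratio is
#' `fc = 2^delta` and the amplitude is the symmetric magnitude
#' `2^|delta| = max(fc, 1/fc)`.
#'
#' @param mat a normalized `expression_matrix`.
#' @return object of class `diff_table`: data.frame with one row per gene
#'   (`id`, `mean_depleted`, `mean_induced`, `delta`, `fc`, `amplitude`,
#'   `direction`); masked genes carry `NA`. Columns `t_stat`, `p_value`,
#'   `lfdr`, `called` are added by [diff_test()] / [call_differential()].
#' @export
fold_change <- function(mat) {
  v <- mat$values
  dep <- mat$design$array_id[mat$design$condition == "depleted"]
  ind <- mat$design$array_id[mat$design$condition == "induced"]
  assert_that(length(dep) >= 1 && length(ind) >= 1,
              "both conditions must be present in the design")
  m_dep <- rowMeans(v[, dep, drop = FALSE])
  m_ind <- rowMeans(v[, ind, drop = FALSE])
  delta <- m_dep - m_ind
  d <- data.frame(id = rownames(v), mean_depleted = m_dep,
                  mean_induced = m_ind, delta = delta, fc = 2^delta,
                  amplitude = 2^abs(delta),
                  direction = ifelse(is.na(delta), NA_character_,
                                     ifelse(delta > 0, "up", "down")),
                  stringsAsFactors = FALSE, row.names = NULL)
  structure(d, class = c("diff_table", "data.frame"))
}

#' Pooled-variance two-sample t-test for one gene
#'
#' Classic equal-variance t with `df = n1 + n2 - 2` and a two-sided p-value.
#' A small variance floor is added to the pooled variance so that exact ties
#' (zero variance) yield `t = 0`, `p = 1` rather than 0/0; p-values are
#' floored away from exactly zero. Welch is deliberately not used: its df
#' estimate is degenerate at n = 2 per group, the design this pipeline
#' targets.
#'
#' @param a,b numeric log2 expression values per condition (>= 2 each).
#' @param var_floor added to the pooled variance (log2^2 units).
#' @return named numeric `c(t_stat, p_value)`; `NA`s (with a warning) when
#'   a group has fewer than 2 values.
#' @export
t_test_gene <- function(a, b, var_floor = 1e-8) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2 || n2 < 2) {
    warning("fewer than 2 values in a group; p-value masked")
    return(c(t_stat = NA_real_, p_value = NA_real_))
  }
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / df + var_floor
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * pt(-abs(t), df)
  p <- min(max(p, 1e-300), 1)
  c(t_stat = t, p_value = p)
}

#' Estimate the local false discovery rate from a vector of p-values
#'
#' The null proportion is `eta0 = min(1, #\{p > lambda\} / ((1 - lambda) m))`
#' with `lambda = 0.5`. The marginal p-value density is estimated by the
#' Grenander estimator -- the slopes of the least concave majorant of the
#' empirical CDF -- which is monotone non-increasing by construction; then
#' `lfdr(p) = min(1, eta0 / f(p))`, non-decreasing in p.
#'
#' @param p p-values in \[0, 1\]. Fewer than 100 values triggers a warning
#'   and an all-ones return (the density cannot be estimated usefully).
#' @param lambda censoring point for the null-proportion estimate.
#' @return numeric lfdr, same order as `p` (`NA` in, `NA` out).
#' @export
estimate_lfdr <- function(p, lambda = 0.5) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  out <- rep(NA_real_, length(p))
  m <- sum(ok)
  if (m < 100) {
    warning("fewer than 100 p-values; returning lfdr = 1 for all")
    out[ok] <- 1
    return(out)
  }
  pv <- p[ok]
  eta0 <- min(1, sum(pv > lambda) / ((1 - lambda) * m))
  f <- grenander_density(pv)
  out[ok] <- pmin(1, eta0 / f)
  out
}

# Grenander (monotone non-increasing) density estimate evaluated at the
# sample points: slopes of the least concave majorant of the ECDF on [0,1].
grenander_density <- function(pv) {
  m <- length(pv)
  o <- order(pv)
  ps <- pv[o]
  # ECDF knots at unique sorted values (max cumulative count per value)
  ux <- unique(ps)
  uF <- cumsum(tabulate(match(ps, ux), length(ux))) / m
  x <- c(0, ux); F <- c(0, uF)
  if (x[length(x)] < 1) { x <- c(x, 1); F <- c(F, 1) }
  # least concave majorant: upper hull by a monotone-chain stack
  hx <- numeric(length(x)); hF <- numeric(length(x))
  k <- 0
  for (i in seq_along(x)) {
    while (k >= 2) {
      s1 <- (hF[k] - hF[k - 1]) / (hx[k] - hx[k - 1])
      s2 <- (F[i] - hF[k]) / (x[i] - hx[k])
      if (s2 >= s1) k <- k - 1 else break
    }
    k <- k + 1
    hx[k] <- x[i]; hF[k] <- F[i]
  }
  hx <- hx[seq_len(k)]; hF <- hF[seq_len(k)]
  slopes <- diff(hF) / diff(hx)   # non-increasing
  # left-continuous evaluation: p in (hx[j], hx[j+1]] gets slopes[j]
  seg <- findInterval(ps, hx, left.open = TRUE, rightmost.closed = TRUE)
  seg[seg < 1] <- 1
  seg[seg > length(slopes)] <- length(slopes)
  fs <- slopes[seg]
  fs[fs <= 0] <- .Machine$double.eps
  f <- numeric(m)
  f[o] <- fs
  f
}

#' Run the full per-gene differential test on an expression matrix
#'
#' Combines [fold_change()], per-gene [t_test_gene()] and [estimate_lfdr()],
#' then applies the calling rule via [call_differential()].
#'
#' @param mat a normalized `expression_matrix`.
#' @param lfdr_max lfdr calling threshold (default 0.1).
#' @param var_floor variance floor for the t-test.
#' @return a complete `diff_table`.
#' @export
diff_test <- function(mat, lfdr_max = 0.1, var_floor = 1e-8) {
  d <- fold_change(mat)
  v <- mat$values
  dep <- mat$design$array_id[mat$design$condition == "depleted"]
  ind <- mat$design$array_id[mat$design$condition == "induced"]
  tp <- t(vapply(seq_len(nrow(v)), function(i) {
    if (any(is.na(v[i, c(dep, ind)])))
      return(c(t_stat = NA_real_, p_value = NA_real_))
    suppressWarnings(t_test_gene(v[i, dep], v[i, ind], var_floor = var_floor))
  }, c(t_stat = 0, p_value = 0)))
  d$t_stat <- tp[, "t_stat"]
  d$p_value <- tp[, "p_value"]
  d$lfdr <- suppressWarnings(estimate_lfdr(d$p_value))
  call_differential(d, lfdr_max = lfdr_max)
}

#' Apply the lfdr calling rule
#'
#' A gene is called differentially expressed iff `lfdr <= lfdr_max`
#' (inclusive): the least-significant called gene still has at most a
#' `lfdr_max` probability of being a false positive.
#'
#' @param diff a `diff_table` with an `lfdr` column.
#' @param lfdr_max threshold (default 0.1).
#' @return the `diff_table` with a logical `called` column.
#' @export
call_differential <- function(diff, lfdr_max = 0.1) {
  assert_that("lfdr" %in% names(diff), "lfdr column must be populated first")
  diff$called <- !is.na(diff$lfdr) & diff$lfdr <= lfdr_max
  attr(diff, "lfdr_max") <- lfdr_max
  diff
}

#' Average false discovery rate over the called set
#'
#' The mean lfdr over called genes: the expected fraction of false
#' positives among the calls.
#'
#' @param diff a called `diff_table`.
#' @return proportion in \[0, 1\].
#' @export
average_fdr <- function(diff) {
  assert_that("called" %in% names(diff), "run call_differential() first")
  if (!any(diff$called)) stop("no called genes: average FDR is undefined",
                              call. = FALSE)
  mean(diff$lfdr[diff$called])
}
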