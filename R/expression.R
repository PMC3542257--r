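# Probe-to-gene aggregation and least-variant-set between-array
# normalization.

#' Construct a gene x array expression matrix object
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids), arrays
#'   in columns (colnames = array ids), log2 scale. Genes without probes are
#'   rows of `NA` (masked).
#' @param design data.frame `array_id`, `condition`, `replicate` matching
#'   the columns.
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, design) {
  assert_that(is.matrix(values) && !is.null(rownames(values)) &&
                !is.null(colnames(values)),
              "values must be a matrix with gene and array names")
  assert_that(identical(colnames(values), design$array_id),
              "array columns must match the design table")
  structure(list(values = values, design = design),
            class = "expression_matrix")
}

#' Gene ids masked (no data) in an expression matrix
#' @param mat an `expression_matrix`.
#' @return character vector of gene ids whose whole row is `NA`.
#' @export
masked_genes <- function(mat) {
  rownames(mat$values)[apply(is.na(mat$values), 1, all)]
}

#' Aggregate probe-level intensities to gene level by the median
#'
#' For each annotated feature and each array, the value is the median of the
#' same-strand probes whose position falls in `[start, end)`; an even probe
#' count gives the mean of the two middle values. Features spanning no probe
#' are masked (`NA`), not zero.
#'
#' @param probes a `probe_signals` object, or a data.frame with columns
#'   `chrom`, `position`, `strand` plus one intensity column per array
#'   (log2 scale).
#' @param annotation a `genome_annotation`.
#' @param design design table; taken from `probes` when it is a
#'   `probe_signals` object.
#' @return an [expression_matrix()].
#' @export
aggregate_gene_level <- function(probes, annotation, design = NULL) {
  if (inherits(probes, "probe_signals")) {
    design <- design %||% probes$design
    ptab <- cbind(probes$layout[, c("chrom", "position", "strand")],
                  as.data.frame(probes$values))
  } else {
    assert_that(!is.null(design), "a design table is required for probe tables")
    ptab <- as.data.frame(probes)
  }
  assert_that(all(c("chrom", "position", "strand") %in% names(ptab)),
              "probe table needs chrom, position, strand columns")
  arrays <- design$array_id
  assert_that(all(arrays %in% names(ptab)),
              "probe table is missing intensity columns for some arrays")
  missing_chrom <- setdiff(unique(annotation$chrom), unique(ptab$chrom))
  if (length(missing_chrom) > 0)
    stop("annotation chromosomes absent from probe table: ",
         paste(missing_chrom, collapse = ", "), call. = FALSE)

  pdt <- data.table::as.data.table(ptab)
  fdt <- data.table::data.table(id = annotation$id, chrom = annotation$chrom,
                                strand = annotation$strand,
                                start = annotation$start, end = annotation$end)
  pdt[, `:=`(pos2 = position, pos1 = position)]
  joined <- pdt[fdt, on = .(chrom, strand, pos1 >= start, pos2 < end),
                allow.cartesian = TRUE]
  vals <- matrix(NA_real_, nrow(annotation), length(arrays),
                 dimnames = list(annotation$id, arrays))
  if (nrow(joined) > 0) {
    agg <- joined[!is.na(position),
                  lapply(.SD, function(x) median(x, na.rm = TRUE)),
                  by = id, .SDcols = arrays]
    idx <- match(agg$id, annotation$id)
    vals[idx, ] <- as.matrix(agg[, arrays, with = FALSE])
  }
  n_masked <- sum(apply(is.na(vals), 1, all))
  if (n_masked > 0)
    log_stage("aggregate", sprintf("%d/%d features span no probe and are masked",
                                   n_masked, nrow(annotation)))
  expression_matrix(vals, design)
}

#' Select the least-variant set of genes across arrays
#'
#' For every gene with complete data, expression values are ranked within
#' each array; the statistic is the variance of that gene's rank across
#' arrays. The `fraction` of genes with the smallest rank-variance (ties
#' broken by gene id) forms the anchor set for normalization -- genes whose
#' relative standing is most stable across hybridizations.
#'
#' Genes whose mean rank sits within `rank_trim` of either boundary are
#' ineligible: a gene at the very top or bottom of the expression range
#' keeps its rank no matter how strongly it changes (rank saturation), so a
#' small rank-variance there says nothing about stability and would let
#' strongly regulated extreme genes contaminate the anchor set.
#'
#' @param mat an `expression_matrix` with at least 2 arrays.
#' @param fraction proportion of complete-data genes to select, in (0, 1].
#' @param rank_trim proportion trimmed off each rank boundary when deciding
#'   eligibility (default 0.05); trimming is skipped when it would leave
#'   fewer genes than the selection needs.
#' @return object of class `lvs_selection`: list with `gene_ids`,
#'   `fraction`, `variance_statistic` (named, all complete genes).
#' @export
select_least_variant_set <- function(mat, fraction = 0.4, rank_trim = 0.05) {
  assert_that(fraction > 0 && fraction <= 1, "fraction must be in (0, 1]")
  v <- mat$values
  assert_that(ncol(v) >= 2, "least-variant-set selection needs >= 2 arrays")
  complete <- !apply(is.na(v), 1, any)
  if (!any(complete)) stop("all genes are masked; cannot select a least-variant set",
                           call. = FALSE)
  vc <- v[complete, , drop = FALSE]
  ranks <- apply(vc, 2, rank, ties.method = "average")
  if (!is.matrix(ranks)) ranks <- matrix(ranks, nrow = 1,
                                         dimnames = list(rownames(vc), NULL))
  rv <- apply(ranks, 1, var)
  names(rv) <- rownames(vc)
  n <- nrow(vc)
  n_sel <- max(1L, round(fraction * n))
  mean_rank <- rowMeans(ranks)
  eligible <- mean_rank > rank_trim * n & mean_rank <= (1 - rank_trim) * n
  if (sum(eligible) < n_sel) eligible <- rep(TRUE, n)
  cand <- rv[eligible]
  ord <- order(cand, names(cand))
  structure(list(gene_ids = names(cand)[ord][seq_len(n_sel)],
                 fraction = fraction, variance_statistic = rv),
            class = "lvs_selection")
}

#' Normalize arrays against the least-variant-set baseline
#'
#' The baseline is the per-gene mean over arrays of the LVS genes. Each
#' array is affine-corrected so that the least-squares regression of its LVS
#' values on the baseline has slope 1 and intercept 0; because the baseline
#' itself moves after correction, the affine fit is iterated to its fixed
#' point (one pass is exact on noiseless affine distortions), which makes
#' the operation an idempotent projection. Only slope and offset are
#' touched, so genuine up/down imbalance outside the anchor set is
#' preserved.
#'
#' @param mat an `expression_matrix`.
#' @param lvs an [select_least_variant_set()] result (>= 3 genes).
#' @param max_iter,tol fixed-point iteration controls.
#' @return a normalized `expression_matrix`.
#' @export
normalize_lvs <- function(mat, lvs, max_iter = 100, tol = 1e-12) {
  ids <- intersect(lvs$gene_ids, rownames(mat$values))
  if (length(ids) < 3)
    stop("need at least 3 least-variant-set genes for the affine fit",
         call. = FALSE)
  v <- mat$values
  for (iter in seq_len(max_iter)) {
    b <- rowMeans(v[ids, , drop = FALSE])
    worst <- 0
    for (a in seq_len(ncol(v))) {
      y <- v[ids, a]
      if (var(b) < .Machine$double.eps) {
        slope <- 1; int <- mean(y) - mean(b)
      } else {
        slope <- sum((b - mean(b)) * (y - mean(y))) / sum((b - mean(b))^2)
        int <- mean(y) - slope * mean(b)
      }
      if (abs(slope) < .Machine$double.eps)
        stop("degenerate affine fit (zero slope) in LVS normalization",
             call. = FALSE)
      v[, a] <- (v[, a] - int) / slope
      worst <- max(worst, abs(slope - 1), abs(int))
    }
    if (worst < tol) break
  }
  expression_matrix(v, mat$design)
}
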