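# Functional-category over/under-representation of up-regulated genes
# against the whole-genome reference fraction.

#' Per-category up-regulated fractions
#'
#' @param up_set character vector of up-regulated gene ids.
#' @param category_map data.frame `gene_id`, `category` (one row per
#'   membership; a gene may belong to several categories).
#' @param n_coding_reference size of the whole-genome coding pool.
#' @param n_up_reference total number of up-regulated coding genes.
#' @return object of class `category_table`: data.frame `category`,
#'   `n_genes`, `n_up`, `pct_up` (one decimal), with attribute
#'   `reference_pct` = `100 * n_up_reference / n_coding_reference` (one
#'   decimal). Categories with zero genes are dropped with a warning.
#' @export
category_fractions <- function(up_set, category_map, n_coding_reference,
                               n_up_reference) {
  assert_that(all(c("gene_id", "category") %in% names(category_map)),
              "category_map needs gene_id and category columns")
  up_set <- tolower(up_set)
  cm <- category_map
  cm$gene_id <- tolower(cm$gene_id)
  empty <- is.na(cm$category) | !nzchar(cm$category)
  if (any(empty)) {
    warning(sprintf("%d memberships with empty category dropped", sum(empty)))
    cm <- cm[!empty, ]
  }
  cats <- sort(unique(cm$category))
  n_genes <- vapply(cats, function(cc)
    length(unique(cm$gene_id[cm$category == cc])), 0L)
  n_up <- vapply(cats, function(cc)
    length(intersect(unique(cm$gene_id[cm$category == cc]), up_set)), 0L)
  tab <- data.frame(category = cats, n_genes = n_genes, n_up = n_up,
                    pct_up = round(100 * n_up / n_genes, 1),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(tab,
            reference_pct = round(100 * n_up_reference / n_coding_reference, 1),
            n_coding_reference = n_coding_reference,
            n_up_reference = n_up_reference,
            class = c("category_table", "data.frame"))
}

#' Exact two-sided hypergeometric test for one category
#'
#' With `X ~ Hypergeom(N, K, n_cat)` (population N, K up-regulated, a
#' category of `n_cat` genes of which `k_cat` are up), the two-sided p-value
#' is `min(1, 2 * min(P(X <= k), P(X >= k)))`.
#'
#' @param n_cat category size.
#' @param k_cat up-regulated genes in the category.
#' @param N population (coding pool) size.
#' @param K total up-regulated genes in the population.
#' @return list with `p_value` and `flag` (`"over"`, `"under"` or `"none"`;
#'   for a single test the flag uses `p <= 0.05` directly -- across many
#'   categories use [enrich_categories()], which applies
#'   Benjamini-Hochberg first).
#' @export
category_test <- function(n_cat, k_cat, N, K) {
  assert_that(k_cat >= 0 && k_cat <= min(n_cat, K) && n_cat <= N && K <= N,
              "impossible hypergeometric counts")
  lower <- phyper(k_cat, K, N - K, n_cat)
  upper <- phyper(k_cat - 1, K, N - K, n_cat, lower.tail = FALSE)
  p <- min(1, 2 * min(lower, upper))
  ref <- K / N
  flag <- if (p <= 0.05) {
    if (k_cat / n_cat > ref) "over" else if (k_cat / n_cat < ref) "under"
    else "none"
  } else "none"
  list(p_value = p, flag = flag)
}

#' Full category enrichment table with multiplicity-corrected flags
#'
#' Builds the fraction table, tests every category against the genome
#' reference with the exact hypergeometric test, adjusts p-values by
#' Benjamini-Hochberg, and flags categories with `q <= q_max` as over- or
#' under-represented according to the sign of the deviation.
#'
#' @inheritParams category_fractions
#' @param q_max BH-adjusted significance threshold (default 0.05).
#' @return the `category_table` with added `p_value`, `q_value`, `flag`.
#' @export
enrich_categories <- function(up_set, category_map, n_coding_reference,
                              n_up_reference, q_max = 0.05) {
  tab <- category_fractions(up_set, category_map, n_coding_reference,
                            n_up_reference)
  res <- mapply(function(n, k) category_test(n, k, n_coding_reference,
                                             n_up_reference)$p_value,
                tab$n_genes, tab$n_up)
  tab$p_value <- as.numeric(res)
  tab$q_value <- p.adjust(tab$p_value, method = "BH")
  ref <- n_up_reference / n_coding_reference
  tab$flag <- ifelse(tab$q_value <= q_max & tab$n_up / tab$n_genes > ref, "over",
                     ifelse(tab$q_value <= q_max & tab$n_up / tab$n_genes < ref,
                            "under", "none"))
  tab
}
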