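# Direction-aware cross-study comparison of differential gene lists.

#' Construct a per-study differential gene set
#'
#' Gene identity is the locus tag after case-folding; duplicate ids within a
#' direction are removed with a warning; a gene may not be both up and down
#' within one study.
#'
#' @param study_id label.
#' @param up,down character vectors of gene ids.
#' @return object of class `study_gene_set`.
#' @export
study_gene_set <- function(study_id, up = character(), down = character()) {
  up <- tolower(up); down <- tolower(down)
  if (anyDuplicated(up) || anyDuplicated(down)) {
    warning(sprintf("duplicate gene ids in study '%s' deduplicated", study_id))
    up <- unique(up); down <- unique(down)
  }
  assert_that(length(intersect(up, down)) == 0,
              sprintf("study '%s': a gene cannot be both up and down", study_id))
  structure(list(study_id = study_id, up = up, down = down),
            class = "study_gene_set")
}

#' Exclusive Venn region counts for 2 or 3 study gene sets
#'
#' @param sets list of 2 or 3 [study_gene_set()] objects.
#' @param direction `"up"` or `"down"`; the comparison is done on the
#'   direction-specific sets.
#' @return named list: one count per exclusive region (names built from the
#'   study ids, e.g. `"A&B"`), plus `union`. The region counts partition the
#'   union (asserted).
#' @export
venn_counts <- function(sets, direction = c("up", "down")) {
  direction <- match.arg(direction)
  assert_that(length(sets) %in% c(2, 3), "venn_counts takes 2 or 3 sets")
  ids <- vapply(sets, function(s) s$study_id, "")
  gl <- lapply(sets, function(s) unique(s[[direction]]))
  all_genes <- unique(unlist(gl))
  member <- vapply(gl, function(g) all_genes %in% g,
                   logical(length(all_genes)))
  if (length(all_genes) == 1) member <- matrix(member, nrow = 1)
  out <- list()
  n <- length(sets)
  for (size in seq_len(n)) {
    for (combo in utils::combn(n, size, simplify = FALSE)) {
      inside <- rowSums(member[, combo, drop = FALSE]) == size &
        rowSums(member) == size
      out[[paste(ids[combo], collapse = "&")]] <- sum(inside)
    }
  }
  out$union <- length(all_genes)
  stopifnot(sum(unlist(out[names(out) != "union"])) == out$union)
  out
}

#' Percentage of the union shared by all studies
#'
#' @param common number of genes in the all-studies intersection region.
#' @param union cumulative non-redundant total across studies (> 0).
#' @return percentage rounded to one decimal.
#' @export
overlap_fraction <- function(common, union) {
  assert_that(union > 0, "union must be positive")
  assert_that(common <= union, "common cannot exceed the union")
  round(100 * common / union, 1)
}

#' Re-derive study gene sets at a uniform amplitude cut-off
#'
#' Applies one shared amplitude threshold to each study's fold-changes
#' (keeping each study's significance filter where its table has a `called`
#' column, mirroring the availability of statistical evaluation per study)
#' and recomputes the Venn regions in both directions.
#'
#' @param diff_tables named list of per-study `diff_table`s (or data.frames
#'   with at least `id` and `fc`).
#' @param amplitude_min shared cut-off (default 1.5).
#' @return list with `sets` (per-study [study_gene_set()]), `venn_up`,
#'   `venn_down`.
#' @export
uniform_cutoff_comparison <- function(diff_tables, amplitude_min = 1.5) {
  assert_that(!is.null(names(diff_tables)) && all(nzchar(names(diff_tables))),
              "diff_tables must be a named list (one name per study)")
  sets <- lapply(names(diff_tables), function(nm) {
    d <- diff_tables[[nm]]
    if (!"fc" %in% names(d))
      stop(sprintf("study '%s' has no fold-change column", nm), call. = FALSE)
    keep <- if ("called" %in% names(d)) d$called else rep(TRUE, nrow(d))
    keep <- keep & !is.na(d$fc)
    study_gene_set(nm,
                   up = d$id[keep & d$fc >= amplitude_min],
                   down = d$id[keep & d$fc <= 1 / amplitude_min])
  })
  names(sets) <- names(diff_tables)
  list(sets = sets,
       venn_up = venn_counts(sets, "up"),
       venn_down = venn_counts(sets, "down"))
}
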