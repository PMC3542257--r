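# Orchestration: configuration handling and the end-to-end pipeline.

#' Default pipeline configuration
#'
#' Defaults follow the study design this pipeline operationalizes: lfdr
#' calling cut-off 0.1, final amplitude threshold 1.6 (or `"auto"` to use
#' the detected break point), density bandwidth 0.5, uniform cross-study
#' cut-off 1.5, BH q threshold 0.05.
#'
#' @param ... overrides for any field (see source for the full list; notable
#'   fields: `simulate` list for the generator, `probes`/`annotation`/
#'   `design`/`categories` input paths, `lvs_fraction`, `lfdr_max`,
#'   `amplitude_min`, `grid`, `bandwidth`, `bh_q`, `slope_min`, `seed`,
#'   `outdir`).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    simulate = list(n_coding = 400, n_ncrna = 40, genome_length = 400000,
                    resolution = 22, n_replicates = 2,
                    category_scheme = NULL, effects = list()),
    probes = NULL, annotation = NULL, design = NULL, categories = NULL,
    lvs_fraction = 0.4, lfdr_max = 0.1, amplitude_min = 1.6,
    grid = seq(1, 4, by = 0.05), bandwidth = 0.5, bh_q = 0.05,
    slope_min = 1e-4, seed = 1, outdir = NULL)
  ov <- list(...)
  for (nm in names(ov)) {
    if (nm %in% c("simulate") && is.list(ov[[nm]])) {
      for (k in names(ov[[nm]])) cfg$simulate[[k]] <- ov[[nm]][[k]]
    } else cfg[[nm]] <- ov[[nm]]
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a JSON file
#' @param path JSON file with any subset of the [pipeline_config()] fields.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$grid) && length(raw$grid) == 3 && !is.null(names(raw$grid)))
    raw$grid <- seq(raw$grid[["from"]], raw$grid[["to"]], by = raw$grid[["by"]])
  do.call(pipeline_config, raw)
}

#' Run the full depletion-analysis pipeline
#'
#' Stages: simulate (when no probe input is configured) -> aggregate ->
#' normalize -> test -> threshold (curve + break point) -> final gene sets
#' -> category enrichment -> expression-level profile and projection. Every
#' stage logs its parameters and row counts; all randomness derives from
#' `config$seed`, so results are deterministic per seed. When `outdir` is
#' set, every artifact is written as TSV.
#'
#' @param config a [pipeline_config()] (or path to a JSON config).
#' @return list with every intermediate object plus a `summary` data.frame;
#'   on simulated input the summary includes recall and precision of the
#'   planted direct-up targets.
#' @export
run_all <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_config(config)
  out <- list(config = config)
  outdir <- config$outdir
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  wpath <- function(f) file.path(outdir, f)

  if (is.null(config$probes)) {
    sim <- config$simulate
    log_stage("simulate", sprintf("n_coding=%d n_ncrna=%d L=%d res=%d seed=%d",
                                  sim$n_coding, sim$n_ncrna, sim$genome_length,
                                  sim$resolution, config$seed))
    ann <- generate_annotation(sim$n_coding, sim$n_ncrna, sim$genome_length,
                               category_scheme = sim$category_scheme,
                               seed = config$seed)
    layout <- generate_probe_layout(ann, resolution = sim$resolution)
    design <- depletion_design(sim$n_replicates %||% 2)
    eff <- do.call(effect_config, c(sim$effects, list(seed = config$seed)))
    signals <- simulate_expression(ann, layout, design, eff)
    out$annotation <- ann; out$signals <- signals; out$truth <- signals$truth
    probes <- signals
    if (!is.null(outdir)) {
      write_annotation(ann, wpath("annotation.bed"), wpath("categories.tsv"))
      fwrite(design, wpath("design.tsv"), sep = "\t", quote = FALSE)
      write_probe_table(signals, wpath("probes.tsv"))
      fwrite(signals$truth, wpath("truth.tsv"), sep = "\t", na = "NA",
             quote = FALSE)
    }
  } else {
    log_stage("read", sprintf("probes=%s annotation=%s", config$probes,
                              config$annotation))
    ann <- read_annotation(config$annotation,
                           format = if (grepl("\\.gff3?$", config$annotation))
                             "gff3" else "bed6",
                           categories_path = config$categories)
    design <- read_design(config$design)
    probes <- read_probe_table(config$probes)
    out$annotation <- ann
  }

  log_stage("aggregate", sprintf("%d features", nrow(ann)))
  mat <- aggregate_gene_level(probes, ann,
                              design = if (inherits(probes, "probe_signals"))
                                NULL else design)
  log_stage("normalize", sprintf("lvs_fraction=%.2f", config$lvs_fraction))
  lvs <- select_least_variant_set(mat, fraction = config$lvs_fraction)
  nmat <- normalize_lvs(mat, lvs)
  out$matrix <- nmat; out$lvs <- lvs
  if (!is.null(outdir)) write_expression_matrix(nmat, wpath("matrix.tsv"))

  log_stage("test", sprintf("lfdr_max=%.2f", config$lfdr_max))
  diff <- diff_test(nmat, lfdr_max = config$lfdr_max)
  out$diff <- diff
  if (!is.null(outdir)) write_diff_table(diff, wpath("diff_table.tsv"))

  coding_ids <- ann$id[ann$kind == "coding"]
  log_stage("threshold", sprintf("grid %.2f..%.2f (%d points)",
                                 min(config$grid), max(config$grid),
                                 length(config$grid)))
  curve <- cutoff_curve(diff, grid = config$grid, n_coding = n_coding(ann),
                        coding_ids = coding_ids)
  bp <- detect_breakpoint(curve)
  amp <- config$amplitude_min
  if (identical(amp, "auto"))
    amp <- if (!is.na(bp$cutoff_at_break)) bp$cutoff_at_break else 1.6
  sets <- final_gene_sets(diff, amplitude_min = amp)
  out$curve <- curve; out$breakpoint <- bp; out$gene_sets <- sets
  out$amplitude_min <- amp
  log_stage("sets", sprintf("amplitude_min=%.2f: %d up, %d down", amp,
                            length(sets$up), length(sets$down)))
  if (!is.null(outdir)) {
    fwrite(as.data.frame(curve), wpath("cutoff_curve.tsv"), sep = "\t",
           quote = FALSE)
    fwrite(data.frame(cutoff_at_break = bp$cutoff_at_break,
                      slope_low = bp$segment_slopes[["slope_low"]],
                      slope_high = bp$segment_slopes[["slope_high"]],
                      rss_single = bp$rss_single,
                      rss_two_segment = bp$rss_two_segment,
                      improvement = bp$improvement),
           wpath("breakpoint.tsv"), sep = "\t", na = "NA", quote = FALSE)
    fwrite(data.frame(id = c(sets$up, sets$down),
                      direction = rep(c("up", "down"),
                                      c(length(sets$up), length(sets$down)))),
           wpath("gene_sets.tsv"), sep = "\t", quote = FALSE)
  }

  cat_map <- NULL
  if (!is.null(config$categories)) {
    cat_map <- read_categories(config$categories)
  } else if (any(!is.na(ann$category))) {
    cat_map <- data.frame(gene_id = ann$id, category = ann$category)
    cat_map <- cat_map[!is.na(cat_map$category), ]
  }
  if (!is.null(cat_map) && nrow(cat_map) > 0) {
    up_coding <- intersect(sets$up, coding_ids)
    log_stage("enrich", sprintf("%d categories", length(unique(cat_map$category))))
    out$categories <- enrich_categories(up_coding, cat_map, n_coding(ann),
                                        length(up_coding), q_max = config$bh_q)
    if (!is.null(outdir))
      fwrite(as.data.frame(out$categories), wpath("category_table.tsv"),
             sep = "\t", na = "NA", quote = FALSE)
  }

  log_stage("profile", sprintf("bandwidth=%.2f", config$bandwidth))
  ind_arrays <- nmat$design$array_id[nmat$design$condition == "induced"]
  ref_expr <- rowMeans(nmat$values[, ind_arrays, drop = FALSE])
  cls <- rep("other", nrow(diff))
  cls[diff$id %in% sets$up] <- "up"
  cls[diff$id %in% sets$down] <- "down"
  keep <- diff$id %in% coding_ids
  prof <- suppressWarnings(
    density_profiles(ref_expr[match(diff$id[keep], names(ref_expr))],
                     cls[keep], bandwidth = config$bandwidth))
  out$profile <- prof
  if (all(c("up", "down") %in% colnames(prof$scaled))) {
    out$projection <- project_from_profile(prof)
    log_stage("profile", sprintf(
      "up-fraction max %.1f%% at x=%.2f; indirect share %.1f%%",
      out$projection$up_max_pct, out$projection$x_star,
      out$projection$indirect_share_pct))
  }
  if (!is.null(outdir)) {
    fwrite(data.frame(grid = prof$grid, prof$scaled, total = prof$total,
                      check.names = FALSE),
           wpath("density_profile.tsv"), sep = "\t", quote = FALSE)
    if (!is.null(out$projection))
      fwrite(as.data.frame(unclass(out$projection)), wpath("projection.tsv"),
             sep = "\t", quote = FALSE)
  }

  if (!is.null(out$truth)) {
    planted <- out$truth[out$truth$class == "direct_up" &
                           2^out$truth$log2_effect >= 2, "id"]
    planted <- intersect(planted, coding_ids)
    recall <- if (length(planted) > 0)
      length(intersect(planted, sets$up)) / length(planted) else NA_real_
    true_up <- out$truth$id[out$truth$log2_effect > 0]
    precision <- if (length(sets$up) > 0)
      length(intersect(sets$up, true_up)) / length(sets$up) else NA_real_
    out$summary <- data.frame(
      n_called = sum(diff$called, na.rm = TRUE),
      n_up = length(sets$up), n_down = length(sets$down),
      average_fdr = if (any(diff$called, na.rm = TRUE)) average_fdr(diff)
      else NA_real_,
      amplitude_min = amp,
      recall_direct_up_amp2 = recall, precision_up = precision)
    log_stage("summary", sprintf("recall(direct-up, amp>=2)=%.3f precision=%.3f",
                                 recall, precision))
  } else {
    out$summary <- data.frame(
      n_called = sum(diff$called, na.rm = TRUE),
      n_up = length(sets$up), n_down = length(sets$down),
      average_fdr = if (any(diff$called, na.rm = TRUE)) average_fdr(diff)
      else NA_real_,
      amplitude_min = amp)
  }
  if (!is.null(outdir))
    fwrite(out$summary, wpath("summary.tsv"), sep = "\t", na = "NA",
           quote = FALSE)
  out
}
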