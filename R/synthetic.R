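# Synthetic data generators for a two-condition ribonuclease-depletion
# tiling-array design: annotation, probe layout, probe-level intensities with
# planted effects, and rifampicin-chase decay series with known half-lives.

#' Construct a genome annotation object
#'
#' @param features data.frame with columns `id`, `chrom`, `start`, `end`,
#'   `strand` (`"+"`/`"-"`), `kind` (`"coding"`/`"ncRNA"`) and optionally
#'   `category` (character, `NA` for none).
#' @param genome_length total chromosome length in base pairs (attribute,
#'   used by the probe-layout generator).
#' @return an object of class `genome_annotation`: the feature data.frame
#'   with attributes `n_coding` and `genome_length`. Coordinates are 0-based
#'   half-open throughout the package.
#' @export
genome_annotation <- function(features, genome_length = NA_real_) {
  cols <- c("id", "chrom", "start", "end", "strand", "kind")
  assert_that(all(cols %in% names(features)),
              paste("annotation must have columns:", paste(cols, collapse = ", ")))
  if (!"category" %in% names(features)) features$category <- NA_character_
  if (nrow(features) > 0) {
    assert_that(all(features$start >= 0 & features$start < features$end),
                "annotation requires 0 <= start < end")
    assert_that(!anyDuplicated(features$id), "feature ids must be unique")
    assert_that(all(features$strand %in% c("+", "-")),
                "strand must be '+' or '-'")
    assert_that(all(features$kind %in% c("coding", "ncRNA")),
                "kind must be 'coding' or 'ncRNA'")
    # same-strand features must not overlap
    sp <- split(features, list(features$chrom, features$strand), drop = TRUE)
    for (grp in sp) {
      grp <- grp[order(grp$start), ]
      if (nrow(grp) > 1 && any(grp$start[-1] < grp$end[-nrow(grp)]))
        stop("overlapping same-strand features in annotation", call. = FALSE)
    }
  }
  structure(as.data.frame(features, stringsAsFactors = FALSE),
            n_coding = sum(features$kind == "coding"),
            genome_length = genome_length,
            class = c("genome_annotation", "data.frame"))
}

#' Number of protein-coding features in an annotation
#' @param annotation a `genome_annotation`.
#' @return integer count; the denominator for all coding-pool percentages.
#' @export
n_coding <- function(annotation) attr(annotation, "n_coding")

#' Generate a random non-overlapping genome annotation
#'
#' Features are laid out per strand without same-strand overlap; coding genes
#' receive a functional category drawn from `category_scheme` proportions.
#'
#' @param n_coding number of protein-coding genes.
#' @param n_ncrna number of non-coding RNA features.
#' @param genome_length chromosome length (bp).
#' @param category_scheme named numeric vector of category proportions for
#'   coding genes (normalized internally); `NULL` for no categories.
#' @param seed integer seed (deterministic output for fixed seed).
#' @param coding_length,ncrna_length length ranges (bp) for the two kinds.
#' @return a `genome_annotation`.
#' @export
generate_annotation <- function(n_coding, n_ncrna, genome_length,
                                category_scheme = NULL, seed = 1,
                                coding_length = c(300, 1500),
                                ncrna_length = c(80, 300)) {
  stopifnot(n_coding >= 0, n_ncrna >= 0, genome_length >= 1)
  n <- n_coding + n_ncrna
  if (n == 0) {
    return(genome_annotation(data.frame(id = character(), chrom = character(),
                                        start = numeric(), end = numeric(),
                                        strand = character(), kind = character(),
                                        category = character(),
                                        stringsAsFactors = FALSE),
                             genome_length = genome_length))
  }
  with_seed(child_seed(seed, "annotation"), {
    kind <- c(rep("coding", n_coding), rep("ncRNA", n_ncrna))
    id <- c(sprintf("gene%04d", seq_len(n_coding) + 0L)[seq_len(n_coding)],
            sprintf("ncr%04d", seq_len(n_ncrna) + 0L)[seq_len(n_ncrna)])
    len <- ifelse(kind == "coding",
                  round(runif(n, coding_length[1], coding_length[2])),
                  round(runif(n, ncrna_length[1], ncrna_length[2])))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    rows <- vector("list", 2)
    for (si in 1:2) {
      s <- c("+", "-")[si]
      idx <- which(strand == s)
      if (length(idx) == 0) next
      tot <- sum(len[idx])
      if (tot > genome_length)
        stop(sprintf(paste0("cannot pack %d features (total length %d bp) on ",
                            "strand '%s' of a %d bp genome without same-strand ",
                            "overlap"), length(idx), tot, s, genome_length),
             call. = FALSE)
      idx <- sample(idx)  # random order along the chromosome
      free <- genome_length - tot
      cuts <- sort(runif(length(idx), 0, free))
      gaps <- floor(c(cuts[1], diff(cuts)))
      start <- cumsum(gaps) + cumsum(c(0, len[idx][-length(idx)]))
      rows[[si]] <- data.frame(id = id[idx], chrom = "chr1",
                               start = start, end = start + len[idx],
                               strand = s, kind = kind[idx],
                               stringsAsFactors = FALSE)
    }
    feats <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    feats <- feats[order(feats$start, feats$id), ]
    feats$category <- NA_character_
    if (!is.null(category_scheme) && n_coding > 0) {
      category_scheme <- unlist(category_scheme)  # tolerate JSON-config lists
      p <- category_scheme / sum(category_scheme)
      is_cod <- feats$kind == "coding"
      feats$category[is_cod] <- sample(names(p), sum(is_cod),
                                       replace = TRUE, prob = p)
    }
    rownames(feats) <- NULL
    genome_annotation(feats, genome_length = genome_length)
  })
}

#' Generate a strand-specific tiling probe layout
#'
#' Probes are placed at fixed spacing on both strands across the whole
#' genome (the array interrogates the genome independently of annotation).
#'
#' @param annotation a `genome_annotation` carrying `genome_length`.
#' @param resolution probe spacing in bp (default 22, the array pitch).
#' @return object of class `probe_layout`: data.frame with `probe_id`,
#'   `chrom`, `position`, `strand` and attribute `resolution`.
#' @export
generate_probe_layout <- function(annotation, resolution = 22) {
  stopifnot(resolution >= 1)
  L <- attr(annotation, "genome_length")
  assert_that(is.numeric(L) && !is.na(L) && L >= 1,
              "annotation must carry a genome_length to lay out probes")
  pos <- seq(0, L - 1, by = resolution)
  chroms <- unique(annotation$chrom)
  if (length(chroms) == 0) chroms <- "chr1"
  grid <- expand.grid(position = pos, strand = c("+", "-"), chrom = chroms,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("chrom", "position", "strand")]
  grid$probe_id <- sprintf("P%s%07d", ifelse(grid$strand == "+", "p", "m"),
                           grid$position)
  structure(grid[, c("probe_id", "chrom", "position", "strand")],
            resolution = resolution,
            class = c("probe_layout", "data.frame"))
}

#' Effect and noise configuration for the expression simulator
#'
#' Defaults emulate the depletion study design: about 22.5% of genes planted
#' as direct up-effects and 7.5% as indirect down-effects (matching the
#' observed 958 up / 310 down of a 4244-gene coding pool), log2 baselines
#' centred near 10 where the up-fraction of real data peaks, and a hard
#' saturation ceiling clipping the most highly expressed genes.
#'
#' @param frac_direct_up proportion of features planted with positive log2
#'   effects (direct stabilization targets).
#' @param frac_indirect_down proportion planted with negative log2 effects.
#' @param log2_effect_up,log2_effect_down `(mean, sd)` of the absolute log2
#'   effect size per class.
#' @param noise_sd_probe_affinity per-probe affinity offset sd (log2 units;
#'   shared across arrays, cancels in comparisons).
#' @param noise_sd_replicate per-probe, per-array measurement noise sd.
#' @param baseline_mean,baseline_sd gene baseline log2 expression.
#' @param saturation_ceiling hard clip on every probe value (log2 units).
#' @param background_mean log2 level of probes outside any feature.
#' @param seed integer master seed.
#' @return list of class `effect_config`.
#' @export
effect_config <- function(frac_direct_up = 0.225, frac_indirect_down = 0.075,
                          log2_effect_up = c(mean = 1.2, sd = 0.6),
                          log2_effect_down = c(mean = 0.8, sd = 0.4),
                          noise_sd_probe_affinity = 0.15,
                          noise_sd_replicate = 0.1,
                          baseline_mean = 10, baseline_sd = 2,
                          saturation_ceiling = 14.5,
                          background_mean = 4, seed = 1) {
  assert_that(frac_direct_up >= 0 && frac_direct_up <= 1 &&
                frac_indirect_down >= 0 && frac_indirect_down <= 1 &&
                frac_direct_up + frac_indirect_down <= 1,
              "effect fractions must lie in [0,1] and sum to at most 1")
  assert_that(noise_sd_probe_affinity >= 0 && noise_sd_replicate >= 0 &&
                baseline_sd >= 0, "noise sds must be non-negative")
  structure(list(frac_direct_up = frac_direct_up,
                 frac_indirect_down = frac_indirect_down,
                 log2_effect_up = log2_effect_up,
                 log2_effect_down = log2_effect_down,
                 noise_sd_probe_affinity = noise_sd_probe_affinity,
                 noise_sd_replicate = noise_sd_replicate,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 saturation_ceiling = saturation_ceiling,
                 background_mean = background_mean, seed = seed),
            class = "effect_config")
}

#' Build the array design table for a duplicate-culture depletion experiment
#'
#' @param n_replicates biological replicates per condition (default 2,
#'   duplicate cultures).
#' @return data.frame with `array_id`, `condition` (`depleted` = grown
#'   without inducer, `induced` = with inducer), `replicate`.
#' @export
depletion_design <- function(n_replicates = 2) {
  data.frame(
    array_id = c(sprintf("dep_%d", seq_len(n_replicates)),
                 sprintf("ind_%d", seq_len(n_replicates))),
    condition = rep(c("depleted", "induced"), each = n_replicates),
    replicate = rep(seq_len(n_replicates), 2),
    stringsAsFactors = FALSE)
}

#' Simulate probe-level intensities under a depletion design
#'
#' Gene baselines are Normal(baseline_mean, baseline_sd); each probe adds a
#' fixed affinity offset, the planted log2 effect on depleted arrays, and
#' per-array replicate noise; every value is hard-clipped at the saturation
#' ceiling (a further increase of an already saturated transcript is
#' undetectable).
#'
#' @param annotation a `genome_annotation`.
#' @param layout a `probe_layout`.
#' @param design design table as from [depletion_design()].
#' @param effects an [effect_config()].
#' @return object of class `probe_signals`: list with `layout`, `design`,
#'   `values` (probe x array matrix, log2) and `truth` (per-feature planted
#'   log2 effect and class).
#' @export
simulate_expression <- function(annotation, layout, design,
                                effects = effect_config()) {
  assert_that(nrow(design) >= 2 &&
                all(c("depleted", "induced") %in% design$condition),
              "design must contain at least one array per condition")
  n_feat <- nrow(annotation)
  with_seed(child_seed(effects$seed, "expression"), {
    # planted truth
    cls <- rep("none", n_feat)
    if (n_feat > 0) {
      n_up <- round(effects$frac_direct_up * n_feat)
      n_dn <- round(effects$frac_indirect_down * n_feat)
      pick <- sample(seq_len(n_feat), n_up + n_dn)
      cls[pick[seq_len(n_up)]] <- "direct_up"
      if (n_dn > 0) cls[pick[n_up + seq_len(n_dn)]] <- "indirect_down"
    }
    eff <- numeric(n_feat)
    eff[cls == "direct_up"] <- abs(rnorm(sum(cls == "direct_up"),
                                         effects$log2_effect_up[["mean"]],
                                         effects$log2_effect_up[["sd"]]))
    eff[cls == "indirect_down"] <- -abs(rnorm(sum(cls == "indirect_down"),
                                              effects$log2_effect_down[["mean"]],
                                              effects$log2_effect_down[["sd"]]))
    mu <- rnorm(n_feat, effects$baseline_mean, effects$baseline_sd)

    # map probes to same-strand features; non-overlap makes the assignment
    # unique, so an interval search per chrom/strand suffices
    feat_of <- rep(NA_integer_, nrow(layout))
    if (n_feat > 0) {
      for (key in unique(paste(annotation$chrom, annotation$strand))) {
        fi <- which(paste(annotation$chrom, annotation$strand) == key)
        fi <- fi[order(annotation$start[fi])]
        pi <- which(paste(layout$chrom, layout$strand) == key)
        if (length(pi) == 0) next
        slot <- findInterval(layout$position[pi], annotation$start[fi])
        ok <- slot >= 1
        ok[ok] <- layout$position[pi][ok] < annotation$end[fi][slot[ok]]
        feat_of[pi[ok]] <- fi[slot[ok]]
      }
    }
    affinity <- rnorm(nrow(layout), 0, effects$noise_sd_probe_affinity)
    base_probe <- ifelse(is.na(feat_of), effects$background_mean, mu[feat_of])
    eff_probe <- ifelse(is.na(feat_of), 0, eff[feat_of])

    values <- matrix(NA_real_, nrow(layout), nrow(design),
                     dimnames = list(layout$probe_id, design$array_id))
    for (a in seq_len(nrow(design))) {
      v <- base_probe + affinity +
        eff_probe * (design$condition[a] == "depleted") +
        rnorm(nrow(layout), 0, effects$noise_sd_replicate)
      values[, a] <- pmin(v, effects$saturation_ceiling)
    }
    truth <- data.frame(id = annotation$id, log2_effect = eff, class = cls,
                        baseline = mu, stringsAsFactors = FALSE)
    structure(list(layout = layout, design = design, values = values,
                   truth = truth, effects = effects),
              class = "probe_signals")
  })
}

#' Simulate a rifampicin-chase decay series
#'
#' Expected intensity follows first-order decay, `E[I(t)] = i0 *
#' 2^(-t / half_life)`, with multiplicative log-normal noise of the stated
#' coefficient of variation (mean-one, so the expectation is unbiased).
#'
#' @param half_life half-life in minutes, or the sentinel string `"stable"`
#'   for a non-decaying transcript.
#' @param times sampling times in minutes (non-negative).
#' @param i0 initial intensity.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed integer seed.
#' @param transcript_id,condition metadata carried on the result.
#' @return object of class `decay_series`: data.frame `time`, `intensity`
#'   with attributes `transcript_id` and `condition`.
#' @export
simulate_decay <- function(half_life, times, i0 = 100, noise_cv = 0, seed = 1,
                           transcript_id = "t1", condition = "depleted") {
  assert_that(all(times >= 0), "decay sampling times must be non-negative")
  stable <- identical(half_life, "stable")
  assert_that(stable || (is.numeric(half_life) && half_life > 0),
              "half_life must be positive or the sentinel 'stable'")
  expected <- if (stable) rep(i0, length(times)) else i0 * 2^(-times / half_life)
  intensity <- if (noise_cv > 0) {
    with_seed(child_seed(seed, "decay"), {
      sdlog <- sqrt(log(1 + noise_cv^2))
      expected * exp(rnorm(length(times), 0, sdlog) - sdlog^2 / 2)
    })
  } else expected
  decay_series(data.frame(time = times, intensity = intensity),
               transcript_id = transcript_id, condition = condition)
}

#' Construct a decay series object
#' @param points data.frame with `time` (minutes, strictly increasing) and
#'   `intensity` (positive).
#' @param transcript_id,condition metadata.
#' @return a `decay_series`.
#' @export
decay_series <- function(points, transcript_id = NA_character_,
                         condition = NA_character_) {
  assert_that(all(c("time", "intensity") %in% names(points)),
              "decay series needs 'time' and 'intensity' columns")
  assert_that(all(diff(points$time) > 0), "times must be strictly increasing")
  structure(as.data.frame(points), transcript_id = transcript_id,
            condition = condition, class = c("decay_series", "data.frame"))
}
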