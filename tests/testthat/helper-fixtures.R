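# Shared fixture builders. Everything is generated in code; no files.

# tiny expression matrix with explicit values
make_matrix <- function(values, n_rep = 2) {
  design <- depletion_design(n_rep)
  stopifnot(ncol(values) == nrow(design))
  colnames(values) <- design$array_id
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  expression_matrix(values, design)
}

# gene-level null/effect matrix: baseline N(10, 2), replicate noise sd,
# planted log2 effects added to the depleted arrays
make_gene_matrix <- function(n_genes, effects = numeric(n_genes),
                             noise_sd = 0.05, n_rep = 2, seed = 1) {
  set.seed(seed)
  base <- rnorm(n_genes, 10, 2)
  design <- depletion_design(n_rep)
  v <- sapply(seq_len(nrow(design)), function(a) {
    base + effects * (design$condition[a] == "depleted") +
      rnorm(n_genes, 0, noise_sd)
  })
  rownames(v) <- sprintf("g%04d", seq_len(n_genes))
  colnames(v) <- design$array_id
  expression_matrix(v, design)
}

# a small probe-level world with known geometry
make_world <- function(n_coding = 100, n_ncrna = 0, genome_length = 120000,
                       seed = 1, ...) {
  ann <- generate_annotation(n_coding, n_ncrna, genome_length, seed = seed)
  layout <- generate_probe_layout(ann, 22)
  design <- depletion_design(2)
  eff <- effect_config(..., seed = seed)
  sig <- simulate_expression(ann, layout, design, eff)
  list(ann = ann, layout = layout, design = design, sig = sig)
}

# construct a diff_table directly from fold-changes (all called)
make_diff <- function(fc, lfdr = 0.01, called = TRUE,
                      ids = sprintf("g%d", seq_along(fc))) {
  d <- data.frame(id = ids, fc = fc, delta = log2(fc),
                  amplitude = 2^abs(log2(fc)),
                  direction = ifelse(fc > 1, "up", "down"),
                  lfdr = lfdr, called = called, stringsAsFactors = FALSE)
  structure(d, class = c("diff_table", "data.frame"))
}

# amplitude-mixture diff table with a planted knee at `knee` (see the
# methods vignette: proportions derived from the published study counts)
make_knee_diff <- function(seed, n_up = 1600, n_down = 1280,
                           frac_up_above = 0.60, frac_down_above = 0.24,
                           knee = 1.6, amp_max = 4) {
  set.seed(seed)
  lk <- log2(knee); lmax <- log2(amp_max)
  a_up <- ifelse(runif(n_up) < frac_up_above,
                 runif(n_up, lk, lmax), runif(n_up, 0, lk))
  a_dn <- ifelse(runif(n_down) < frac_down_above,
                 runif(n_down, lk, lmax), runif(n_down, 0, lk))
  make_diff(c(2^a_up, 2^(-a_dn)))
}

# construct a cutoff_curve object directly
make_curve <- function(cutoff, up_pct, down_pct, n_coding = 4244) {
  structure(data.frame(cutoff = cutoff, up_pct = up_pct, down_pct = down_pct),
            n_coding_reference = n_coding,
            class = c("cutoff_curve", "data.frame"))
}

# the noiseless two-slope reference curve of the detector tests: knot at
# the 1.6 grid point, slope 2 below / 0.5 above in the (down%, up%) plane
make_twoslope_curve <- function(noise_sd = 0, seed = NULL) {
  grid <- seq(1, 4, by = 0.05)
  dn <- ifelse(grid <= 1.6, 20 - 10 * (grid - 1), 14 - 2 * (grid - 1.6))
  up <- ifelse(dn >= 14, 10 + 2 * (dn - 14), 10 + 0.5 * (dn - 14))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    up <- up + rnorm(length(grid), 0, noise_sd)
    dn <- dn + rnorm(length(grid), 0, noise_sd)
  }
  make_curve(grid, up, dn)
}
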