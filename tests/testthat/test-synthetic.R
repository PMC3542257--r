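test_that("generate_annotation handles the empty case and is deterministic", {
  a0 <- generate_annotation(0, 0, 1000)
  expect_equal(nrow(a0), 0)
  expect_equal(n_coding(a0), 0)

  a1 <- generate_annotation(10, 2, 50000, seed = 1)
  a2 <- generate_annotation(10, 2, 50000, seed = 1)
  expect_identical(a1, a2)
  expect_equal(n_coding(a1), 10)
  expect_false(identical(a1, generate_annotation(10, 2, 50000, seed = 2)))
})

test_that("generate_annotation packs features without same-strand overlap", {
  a <- generate_annotation(40, 10, 80000, seed = 3)
  for (s in c("+", "-")) {
    g <- a[a$strand == s, ]
    g <- g[order(g$start), ]
    expect_true(all(g$start >= 0), info = s)
    expect_true(all(g$end <= 80000), info = s)
    if (nrow(g) > 1)
      expect_true(all(g$start[-1] >= g$end[-nrow(g)]), info = s)
  }
  # infeasible packing errors with the constraint named
  expect_error(generate_annotation(100, 0, 5000, seed = 1), "cannot pack")
})

test_that("category assignment matches the scheme proportions in expectation", {
  # 4244-gene pool scaled to 100; 0.9% minor-category share; multinomial
  # oracle: mean count over seeds ~ Binom(100, p), sd of the mean =
  # sqrt(p (1 - p) / 100 seeds) * 10
  scheme <- c(minor = 0.009, translation = 0.3, rest = 0.691)
  counts <- vapply(1:100, function(s) {
    a <- generate_annotation(100, 0, 200000, category_scheme = scheme, seed = s)
    sum(a$category == "minor", na.rm = TRUE)
  }, 0)
  expect_gt(mean(counts), 0.9 - 5 * sqrt(100 * 0.009 * 0.991) / 10)
  expect_lt(mean(counts), 0.9 + 5 * sqrt(100 * 0.009 * 0.991) / 10)
})

test_that("probe layout arithmetic follows the half-open convention", {
  ann <- genome_annotation(
    data.frame(id = "geneA", chrom = "chr1", start = 0, end = 220,
               strand = "+", kind = "coding"), genome_length = 220)
  lay <- generate_probe_layout(ann, 22)
  inside <- lay$position[lay$strand == "+" & lay$position >= 0 &
                           lay$position < 220]
  expect_equal(inside, seq(0, 198, by = 22))  # 10 probes, 220 excluded
  expect_equal(length(inside), 10)

  # resolution = genome length -> one probe per strand
  lay1 <- generate_probe_layout(ann, 220)
  expect_equal(nrow(lay1), 2)
  expect_equal(lay1$position, c(0, 0))

  # a 66 bp feature at default 22 nt pitch spans 3 probes
  ann2 <- genome_annotation(
    data.frame(id = "g", chrom = "chr1", start = 0, end = 66,
               strand = "+", kind = "coding"), genome_length = 66)
  lay2 <- generate_probe_layout(ann2, 22)
  expect_equal(sum(lay2$strand == "+" & lay2$position < 66), 3)
})

test_that("probe positions on one strand differ by exactly the resolution", {
  ann <- generate_annotation(5, 0, 10000, seed = 1)
  lay <- generate_probe_layout(ann, 22)
  for (s in c("+", "-"))
    expect_true(all(diff(sort(lay$position[lay$strand == s])) == 22))
  expect_equal(attr(lay, "resolution"), 22)
})

test_that("noiseless null simulation gives identical arrays", {
  w <- make_world(20, 0, 30000, seed = 1,
                  frac_direct_up = 0, frac_indirect_down = 0,
                  noise_sd_probe_affinity = 0, noise_sd_replicate = 0)
  v <- w$sig$values
  expect_equal(v[, "dep_1"], v[, "ind_1"])
  expect_equal(v[, "dep_1"], v[, "dep_2"])
})

test_that("a planted effect is recovered exactly without noise", {
  w <- make_world(20, 0, 30000, seed = 2,
                  frac_direct_up = 0.1, frac_indirect_down = 0,
                  noise_sd_probe_affinity = 0, noise_sd_replicate = 0,
                  saturation_ceiling = Inf,
                  log2_effect_up = c(mean = 1, sd = 0))
  mat <- aggregate_gene_level(w$sig, w$ann)
  fc <- fold_change(mat)
  tr <- w$sig$truth
  up <- tr$id[tr$class == "direct_up"]
  expect_true(length(up) >= 1)
  expect_equal(fc$fc[match(up, fc$id)], rep(2, length(up)), tolerance = 1e-12)
})

test_that("saturation clipping censors planted effects", {
  w <- make_world(20, 0, 30000, seed = 3,
                  frac_direct_up = 0.5, frac_indirect_down = 0,
                  noise_sd_probe_affinity = 0, noise_sd_replicate = 0,
                  baseline_mean = 15, baseline_sd = 0,  # above the ceiling
                  saturation_ceiling = 14.5,
                  log2_effect_up = c(mean = 1, sd = 0))
  expect_true(all(w$sig$values <= 14.5))
  mat <- aggregate_gene_level(w$sig, w$ann)
  fc <- fold_change(mat)
  up <- w$sig$truth$id[w$sig$truth$class == "direct_up"]
  expect_true(all(fc$fc[match(up, fc$id)] < 2))  # observed < planted 2.0
})

test_that("truth covers every feature and respects effect signs", {
  w <- make_world(50, 10, 80000, seed = 4)
  tr <- w$sig$truth
  expect_setequal(tr$id, w$ann$id)
  expect_true(all(tr$log2_effect[tr$class == "direct_up"] > 0))
  expect_true(all(tr$log2_effect[tr$class == "indirect_down"] < 0))
  expect_true(all(tr$log2_effect[tr$class == "none"] == 0))
})

test_that("effect_config validates proportions and sds", {
  expect_error(effect_config(frac_direct_up = 0.7, frac_indirect_down = 0.5),
               "sum")
  expect_error(effect_config(noise_sd_replicate = -1), "non-negative")
})

test_that("simulate_decay follows the exponential exactly and per seed", {
  d <- simulate_decay(5, c(0, 5, 10), i0 = 100, noise_cv = 0)
  expect_equal(d$intensity, c(100, 50, 25))

  s <- simulate_decay("stable", c(0, 5, 10), i0 = 7, noise_cv = 0)
  expect_equal(s$intensity, rep(7, 3))

  expect_error(simulate_decay(5, c(-1, 0, 5)), "non-negative")
  expect_identical(simulate_decay(4, 0:5, noise_cv = 0.1, seed = 9),
                   simulate_decay(4, 0:5, noise_cv = 0.1, seed = 9))
})

test_that("decay noise is mean-one: E[I(5)/i0] stays at 0.5", {
  # Monte-Carlo oracle: mean over 200 seeds within 1% of 2^(-1)
  vals <- vapply(1:200, function(s)
    simulate_decay(5, c(0, 5, 10), i0 = 1, noise_cv = 0.05,
                   seed = s)$intensity[2], 0)
  expect_lt(abs(mean(vals) - 0.5), 0.005)
})
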