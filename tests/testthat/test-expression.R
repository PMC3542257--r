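test_that("median aggregation follows the stated median rules", {
  # one gene, probes every 22 bp; three arrays worth of direct checks
  ann <- genome_annotation(
    data.frame(id = c("gA", "gB"), chrom = "chr1", start = c(0, 200),
               end = c(66, 288), strand = "+", kind = "coding"),
    genome_length = 300)
  probes <- data.frame(
    chrom = "chr1",
    position = c(0, 22, 44, 200, 222, 244, 266),
    strand = "+",
    dep_1 = c(5, 7, 6, 1, 2, 3, 10),
    dep_2 = c(5, 7, 6, 1, 2, 3, 10),
    ind_1 = c(5, 7, 6, 1, 2, 3, 10),
    ind_2 = c(5, 7, 6, 1, 2, 3, 10))
  mat <- aggregate_gene_level(probes, ann, design = depletion_design(2))
  expect_equal(unname(mat$values["gA", "dep_1"]), 6)    # odd count
  expect_equal(unname(mat$values["gB", "dep_1"]), 2.5)  # even: mean of middle two
})

test_that("a gene spanning no probes is masked, not zero", {
  ann <- genome_annotation(
    data.frame(id = c("gA", "gNone"), chrom = "chr1", start = c(0, 100),
               end = c(44, 110), strand = "+", kind = "coding"),
    genome_length = 300)
  probes <- data.frame(chrom = "chr1", position = c(0, 22), strand = "+",
                       dep_1 = c(1, 2), dep_2 = c(1, 2),
                       ind_1 = c(1, 2), ind_2 = c(1, 2))
  mat <- suppressMessages(
    aggregate_gene_level(probes, ann, design = depletion_design(2)))
  expect_true(all(is.na(mat$values["gNone", ])))
  expect_equal(masked_genes(mat), "gNone")
})

test_that("chromosome mismatches are reported by name", {
  ann <- genome_annotation(
    data.frame(id = "g", chrom = "chrX", start = 0, end = 44,
               strand = "+", kind = "coding"), genome_length = 100)
  probes <- data.frame(chrom = "chr1", position = 0, strand = "+",
                       dep_1 = 1, dep_2 = 1, ind_1 = 1, ind_2 = 1)
  expect_error(aggregate_gene_level(probes, ann, design = depletion_design(2)),
               "chrX")
})

test_that("aggregation matches a brute-force median oracle on random instances", {
  set.seed(42)
  for (rep in 1:50) {
    n_genes <- sample(1:4, 1)
    starts <- cumsum(sample(130:250, n_genes))   # gaps exceed max length:
    ends <- starts + sample(40:120, n_genes, replace = TRUE)  # no overlap
    strands <- sample(c("+", "-"), n_genes, replace = TRUE)
    ann <- genome_annotation(
      data.frame(id = sprintf("g%d", 1:n_genes), chrom = "chr1",
                 start = starts, end = ends, strand = strands,
                 kind = "coding"), genome_length = max(ends) + 50)
    n_probes <- sample(10:40, 1)
    probes <- data.frame(
      chrom = "chr1",
      position = sample(0:(max(ends) + 40), n_probes),
      strand = sample(c("+", "-"), n_probes, replace = TRUE),
      dep_1 = rnorm(n_probes), dep_2 = rnorm(n_probes),
      ind_1 = rnorm(n_probes), ind_2 = rnorm(n_probes))
    mat <- suppressMessages(
      aggregate_gene_level(probes, ann, design = depletion_design(2)))
    # oracle: explicit per-gene median by scanning probes
    for (i in seq_len(n_genes)) {
      hit <- probes$strand == strands[i] & probes$position >= starts[i] &
        probes$position < ends[i]
      for (a in c("dep_1", "dep_2", "ind_1", "ind_2")) {
        want <- if (any(hit)) median(probes[[a]][hit]) else NA_real_
        expect_equal(unname(mat$values[sprintf("g%d", i), a]), want,
                     info = sprintf("rep %d gene %d array %s", rep, i, a))
      }
    }
  }
})

test_that("least-variant-set selection matches brute-force rank variances", {
  set.seed(7)
  v <- matrix(rnorm(80, 10, 2), 20, 4)
  mat <- make_matrix(v)
  sel <- select_least_variant_set(mat, fraction = 0.5, rank_trim = 0)
  # brute-force oracle: independent rank + variance computation
  rk <- sapply(1:4, function(a) rank(v[, a], ties.method = "average"))
  rv <- sapply(1:20, function(g) var(rk[g, ]))
  names(rv) <- rownames(mat$values)
  want <- names(sort(rv))[1:10]  # no exact ties in this draw
  expect_setequal(sel$gene_ids, want)
  expect_equal(length(sel$gene_ids), round(0.5 * 20))
})

test_that("degenerate ties select by gene id and planted outliers are excluded", {
  # identical arrays: all rank variances 0, tie-break on id
  v <- matrix(rep(seq(1, 10), 4), 10, 4)
  mat <- make_matrix(v)
  sel <- select_least_variant_set(mat, fraction = 0.5, rank_trim = 0)
  expect_equal(sel$gene_ids, sort(rownames(mat$values))[1:5])
  expect_true(all(sel$variance_statistic == 0))

  # permute one mid-rank gene to the top in a single array: excluded at 0.5
  v2 <- v
  v2[5, 2] <- 100
  mm2 <- make_matrix(v2)
  sel2 <- select_least_variant_set(mm2, fraction = 0.5, rank_trim = 0)
  expect_false(rownames(mm2$values)[5] %in% sel2$gene_ids)
})

test_that("rank-trim keeps strongly regulated extreme genes out of the LVS", {
  set.seed(11)
  eff <- numeric(50)
  mat <- make_gene_matrix(50, eff, noise_sd = 0.02, seed = 11)
  # plant a big effect on the most highly expressed gene: its rank cannot
  # move, so without trimming it would look perfectly stable
  top <- rownames(mat$values)[which.max(rowMeans(mat$values))]
  dep <- mat$design$condition == "depleted"
  mat$values[top, dep] <- mat$values[top, dep] + 3
  sel <- select_least_variant_set(mat, fraction = 0.4)
  expect_false(top %in% sel$gene_ids)
})

test_that("normalization removes affine distortions and is idempotent", {
  set.seed(3)
  mat <- make_gene_matrix(60, noise_sd = 0, seed = 3)
  # distort one array by y = 0.8 x + 0.5, shift another by +1
  mat$values[, 2] <- 0.8 * mat$values[, 2] + 0.5
  mat$values[, 3] <- mat$values[, 3] + 1
  lvs <- select_least_variant_set(mat, 0.5)
  nm <- normalize_lvs(mat, lvs)
  # all arrays agree after normalization (distortion removed)
  b <- rowMeans(nm$values)
  expect_lt(max(abs(nm$values - b)), 1e-6)

  # constant +1 shift on one array with planted effects: shift removed and
  # the planted (non-LVS) fold-changes preserved exactly
  eff <- c(rep(1.5, 6), rep(0, 54))
  mat2 <- make_gene_matrix(60, eff, noise_sd = 0, seed = 3)
  mat2$values[, 1] <- mat2$values[, 1] + 1
  nm2 <- normalize_lvs(mat2, select_least_variant_set(mat2, 0.5))
  d2 <- fold_change(nm2)
  expect_equal(d2$delta[match(rownames(mat2$values), d2$id)], eff,
               tolerance = 1e-9)

  # idempotency within 1e-9, also on noisy data
  set.seed(4)
  mat2 <- make_gene_matrix(80, noise_sd = 0.3, seed = 4)
  mat2$values[, 1] <- 1.1 * mat2$values[, 1] - 0.4
  lvs2 <- select_least_variant_set(mat2, 0.4)
  n1 <- normalize_lvs(mat2, lvs2)
  n2 <- normalize_lvs(n1, lvs2)
  expect_lt(max(abs(n1$values - n2$values)), 1e-9)
})

test_that("an array already equal to the baseline is unchanged", {
  v <- matrix(rep(seq(2, 12, length.out = 30), 4), 30, 4)
  mat <- make_matrix(v)
  nm <- normalize_lvs(mat, select_least_variant_set(mat, 1))
  expect_equal(nm$values, mat$values, tolerance = 1e-9)
})

test_that("post-normalization LVS regression has slope 1, intercept 0", {
  set.seed(5)
  mat <- make_gene_matrix(100, noise_sd = 0.2, seed = 5)
  mat$values[, 4] <- 0.9 * mat$values[, 4] + 0.8
  lvs <- select_least_variant_set(mat, 0.4)
  nm <- normalize_lvs(mat, lvs)
  b <- rowMeans(nm$values[lvs$gene_ids, ])
  for (a in 1:4) {
    f <- lm(nm$values[lvs$gene_ids, a] ~ b)
    expect_lt(abs(coef(f)[2] - 1), 1e-9)
    expect_lt(abs(coef(f)[1]), 1e-9)
  }
})

test_that("normalization preserves planted effect signs under distortion", {
  # 20% up-effects planted, every array affinely distorted
  set.seed(6)
  n <- 200
  eff <- ifelse(seq_len(n) <= 40, runif(n, 0.5, 2), 0)
  mat <- make_gene_matrix(n, eff, noise_sd = 0.05, seed = 6)
  slopes <- c(0.9, 1.1, 0.95, 1.05); ints <- c(0.5, -0.3, 0.2, -0.6)
  for (a in 1:4) mat$values[, a] <- slopes[a] * mat$values[, a] + ints[a]
  nm <- normalize_lvs(mat, select_least_variant_set(mat, 0.4))
  d <- fold_change(nm)
  got <- d$delta[match(rownames(mat$values)[eff > 0], d$id)]
  expect_gte(mean(got > 0), 0.99)
})

test_that("LVS errors are explicit", {
  v <- matrix(NA_real_, 5, 4)
  rownames(v) <- sprintf("g%d", 1:5)
  expect_error(select_least_variant_set(make_matrix(v), 0.4), "masked")
  mat <- make_gene_matrix(10, seed = 1)
  lvs <- select_least_variant_set(mat, 0.4)
  lvs$gene_ids <- lvs$gene_ids[1:2]
  expect_error(normalize_lvs(mat, lvs), "at least 3")
})
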