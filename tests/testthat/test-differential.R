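test_that("fold-change columns follow the amplitude semantics", {
  v <- rbind(c(3, 3, 3, 3),    # null
             c(4, 4, 3, 3),    # 2x up
             c(2, 2, 3, 3))    # 2x down
  rownames(v) <- c("null", "up2", "down2")
  d <- fold_change(make_matrix(v))
  expect_equal(d$fc, c(1, 2, 0.5))
  expect_equal(d$amplitude, c(1, 2, 2))
  expect_equal(d$direction[2:3], c("up", "down"))
  expect_equal(d$fc, 2^d$delta, tolerance = 1e-12)
  expect_true(all(d$amplitude >= 1))
})

test_that("pooled t-test matches the hand-computed df = 2 case", {
  # a = {1,2}, b = {3,4}: pooled s^2 = 0.5, t = -2/sqrt(0.5) = -2.828
  r <- t_test_gene(c(1, 2), c(3, 4))
  expect_equal(unname(r["t_stat"]), -2 * sqrt(2), tolerance = 1e-4)
  # closed form for df = 2: P(T <= t) = 1/2 + t / (2 sqrt(2 + t^2))
  t <- unname(r["t_stat"])
  p_oracle <- 2 * (1 / 2 + t / (2 * sqrt(2 + t^2)))
  expect_equal(unname(r["p_value"]), p_oracle, tolerance = 1e-10)
  expect_equal(unname(r["p_value"]), 0.1056, tolerance = 1e-3)
})

test_that("exact ties give p = 1 and never p = 0", {
  r <- t_test_gene(c(1, 1), c(1, 1))
  expect_equal(unname(r["p_value"]), 1)
  # zero variance but different means: finite t, p > 0
  r2 <- t_test_gene(c(2, 2), c(1, 1))
  expect_gt(unname(r2["p_value"]), 0)
  expect_true(is.finite(r2["t_stat"]))
  # short group is masked with a warning
  expect_warning(r3 <- t_test_gene(1, c(1, 2)), "fewer than 2")
  expect_true(is.na(r3["p_value"]))
})

test_that("lfdr on uniform p-values is near 1", {
  for (s in 1:5) {
    set.seed(s)
    p <- runif(10000)
    l <- estimate_lfdr(p)
    eta0 <- min(1, sum(p > 0.5) / 5000)
    expect_gte(median(l), 0.9)
    expect_gte(eta0, 0.95)
  }
})

test_that("lfdr identifies a planted signal mixture", {
  # oracle: mixture density f(p) = 0.8 + 0.2 * dbeta(p, 0.05, 1) is huge
  # below 1e-4, so the true lfdr there is << 0.2
  for (s in 1:5) {
    set.seed(s)
    p <- c(runif(8000), rbeta(2000, 0.05, 1))
    l <- estimate_lfdr(p)
    expect_lte(mean(l[p < 1e-4]), 0.2)
  }
})

test_that("lfdr handles degenerate inputs per contract", {
  expect_equal(estimate_lfdr(rep(1, 200)), rep(1, 200))
  expect_error(estimate_lfdr(c(runif(200), 1.5)), "0, 1")
  expect_warning(l <- estimate_lfdr(runif(50)), "fewer than 100")
  expect_equal(l, rep(1, 50))
})

test_that("lfdr is monotone non-decreasing in p", {
  for (s in 1:5) {
    set.seed(s)
    p <- c(runif(500), rbeta(200, 0.2, 1))
    l <- estimate_lfdr(p)
    o <- order(p)
    expect_true(all(diff(l[o]) >= -1e-12))
  }
})

test_that("calling rule is inclusive at the boundary", {
  d <- make_diff(c(2, 2, 2), lfdr = c(0.01, 0.09, 0.11), called = FALSE)
  d <- call_differential(d, lfdr_max = 0.1)
  expect_equal(sum(d$called), 2)

  d2 <- call_differential(make_diff(2, lfdr = 0.1, called = FALSE))
  expect_true(d2$called)  # exactly 0.1 is called

  d3 <- call_differential(make_diff(c(2, 2), lfdr = 1, called = FALSE))
  expect_equal(sum(d3$called), 0)
})

test_that("average FDR is the mean lfdr over calls and bounded by the rule", {
  d <- call_differential(make_diff(c(2, 2), lfdr = c(0.1, 0.1)))
  expect_equal(average_fdr(d), 0.1)
  d2 <- call_differential(make_diff(c(2, 2), lfdr = c(0, 0.1)))
  expect_equal(average_fdr(d2), 0.05)
  d3 <- call_differential(make_diff(2, lfdr = 0.9))
  expect_error(average_fdr(d3), "undefined")
  # follows from the call rule: average over 20 planted simulations
  for (s in 1:20) {
    eff <- c(rnorm(60, 1.5, 0.3), rep(0, 440))
    mat <- make_gene_matrix(500, eff, noise_sd = 0.05, seed = s)
    d <- diff_test(mat)
    if (any(d$called)) expect_lte(average_fdr(d), 0.1)
  }
})

test_that("swapping condition labels negates delta and preserves p and lfdr", {
  set.seed(8)
  eff <- c(rnorm(30, 1, 0.5), rep(0, 170))
  mat <- make_gene_matrix(200, eff, noise_sd = 0.1, seed = 8)
  d1 <- diff_test(mat)
  swapped <- mat
  swapped$design$condition <- ifelse(mat$design$condition == "depleted",
                                     "induced", "depleted")
  d2 <- diff_test(swapped)
  expect_equal(d2$delta, -d1$delta)
  expect_equal(d2$p_value, d1$p_value)
  expect_equal(d2$lfdr, d1$lfdr)
})

test_that("masked genes propagate as masked rows", {
  mat <- make_gene_matrix(150, seed = 2)
  mat$values[3, ] <- NA
  d <- diff_test(mat)
  expect_true(is.na(d$fc[3]))
  expect_true(is.na(d$p_value[3]))
  expect_false(d$called[3])
})
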