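test_that("the causal direction of a two-variable system is identified", {
  set.seed(1)
  x <- runif(5000, -sqrt(3), sqrt(3))
  y <- 1.5 * x + runif(5000, -sqrt(3), sqrt(3))
  X <- cbind(x = x, y = y)
  expect_equal(estimate_causal_order(X), c("x", "y"))
  # agrees with the exhaustive two-order independence oracle
  expect_equal(estimate_causal_order(X), exhaustive_lingam_order(X))
})

test_that("the three-variable chain order is recovered across seeds", {
  hits <- 0
  for (s in 1:20) {
    tr <- sample_traits(trait_model(), 2000, seed = s)
    ord <- estimate_causal_order(tr[, c("M", "L", "A")])
    if (identical(ord, c("A", "M", "L"))) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("the order is equivariant to column permutation", {
  tr <- sample_traits(trait_model(), 1500, seed = 4)
  o1 <- estimate_causal_order(tr[, c("A", "M", "L")])
  o2 <- estimate_causal_order(tr[, c("L", "M", "A")])
  expect_equal(o1, o2)
})

test_that("degenerate inputs are rejected", {
  X <- cbind(a = rnorm(50), b = rep(1, 50))
  expect_error(estimate_causal_order(X), "constant")
  x <- rnorm(100)
  expect_error(estimate_causal_order(cbind(a = x, b = 2 * x)),
               "rank-deficient")
  expect_error(estimate_causal_order(matrix(rnorm(6), 2, 3)),
               "more observations")
})

test_that("adaptive-LASSO pruning keeps true edges and drops null ones", {
  # noiseless proportionality: coefficient retained at its exact value
  set.seed(2)
  x <- runif(500)
  X0 <- cbind(x = x, y = 2 * x + rnorm(500, sd = 1e-8))
  B0 <- prune_adaptive_lasso(X0, c("x", "y"))
  # standardized scale: coefficient of a perfect fit is 1
  expect_equal(B0["y", "x"], 1, tolerance = 1e-6)
  expect_equal(B0["x", "y"], 0)          # first variable: no predecessors

  # the true-zero A->L edge is pruned to exactly 0 in most seeds
  zeros <- 0
  for (s in 1:20) {
    tr <- sample_traits(trait_model(), 2000, seed = 100 + s)
    B <- prune_adaptive_lasso(tr[, c("A", "M", "L")], c("A", "M", "L"))
    if (B["L", "A"] == 0) zeros <- zeros + 1
    expect_equal(B["L", "M"], 0.70, tolerance = 0.08 / 0.70)
    expect_equal(B["M", "A"], -0.39, tolerance = 0.08 / 0.39)
  }
  expect_gte(zeros, 16)
})

test_that("direct_lingam composes order search and pruning", {
  tr <- sample_traits(trait_model(), 2000, seed = 5)
  fit <- direct_lingam(tr[, c("A", "M", "L")])
  expect_s3_class(fit, "lingam_fit")
  expect_equal(fit$order, c("A", "M", "L"))
  expect_equal(fit$B["L", "M"], 0.70, tolerance = 0.07)
  expect_equal(fit$B["M", "A"], -0.39, tolerance = 0.07)
  expect_equal(fit$B["L", "A"], 0)
  expect_true(fit$exogenous["A"])
  expect_false(fit$exogenous["L"])
  # B is strictly lower-triangular under the causal order
  Bp <- fit$B[fit$order, fit$order]
  expect_true(all(Bp[upper.tri(Bp, diag = TRUE)] == 0))
})

test_that("Gaussian data warn (unidentifiable) but still return a graph", {
  set.seed(6)
  X <- cbind(a = rnorm(300), b = rnorm(300))
  expect_warning(fit <- direct_lingam(X), "not\\s+identifiable")
  expect_s3_class(fit, "lingam_fit")
})

test_that("a single variable yields a trivial edgeless graph", {
  fit <- direct_lingam(matrix(runif(100), ncol = 1,
                              dimnames = list(NULL, "x")))
  expect_equal(sum(fit$B != 0), 0)
  expect_true(fit$exogenous[["x"]])
})

test_that("standardized coefficients are scale equivariant", {
  tr <- sample_traits(trait_model(), 1000, seed = 7)
  X1 <- as.matrix(tr[, c("A", "M", "L")])
  X2 <- X1
  X2[, "M"] <- X2[, "M"] * 37.5       # rescale one column before z-scoring
  f1 <- direct_lingam(X1)
  f2 <- direct_lingam(X2)
  expect_equal(f1$order, f2$order)
  expect_equal(f1$B, f2$B, tolerance = 1e-9)
})

test_that("structural residuals are orthogonal to their predictors", {
  tr <- sample_traits(trait_model(), 2000, seed = 8)
  fit <- direct_lingam(tr[, c("A", "M", "L")])
  expect_lt(abs(cor(fit$E[, "M"], fit$Z[, "A"])), 0.05)
  expect_lt(abs(cor(fit$E[, "L"], fit$Z[, "M"])), 0.05)
})

test_that("bootstrap probabilities are well-formed and deterministic", {
  tr <- sample_traits(trait_model(), 400, seed = 9)
  X <- tr[, c("A", "M", "L")]
  b1 <- bootstrap_paths(X, n_resamples = 25, seed = 3)
  b2 <- bootstrap_paths(X, n_resamples = 25, seed = 3)
  expect_identical(b1$edge_probability, b2$edge_probability)
  expect_true(all(b1$edge_probability >= 0 & b1$edge_probability <= 1))
  expect_true(b1$graph_probability >= 0 && b1$graph_probability <= 1)

  single <- bootstrap_paths(X, n_resamples = 1, seed = 4)
  expect_true(all(single$edge_probability %in% c(0, 1)))
  expect_error(bootstrap_paths(X, n_resamples = 0), "positive integer")
})

test_that("a strong clean chain has near-certain memory->learning support", {
  tr <- sample_traits(trait_model(), 5000, seed = 10)
  b <- bootstrap_paths(tr[, c("A", "M", "L")], n_resamples = 200, seed = 5)
  expect_gte(b$edge_probability["L", "M"], 0.99)
})
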