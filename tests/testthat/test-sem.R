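test_that("a saturated three-variable model is just-identified", {
  tr <- sample_traits(trait_model(), 500, seed = 1)
  fit <- fit_path_model(tr[, c("A", "M", "L")],
                        rbind(c("A", "M"), c("A", "L"), c("M", "L")))
  expect_equal(fit$df, 0)
  expect_equal(fit$chi_square, 0, tolerance = 1e-6)
  expect_equal(unname(fit$fit_indices["CFI"]), 1)
  expect_equal(unname(fit$fit_indices["RMSEA"]), 0)
})

test_that("ML standardized paths equal per-equation OLS coefficients", {
  tr <- sample_traits(trait_model(), 2000, seed = 2)
  Z <- scale(as.matrix(tr[, c("A", "M", "L")]))
  fit <- fit_path_model(Z, rbind(c("A", "M"), c("M", "L")))
  ols_am <- unname(stats::lm.fit(Z[, "A", drop = FALSE], Z[, "M"])$coefficients)
  ols_ml <- unname(stats::lm.fit(Z[, "M", drop = FALSE], Z[, "L"])$coefficients)
  est <- coef(fit)
  expect_equal(unname(est["A -> M"]), ols_am, tolerance = 1e-6)
  expect_equal(unname(est["M -> L"]), ols_ml, tolerance = 1e-6)
})

test_that("the true chain model fits well and recovers its paths", {
  tr <- sample_traits(trait_model(), 2000, seed = 3)
  fit <- fit_path_model(tr[, c("A", "M", "L")],
                        rbind(c("A", "M"), c("M", "L")))
  expect_equal(fit$df, 1)
  est <- coef(fit)
  expect_equal(unname(est["M -> L"]), 0.70, tolerance = 0.06)
  expect_equal(unname(est["A -> M"]), -0.39, tolerance = 0.06)
  expect_lt(unname(fit$fit_indices["RMSEA"]), 0.05)
  expect_gt(unname(fit$fit_indices["CFI"]), 0.95)
  expect_lt(unname(fit$fit_indices["SRMR"]), 0.05)
  # strong paths have decisive z statistics
  expect_gt(fit$paths$z[fit$paths$from == "M"], 10)
})

test_that("adding an edge never increases the chi-square", {
  tr <- sample_traits(trait_model(), 800, seed = 4)
  X <- tr[, c("A", "M", "L")]
  chain <- fit_path_model(X, rbind(c("A", "M"), c("M", "L")))
  full <- fit_path_model(X, rbind(c("A", "M"), c("M", "L"), c("A", "L")))
  expect_lte(full$chi_square, chain$chi_square + 1e-8)
})

test_that("cyclic specifications are rejected", {
  tr <- sample_traits(trait_model(), 200, seed = 5)
  expect_error(fit_path_model(tr[, c("A", "M", "L")],
                              rbind(c("A", "M"), c("M", "A"))),
               "acyclic")
})

test_that("a single-edge model on independent data has small |z|", {
  rejections <- 0
  for (s in 1:20) {
    tr <- sample_traits(trait_model(coeff_AM = 0, coeff_ML = 0), 300,
                        seed = 50 + s)
    fit <- fit_path_model(tr[, c("M", "L")], rbind(c("M", "L")))
    if (abs(fit$paths$z[1]) > 2) rejections <- rejections + 1
    expect_equal(fit$paths$std_estimate[1], 0, tolerance = 0.2)
  }
  # approximately 5% type-I at |z| > 2
  expect_lte(rejections, 4)
})

test_that("fit indices behave at the two extremes", {
  tr <- sample_traits(trait_model(), 600, seed = 6)
  S <- stats::cov(scale(as.matrix(tr[, c("A", "M", "L")])))
  # implied = sample: perfect fit
  fi <- fit_indices(S, S, n = 600, df = 1,
                    chi_baseline = 500, df_baseline = 3)
  expect_equal(unname(fi["chi_square"]), 0, tolerance = 1e-10)
  expect_equal(unname(fi["SRMR"]), 0, tolerance = 1e-10)
  expect_equal(unname(fi["CFI"]), 1)
  # fitting the independence model to correlated data: CFI collapses to 0
  Sg <- diag(diag(S))
  base <- fit_indices(S, Sg, n = 600, df = 3,
                      chi_baseline = NA, df_baseline = NA)
  fi0 <- fit_indices(S, Sg, n = 600, df = 3,
                     chi_baseline = unname(base["chi_square"]),
                     df_baseline = 3)
  expect_equal(unname(fi0["CFI"]), 0, tolerance = 1e-8)
})

test_that("edges can be taken from a fitted causal graph", {
  tr <- sample_traits(trait_model(), 1500, seed = 7)
  lf <- direct_lingam(tr[, c("A", "M", "L")])
  sem <- fit_path_model(tr[, c("A", "M", "L")], lf)
  expect_equal(sort(paste(sem$paths$from, sem$paths$to)),
               sort(c("A M", "M L")))
})
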