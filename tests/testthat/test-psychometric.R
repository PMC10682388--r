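test_that("the fit recovers the generating curve from exact proportions", {
  dev <- c(-8, -6, -4, -2, 2, 4, 6, 8)
  n <- 1e5
  cells <- data.frame(deviation = dev, k = round(n * pnorm(dev / 3)), n = n)
  fit <- fit_cumulative_gaussian(cells)
  expect_true(fit$converged)
  expect_equal(fit$mu, 0, tolerance = 0.02)
  expect_equal(fit$sigma, 3, tolerance = 0.01)
})

test_that("the ML fit agrees with a probit GLM on regular data", {
  ses <- generate_judgment_session(manual_profile(sigma_p = 4),
                                   cohort_config(), seed = 5)
  agg <- aggregate_2afc(ses)
  fit <- fit_cumulative_gaussian(agg)
  glmfit <- stats::glm(cbind(k, n - k) ~ deviation, data = agg,
                       family = binomial("probit"))
  sigma_glm <- 1 / coef(glmfit)[["deviation"]]
  mu_glm <- -coef(glmfit)[["(Intercept)"]] * sigma_glm
  expect_equal(fit$sigma, sigma_glm, tolerance = 1e-3)
  expect_equal(fit$mu, mu_glm, tolerance = 1e-3)
})

test_that("degenerate sessions end on a sigma bound with converged = FALSE", {
  dev <- c(-8, -6, -4, -2, 2, 4, 6, 8)
  flat <- data.frame(deviation = dev, k = 5, n = 10)
  f1 <- fit_cumulative_gaussian(flat)
  expect_equal(f1$sigma, 50)
  expect_false(f1$converged)

  step <- data.frame(deviation = dev, k = c(0, 0, 0, 0, 10, 10, 10, 10),
                     n = 10)
  f2 <- fit_cumulative_gaussian(step)
  expect_equal(f2$sigma, 0.1)
  expect_false(f2$converged)
})

test_that("JND equals sigma times the 75% normal quantile", {
  dev <- c(-8, -6, -4, -2, 2, 4, 6, 8)
  n <- 1e5
  for (sig in c(1, 3)) {
    cells <- data.frame(deviation = dev, k = round(n * pnorm(dev / sig)),
                        n = n)
    fit <- fit_cumulative_gaussian(cells)
    expect_equal(jnd_from_fit(fit), sig * qnorm(0.75), tolerance = 1e-2)
    expect_equal(fit$jnd, fit$sigma * qnorm(0.75), tolerance = 1e-9)
  }
  # frozen quantile values: 0.6745 per unit sigma
  expect_equal(1 * qnorm(0.75), 0.6745, tolerance = 1e-4)
  expect_equal(3 * qnorm(0.75), 2.0234, tolerance = 1e-3)
  expect_equal(0.1 * qnorm(0.75), 0.0674, tolerance = 1e-3)
})

test_that("JND is invariant to a horizontal shift of the curve", {
  dev <- c(-8, -6, -4, -2, 2, 4, 6, 8)
  n <- 2e4
  base <- data.frame(deviation = dev, k = round(n * pnorm(dev / 3)), n = n)
  shifted <- base
  shifted$deviation <- shifted$deviation + 3
  f0 <- fit_cumulative_gaussian(base)
  f1 <- fit_cumulative_gaussian(shifted)
  expect_equal(f1$mu - f0$mu, 3, tolerance = 0.05)
  expect_equal(jnd_from_fit(f1), jnd_from_fit(f0), tolerance = 1e-3)
})

test_that("fitting is deterministic for fixed input", {
  ses <- generate_judgment_session(manual_profile(sigma_p = 5),
                                   cohort_config(), seed = 6)
  expect_identical(coef(fit_cumulative_gaussian(ses)),
                   coef(fit_cumulative_gaussian(ses)))
})

test_that("fitted JND recovers the two-percept prediction on average", {
  # For the generative response model, JND -> qnorm(0.75) * sqrt(2) * sigma_p.
  cfg <- cohort_config()
  for (sp in c(2, 5)) {
    pr <- manual_profile(sigma_p = sp)
    jnds <- vapply(1:120, function(s) {
      fit_cumulative_gaussian(generate_judgment_session(pr, cfg, seed = s))$jnd
    }, numeric(1))
    expect_equal(median(jnds), qnorm(0.75) * sqrt(2) * sp,
                 tolerance = 0.10)
  }
})
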