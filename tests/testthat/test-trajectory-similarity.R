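test_that("identical trajectories peak at r = 1, lag 0", {
  t <- seq(0, 10, by = 1 / 250)[-1]
  a <- 40 + 20 * sin(2 * pi * 0.3 * t)
  pk <- xcorr_peak(a, a)
  expect_equal(pk$r, 1, tolerance = 1e-9)
  expect_equal(pk$lag, 0)
})

test_that("a pure delay is recovered exactly within the lag window", {
  t <- seq(0, 10, by = 1 / 250)[-1]
  a <- sin(2 * pi * 0.3 * t) + 0.4 * sin(2 * pi * 0.7 * t + 1)
  delay <- 125                       # 0.5 s at 250 Hz
  b <- c(rep(a[1], delay), a[seq_len(length(a) - delay)])
  pk <- xcorr_peak(a, b, max_lag = 2.5)
  expect_equal(pk$r, 1, tolerance = 1e-6)
  expect_equal(pk$lag, 0.5)
})

test_that("independent white noise has a small peak correlation", {
  set.seed(42)
  a <- rnorm(2500)
  b <- rnorm(2500)
  expect_lt(xcorr_peak(a, b, max_lag = 2.5)$r, 0.2)
})

test_that("the FFT implementation matches the brute-force oracle", {
  set.seed(7)
  for (case in 1:12) {
    n <- sample(40:120, 1)
    a <- cumsum(rnorm(n))            # smooth-ish random walks
    b <- cumsum(rnorm(n))
    L <- sample(3:15, 1)
    fast <- xcorr_peak(a, b, max_lag = L, rate = 1)
    slow <- naive_xcorr_peak(a, b, L)
    expect_equal(fast$r, slow$r, tolerance = 1e-9)
    expect_equal(fast$lag_samples, slow$lag_samples)
  }
})

test_that("peak correlation is invariant to affine rescaling", {
  set.seed(8)
  a <- cumsum(rnorm(500))
  b <- cumsum(rnorm(500))
  p0 <- xcorr_peak(a, b, max_lag = 20, rate = 1)
  p1 <- xcorr_peak(2.5 * a + 7, b, max_lag = 20, rate = 1)
  p2 <- xcorr_peak(a, -0.1 + 0.3 * b, max_lag = 20, rate = 1)
  expect_equal(p1$r, p0$r, tolerance = 1e-9)
  expect_equal(p2$r, p0$r, tolerance = 1e-9)
  # symmetric up to lag negation
  pr <- xcorr_peak(b, a, max_lag = 20, rate = 1)
  expect_equal(pr$r, p0$r, tolerance = 1e-9)
  expect_equal(pr$lag_samples, -p0$lag_samples)
})

test_that("the peak never decreases when the lag window widens", {
  set.seed(9)
  a <- cumsum(rnorm(800))
  b <- cumsum(rnorm(800))
  r <- vapply(c(5, 20, 60, 150), function(L) {
    xcorr_peak(a, b, max_lag = L, rate = 1)$r
  }, numeric(1))
  expect_true(all(diff(r) >= -1e-12))
})

test_that("constant overlaps are skipped or rejected", {
  expect_error(xcorr_peak(rep(1, 100), rnorm(100), max_lag = 10, rate = 1),
               "constant")
})

test_that("zero-lag RMSE matches hand arithmetic", {
  a <- c(10, 20, 30)
  expect_equal(rmse_at_zero_lag(a, a), 0)
  expect_equal(rmse_at_zero_lag(a, a + 2), 2)
  expect_equal(rmse_at_zero_lag(c(0, 0, 0, 0), c(3, -3, 3, -3)), 3)
  expect_error(rmse_at_zero_lag(1:5, 1:4), "equal length")
})

test_that("the improvement index is the post-pre mean difference", {
  expect_equal(improvement_index(0.76, 0.90), 0.14)
  expect_equal(improvement_index(c(0.5, 0.6), c(0.5, 0.6)), 0)
  expect_equal(improvement_index(c(0.2, 0.4), c(0.9, 0.7)), 0.5)
  expect_error(improvement_index(numeric(0), 0.5), "non-empty")
})

test_that("cohort trajectory scoring is internally consistent", {
  co <- simulate_cohort(cohort_config(n_participants = 3, seed = 5))
  sc <- score_trajectories(co)
  expect_equal(nrow(sc), 3)
  expect_equal(sc$improvement, sc$post_mean_r - sc$pre_mean_r)
  expect_true(all(abs(c(sc$pre_mean_r, sc$post_mean_r)) <= 1))
  # recompute one participant's pre mean from raw trajectories
  pre1 <- mean(vapply(co$reproductions[[1]]$pre, function(tr) {
    xcorr_peak(co$target, tr)$r
  }, numeric(1)))
  expect_equal(sc$pre_mean_r[1], pre1)
})
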