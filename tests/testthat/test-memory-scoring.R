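# Build a session table directly from counts, bypassing the generator.
make_session <- function(hits, misses, fas, crs,
                         pos_hits = NULL, pos_n = NULL) {
  if (is.null(pos_hits)) {
    n_present <- hits + misses
    matched <- rep_len(1:3, n_present)
    resp_p <- rep(c("present", "absent"), c(hits, misses))
  } else {
    matched <- rep(1:3, pos_n)
    resp_p <- unlist(lapply(1:3, function(i) {
      rep(c("present", "absent"), c(pos_hits[i], pos_n[i] - pos_hits[i]))
    }))
    n_present <- sum(pos_n)
  }
  n_absent <- fas + crs
  data.frame(
    condition = rep(c("present", "absent"), c(n_present, n_absent)),
    response = c(resp_p, rep(c("present", "absent"), c(fas, crs))),
    matched_position = c(matched, rep(NA_integer_, n_absent)),
    named_position = NA_integer_)
}

test_that("sensitivity and precision follow the printed count formulas", {
  s <- score_memory_session(make_session(25, 5, 10, 20))
  expect_equal(s$hits, 25)
  expect_equal(s$misses, 5)
  expect_equal(s$false_alarms, 10)
  expect_equal(s$correct_rejections, 20)
  expect_equal(s$sensitivity, 0.8333, tolerance = 1e-4)
  expect_equal(s$precision, 0.7143, tolerance = 1e-4)
})

test_that("a perfect session scores 1/1 with zero preference", {
  s <- score_memory_session(make_session(30, 0, 0, 30))
  expect_equal(s$sensitivity, 1)
  expect_equal(s$precision, 1)
  expect_equal(s$preference_index, 0)
})

test_that("per-position sensitivities and the preference index", {
  s <- score_memory_session(make_session(21, 9, 5, 25,
                                         pos_hits = c(9, 7, 5),
                                         pos_n = c(10, 10, 10)))
  expect_equal(s$position_sensitivity, c(0.9, 0.7, 0.5))
  expect_equal(s$preference_index, -0.4)
})

test_that("undefined precision is flagged missing, not zero", {
  s <- score_memory_session(make_session(0, 30, 0, 30))
  expect_true(is.na(s$precision))
  expect_equal(s$sensitivity, 0)
})

test_that("scoring requires both present and absent trials", {
  ses <- make_session(25, 5, 10, 20)
  expect_error(score_memory_session(ses[ses$condition == "absent", ]),
               "no present trials")
  expect_error(score_memory_session(ses[ses$condition == "present", ]),
               "no absent trials")
})

test_that("scores are invariant to trial order", {
  ses <- make_session(22, 8, 12, 18, pos_hits = c(8, 7, 7),
                      pos_n = c(10, 10, 10))
  set.seed(1)
  perm <- ses[sample(nrow(ses)), ]
  expect_equal(score_memory_session(ses), score_memory_session(perm))
})

test_that("d-prime matches a direct normal-quantile computation", {
  expect_equal(d_prime(0.5, 0.5, 30, 30), 0)
  # Z(25/30) - Z(10/30), frozen from qnorm
  expect_equal(d_prime(25 / 30, 10 / 30, 30, 30), 1.39815, tolerance = 1e-3)
  expect_equal(d_prime(25 / 30, 10 / 30, 30, 30),
               qnorm(25 / 30) - qnorm(10 / 30), tolerance = 1e-10)
})

test_that("extreme rates are clipped to 1/(2n) before the quantile", {
  v <- d_prime(1, 0, 30, 30)
  expect_true(is.finite(v))
  expect_equal(v, qnorm(59 / 60) - qnorm(1 / 60), tolerance = 1e-10)
  # asymmetric trial counts use their own n
  expect_equal(d_prime(1, 0, 10, 40), qnorm(19 / 20) - qnorm(1 / 80),
               tolerance = 1e-10)
})

test_that("d-prime is antisymmetric in its rates", {
  for (h in c(0.2, 0.6, 0.9)) for (f in c(0.1, 0.5)) {
    expect_equal(d_prime(h, f, 30, 30), -d_prime(f, h, 30, 30))
  }
  expect_error(d_prime(0.5, 0.5, 0, 30), "positive integer")
})

test_that("cohort-level scoring returns one row per participant", {
  co <- simulate_cohort(cohort_config(n_participants = 4, seed = 3))
  sc <- score_memory_cohort(co$memory)
  expect_equal(nrow(sc), 4)
  expect_equal(sc$hits + sc$misses, rep(30, 4))
  expect_equal(sc$false_alarms + sc$correct_rejections, rep(30, 4))
  expect_equal(sc$preference_index, sc$pos_sens_3 - sc$pos_sens_1)
})
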