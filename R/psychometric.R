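#' Aggregate 2AFC trials into deviation cells
#'
#' Pools a judgment session over the two reference angles and counts, for
#' each signed deviation, how often the test angle was judged "larger".
#'
#' @param trials Data frame with columns `deviation` and `response`
#'   ("larger"/"smaller"), as produced by [generate_judgment_session()].
#' @param by_reference If `TRUE`, keep the references separate (diagnostic
#'   use); the default pools them, matching the definition of the
#'   psychometric function as a function of deviation alone.
#' @return A data frame with columns `deviation`, `k` (count of "larger"),
#'   `n` (trials) and `prop`, ordered by deviation (plus `reference` when
#'   `by_reference = TRUE`).
#' @export
aggregate_2afc <- function(trials, by_reference = FALSE) {
  if (is.null(trials) || nrow(trials) == 0) stopf("no judgment trials to aggregate")
  if (!all(c("deviation", "response") %in% names(trials))) {
    stopf("judgment trials need columns `deviation` and `response`")
  }
  keys <- if (by_reference) c("reference", "deviation") else "deviation"
  agg <- stats::aggregate(
    cbind(k = trials$response == "larger", n = rep(1L, nrow(trials))),
    by = trials[keys], FUN = sum)
  agg <- agg[do.call(order, agg[keys]), , drop = FALSE]
  agg$prop <- agg$k / agg$n
  rownames(agg) <- NULL
  agg
}

#' Fit a cumulative-Gaussian psychometric function
#'
#' Maximum-likelihood Bernoulli fit of
#' `P(respond "larger" | deviation) = pnorm((deviation - mu) / sigma)`
#' to a 2AFC cell table, with `sigma` bounded in `[0.1, 50]` degrees.
#' Degenerate sessions (all responses identical, or no slope information)
#' end on a bound and are reported with `converged = FALSE` rather than
#' raising an error.
#'
#' @param cells Cell table from [aggregate_2afc()] (columns `deviation`,
#'   `k`, `n`), or a raw trial table, which is aggregated first.
#' @param sigma_bounds Lower/upper bound for `sigma` (degrees).
#' @return An object of class `psychfit` with elements `mu`, `sigma`,
#'   `jnd`, `cells`, `logLik` and `converged`.
#' @examples
#' pr <- sample_traits(trait_model(), 1, seed = 1)
#' ses <- generate_judgment_session(pr[1, ], cohort_config(), seed = 3)
#' fit <- fit_cumulative_gaussian(ses)
#' fit
#' @export
fit_cumulative_gaussian <- function(cells, sigma_bounds = c(0.1, 50)) {
  if (!all(c("k", "n") %in% names(cells))) cells <- aggregate_2afc(cells)
  if (nrow(cells) < 2) stopf("need at least two deviation cells to fit")
  x <- cells$deviation
  k <- cells$k
  n <- cells$n
  lo <- log(sigma_bounds[1])
  hi <- log(sigma_bounds[2])

  nll <- function(par) {
    p <- stats::pnorm((x - par[1]) / exp(par[2]))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(k * log(p) + (n - k) * log(1 - p))
  }
  # A few deterministic starts guard against flat or step-like data.
  starts <- list(c(0, log(3)), c(0, log(1)), c(0, log(10)),
                 c(mean(x), log(5)))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, nll, method = "L-BFGS-B",
                   lower = c(-60, lo), upper = c(60, hi),
                   control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stopf("psychometric fit failed on all starts")
  mu <- best$par[1]
  sigma <- exp(best$par[2])
  at_bound <- sigma <= sigma_bounds[1] * (1 + 1e-6) ||
    sigma >= sigma_bounds[2] * (1 - 1e-6)
  structure(list(
    mu = mu, sigma = sigma,
    jnd = sigma * stats::qnorm(0.75),
    cells = cells, logLik = -best$value,
    converged = best$convergence == 0 && !at_bound
  ), class = "psychfit")
}

#' Just-noticeable difference from a psychometric fit
#'
#' Half the distance between the 25% and 75% points of the fitted
#' cumulative Gaussian, `(x75 - x25) / 2`, which for a Gaussian equals
#' `sigma * qnorm(0.75)` (about `0.6745 * sigma`).
#'
#' @param fit A [fit_cumulative_gaussian()] result.
#' @return JND in degrees.
#' @export
jnd_from_fit <- function(fit) {
  stopifnot(inherits(fit, "psychfit"))
  x75 <- fit$mu + fit$sigma * stats::qnorm(0.75)
  x25 <- fit$mu + fit$sigma * stats::qnorm(0.25)
  (x75 - x25) / 2
}

#' @export
print.psychfit <- function(x, ...) {
  cat(sprintf("Cumulative-Gaussian psychometric fit%s\n",
              if (x$converged) "" else " (NOT converged: bound reached)"))
  cat(sprintf("  mu = %.3f deg, sigma = %.3f deg, JND = %.3f deg\n",
              x$mu, x$sigma, x$jnd))
  invisible(x)
}

#' @export
coef.psychfit <- function(object, ...) {
  c(mu = object$mu, sigma = object$sigma, jnd = object$jnd)
}

#' @export
predict.psychfit <- function(object, deviation = NULL, ...) {
  if (is.null(deviation)) deviation <- object$cells$deviation
  stats::pnorm((deviation - object$mu) / object$sigma)
}

#' @export
plot.psychfit <- function(x, ...) {
  d <- x$cells
  plot(d$deviation, d$prop, ylim = c(0, 1), pch = 19,
       xlab = "deviation from reference (deg)",
       ylab = "P(judged larger)", ...)
  xs <- seq(min(d$deviation), max(d$deviation), length.out = 200)
  lines(xs, predict(x, xs))
  abline(h = c(0.25, 0.75), lty = 3, col = "grey60")
  invisible(x)
}

#' Fit every participant's judgment session in a trial table
#'
#' @param judgment_trials Trial table with a `participant_id` column.
#' @return A data frame with one row per participant: `participant_id`,
#'   `mu`, `sigma`, `jnd`, `converged`.
#' @export
fit_acuity_cohort <- function(judgment_trials) {
  ids <- unique(judgment_trials$participant_id)
  rows <- lapply(ids, function(id) {
    f <- fit_cumulative_gaussian(
      judgment_trials[judgment_trials$participant_id == id, ])
    data.frame(participant_id = id, mu = f$mu, sigma = f$sigma, jnd = f$jnd,
               converged = f$converged)
  })
  do.call(rbind, rows)
}
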