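#' Peak normalized cross-correlation between two trajectories
#'
#' Slides one trajectory over the other in integer-sample lags up to
#' `max_lag` seconds and computes, at every lag, the Pearson correlation
#' over the overlapping segment only (both segments re-centred and
#' re-scaled per lag; no zero padding).  Returns the maximum correlation
#' and the lag at which it occurs; the peak over lags deliberately ignores
#' onset-time differences between the two movements.  Ties are broken
#' toward the smallest absolute lag.
#'
#' All lags are evaluated in `O(n log n)` via FFT cross-products plus
#' prefix sums; lags whose overlap is constant (undefined correlation) or
#' shorter than 2 samples are skipped.
#'
#' @param a,b [trajectory()] objects or numeric vectors (equal sampling
#'   rates; `rate` is used for plain vectors).
#' @param max_lag Maximum absolute lag in seconds (default 2.5 s, a
#'   quarter of the standard 10-s trajectory).
#' @param rate Sampling rate for plain numeric inputs (Hz).
#' @return A list with `r` (peak correlation), `lag` (seconds; positive
#'   means `b` is delayed relative to `a`) and `lag_samples`.
#' @examples
#' t <- seq(0, 10, by = 1 / 250)
#' a <- sin(2 * pi * 0.3 * t)
#' b <- sin(2 * pi * 0.3 * (t - 0.5))   # delayed copy
#' xcorr_peak(a, b)[c("r", "lag")]
#' @export
xcorr_peak <- function(a, b, max_lag = 2.5, rate = 250) {
  ra <- traj_rate(a, rate)
  rb <- traj_rate(b, rate)
  if (abs(ra - rb) > 1e-9) stopf("trajectories must share a sampling rate")
  x <- traj_angles(a)
  y <- traj_angles(b)
  na <- length(x)
  nb <- length(y)
  if (na < 2 || nb < 2) stopf("trajectories must have at least 2 samples")
  L <- floor(max_lag * ra)
  L <- min(L, nb - 2, na - 2)
  if (L < 0) stopf("max_lag leaves no admissible lag")
  lags <- -L:L

  # Cross products S_xy(l) = sum_t x[t] * y[t + l] for all lags via FFT.
  m <- stats::nextn(na + nb - 1, 2)
  fx <- stats::fft(c(x, rep(0, m - na)))
  fy <- stats::fft(c(y, rep(0, m - nb)))
  cc <- Re(stats::fft(Conj(fx) * fy, inverse = TRUE)) / m
  # cc[k + 1] = sum_t x[t] y[t + k] for k = 0..  and negative lags wrap.
  s_xy <- cc[ifelse(lags >= 0, lags + 1, m + lags + 1)]

  # Windowed sums of each series via prefix sums.
  cx <- cumsum(x); cx2 <- cumsum(x^2)
  cy <- cumsum(y); cy2 <- cumsum(y^2)
  wsum <- function(cs, from, to) {
    cs[to] - ifelse(from > 1, cs[pmax(from - 1, 1)], 0)
  }

  from_x <- pmax(1, 1 - lags)
  to_x <- pmin(na, nb - lags)
  nwin <- to_x - from_x + 1
  from_y <- from_x + lags
  to_y <- to_x + lags

  sx <- wsum(cx, from_x, to_x);  sx2 <- wsum(cx2, from_x, to_x)
  sy <- wsum(cy, from_y, to_y);  sy2 <- wsum(cy2, from_y, to_y)

  num <- s_xy - sx * sy / nwin
  vx <- sx2 - sx^2 / nwin
  vy <- sy2 - sy^2 / nwin
  ok <- nwin >= 2 & vx > 1e-9 * nwin & vy > 1e-9 * nwin
  if (!any(ok)) stopf("correlation undefined at every admissible lag (constant overlap)")
  r <- rep(NA_real_, length(lags))
  r[ok] <- pmin(pmax(num[ok] / sqrt(vx[ok] * vy[ok]), -1), 1)

  best <- max(r, na.rm = TRUE)
  cand <- which(!is.na(r) & r >= best - 1e-12)
  cand <- cand[order(abs(lags[cand]), lags[cand])][1]
  list(r = r[cand], lag = lags[cand] / ra, lag_samples = lags[cand])
}

#' Root-mean-square error at zero lag
#'
#' `sqrt(mean((a - b)^2))` with no temporal alignment, so timing errors
#' count: the complementary similarity measure to [xcorr_peak()].
#'
#' @param a,b Trajectories or numeric vectors of equal length.
#' @return RMSE in degrees.
#' @examples
#' rmse_at_zero_lag(c(0, 0, 0, 0), c(3, -3, 3, -3))
#' @export
rmse_at_zero_lag <- function(a, b) {
  x <- traj_angles(a)
  y <- traj_angles(b)
  if (length(x) != length(y)) stopf("trajectories must have equal length for zero-lag RMSE")
  sqrt(mean((x - y)^2))
}

#' Learning-improvement index
#'
#' Mean post-learning similarity minus mean pre-learning similarity;
#' positive values mean the reproduction got closer to the target after
#' passive guidance.
#'
#' @param pre,post Numeric vectors of per-trial peak correlations
#'   (nominally 5 each).
#' @return `mean(post) - mean(pre)`.
#' @export
improvement_index <- function(pre, post) {
  if (length(pre) == 0 || length(post) == 0) {
    stopf("pre and post score vectors must be non-empty")
  }
  mean(post) - mean(pre)
}

#' Score all reproductions of a cohort against the target
#'
#' Computes per-trial peak normalized cross-correlation and zero-lag RMSE
#' for every pre- and post-learning reproduction, and the per-participant
#' improvement indices.
#'
#' @param cohort A [simulate_cohort()] (or [read_cohort()]) result.
#' @param max_lag Maximum lag passed to [xcorr_peak()] (seconds).
#' @return A data frame with one row per participant: `participant_id`,
#'   `pre_mean_r`, `post_mean_r`, `improvement`, `pre_mean_rmse`,
#'   `post_mean_rmse`, `improvement_rmse` (pre minus post, so positive =
#'   improvement).
#' @export
score_trajectories <- function(cohort, max_lag = 2.5) {
  stopifnot(inherits(cohort, "prl_cohort"))
  target <- cohort$target
  rows <- lapply(seq_along(cohort$reproductions), function(i) {
    ph <- lapply(c(pre = "pre", post = "post"), function(phase) {
      reps <- cohort$reproductions[[i]][[phase]]
      r <- vapply(reps, function(tr) xcorr_peak(target, tr, max_lag)$r,
                  numeric(1))
      e <- vapply(reps, function(tr) rmse_at_zero_lag(target, tr), numeric(1))
      list(r = r, rmse = e)
    })
    data.frame(participant_id = i,
               pre_mean_r = mean(ph$pre$r), post_mean_r = mean(ph$post$r),
               improvement = improvement_index(ph$pre$r, ph$post$r),
               pre_mean_rmse = mean(ph$pre$rmse),
               post_mean_rmse = mean(ph$post$rmse),
               improvement_rmse = mean(ph$pre$rmse) - mean(ph$post$rmse))
  })
  do.call(rbind, rows)
}
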