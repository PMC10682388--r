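# Independent oracles used to validate the package's estimators.  These are
# deliberately naive implementations kept separate from the package code.

# Brute-force peak normalized cross-correlation: explicit loop over lags.
naive_xcorr_peak <- function(a, b, max_lag_samples) {
  best <- -2
  best_lag <- NA_integer_
  na <- length(a)
  nb <- length(b)
  for (l in -max_lag_samples:max_lag_samples) {
    i <- max(1, 1 - l):min(na, nb - l)
    if (length(i) < 2) next
    r <- suppressWarnings(stats::cor(a[i], b[i + l]))
    if (is.na(r)) next
    if (r > best + 1e-12 ||
        (abs(r - best) <= 1e-12 && abs(l) < abs(best_lag))) {
      best <- r
      best_lag <- l
    }
  }
  list(r = best, lag_samples = best_lag)
}

# Plain biased HSIC statistic (no gamma approximation) for oracle use.
oracle_hsic_stat <- function(x, y) {
  n <- length(x)
  gram <- function(v) {
    d2 <- outer(v, v, `-`)^2
    md <- stats::median(d2[d2 > 0])
    if (!is.finite(md) || md <= 0) md <- 1
    exp(-d2 / md)
  }
  H <- diag(n) - 1 / n
  Kc <- H %*% gram(x) %*% H
  Lc <- H %*% gram(y) %*% H
  sum(Kc * Lc) / n^2
}

# Permutation p-value for HSIC dependence.
perm_hsic_p <- function(x, y, n_perm = 200) {
  s0 <- oracle_hsic_stat(x, y)
  null <- replicate(n_perm, oracle_hsic_stat(x, sample(y)))
  (1 + sum(null >= s0)) / (n_perm + 1)
}

# Exhaustive causal-order oracle: score every permutation by the summed
# pairwise HSIC dependence among the residuals of the fully recursive OLS
# model implied by that order (the true order gives mutually independent
# residuals).  Rows are subsampled for tractability.
exhaustive_lingam_order <- function(X, max_rows = 300) {
  X <- scale(as.matrix(X))
  if (nrow(X) > max_rows) X <- X[seq_len(max_rows), , drop = FALSE]
  p <- ncol(X)
  perms <- all_perms(seq_len(p))
  scores <- vapply(perms, function(ord) {
    E <- X[, ord, drop = FALSE]
    for (k in seq_len(p)[-1]) {
      fit <- stats::lm.fit(E[, seq_len(k - 1), drop = FALSE], X[, ord[k]])
      E[, k] <- fit$residuals
    }
    s <- 0
    for (i in seq_len(p - 1)) for (j in (i + 1):p) {
      s <- s + oracle_hsic_stat(E[, i], E[, j])
    }
    s
  }, numeric(1))
  colnames(X)[perms[[which.min(scores)]]]
}

all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}

# A profile row with directly chosen task parameters, bypassing the trait
# links (for controlled-response tests).
manual_profile <- function(sigma_p = 3, sigma_enc = 4, decay_slope = 0,
                           match_criterion = 6, rho_pre = 0.5,
                           rho_post = 0.8) {
  data.frame(id = 1, A = 0, M = 0, L = 0, sigma_p = sigma_p,
             sigma_enc = sigma_enc, decay_slope = decay_slope,
             match_criterion = match_criterion, rho_pre = rho_pre,
             rho_post = rho_post)
}
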