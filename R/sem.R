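#' Fit a recursive path model by maximum likelihood
#'
#' Maximum-likelihood SEM path analysis of an acyclic directed model over
#' observed variables: the implied covariance
#' `Sigma = (I - B)^-1 Psi (I - B)^-T` (with `B` the path-coefficient
#' matrix and `Psi` the diagonal disturbance covariance) is fitted to the
#' sample covariance of the z-scored data by minimizing the ML
#' discrepancy `log|Sigma| + tr(S Sigma^-1) - log|S| - p`.  For recursive
#' models with independent disturbances the standardized path estimates
#' coincide with per-equation OLS coefficients; the optimizer is started
#' there.  Standard errors come from the inverse information (Hessian of
#' the discrepancy), giving per-path z statistics and two-sided p-values.
#'
#' @param X Data matrix or data frame (z-scored internally).
#' @param edges A two-column matrix or data frame of directed edges
#'   (`from`, `to`) using column names of `X`, or a `lingam_fit` whose
#'   nonzero coefficients define the edges.
#' @return An object of class `sem_path_fit`: `paths` (edge table with
#'   standardized estimate, SE, z, p), `chi_square`, `df`, `fit_indices`
#'   (CFI, TLI, RMSEA, SRMR), `implied_cov`, `sample_cov`, `n`.
#' @examples
#' tr <- sample_traits(trait_model(), 500, seed = 1)
#' fit <- fit_path_model(tr[, c("A", "M", "L")],
#'                       edges = rbind(c("A", "M"), c("M", "L")))
#' fit
#' @export
fit_path_model <- function(X, edges) {
  if (inherits(edges, "lingam_fit")) {
    nz <- which(edges$B != 0, arr.ind = TRUE)
    edges <- cbind(from = colnames(edges$B)[nz[, 2]],
                   to = rownames(edges$B)[nz[, 1]])
  }
  edges <- as.matrix(edges)
  if (ncol(edges) != 2) stopf("`edges` must have two columns (from, to)")
  colnames(edges) <- c("from", "to")
  X <- as.matrix(X)
  vars <- colnames(X)
  if (is.null(vars)) stopf("X must have column names")
  if (!all(edges %in% vars)) stopf("edge endpoints must be columns of X")
  if (nrow(edges) > 0 && is_cyclic(edges, vars)) stopf("the path model must be acyclic")
  n <- nrow(X)
  p <- ncol(X)
  n_par <- nrow(edges) + p
  if (n <= n_par) stopf("need more observations than free parameters")
  Z <- scale(X)
  S <- stats::cov(Z)
  if (rcond_psd(S) < 1e-12) stopf("singular sample covariance")

  ne <- nrow(edges)
  build_sigma <- function(theta) {
    B <- matrix(0, p, p, dimnames = list(vars, vars))
    if (ne > 0) {
      for (k in seq_len(ne)) B[edges[k, "to"], edges[k, "from"]] <- theta[k]
    }
    Psi <- diag(exp(theta[ne + seq_len(p)]), p)
    IB <- solve(diag(p) - B)
    IB %*% Psi %*% t(IB)
  }
  fml <- function(theta) {
    Sg <- build_sigma(theta)
    dt <- determinant(Sg, logarithm = TRUE)
    if (dt$sign <= 0) return(1e10)
    as.numeric(dt$modulus) + sum(diag(S %*% solve(Sg))) -
      as.numeric(determinant(S, logarithm = TRUE)$modulus) - p
  }

  # Start at the per-equation OLS solution (the exact ML optimum for
  # recursive models with independent disturbances).
  theta0 <- numeric(ne + p)
  psi0 <- diag(S) * (n - 1) / n
  if (ne > 0) {
    for (v in unique(edges[, "to"])) {
      pa <- edges[edges[, "to"] == v, "from"]
      fitv <- stats::lm.fit(Z[, pa, drop = FALSE], Z[, v])
      for (k in which(edges[, "to"] == v)) {
        theta0[k] <- fitv$coefficients[edges[k, "from"]]
      }
      psi0[v] <- sum(fitv$residuals^2) / n
    }
  }
  theta0[ne + seq_len(p)] <- log(pmax(psi0, 1e-8))

  opt <- stats::optim(theta0, fml, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  theta <- opt$par
  Sigma <- build_sigma(theta)
  Fmin <- fml(theta)
  chi2 <- max((n - 1) * Fmin, 0)
  df <- p * (p + 1) / 2 - n_par

  # Standard errors: asymptotic covariance = (2/(n-1)) * H^-1.
  H <- stats::optimHess(theta, fml)
  se <- rep(NA_real_, ne)
  cov_theta <- tryCatch(2 / (n - 1) * solve(H), error = function(e) NULL)
  if (!is.null(cov_theta)) {
    d <- diag(cov_theta)[seq_len(ne)]
    se <- ifelse(d > 0, sqrt(d), NA_real_)
  }

  # Standardize paths by the implied SDs of the connected variables.
  sds <- sqrt(diag(Sigma))
  est_std <- numeric(ne)
  if (ne > 0) {
    for (k in seq_len(ne)) {
      est_std[k] <- theta[k] * sds[edges[k, "from"]] / sds[edges[k, "to"]]
    }
  }
  zstat <- theta[seq_len(ne)] / se
  paths <- data.frame(from = edges[, "from"], to = edges[, "to"],
                      estimate = theta[seq_len(ne)],
                      std_estimate = est_std, se = se, z = zstat,
                      p = 2 * stats::pnorm(-abs(zstat)),
                      row.names = NULL, stringsAsFactors = FALSE)

  # Independence baseline for the incremental fit indices.
  base_F <- fml_indep(S, p)
  chi_base <- (n - 1) * base_F
  df_base <- p * (p - 1) / 2
  fi <- fit_indices(S, Sigma, n, df, chi_baseline = chi_base,
                    df_baseline = df_base)

  structure(list(paths = paths, chi_square = chi2, df = df,
                 fit_indices = fi, implied_cov = Sigma, sample_cov = S,
                 n = n, converged = opt$convergence == 0),
            class = "sem_path_fit")
}

fml_indep <- function(S, p) {
  Sg <- diag(diag(S), p)
  as.numeric(determinant(Sg, logarithm = TRUE)$modulus) +
    sum(diag(S %*% solve(Sg))) -
    as.numeric(determinant(S, logarithm = TRUE)$modulus) - p
}

is_cyclic <- function(edges, vars) {
  adj <- matrix(FALSE, length(vars), length(vars),
                dimnames = list(vars, vars))
  for (k in seq_len(nrow(edges))) adj[edges[k, "from"], edges[k, "to"]] <- TRUE
  # Kahn's algorithm.
  indeg <- colSums(adj)
  queue <- vars[indeg == 0]
  seen <- 0
  indeg2 <- indeg
  while (length(queue) > 0) {
    v <- queue[1]
    queue <- queue[-1]
    seen <- seen + 1
    out <- vars[adj[v, ]]
    for (w in out) {
      indeg2[w] <- indeg2[w] - 1
      if (indeg2[w] == 0) queue <- c(queue, w)
    }
  }
  seen < length(vars)
}

rcond_psd <- function(S) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  min(ev) / max(ev)
}

#' Goodness-of-fit indices for a covariance-structure model
#'
#' Computes the four conventional indices from the ML discrepancy: the
#' comparative fit index (CFI) and Tucker-Lewis index (TLI) against the
#' independence baseline, the root-mean-square error of approximation
#' (RMSEA), and the standardized root-mean-square residual (SRMR).  A
#' saturated model (`df = 0`) reports CFI = 1 and RMSEA = 0 by
#' convention.
#'
#' @param sample_cov,implied_cov Sample and model-implied covariance
#'   matrices.
#' @param n Sample size.
#' @param df Model degrees of freedom.
#' @param chi_baseline,df_baseline Chi-square and df of the independence
#'   baseline model.
#' @return Named numeric vector: `chi_square`, `CFI`, `TLI`, `RMSEA`,
#'   `SRMR`.
#' @export
fit_indices <- function(sample_cov, implied_cov, n, df,
                        chi_baseline, df_baseline) {
  S <- as.matrix(sample_cov)
  Sg <- as.matrix(implied_cov)
  p <- ncol(S)
  Fv <- as.numeric(determinant(Sg, logarithm = TRUE)$modulus) +
    sum(diag(S %*% solve(Sg))) -
    as.numeric(determinant(S, logarithm = TRUE)$modulus) - p
  chi <- max((n - 1) * Fv, 0)

  d_model <- max(chi - df, 0)
  no_base <- is.na(chi_baseline) || is.na(df_baseline)
  d_base <- if (no_base) NA_real_ else max(chi_baseline - df_baseline, 0)
  cfi <- if (df == 0) 1 else if (no_base) NA_real_ else {
    1 - d_model / max(d_base, d_model, .Machine$double.eps)
  }
  tli <- if (df == 0) 1 else if (no_base || df_baseline == 0) NA_real_ else {
    num <- chi_baseline / df_baseline - chi / df
    den <- chi_baseline / df_baseline - 1
    if (abs(den) < .Machine$double.eps) 1 else num / den
  }
  rmsea <- if (df == 0) 0 else sqrt(max(chi - df, 0) / (df * (n - 1)))
  Ds <- diag(1 / sqrt(diag(S)))
  res <- Ds %*% S %*% Ds - Ds %*% Sg %*% Ds
  srmr <- sqrt(mean(res[lower.tri(res, diag = TRUE)]^2))
  c(chi_square = chi, CFI = cfi, TLI = tli, RMSEA = rmsea, SRMR = srmr)
}

#' @export
print.sem_path_fit <- function(x, digits = 3, ...) {
  cat("Path model (ML)\n")
  if (nrow(x$paths) > 0) {
    for (k in seq_len(nrow(x$paths))) {
      r <- x$paths[k, ]
      cat(sprintf("  %s -> %s : %+.*f (se %.3f, z = %.2f, p = %.3g)\n",
                  r$from, r$to, digits, r$std_estimate, r$se, r$z, r$p))
    }
  } else {
    cat("  (no paths)\n")
  }
  cat(sprintf("  chi^2(%d) = %.3f | CFI %.3f | TLI %.3f | RMSEA %.3f | SRMR %.3f\n",
              x$df, x$chi_square, x$fit_indices["CFI"], x$fit_indices["TLI"],
              x$fit_indices["RMSEA"], x$fit_indices["SRMR"]))
  invisible(x)
}

#' @export
coef.sem_path_fit <- function(object, ...) {
  stats::setNames(object$paths$std_estimate,
                  paste(object$paths$from, "->", object$paths$to))
}
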