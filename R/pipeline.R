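#' Join the three scoring stages into one metrics table
#'
#' Scores every participant's memory session ([score_memory_cohort()]),
#' judgment session ([fit_acuity_cohort()]) and trajectory reproductions
#' ([score_trajectories()]) and joins them into one row per participant.
#' Participants missing a task are listed in the `exclusions` attribute
#' rather than silently dropped; degenerate metrics (undefined precision,
#' unconverged psychometric fit) stay in the table flagged as such.
#'
#' @param cohort A [simulate_cohort()] or [read_cohort()] result.
#' @param max_lag Lag window for [xcorr_peak()] (seconds).
#' @return A data frame with one row per participant: signal-detection
#'   metrics, `jnd` (+ fit diagnostics), trajectory metrics and an
#'   `incomplete` flag.  Attribute `exclusions` names participants with a
#'   missing task.
#' @export
compute_participant_metrics <- function(cohort, max_lag = 2.5) {
  stopifnot(inherits(cohort, "prl_cohort"))
  ids <- cohort$traits$id %||% unique(cohort$memory$participant_id)
  mem <- score_memory_cohort(cohort$memory)
  acu <- fit_acuity_cohort(cohort$judgment)
  trj <- score_trajectories(cohort, max_lag = max_lag)
  out <- merge(merge(mem, acu, by = "participant_id", all = TRUE),
               trj, by = "participant_id", all = TRUE)
  out <- out[order(out$participant_id), ]
  rownames(out) <- NULL
  missing_any <- !(ids %in% mem$participant_id) |
    !(ids %in% acu$participant_id) | !(ids %in% trj$participant_id)
  out$incomplete <- is.na(out$sensitivity) | is.na(out$jnd) |
    is.na(out$improvement) | is.na(out$precision) | !out$converged
  attr(out, "exclusions") <- ids[missing_any]
  out
}

#' Pearson correlation with a t-distribution p-value
#'
#' @param x,y Numeric vectors of equal length (>= 3), complete cases.
#' @return A list with `r`, `p` (two-sided, `n - 2` df) and `n`.
#' @export
correlation_with_p <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stopf("need at least 3 complete pairs")
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) {
    stopf("correlation undefined: an input has zero variance")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Paired t-test on pre/post scores
#'
#' @param pre,post Numeric vectors of equal length (>= 2).
#' @return A list with `t`, `df` (`n - 1`) and the two-sided `p`.
#' @export
paired_t_test <- function(pre, post) {
  if (length(pre) != length(post)) stopf("pre and post must have equal length")
  if (length(pre) < 2) stopf("need at least 2 pairs")
  d <- post - pre
  if (stats::sd(d) < 1e-12) stopf("paired t undefined: constant differences")
  tt <- stats::t.test(post, pre, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Serial-position (chronological) correlation analysis
#'
#' Correlates the per-position memory sensitivities (position 1 = oldest
#' item) and the memory-preference index with the learning-improvement
#' index across participants.
#'
#' @param metrics A [compute_participant_metrics()] table.
#' @return A data frame with one row per predictor (`pos_sens_1..3`,
#'   `preference_index`) and columns `r`, `p`, `n`.
#' @export
chronological_analysis <- function(metrics) {
  preds <- c("pos_sens_1", "pos_sens_2", "pos_sens_3", "preference_index")
  if (!all(c(preds, "improvement") %in% names(metrics))) {
    stopf("metrics table lacks position sensitivities or improvement")
  }
  do.call(rbind, lapply(preds, function(v) {
    ct <- correlation_with_p(metrics[[v]], metrics$improvement)
    data.frame(predictor = v, r = ct$r, p = ct$p, n = ct$n)
  }))
}

#' Run the full study pipeline on a simulated cohort
#'
#' Simulates a cohort, scores all three tasks, computes the cohort
#' summary statistics, the pre/post paired t-test, the correlation
#' analyses (overall and chronological), the DirectLiNGAM causal graph
#' over the standardized triple (JND, memory sensitivity, improvement)
#' with bootstrap edge probabilities and assumption checks, and the SEM
#' re-fit of the selected graph.
#'
#' @param config A [cohort_config()].
#' @param model A [trait_model()].
#' @param links A [trait_links()].
#' @param n_resamples Bootstrap resamples for the causal stage.
#' @param out Optional directory; when given, `report.json`,
#'   `participant_metrics.csv`, `memory_scores.csv`, `acuity.csv`,
#'   `learning_scores.csv`, `causal_graph.json` and `causal_graph.dot`
#'   are written there.
#' @return An object of class `study_report` (a list; see elements
#'   `summary`, `paired_t`, `correlations`, `chronological`, `causal`,
#'   `sem`, `provenance`).
#' @examples
#' \donttest{
#' rep <- run_study(cohort_config(n_participants = 30, seed = 1),
#'                  n_resamples = 50)
#' rep
#' }
#' @export
run_study <- function(config = cohort_config(), model = trait_model(),
                      links = trait_links(), n_resamples = 3000,
                      out = NULL) {
  if (config$n_participants <= 3) {
    stopf("causal stage needs more participants than variables (have %d)",
          config$n_participants)
  }
  cohort <- simulate_cohort(config, model, links)
  metrics <- compute_participant_metrics(cohort)

  num_cols <- c("sensitivity", "precision", "d_prime", "jnd",
                "pre_mean_r", "post_mean_r", "improvement",
                "pre_mean_rmse", "post_mean_rmse",
                "pos_sens_1", "pos_sens_2", "pos_sens_3", "preference_index")
  summary_tab <- data.frame(
    metric = num_cols,
    mean = vapply(num_cols, function(v) mean(metrics[[v]], na.rm = TRUE),
                  numeric(1)),
    sd = vapply(num_cols, function(v) stats::sd(metrics[[v]], na.rm = TRUE),
                numeric(1)),
    row.names = NULL)

  paired <- paired_t_test(metrics$pre_mean_r, metrics$post_mean_r)
  cors <- do.call(rbind, lapply(
    c("sensitivity", "precision", "d_prime", "jnd"), function(v) {
      ct <- correlation_with_p(metrics[[v]], metrics$improvement)
      data.frame(predictor = v, r = ct$r, p = ct$p, n = ct$n)
    }))
  chron <- chronological_analysis(metrics)

  causal_vars <- c("jnd", "sensitivity", "improvement")
  Xc <- as.matrix(metrics[stats::complete.cases(metrics[causal_vars]),
                          causal_vars])
  if (nrow(Xc) <= ncol(Xc)) {
    stopf("causal stage needs more participants than variables (have %d)",
          nrow(Xc))
  }
  Zc <- scale(Xc)
  lingam <- suppressWarnings(direct_lingam(Zc))
  boot <- bootstrap_paths(Zc, n_resamples = n_resamples,
                          seed = substream_seed(config$seed, 0L, 99L))
  assumptions <- check_exogenous_assumptions(lingam)
  sem <- if (sum(lingam$B != 0) > 0) {
    fit_path_model(Zc, lingam)
  } else {
    NULL
  }

  report <- structure(list(
    summary = summary_tab,
    paired_t = paired,
    correlations = cors,
    chronological = chron,
    causal = list(fit = lingam, bootstrap = boot,
                  assumptions = assumptions),
    sem = sem,
    metrics = metrics,
    provenance = list(
      seed = config$seed, n_participants = config$n_participants,
      n_resamples = n_resamples,
      multiple_testing = "none (unadjusted r/p values reported)",
      package_version = as.character(utils::packageVersion("propriolearn")))
  ), class = "study_report")

  if (!is.null(out)) write_study_report(report, cohort, out)
  report
}

write_study_report <- function(report, cohort, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  m <- report$metrics
  utils::write.csv(m, file.path(out, "participant_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(m[, c("participant_id", "hits", "misses", "false_alarms",
                         "correct_rejections", "sensitivity", "precision",
                         "d_prime", "pos_sens_1", "pos_sens_2", "pos_sens_3",
                         "preference_index")],
                   file.path(out, "memory_scores.csv"), row.names = FALSE)
  utils::write.csv(m[, c("participant_id", "mu", "sigma", "jnd", "converged")],
                   file.path(out, "acuity.csv"), row.names = FALSE)
  utils::write.csv(m[, c("participant_id", "pre_mean_r", "post_mean_r",
                         "improvement", "pre_mean_rmse", "post_mean_rmse")],
                   file.path(out, "learning_scores.csv"), row.names = FALSE)
  fit <- report$causal$fit
  graph <- list(order = fit$order, B = fit$B,
                edge_probability = report$causal$bootstrap$edge_probability,
                graph_probability = report$causal$bootstrap$graph_probability,
                independence = report$causal$assumptions$independence,
                normality = report$causal$assumptions$normality)
  jsonlite::write_json(graph, file.path(out, "causal_graph.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  causal_graph_dot(fit, file.path(out, "causal_graph.dot"),
                   boot = report$causal$bootstrap)
  rep_json <- list(
    summary = report$summary, paired_t = report$paired_t,
    correlations = report$correlations, chronological = report$chronological,
    sem = if (!is.null(report$sem)) {
      list(paths = report$sem$paths, chi_square = report$sem$chi_square,
           df = report$sem$df, fit_indices = as.list(report$sem$fit_indices))
    },
    provenance = report$provenance)
  jsonlite::write_json(rep_json, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out)
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report (synthetic cohort)\n")
  cat(sprintf("  participants: %d (seed %d)\n",
              x$provenance$n_participants, x$provenance$seed))
  s <- x$summary
  for (v in c("sensitivity", "precision", "d_prime", "jnd", "improvement")) {
    r <- s[s$metric == v, ]
    cat(sprintf("  %-12s mean %.3f (sd %.3f)\n", v, r$mean, r$sd))
  }
  cat(sprintf("  pre vs post peak r: t(%d) = %.3f, p = %.3g\n",
              x$paired_t$df, x$paired_t$t, x$paired_t$p))
  cat("  correlations with improvement:\n")
  for (k in seq_len(nrow(x$correlations))) {
    r <- x$correlations[k, ]
    cat(sprintf("    %-12s r = %+.3f (p = %.3g)\n", r$predictor, r$r, r$p))
  }
  cat("  causal graph: order",
      paste(x$causal$fit$order, collapse = " -> "), "\n")
  invisible(x)
}
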