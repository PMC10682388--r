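#' Signal-detection scoring of a recognition-memory session
#'
#' Classifies every trial of a present/absent recognition session into
#' hits, misses, false alarms and correct rejections, and derives the
#' standard signal-detection summaries: sensitivity `hit / (hit + miss)`,
#' precision `hit / (hit + false alarm)`, and d-prime
#' `Z(hit rate) - Z(false-alarm rate)`.  Per-serial-position sensitivity
#' (position 1 = oldest item, 3 = most recent) and the memory-preference
#' index `sensitivity(position 3) - sensitivity(position 1)` are also
#' returned; negative preference values indicate better memory for older
#' items.
#'
#' A present-trial "hit" requires only a correct "present" response;
#' naming the wrong matched position does not cancel it.  The stricter
#' reading (response and named position both correct) is reported
#' separately as `position_naming_accuracy`.
#'
#' @param trials A data frame with columns `condition`
#'   ("present"/"absent"), `response` ("present"/"absent"),
#'   `matched_position` (1--3 or `NA`) and optionally `named_position`, as
#'   produced by [generate_memory_session()].
#' @return An object of class `memory_score`: a list with counts (`hits`,
#'   `misses`, `false_alarms`, `correct_rejections`), `sensitivity`,
#'   `precision` (`NA` when `hits + false_alarms = 0`), `d_prime`,
#'   `position_sensitivity` (length 3), `preference_index` and
#'   `position_naming_accuracy`.
#' @examples
#' pr <- sample_traits(trait_model(), 1, seed = 1)
#' ses <- generate_memory_session(pr[1, ], cohort_config(), seed = 2)
#' score_memory_session(ses)
#' @export
score_memory_session <- function(trials) {
  req <- c("condition", "response", "matched_position")
  if (!all(req %in% names(trials))) {
    stopf("memory trials need columns: %s", paste(req, collapse = ", "))
  }
  present <- trials$condition == "present"
  absent <- trials$condition == "absent"
  if (!any(present)) stopf("cannot score a session with no present trials")
  if (!any(absent)) stopf("cannot score a session with no absent trials")
  said_present <- trials$response == "present"

  hits <- sum(present & said_present)
  misses <- sum(present & !said_present)
  fas <- sum(absent & said_present)
  crs <- sum(absent & !said_present)

  sensitivity <- hits / (hits + misses)
  precision <- if (hits + fas > 0) hits / (hits + fas) else NA_real_
  dp <- d_prime(hits / (hits + misses), fas / (fas + crs),
                n_present = hits + misses, n_absent = fas + crs)

  pos_sens <- vapply(1:3, function(p) {
    idx <- present & trials$matched_position %in% p
    if (!any(idx)) NA_real_ else mean(said_present[idx])
  }, numeric(1))
  naming <- if ("named_position" %in% names(trials)) {
    vapply(1:3, function(p) {
      idx <- present & trials$matched_position %in% p
      if (!any(idx)) NA_real_ else {
        mean(said_present[idx] & trials$named_position[idx] %in% p)
      }
    }, numeric(1))
  } else {
    rep(NA_real_, 3)
  }

  structure(list(
    hits = hits, misses = misses, false_alarms = fas,
    correct_rejections = crs,
    sensitivity = sensitivity, precision = precision, d_prime = dp,
    position_sensitivity = pos_sens,
    preference_index = pos_sens[3] - pos_sens[1],
    position_naming_accuracy = naming
  ), class = "memory_score")
}

#' @export
print.memory_score <- function(x, ...) {
  cat(sprintf("Recognition-memory score: %d hits, %d misses, %d FAs, %d CRs\n",
              x$hits, x$misses, x$false_alarms, x$correct_rejections))
  cat(sprintf("  sensitivity %.3f | precision %s | d' %.3f\n",
              x$sensitivity,
              ifelse(is.na(x$precision), "NA", sprintf("%.3f", x$precision)),
              x$d_prime))
  cat(sprintf("  position sensitivity %s | preference %+.3f\n",
              paste(sprintf("%.2f", x$position_sensitivity), collapse = "/"),
              x$preference_index))
  invisible(x)
}

#' d-prime with extreme-rate correction
#'
#' Signal-detection discriminability `Z(hit rate) - Z(false-alarm rate)`.
#' Rates of exactly 0 or 1 are replaced by `1/(2n)` and `1 - 1/(2n)`
#' (with the condition's own trial count) before the normal-quantile
#' transform, so the statistic is always finite.
#'
#' @param hit_rate,fa_rate Proportions in `[0, 1]`.
#' @param n_present,n_absent Trial counts behind each rate.
#' @return A finite numeric scalar.
#' @examples
#' d_prime(25 / 30, 10 / 30, 30, 30)
#' @export
d_prime <- function(hit_rate, fa_rate, n_present, n_absent) {
  assert_count(n_present, "n_present")
  assert_count(n_absent, "n_absent")
  assert_number(hit_rate, "hit_rate", 0, 1)
  assert_number(fa_rate, "fa_rate", 0, 1)
  clip <- function(r, n) min(max(r, 1 / (2 * n)), 1 - 1 / (2 * n))
  stats::qnorm(clip(hit_rate, n_present)) - stats::qnorm(clip(fa_rate, n_absent))
}

#' Score every participant's memory session in a trial table
#'
#' @param memory_trials Trial table with a `participant_id` column
#'   (`memory` element of a [simulate_cohort()] result or
#'   `memory_trials.csv`).
#' @return A data frame with one row per participant and all
#'   [score_memory_session()] fields.
#' @export
score_memory_cohort <- function(memory_trials) {
  ids <- unique(memory_trials$participant_id)
  rows <- lapply(ids, function(id) {
    s <- score_memory_session(memory_trials[memory_trials$participant_id == id, ])
    data.frame(participant_id = id, hits = s$hits, misses = s$misses,
               false_alarms = s$false_alarms,
               correct_rejections = s$correct_rejections,
               sensitivity = s$sensitivity, precision = s$precision,
               d_prime = s$d_prime,
               pos_sens_1 = s$position_sensitivity[1],
               pos_sens_2 = s$position_sensitivity[2],
               pos_sens_3 = s$position_sensitivity[3],
               preference_index = s$preference_index)
  })
  do.call(rbind, rows)
}
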