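#' Cohort and task-design configuration
#'
#' Collects the task-design constants of the three behavioural tasks and
#' the trajectory generator.  The defaults reproduce the study design:
#' a 60-trial recognition-memory task (30 present / 30 absent) over the 38
#' elbow angles from 8 to 82 degrees in 2-degree steps with pairwise
#' separations of at least 10 degrees; an 80-trial 2AFC judgment task with
#' reference angles 30 and 50 degrees and signed deviations of 2, 4, 6 and
#' 8 degrees (5 trials per reference-by-deviation cell); and a 10-s target
#' trajectory sampled at 250 Hz, reproduced 5 times before and 5 times
#' after 30 passive guidance repetitions.
#'
#' @param n_participants Number of simulated participants.
#' @param seed Master RNG seed; every participant and task draws from its
#'   own substream derived from this seed.
#' @param memory_trials,memory_present Total and present-condition trial
#'   counts of the recognition task.
#' @param angle_min,angle_max,angle_step Elbow-angle grid (degrees).
#' @param min_separation Minimum absolute angular separation between the
#'   stimulus angles of a trial (degrees).
#' @param judgment_reps Repetitions per (reference x signed deviation) cell.
#' @param references,deviations Reference angles and unsigned deviation
#'   magnitudes of the judgment task (degrees).
#' @param traj_duration Trajectory duration (seconds).
#' @param traj_rate Sampling rate (Hz).
#' @param target_seed Fixed stimulus seed for the shared target trajectory.
#'   The target is part of the task design (one movement for every
#'   participant, equalizing difficulty), so by default it does not vary
#'   with the cohort seed; change it to study a different target.
#' @param reps_pre,reps_post,reps_guidance Reproduction and guidance counts.
#' @param harmonics Number of sinusoids in the target generator (2--4).
#' @param freq_band Frequency band of the sinusoids (Hz).
#' @param amp_range Half-amplitude range of the target waveform (degrees).
#' @param center_range Range of the waveform's central angle (degrees).
#' @param motor_noise_sd SD of the smooth motor noise added to
#'   reproductions (degrees).
#' @return An object of class `prl_cohort_config`.
#' @seealso [simulate_cohort()]
#' @export
cohort_config <- function(n_participants = 21, seed = 1,
                          memory_trials = 60, memory_present = 30,
                          angle_min = 8, angle_max = 82, angle_step = 2,
                          min_separation = 10,
                          judgment_reps = 5,
                          references = c(30, 50),
                          deviations = c(2, 4, 6, 8),
                          traj_duration = 10, traj_rate = 250,
                          target_seed = 424242,
                          reps_pre = 5, reps_post = 5, reps_guidance = 30,
                          harmonics = 3, freq_band = c(0.1, 0.8),
                          amp_range = c(22, 32), center_range = c(36, 44),
                          motor_noise_sd = 2.2) {
  assert_count(n_participants, "n_participants")
  assert_count(memory_trials, "memory_trials")
  assert_count(memory_present, "memory_present")
  if (memory_present >= memory_trials) {
    stopf("memory_present must be smaller than memory_trials")
  }
  grid <- seq(angle_min, angle_max, by = angle_step)
  if (length(grid) < 4) stopf("angle grid too small for three memory angles plus a test angle")
  assert_number(min_separation, "min_separation", lower = 0)
  assert_count(judgment_reps, "judgment_reps")
  assert_number(traj_duration, "traj_duration", lower = 1e-9)
  assert_number(traj_rate, "traj_rate", lower = 1e-9)
  if (harmonics < 0 || harmonics != round(harmonics)) {
    stopf("harmonics must be a non-negative integer")
  }
  if (max(center_range) + max(amp_range) > 90 || min(center_range) - max(amp_range) < 0) {
    stopf("amplitude/center ranges exceed the elbow joint range [0, 90] degrees")
  }
  structure(list(
    n_participants = as.integer(n_participants), seed = as.integer(seed),
    memory_trials = as.integer(memory_trials),
    memory_present = as.integer(memory_present),
    angle_grid = grid, min_separation = min_separation,
    judgment_reps = as.integer(judgment_reps),
    references = references, deviations = deviations,
    traj_duration = traj_duration, traj_rate = traj_rate,
    target_seed = as.integer(target_seed),
    reps_pre = as.integer(reps_pre), reps_post = as.integer(reps_post),
    reps_guidance = as.integer(reps_guidance),
    harmonics = as.integer(harmonics), freq_band = freq_band,
    amp_range = amp_range, center_range = center_range,
    motor_noise_sd = motor_noise_sd
  ), class = "prl_cohort_config")
}

#' @export
print.prl_cohort_config <- function(x, ...) {
  cat("Cohort configuration\n")
  cat(sprintf("  participants : %d (master seed %d)\n", x$n_participants, x$seed))
  cat(sprintf("  memory task  : %d trials (%d present), angles %g..%g step %g, separation >= %g deg\n",
              x$memory_trials, x$memory_present, min(x$angle_grid),
              max(x$angle_grid), diff(x$angle_grid[1:2]), x$min_separation))
  cat(sprintf("  judgment task: %d trials (%d refs x %d deviations x 2 signs x %d reps)\n",
              2 * length(x$references) * length(x$deviations) * x$judgment_reps,
              length(x$references), length(x$deviations), x$judgment_reps))
  cat(sprintf("  trajectories : %g s @ %g Hz; %d pre / %d guidance / %d post\n",
              x$traj_duration, x$traj_rate, x$reps_pre, x$reps_guidance,
              x$reps_post))
  invisible(x)
}
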