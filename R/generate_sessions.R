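#' Simulate one recognition-memory session
#'
#' Generates the 60 trials of the proprioceptive recognition-memory task
#' for one participant and simulates their responses under the stored-trace
#' model.  In each trial three memory angles are drawn from the angle grid
#' with pairwise separations of at least `min_separation`; in present
#' trials the test angle equals one of them (10 trials per serial
#' position), in absent trials it is a new grid angle at least
#' `min_separation` away from every memorized angle.  The participant's
#' stored trace of angle `i` is
#' `angle_i + Normal(0, sigma_enc + decay_slope * (3 - i))` (older items
#' noisier when `decay_slope > 0`), and they respond "present" whenever the
#' closest trace lies within `match_criterion` degrees of the test angle,
#' naming the position of that closest trace.
#'
#' @param profile One row of the data frame returned by [sample_traits()]
#'   (or any list with fields `sigma_enc`, `decay_slope`,
#'   `match_criterion`).
#' @param config A [cohort_config()].
#' @param seed Optional integer seed for this session's RNG substream.
#' @return A data frame with one row per trial: `trial`, `angle1`,
#'   `angle2`, `angle3`, `test_angle`, `condition` ("present"/"absent"),
#'   `matched_position` (1--3, `NA` in absent trials), `response`,
#'   `named_position` (`NA` when the response is "absent").
#' @examples
#' pr <- sample_traits(trait_model(), 1, seed = 1)
#' ses <- generate_memory_session(pr[1, ], cohort_config(), seed = 2)
#' table(ses$condition)
#' @export
generate_memory_session <- function(profile, config = cohort_config(),
                                    seed = NULL) {
  stopifnot(inherits(config, "prl_cohort_config"))
  sigma_enc <- as.numeric(profile$sigma_enc)
  decay <- as.numeric(profile$decay_slope)
  criterion <- as.numeric(profile$match_criterion)
  if (!is.finite(sigma_enc) || sigma_enc <= 0) stopf("sigma_enc must be > 0")
  with_seed(seed, {
    n_trials <- config$memory_trials
    n_present <- config$memory_present
    grid <- config$angle_grid
    sep <- config$min_separation

    # Balanced matched positions for present trials, pseudo-random order of
    # conditions across the session.
    pos_pool <- rep_len(1:3, n_present)
    condition <- sample(c(rep("present", n_present),
                          rep("absent", n_trials - n_present)))
    matched <- rep(NA_integer_, n_trials)
    matched[condition == "present"] <- sample(pos_pool)

    ang <- matrix(NA_real_, n_trials, 3)
    test <- numeric(n_trials)
    response <- character(n_trials)
    named <- rep(NA_integer_, n_trials)
    trace_sd <- pmax(sigma_enc + decay * (3 - (1:3)), 0.05)
    for (t in seq_len(n_trials)) {
      angles <- sample_separated_angles(grid, 3, sep)
      ang[t, ] <- angles
      if (condition[t] == "present") {
        test[t] <- angles[matched[t]]
      } else {
        ok <- grid[abs(grid - angles[1]) >= sep & abs(grid - angles[2]) >= sep &
                     abs(grid - angles[3]) >= sep]
        if (length(ok) == 0) {
          stopf("no admissible absent-test angle for separation %g on this grid", sep)
        }
        test[t] <- if (length(ok) == 1) ok else sample(ok, 1)
      }
      # Stored-trace response model; noise grows for older items.
      stored <- angles + stats::rnorm(3, 0, trace_sd)
      dist <- abs(test[t] - stored)
      if (min(dist) < criterion) {
        response[t] <- "present"
        named[t] <- which.min(dist)
      } else {
        response[t] <- "absent"
      }
    }
    data.frame(trial = seq_len(n_trials), angle1 = ang[, 1], angle2 = ang[, 2],
               angle3 = ang[, 3], test_angle = test, condition = condition,
               matched_position = matched, response = response,
               named_position = named)
  })
}

# Draw `k` angles from `grid` with pairwise separations >= sep, by rejection.
sample_separated_angles <- function(grid, k, sep, max_tries = 1000) {
  for (i in seq_len(max_tries)) {
    a <- sample(grid, k)
    if (k < 2 || min(dist(a)) >= sep) return(a)
  }
  stopf("could not draw %d angles with separation >= %g from the grid after %d tries",
        k, sep, max_tries)
}

#' Simulate one 2AFC judgment session
#'
#' Generates the 80 trials of the proprioceptive judgment task (2
#' references x 8 signed deviations x `judgment_reps` repetitions, in
#' pseudo-random order) and simulates "larger"/"smaller" responses under a
#' two-percept signal-detection model: both the reference and the test
#' angle are perceived with independent Gaussian noise of SD `sigma_p`, so
#' the probability of judging the test larger is
#' `pnorm(deviation / (sqrt(2) * sigma_p))`.
#'
#' @inheritParams generate_memory_session
#' @return A data frame with columns `trial`, `reference`, `deviation`
#'   (signed, degrees) and `response` ("larger"/"smaller").
#' @export
generate_judgment_session <- function(profile, config = cohort_config(),
                                      seed = NULL) {
  stopifnot(inherits(config, "prl_cohort_config"))
  sigma_p <- as.numeric(profile$sigma_p)
  if (!is.finite(sigma_p) || sigma_p <= 0) stopf("sigma_p must be > 0")
  with_seed(seed, {
    cells <- expand.grid(reference = config$references,
                         deviation = c(-config$deviations, config$deviations))
    trials <- cells[rep(seq_len(nrow(cells)), each = config$judgment_reps), ]
    trials <- trials[sample(nrow(trials)), ]
    p_larger <- stats::pnorm(trials$deviation / (sqrt(2) * sigma_p))
    larger <- stats::runif(nrow(trials)) < p_larger
    data.frame(trial = seq_len(nrow(trials)),
               reference = trials$reference,
               deviation = trials$deviation,
               response = ifelse(larger, "larger", "smaller"),
               row.names = NULL)
  })
}

#' Generate a smooth band-limited target trajectory
#'
#' Builds a 10-s elbow-joint target trajectory as a sum of `harmonics`
#' sinusoids with frequencies in `freq_band`, shifted and scaled into the
#' joint range, and tapered with cosine ramps so the movement starts and
#' ends at the home angle (0 degrees).
#'
#' @param config A [cohort_config()].
#' @param seed Optional integer seed.
#' @return A [trajectory()] of `traj_duration * traj_rate` samples.
#' @export
generate_target_trajectory <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "prl_cohort_config"))
  n <- round(config$traj_duration * config$traj_rate)
  with_seed(seed, {
    if (config$harmonics == 0) {
      return(trajectory(rep(0, n), rate = config$traj_rate))
    }
    t <- seq_len(n) / config$traj_rate
    f <- stats::runif(config$harmonics, config$freq_band[1], config$freq_band[2])
    ph <- stats::runif(config$harmonics, 0, 2 * pi)
    aw <- stats::runif(config$harmonics, 0.3, 1)
    w <- colSums(aw * sin(outer(2 * pi * f, t) + ph))
    w <- w / max(abs(w))
    amp <- stats::runif(1, config$amp_range[1], config$amp_range[2])
    center <- stats::runif(1, config$center_range[1], config$center_range[2])
    ang <- center + amp * w
    ang <- ang * taper_window(n, config$traj_rate)
    trajectory(pmin(pmax(ang, 0), 90), rate = config$traj_rate)
  })
}

# Cosine on/off ramps (1.5 s) pulling the trajectory to the home angle.
taper_window <- function(n, rate, ramp_s = 1.5) {
  ramp_n <- min(round(ramp_s * rate), floor(n / 2))
  w <- rep(1, n)
  if (ramp_n > 0) {
    r <- 0.5 - 0.5 * cos(pi * seq_len(ramp_n) / ramp_n)
    w[seq_len(ramp_n)] <- r
    w[n + 1 - seq_len(ramp_n)] <- r
  }
  w
}

#' Simulate one active trajectory reproduction
#'
#' Models a participant's reproduction as a fidelity-weighted mixture of
#' the target and a participant-specific distractor trajectory plus smooth
#' motor noise:
#' `reproduction = rho * target + (1 - rho) * distractor + noise`, with
#' `rho = rho_pre` before and `rho = rho_post` after the passive-guidance
#' block.  The distractor is an independent draw from the target generator
#' held fixed per participant, standing in for whatever movement the
#' participant produces when the instructed trajectory is not retained.
#'
#' @inheritParams generate_memory_session
#' @param target The target [trajectory()].
#' @param phase Either `"pre"` or `"post"`.
#' @param distractor The participant's fixed distractor trajectory; drawn
#'   fresh when omitted.
#' @return A [trajectory()] of the same length and rate as `target`.
#' @export
generate_reproduction <- function(profile, target, phase = c("pre", "post"),
                                  config = cohort_config(), distractor = NULL,
                                  seed = NULL) {
  phase <- match.arg(phase)
  tg <- traj_angles(target)
  rate <- traj_rate(target, config$traj_rate)
  with_seed(seed, {
    if (is.null(distractor)) {
      distractor <- generate_target_trajectory(config)
    }
    dg <- traj_angles(distractor)
    if (length(dg) != length(tg)) stopf("distractor length must match target")
    rho <- if (phase == "pre") as.numeric(profile$rho_pre) else as.numeric(profile$rho_post)
    noise <- smooth_noise(length(tg), rate, config$motor_noise_sd)
    trajectory(rho * tg + (1 - rho) * dg + noise, rate = rate)
  })
}

# Band-limited motor noise: random low-frequency sinusoids scaled to `sd`.
smooth_noise <- function(n, rate, sd, n_comp = 8, f_max = 1.5) {
  if (sd <= 0) return(rep(0, n))
  t <- seq_len(n) / rate
  f <- stats::runif(n_comp, 0.05, f_max)
  ph <- stats::runif(n_comp, 0, 2 * pi)
  a <- 1 / f
  x <- colSums(a * sin(outer(2 * pi * f, t) + ph))
  s <- stats::sd(x)
  if (s < 1e-12) rep(0, n) else x * (sd / s)
}
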