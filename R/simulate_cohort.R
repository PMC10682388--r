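#' Simulate a full behavioural cohort
#'
#' Generates, for every participant, a recognition-memory session, a 2AFC
#' judgment session and a trajectory-learning session (5 pre- and 5
#' post-learning reproductions of a shared target trajectory), all driven
#' by latent traits drawn from a [trait_model()].  Every participant and
#' task uses its own RNG substream derived from the master seed, so the
#' dataset is bit-identical across runs with the same configuration and
#' adding participants never perturbs existing ones.
#'
#' @param config A [cohort_config()]; `config$seed` is the master seed.
#' @param model A [trait_model()] for the latent traits.
#' @param links A [trait_links()] object mapping traits to task parameters.
#' @return An object of class `prl_cohort`: a list with elements
#'   `traits` (latent traits and task parameters, one row per participant),
#'   `memory` and `judgment` (trial tables with a `participant_id` column),
#'   `target` (the shared target [trajectory()]), `reproductions` (per
#'   participant, lists `pre` and `post` of 5 trajectories each), and
#'   `config`/`model`/`links` echoes.
#' @examples
#' co <- simulate_cohort(cohort_config(n_participants = 3, seed = 1))
#' co
#' @export
simulate_cohort <- function(config = cohort_config(), model = trait_model(),
                            links = trait_links()) {
  stopifnot(inherits(config, "prl_cohort_config"),
            inherits(model, "prl_trait_model"))
  master <- config$seed
  n <- config$n_participants
  # One trait substream per participant, so extending the cohort never
  # perturbs the draws of existing participants.
  traits <- do.call(rbind, lapply(seq_len(n), function(i) {
    suppressWarnings(
      sample_traits(model, 1, seed = substream_seed(master, i, 0L),
                    links = links))
  }))
  traits$id <- seq_len(n)
  if (model$noise_family == "gaussian") {
    warning("Gaussian disturbances make the causal order unidentifiable ",
            "for LiNGAM; use a non-Gaussian family for recovery studies.",
            call. = FALSE)
  }
  # The target is a fixed stimulus of the task design, shared by every
  # participant and identical across cohorts (see cohort_config).
  target <- generate_target_trajectory(
    config, seed = substream_seed(config$target_seed, 0L, 4L))
  memory <- vector("list", n)
  judgment <- vector("list", n)
  repro <- vector("list", n)
  for (i in seq_len(n)) {
    pr <- traits[i, ]
    mem <- generate_memory_session(pr, config,
                                   seed = substream_seed(master, i, 1L))
    mem <- cbind(participant_id = i, mem)
    jud <- generate_judgment_session(pr, config,
                                     seed = substream_seed(master, i, 2L))
    jud <- cbind(participant_id = i, jud)
    distractor <- generate_target_trajectory(
      config, seed = substream_seed(master, i, 3L))
    pre <- lapply(seq_len(config$reps_pre), function(r) {
      generate_reproduction(pr, target, "pre", config, distractor,
                            seed = substream_seed(master, i, 10L + r))
    })
    post <- lapply(seq_len(config$reps_post), function(r) {
      generate_reproduction(pr, target, "post", config, distractor,
                            seed = substream_seed(master, i, 30L + r))
    })
    memory[[i]] <- mem
    judgment[[i]] <- jud
    repro[[i]] <- list(pre = pre, post = post)
  }
  structure(list(
    traits = traits,
    memory = do.call(rbind, memory),
    judgment = do.call(rbind, judgment),
    target = target,
    reproductions = repro,
    config = config, model = model, links = links
  ), class = "prl_cohort")
}

#' @export
print.prl_cohort <- function(x, ...) {
  cat(sprintf("<synthetic cohort: %d participants, seed %d>\n",
              x$config$n_participants, x$config$seed))
  cat(sprintf("  memory trials  : %d rows\n", nrow(x$memory)))
  cat(sprintf("  judgment trials: %d rows\n", nrow(x$judgment)))
  cat(sprintf("  trajectories   : target + %d x (%d pre, %d post)\n",
              length(x$reproductions), x$config$reps_pre, x$config$reps_post))
  invisible(x)
}

#' Write a simulated cohort to a directory of plain-text files
#'
#' Lays out `memory_trials.csv`, `judgment_trials.csv`,
#' `latent_traits.csv`, a `trajectories/` directory with `target.csv` and
#' `p<ID>_<phase>_<rep>.csv` files (columns `time_s`, `angle_deg`), and a
#' `cohort_config.yaml` provenance echo.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "prl_cohort"))
  tdir <- file.path(dir, "trajectories")
  dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$memory, file.path(dir, "memory_trials.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$judgment, file.path(dir, "judgment_trials.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$traits, file.path(dir, "latent_traits.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(cohort$target), file.path(tdir, "target.csv"),
                   row.names = FALSE)
  for (i in seq_along(cohort$reproductions)) {
    for (phase in c("pre", "post")) {
      reps <- cohort$reproductions[[i]][[phase]]
      for (r in seq_along(reps)) {
        utils::write.csv(as.data.frame(reps[[r]]),
                         file.path(tdir, sprintf("p%d_%s_%d.csv", i, phase, r)),
                         row.names = FALSE)
      }
    }
  }
  cfg <- cohort$config
  cfg_list <- unclass(cfg)
  yaml::write_yaml(cfg_list, file.path(dir, "cohort_config.yaml"))
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory created by [write_cohort()].
#' @return A `prl_cohort` list (without the generator's internal
#'   distractors; sufficient for all scoring stages).
#' @export
read_cohort <- function(dir) {
  need <- c("memory_trials.csv", "judgment_trials.csv", "latent_traits.csv")
  for (f in need) {
    if (!file.exists(file.path(dir, f))) stopf("missing cohort file: %s", file.path(dir, f))
  }
  cfg_list <- yaml::read_yaml(file.path(dir, "cohort_config.yaml"))
  grid <- cfg_list$angle_grid
  config <- do.call(cohort_config, c(
    cfg_list[c("n_participants", "seed", "memory_trials", "memory_present",
               "min_separation", "judgment_reps", "references", "deviations",
               "traj_duration", "traj_rate", "target_seed", "reps_pre", "reps_post",
               "reps_guidance", "harmonics", "freq_band", "amp_range",
               "center_range", "motor_noise_sd")],
    list(angle_min = min(grid), angle_max = max(grid),
         angle_step = grid[2] - grid[1])))
  traits <- utils::read.csv(file.path(dir, "latent_traits.csv"))
  tdir <- file.path(dir, "trajectories")
  read_traj <- function(path) {
    d <- utils::read.csv(path)
    trajectory(d$angle_deg, rate = config$traj_rate)
  }
  target <- read_traj(file.path(tdir, "target.csv"))
  n <- nrow(traits)
  repro <- lapply(seq_len(n), function(i) {
    list(
      pre = lapply(seq_len(config$reps_pre), function(r) {
        read_traj(file.path(tdir, sprintf("p%d_pre_%d.csv", i, r)))
      }),
      post = lapply(seq_len(config$reps_post), function(r) {
        read_traj(file.path(tdir, sprintf("p%d_post_%d.csv", i, r)))
      })
    )
  })
  structure(list(
    traits = traits,
    memory = utils::read.csv(file.path(dir, "memory_trials.csv")),
    judgment = utils::read.csv(file.path(dir, "judgment_trials.csv")),
    target = target,
    reproductions = repro,
    config = config, model = NULL, links = NULL
  ), class = "prl_cohort")
}
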