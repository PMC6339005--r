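#' RSVP authentication protocol constants
#'
#' The design arithmetic of the registration/login protocol: block and trial
#' structure, stimulus timing, cohort composition and the derived quantities
#' every stage relies on (registration trial count, trials after adjacent-pair
#' averaging, number of subject-level datasets, seconds per authentication).
#'
#' @param n_blocks,trials_per_block registration run structure (20 x 10).
#' @param images_per_trial,image_duration_ms RSVP content of one trial
#'   (10 images at 300 ms).
#' @param n_users cohort of legitimate users (15).
#' @param imposters_per_user matched imposters per user (2: one blind, one
#'   non-blind).
#' @param trials_per_login trials consumed by one authentication attempt (2).
#' @return A list of the inputs plus derived fields `registration_trials`,
#'   `paired_trials`, `trial_duration_s`, `login_duration_s`, `n_datasets`.
#' @export
rsvp_protocol <- function(n_blocks = 20, trials_per_block = 10,
                          images_per_trial = 10, image_duration_ms = 300,
                          n_users = 15, imposters_per_user = 2,
                          trials_per_login = 2) {
  trial_s <- images_per_trial * image_duration_ms / 1000
  list(n_blocks = n_blocks, trials_per_block = trials_per_block,
       images_per_trial = images_per_trial,
       image_duration_ms = image_duration_ms,
       n_users = n_users, imposters_per_user = imposters_per_user,
       trials_per_login = trials_per_login,
       registration_trials = n_blocks * trials_per_block,
       paired_trials = (n_blocks * trials_per_block) %/% 2,
       trial_duration_s = trial_s,
       login_duration_s = trials_per_login * trial_s,
       n_datasets = n_users * (1 + imposters_per_user))
}

# ---- run configuration (YAML) ----------------------------------------------

run_config_defaults <- function() {
  list(
    simulate = list(n_channels = 16, fs = 2400, n_blocks = 20,
                    trials_per_block = 10, images_per_trial = 10,
                    image_duration = 300, noise_exponent = 1,
                    noise_rms = 5, common_mode_rms = 1.5, familiarity = 0.35,
                    seed = 1),
    preprocess = list(passband_hz = 40, stopband_hz = 49, ds_factor = 4,
                      tmin = -200, tmax = 1000, baseline = c(-200, 0),
                      crop = c(0, 1000), pair_average = TRUE),
    hdca = list(window_ms = 100, shrinkage = "auto", lambda = 1e-2,
                threshold = 0.5),
    ga = list(pop_size = 100, p_crossover = 0.85, p_mutation = 0.1,
              max_generations = 50, stall_generations = 10, elitism = 1,
              cv_folds = 5, parallel_workers = 1),
    evaluate = list(folds = 5, seed = 1, trials_per_login = 2))
}

#' Read, validate and resolve a run configuration
#'
#' Reads a YAML run configuration, rejects unknown sections or keys, and
#' fills unset values with the defaults (which equal the protocol's stated
#' operating point: 300 ms images, 100 ms windows, GA population 100 with
#' crossover 0.85 / mutation 0.1, 5 folds, 2400 to 600 Hz). The resolved
#' configuration carries an md5 `hash` attribute so outputs can be stamped.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return Nested named list of resolved parameters.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- run_config_defaults()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    bad_sec <- setdiff(names(user), names(cfg))
    if (length(bad_sec))
      stop("unknown config section(s): ", paste(bad_sec, collapse = ", "))
    for (sec in names(user)) {
      bad <- setdiff(names(user[[sec]]), names(cfg[[sec]]))
      if (length(bad))
        stop("unknown key(s) in '", sec, "': ", paste(bad, collapse = ", "))
      cfg[[sec]][names(user[[sec]])] <- user[[sec]]
    }
  }
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, tmp)
  attr(cfg, "hash") <- unname(tools::md5sum(tmp))
  unlink(tmp)
  cfg
}
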