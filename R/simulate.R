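#' ERP component template
#'
#' A Gaussian-bump model of one event-related potential component (N170, N250,
#' P3a, P3b): a peak at `latency` ms post-stimulus with temporal SD `width` ms,
#' scaled per channel by a fixed scalp `topography`, with class-dependent
#' amplitude and latency. Self-face events use `amplitude_self`; non-self-face
#' events use `amplitude_nonself` and are delayed by `latency_shift_nonself`.
#'
#' @param name component label, e.g. `"P3b"`.
#' @param latency peak latency in ms after stimulus onset (self class).
#' @param width Gaussian SD in ms; must be positive.
#' @param amplitude_self,amplitude_nonself peak amplitude in µV (negative for
#'   the N components).
#' @param latency_shift_nonself extra latency in ms for the non-self class.
#' @param topography numeric per-channel gain in `[-1, 1]`.
#' @return An object of class `erp_template`.
#' @export
erp_template <- function(name, latency, width, amplitude_self,
                         amplitude_nonself, latency_shift_nonself = 0,
                         topography) {
  stopifnot(width > 0, all(abs(topography) <= 1 + 1e-12))
  structure(list(name = name, latency = latency, width = width,
                 amplitude_self = amplitude_self,
                 amplitude_nonself = amplitude_nonself,
                 latency_shift_nonself = latency_shift_nonself,
                 topography = as.numeric(topography)),
            class = "erp_template")
}

topo_from_channels <- function(channel_names, gains) {
  topo <- stats::setNames(numeric(length(channel_names)), channel_names)
  keep <- intersect(names(gains), channel_names)
  topo[keep] <- gains[keep]
  unname(topo)
}

#' Default ERP component set for the face-RSVP paradigm
#'
#' Four Gaussian components reproducing the qualitative self vs non-self
#' contrast of face-evoked ERPs: occipito-temporal N170 and N250 with a small
#' class difference, and parieto-central P3a/P3b carrying most of the
#' self-minus-nonself amplitude gap (concentrated on P3, Pz, P4, Po8), with the
#' non-self P3 delayed by 30 ms. Amplitudes are in µV at the peak channel.
#'
#' @param channel_names montage to build topographies for
#'   (default [default_montage()]).
#' @return List of [erp_template] objects.
#' @export
default_erp_templates <- function(channel_names = default_montage()) {
  list(
    erp_template("N170", latency = 170, width = 20,
                 amplitude_self = -5, amplitude_nonself = -4.5,
                 topography = topo_from_channels(channel_names,
                   c(Po7 = 1, Po8 = 1, Oz = 0.7, P3 = 0.3, P4 = 0.3))),
    erp_template("N250", latency = 250, width = 30,
                 amplitude_self = -4, amplitude_nonself = -3.2,
                 topography = topo_from_channels(channel_names,
                   c(Po7 = 1, Po8 = 1, Oz = 0.6, Cp5 = 0.3, Cp6 = 0.3))),
    erp_template("P3a", latency = 300, width = 50,
                 amplitude_self = 7, amplitude_nonself = 3.5,
                 latency_shift_nonself = 30,
                 topography = topo_from_channels(channel_names,
                   c(Cz = 0.8, Pz = 1, P3 = 0.8, P4 = 0.8, Fz = 0.4,
                     Po8 = 0.5, C3 = 0.4, C4 = 0.4))),
    erp_template("P3b", latency = 450, width = 80,
                 amplitude_self = 8, amplitude_nonself = 4,
                 latency_shift_nonself = 30,
                 topography = topo_from_channels(channel_names,
                   c(Pz = 1, P3 = 0.9, P4 = 0.9, Po8 = 0.6, Po7 = 0.4,
                     Cz = 0.6, Cp5 = 0.4, Cp6 = 0.4))))
}

#' Simulation configuration for the RSVP registration protocol
#'
#' Defaults follow the acquisition protocol the framework targets: 16 channels
#' at 2400 Hz, 20 blocks of 10 trials, each trial a rapid serial presentation
#' of 10 face images at 300 ms per image with exactly one self-face target at a
#' random serial position. Background activity is 1/f ("pink") noise,
#' independent per channel plus a common-mode term.
#'
#' @param n_channels channel count.
#' @param channel_names channel labels (length `n_channels`).
#' @param fs sampling rate, Hz.
#' @param n_blocks,trials_per_block block structure of the registration run.
#' @param images_per_trial images per RSVP trial (one is the target).
#' @param image_duration ms per image.
#' @param noise_exponent spectral slope of the 1/f^a background noise.
#' @param noise_rms per-channel noise RMS, µV.
#' @param common_mode_rms RMS of the shared (common-mode) noise term, µV.
#' @param seed integer seed; fixes both trial timing and noise.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_channels = 16, channel_names = default_montage(),
                       fs = 2400, n_blocks = 20, trials_per_block = 10,
                       images_per_trial = 10, image_duration = 300,
                       noise_exponent = 1, noise_rms = 5,
                       common_mode_rms = 1.5, seed = 1) {
  stopifnot(fs > 0, n_blocks >= 1, trials_per_block >= 1,
            images_per_trial >= 1, image_duration > 0,
            length(channel_names) == n_channels, noise_rms >= 0)
  structure(list(n_channels = n_channels, channel_names = channel_names,
                 fs = fs, n_blocks = n_blocks,
                 trials_per_block = trials_per_block,
                 images_per_trial = images_per_trial,
                 image_duration = image_duration,
                 noise_exponent = noise_exponent, noise_rms = noise_rms,
                 common_mode_rms = common_mode_rms, seed = as.integer(seed)),
            class = "sim_config")
}

# 1/f^a noise, unit RMS, via spectral shaping of white Gaussian noise
pink_noise <- function(n, exponent = 1) {
  if (exponent == 0) {
    x <- stats::rnorm(n)
    return(x / stats::sd(x))
  }
  nfft <- 2^ceiling(log2(n))
  w <- stats::rnorm(nfft)
  W <- stats::fft(w)
  f <- c(1, seq_len(nfft - 1))               # avoid DC blow-up
  f <- pmin(f, nfft - f + 1)                 # symmetric (two-sided spectrum)
  W <- W * f^(-exponent / 2)
  W[1] <- 0
  x <- Re(stats::fft(W, inverse = TRUE))[seq_len(n)]
  x / stats::sd(x)
}

# target serial positions for each trial; shared across a subject triplet
rsvp_timing <- function(config) {
  n_trials <- config$n_blocks * config$trials_per_block
  withr_seed(config$seed, {
    positions <- sample.int(config$images_per_trial, n_trials, replace = TRUE)
  })
  trial_ms <- config$images_per_trial * config$image_duration
  pad_start_ms <- 500
  onset_ms <- pad_start_ms + (seq_len(n_trials) - 1) * trial_ms +
    (positions - 1) * config$image_duration
  total_ms <- pad_start_ms + n_trials * trial_ms + 1500
  list(onset_sample = floor(onset_ms * config$fs / 1000) + 1L,
       n_samples = floor(total_ms * config$fs / 1000),
       positions = positions)
}

# run expr with a private RNG state, restoring the caller's
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  eval.parent(substitute(expr))
}

# class mix: 1 = self amplitudes, 0 = nonself amplitudes/latency shift,
# intermediate values model an imposter familiar with the user's face
template_waveform <- function(tmpl, class_mix, fs, n_pre, n_post) {
  amp <- tmpl$amplitude_nonself +
    class_mix * (tmpl$amplitude_self - tmpl$amplitude_nonself)
  lat <- tmpl$latency + (1 - class_mix) * tmpl$latency_shift_nonself
  t_ms <- (seq(-n_pre, n_post) / fs) * 1000
  amp * exp(-((t_ms - lat)^2) / (2 * tmpl$width^2))
}

#' Simulate a continuous RSVP registration recording
#'
#' Generates background 1/f noise for every channel, then superimposes the ERP
#' component templates at each trial's target (self-face image) onset. The
#' event table contains one event per trial, marking that onset, labelled
#' `"self"` when the recording plays the role of the legitimate user
#' (`class_mix = 1`) and `"nonself"` otherwise. Identical `config` (including
#' seed) and `noise_seed` give bit-identical output.
#'
#' @param config a [sim_config].
#' @param templates list of [erp_template]; topography lengths must equal
#'   `config$n_channels`.
#' @param class_mix scalar in `[0, 1]`: 1 = self-face responses (user role),
#'   0 = non-self responses (imposter role), intermediate = familiar imposter.
#' @param noise_seed seed for the noise only; defaults to `config$seed`. Trial
#'   timing always derives from `config$seed`, so recordings simulated with
#'   different `noise_seed` share their event schedule.
#' @return An [eeg_recording] with `config$n_blocks * config$trials_per_block`
#'   events.
#' @export
simulate_recording <- function(config, templates = default_erp_templates(config$channel_names),
                               class_mix = 1, noise_seed = config$seed) {
  stopifnot(inherits(config, "sim_config"), class_mix >= 0, class_mix <= 1)
  for (tm in templates)
    if (length(tm$topography) != config$n_channels)
      stop("template '", tm$name, "' topography length ",
           length(tm$topography), " != n_channels ", config$n_channels)
  timing <- rsvp_timing(config)
  nc <- config$n_channels; ns <- timing$n_samples
  data <- matrix(0, nc, ns)
  if (config$noise_rms > 0 || config$common_mode_rms > 0) {
    withr_seed(noise_seed, {
      if (config$noise_rms > 0)
        for (ch in seq_len(nc))
          data[ch, ] <- config$noise_rms * pink_noise(ns, config$noise_exponent)
      if (config$common_mode_rms > 0) {
        cm <- config$common_mode_rms * pink_noise(ns, config$noise_exponent)
        data <- data + matrix(cm, nc, ns, byrow = TRUE)
      }
    })
  }
  fs <- config$fs
  n_pre <- 0L
  n_post <- as.integer(ceiling(1.2 * fs))     # template support after onset
  waves <- lapply(templates, template_waveform, class_mix = class_mix,
                  fs = fs, n_pre = n_pre, n_post = n_post)
  for (onset in timing$onset_sample) {
    idx <- (onset - n_pre):(onset + n_post)
    keep <- idx >= 1 & idx <= ns
    for (k in seq_along(templates)) {
      bump <- outer(templates[[k]]$topography, waves[[k]][keep])
      data[, idx[keep]] <- data[, idx[keep]] + bump
    }
  }
  label <- if (class_mix >= 1) "self" else "nonself"
  events <- data.frame(sample = timing$onset_sample,
                       label = rep(label, length(timing$onset_sample)),
                       stringsAsFactors = FALSE)
  eeg_recording(data, fs, config$channel_names, events,
                meta = list(simulated = TRUE, class_mix = class_mix,
                            seed = config$seed, noise_seed = noise_seed,
                            config = unclass(config)))
}

#' Simulate a user and two imposters watching the same RSVP sequence
#'
#' Produces three recordings with a shared trial/target schedule: the legal
#' user (self-face responses), a blind imposter who does not know which face
#' belongs to the user (pure non-self responses), and a non-blind imposter who
#' knows the target face; familiarity gives the latter intermediate ERP
#' amplitudes between the non-self and self responses.
#'
#' @param config a [sim_config].
#' @param templates list of [erp_template].
#' @param familiarity class mix of the non-blind imposter in `[0, 1)`;
#'   0 makes the two imposters statistically identical.
#' @return Named list of [eeg_recording]s: `user`, `imposter_blind`,
#'   `imposter_nonblind`.
#' @export
simulate_subject_triplet <- function(config,
                                     templates = default_erp_templates(config$channel_names),
                                     familiarity = 0.35) {
  stopifnot(familiarity >= 0, familiarity < 1)
  base <- config$seed
  list(
    user = simulate_recording(config, templates, class_mix = 1,
                              noise_seed = base + 101L),
    imposter_blind = simulate_recording(config, templates, class_mix = 0,
                                        noise_seed = base + 202L),
    imposter_nonblind = simulate_recording(config, templates,
                                           class_mix = familiarity,
                                           noise_seed = base + 303L))
}
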