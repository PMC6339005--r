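# Small, fast simulation setups shared across tests. Generating at 600 Hz
# with ds_factor = 1 skips the (slow) 2400 Hz filtering stage while keeping
# every downstream quantity (epoch length 600, 10 windows) identical.

tiny_config <- function(n_blocks = 4, fs = 600, noise_rms = 5,
                        common_mode_rms = 1.5, seed = 1, ...) {
  sim_config(n_blocks = n_blocks, fs = fs, noise_rms = noise_rms,
             common_mode_rms = common_mode_rms, seed = seed, ...)
}

# pooled user + two-imposter epochs ready for hdca()
make_pool <- function(n_blocks = 4, seed = 1, noise_rms = 5,
                      common_mode_rms = 1.5, familiarity = 0.35,
                      pair_average = TRUE, templates = NULL, ...) {
  cfg <- tiny_config(n_blocks = n_blocks, seed = seed, noise_rms = noise_rms,
                     common_mode_rms = common_mode_rms, ...)
  if (is.null(templates)) templates <- default_erp_templates(cfg$channel_names)
  tri <- simulate_subject_triplet(cfg, templates, familiarity = familiarity)
  eps <- lapply(tri, preprocess, ds_factor = 1, pair_average = pair_average)
  bind_epochs(eps$user, eps$imposter_blind, eps$imposter_nonblind)
}

# one flat-topography template with the class effect confined to `channels`
effect_template <- function(channel_names, channels = c("P3", "Pz", "P4"),
                            latency = 400, width = 60, amp_self = 8,
                            amp_nonself = 0) {
  topo <- as.numeric(channel_names %in% channels)
  erp_template("effect", latency = latency, width = width,
               amplitude_self = amp_self, amplitude_nonself = amp_nonself,
               topography = topo)
}

# direct epoch construction (Gaussian-class data, no simulator) for the
# classifier-level tests
gaussian_epochs <- function(n_per_class = 30, n_channels = 4, n_time = 60,
                            fs = 60, effect = 1, seed = 1,
                            effect_channels = 1, effect_window = NULL) {
  set.seed(seed)
  n <- 2 * n_per_class
  data <- array(rnorm(n * n_channels * n_time), c(n, n_channels, n_time))
  labels <- rep(c(1L, 0L), each = n_per_class)
  idx_t <- if (is.null(effect_window)) seq_len(n_time) else effect_window
  for (ch in effect_channels)
    data[labels == 1, ch, idx_t] <- data[labels == 1, ch, idx_t] + effect
  eeg_epochs(data, labels, fs = fs, t0 = 0,
             channel_names = paste0("ch", seq_len(n_channels)))
}
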