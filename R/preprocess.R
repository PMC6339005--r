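#' Epoched EEG data
#'
#' Container for stimulus-locked epochs: a trials x channels x time numeric
#' array (µV), per-trial class labels (1 = self-face / legitimate user,
#' 0 = non-self-face / imposter), the sampling rate and the time of the first
#' sample relative to stimulus onset.
#'
#' @param data numeric array, trials x channels x time.
#' @param labels integer vector (0/1), one per trial.
#' @param fs sampling rate, Hz.
#' @param t0 time of the first sample in ms relative to stimulus onset.
#' @param channel_names channel labels, length `dim(data)[2]`.
#' @param meta named list of provenance metadata.
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, labels, fs, t0, channel_names, meta = list()) {
  stopifnot(length(dim(data)) == 3)
  if (length(labels) != dim(data)[1])
    stop("labels length != trial count")
  if (length(channel_names) != dim(data)[2])
    stop("channel_names length != channel count")
  structure(list(data = data, labels = as.integer(labels), fs = fs, t0 = t0,
                 channel_names = as.character(channel_names), meta = meta),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat("<eeg_epochs> ", d[1], " trials x ", d[2], " channels x ", d[3],
      " samples @ ", x$fs, " Hz, t = [", x$t0, ", ",
      x$t0 + d[3] / x$fs * 1000, ") ms\n", sep = "")
  cat("  labels: ", sum(x$labels == 1), " self / ", sum(x$labels == 0),
      " non-self\n", sep = "")
  invisible(x)
}

#' @export
dim.eeg_epochs <- function(x) dim(x$data)

epoch_times <- function(ep) ep$t0 + (seq_len(dim(ep$data)[3]) - 1) / ep$fs * 1000

# ---- re-referencing --------------------------------------------------------

#' Re-reference a recording
#'
#' By default applies a common average reference: each sample has the
#' instantaneous mean across channels subtracted, so the channel mean of every
#' output sample is zero. Alternatively a precomputed square re-referencing
#' matrix (e.g. a reference-electrode-standardisation operator derived from a
#' head model) can be supplied and is applied as `matrix %*% data`.
#'
#' @param rec an [eeg_recording].
#' @param matrix optional channels x channels transform.
#' @return Re-referenced [eeg_recording].
#' @export
rereference <- function(rec, matrix = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  nc <- nrow(rec$data)
  if (is.null(matrix)) {
    matrix <- diag(nc) - 1 / nc
  } else {
    matrix <- as.matrix(matrix)
    if (!all(dim(matrix) == c(nc, nc)))
      stop("re-referencing matrix must be ", nc, " x ", nc)
  }
  out <- rec
  out$data <- matrix %*% rec$data
  out$meta$rereference <- if (isTRUE(all.equal(matrix, diag(nc) - 1 / nc)))
    "common_average" else "user_matrix"
  out
}

# ---- Chebyshev low-pass (second-order-section cascade) ---------------------

# Analytic Chebyshev type-I low-pass as biquad cascade. Direct-form (b, a)
# polynomials of the needed order (>= 11) are numerically unstable at the
# narrow normalized cutoff this pipeline uses (40 Hz at fs = 2400), so poles
# are computed in closed form and kept factored as second-order sections.
cheby1_sos <- function(order, rp, fc, fs) {
  eps <- sqrt(10^(rp / 10) - 1)
  mu <- asinh(1 / eps) / order
  th <- (2 * seq_len(order) - 1) * pi / (2 * order)
  p_proto <- complex(real = -sinh(mu) * sin(th),
                     imaginary = cosh(mu) * cos(th))
  wc <- 2 * fs * tan(pi * fc / fs)            # prewarped analog cutoff
  p <- (2 * fs + p_proto * wc) / (2 * fs - p_proto * wc)   # bilinear
  isreal <- abs(Im(p)) < 1e-9
  sos <- list()
  for (pp in p[!isreal & Im(p) > 0]) {        # conjugate pairs -> biquads
    a <- c(1, -2 * Re(pp), Mod(pp)^2)
    b <- c(1, 2, 1) * sum(a) / 4              # zeros at z = -1, unit DC gain
    sos[[length(sos) + 1]] <- list(b = b, a = a)
  }
  for (rpole in Re(p[isreal])) {
    a <- c(1, -rpole)
    b <- c(1, 1) * sum(a) / 2
    sos[[length(sos) + 1]] <- list(b = b, a = a)
  }
  if (order %% 2 == 0)                        # even order: DC sits at -rp dB
    sos[[1]]$b <- sos[[1]]$b * 10^(-rp / 20)
  sos
}

#' Design the pipeline's low-pass filter
#'
#' Chebyshev type-I low-pass meeting a 0.5 dB passband ripple at
#' `passband_hz` and at least `rs` dB stopband attenuation at `stopband_hz`
#' (single pass; the zero-phase application squares the magnitude response).
#' The minimum order is taken from [signal::cheb1ord] and bumped to the next
#' odd value so the DC gain is exactly 1. The filter is returned as a cascade
#' of second-order sections for numerical stability.
#'
#' @param fs sampling rate, Hz.
#' @param passband_hz passband edge (default 40).
#' @param stopband_hz stopband edge (default 49).
#' @param rp passband ripple budget in dB for the design check (1 dB; the
#'   design itself uses 0.5 dB so that two passes stay within the budget).
#' @param rs stopband attenuation, dB (default 40).
#' @return An object of class `lowpass_design`: sections, order, parameters.
#' @export
design_lowpass <- function(fs, passband_hz = 40, stopband_hz = 49,
                           rp = 1, rs = 40) {
  if (!(passband_hz < stopband_hz && stopband_hz < fs / 2))
    stop("need passband < stopband < fs/2 (got ", passband_hz, ", ",
         stopband_hz, ", fs = ", fs, ")")
  rp_design <- rp / 2                          # two-pass ripple stays <= rp
  ord <- signal::cheb1ord(passband_hz / (fs / 2), stopband_hz / (fs / 2),
                          Rp = rp_design, Rs = rs)$n
  if (ord %% 2 == 0) ord <- ord + 1            # odd order: exact unity DC gain
  structure(list(sos = cheby1_sos(ord, rp_design, passband_hz, fs),
                 order = ord, fs = fs, passband_hz = passband_hz,
                 stopband_hz = stopband_hz, rp = rp_design, rs = rs),
            class = "lowpass_design")
}

#' Frequency response of a designed low-pass filter
#'
#' @param design a `lowpass_design` from [design_lowpass].
#' @param freqs frequencies in Hz.
#' @return Complex response at `freqs` (single pass).
#' @export
lowpass_response <- function(design, freqs) {
  z <- exp(2i * pi * freqs / design$fs)
  h <- rep(1 + 0i, length(z))
  for (s in design$sos) {
    num <- s$b[1] + s$b[2] / z
    den <- s$a[1] + s$a[2] / z
    if (length(s$b) > 2) num <- num + s$b[3] / z^2
    if (length(s$a) > 2) den <- den + s$a[3] / z^2
    h <- h * num / den
  }
  h
}

# single biquad via compiled stats::filter, initialised at the steady state
# for a constant input x[1] (suppresses start-up transients)
biquad_apply <- function(b, a, x) {
  nlag <- length(b) - 1
  v <- stats::filter(c(rep(x[1], nlag), x), b, method = "convolution",
                     sides = 1)
  v <- as.numeric(v)[-seq_len(nlag)]
  if (length(a) > 1) {
    y0 <- x[1] * sum(b) / sum(a)
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive",
                                  init = rep(y0, length(a) - 1)))
  }
  v
}

sos_filtfilt <- function(sos, x, npad) {
  n <- length(x)
  npad <- min(npad, n - 1)
  # odd reflection padding to suppress edge transients
  xp <- c(2 * x[1] - x[(npad + 1):2], x, 2 * x[n] - x[(n - 1):(n - npad)])
  for (s in sos) xp <- biquad_apply(s$b, s$a, xp)
  xp <- rev(xp)
  for (s in sos) xp <- biquad_apply(s$b, s$a, xp)
  rev(xp)[(npad + 1):(npad + n)]
}

#' Zero-phase low-pass filter a recording
#'
#' Applies the Chebyshev low-pass of [design_lowpass] forward and backward
#' (zero phase, squared magnitude) to every channel, with odd-reflection edge
#' padding.
#'
#' @param rec an [eeg_recording].
#' @param passband_hz,stopband_hz band edges in Hz (defaults 40 / 49).
#' @param design optional precomputed `lowpass_design` (overrides the edges).
#' @return Filtered [eeg_recording].
#' @export
lowpass <- function(rec, passband_hz = 40, stopband_hz = 49, design = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.null(design))
    design <- design_lowpass(rec$fs, passband_hz, stopband_hz)
  npad <- as.integer(ceiling(3 * rec$fs / design$passband_hz))
  out <- rec
  for (ch in seq_len(nrow(rec$data)))
    out$data[ch, ] <- sos_filtfilt(design$sos, rec$data[ch, ], npad)
  out$meta$lowpass <- list(passband_hz = design$passband_hz,
                           stopband_hz = design$stopband_hz,
                           order = design$order, rp = design$rp,
                           rs = design$rs, zero_phase = TRUE)
  out
}

# ---- downsampling ----------------------------------------------------------

#' Downsample by averaging consecutive samples
#'
#' Output sample j is the mean of input samples `[(j-1)*factor + 1, j*factor]`;
#' trailing samples that do not fill a block are dropped. Event indices are
#' mapped by integer division. The default factor of 4 takes 2400 Hz to 600 Hz.
#'
#' @param rec an [eeg_recording].
#' @param factor positive integer block size.
#' @return Downsampled [eeg_recording] with `fs = fs / factor`.
#' @export
downsample_avg <- function(rec, factor = 4) {
  stopifnot(inherits(rec, "eeg_recording"), factor >= 1,
            factor == round(factor))
  factor <- as.integer(factor)
  if (factor > ncol(rec$data)) stop("factor exceeds recording length")
  if (factor == 1L) return(rec)
  m <- ncol(rec$data) %/% factor
  acc <- rec$data[, seq(1, m * factor, by = factor), drop = FALSE]
  for (k in seq_len(factor - 1))
    acc <- acc + rec$data[, seq(1 + k, m * factor, by = factor), drop = FALSE]
  out <- rec
  out$data <- acc / factor
  out$fs <- rec$fs / factor
  if (nrow(rec$events))
    out$events$sample <- (rec$events$sample - 1L) %/% factor + 1L
  out$meta$downsample <- list(factor = factor, fs_out = out$fs)
  out
}

# ---- epoching --------------------------------------------------------------

#' Extract stimulus-locked epochs
#'
#' Cuts one epoch per event over the half-open time window `[tmin, tmax)` ms
#' relative to the event onset. Events whose window would cross a recording
#' edge are dropped with a warning. Labels are 1 for `"self"` events, 0 for
#' `"nonself"`.
#'
#' @param rec an [eeg_recording].
#' @param tmin,tmax window in ms relative to stimulus onset
#'   (defaults -200 / 1000).
#' @param events optional event table overriding `rec$events`.
#' @return An [eeg_epochs] with `round((tmax - tmin) * fs / 1000)` samples per
#'   epoch.
#' @export
extract_epochs <- function(rec, tmin = -200, tmax = 1000, events = rec$events) {
  stopifnot(inherits(rec, "eeg_recording"), tmax > tmin)
  fs <- rec$fs
  offset <- round(tmin * fs / 1000)
  len <- round((tmax - tmin) * fs / 1000)
  starts <- events$sample + offset
  ok <- starts >= 1 & (starts + len - 1) <= ncol(rec$data)
  if (any(!ok))
    warning(sum(!ok), " epoch(s) crossed the recording edge and were dropped")
  starts <- starts[ok]
  nc <- nrow(rec$data)
  data <- array(0, c(length(starts), nc, len))
  for (i in seq_along(starts))
    data[i, , ] <- rec$data[, starts[i]:(starts[i] + len - 1)]
  eeg_epochs(data, labels = as.integer(events$label[ok] == "self"),
             fs = fs, t0 = offset / fs * 1000, channel_names = rec$channel_names,
             meta = c(rec$meta, list(epoch_window_ms = c(tmin, tmax))))
}

#' Crop epochs to a time window
#'
#' Keeps samples with time in the half-open interval `[tmin, tmax)` ms. The
#' classification stage uses the 0-1000 ms crop of -200-1000 ms epochs.
#'
#' @param ep an [eeg_epochs].
#' @param tmin,tmax window in ms.
#' @return Cropped [eeg_epochs].
#' @export
crop_epochs <- function(ep, tmin = 0, tmax = 1000) {
  tt <- epoch_times(ep)
  keep <- which(tt >= tmin - 1e-9 & tt < tmax - 1e-9)
  if (!length(keep)) stop("crop window contains no samples")
  out <- ep
  out$data <- ep$data[, , keep, drop = FALSE]
  out$t0 <- tt[keep[1]]
  out
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean amplitude over the baseline
#' window (default -200 to 0 ms) from every sample. Idempotent.
#'
#' @param ep an [eeg_epochs].
#' @param window length-2 ms window, half-open.
#' @return Baseline-corrected [eeg_epochs].
#' @export
baseline_correct <- function(ep, window = c(-200, 0)) {
  tt <- epoch_times(ep)
  idx <- which(tt >= window[1] - 1e-9 & tt < window[2] - 1e-9)
  if (!length(idx)) stop("baseline window contains no samples")
  base <- apply(ep$data[, , idx, drop = FALSE], c(1, 2), mean)
  out <- ep
  out$data <- ep$data - as.vector(base)        # recycles over 3rd dim
  out$meta$baseline_ms <- window
  out
}

#' Average adjacent same-class trials
#'
#' To raise single-trial signal-to-noise ratio, trials are averaged pairwise:
#' within each class, consecutive trials in acquisition order are paired
#' without overlap and replaced by their mean; an odd trailing trial is
#' dropped. 200 registration trials become 100. Output trials keep acquisition
#' order (by the first member of each pair).
#'
#' @param ep an [eeg_epochs].
#' @param shuffle_seed optional seed; when given, trials are paired in a
#'   seeded random order within class instead of acquisition order (for
#'   robustness checks).
#' @return An [eeg_epochs] with `floor(n_class / 2)` trials per class.
#' @export
average_adjacent_pairs <- function(ep, shuffle_seed = NULL) {
  n <- dim(ep$data)[1]
  if (n < 2) stop("need at least 2 trials")
  first <- integer(0); second <- integer(0)
  for (cl in unique(ep$labels)) {
    idx <- which(ep$labels == cl)
    if (!is.null(shuffle_seed))
      idx <- withr_seed(shuffle_seed + cl, sample(idx))
    m <- length(idx) %/% 2
    if (m == 0) next
    first <- c(first, idx[seq(1, 2 * m, by = 2)])
    second <- c(second, idx[seq(2, 2 * m, by = 2)])
  }
  ord <- order(first)
  first <- first[ord]; second <- second[ord]
  out <- ep
  out$data <- (ep$data[first, , , drop = FALSE] +
               ep$data[second, , , drop = FALSE]) / 2
  out$labels <- ep$labels[first]
  out$meta$pair_averaged <- TRUE
  out
}

#' Peak-to-peak artifact rejection
#'
#' Optional, off by default in the pipeline: drops trials whose peak-to-peak
#' amplitude on any channel exceeds `threshold` µV.
#'
#' @param ep an [eeg_epochs].
#' @param threshold µV.
#' @return An [eeg_epochs] containing the surviving trials.
#' @export
reject_peak_to_peak <- function(ep, threshold) {
  p2p <- apply(ep$data, c(1, 2), function(x) diff(range(x)))
  keep <- apply(p2p <= threshold, 1, all)
  out <- ep
  out$data <- ep$data[keep, , , drop = FALSE]
  out$labels <- ep$labels[keep]
  out$meta$p2p_rejected <- sum(!keep)
  out
}

#' Class-average ERPs
#'
#' Mean epoch per class (channels x time), for ERP summaries.
#'
#' @param ep an [eeg_epochs].
#' @return Named list of channels x time matrices (`self`, `nonself` as
#'   present).
#' @export
erp_average <- function(ep) {
  out <- list()
  for (cl in sort(unique(ep$labels), decreasing = TRUE)) {
    m <- apply(ep$data[ep$labels == cl, , , drop = FALSE], c(2, 3), mean)
    out[[if (cl == 1) "self" else "nonself"]] <- m
  }
  out
}

# ---- pipeline --------------------------------------------------------------

#' Run the full preprocessing pipeline
#'
#' Fixed stage order: re-reference, zero-phase Chebyshev low-pass (40/49 Hz),
#' downsample by 4-sample averaging (2400 to 600 Hz), epoch extraction
#' (-200 to 1000 ms), baseline correction (-200 to 0 ms), crop to the
#' classification window (0 to 1000 ms), optional peak-to-peak rejection, and
#' optional adjacent-pair averaging. All parameters are logged into the
#' output's `meta`.
#'
#' @param rec an [eeg_recording].
#' @param ref_matrix optional re-referencing matrix (default: common average).
#' @param passband_hz,stopband_hz filter band edges, Hz.
#' @param ds_factor downsampling factor.
#' @param tmin,tmax epoch window, ms.
#' @param baseline baseline window, ms.
#' @param crop classification crop window, ms (`NULL` to skip).
#' @param pair_average average adjacent same-class trial pairs.
#' @param p2p_reject peak-to-peak rejection threshold in µV (`NULL` = off).
#' @param design optional precomputed `lowpass_design` reused across
#'   recordings.
#' @return An [eeg_epochs] ready for [hdca()].
#' @export
preprocess <- function(rec, ref_matrix = NULL, passband_hz = 40,
                       stopband_hz = 49, ds_factor = 4, tmin = -200,
                       tmax = 1000, baseline = c(-200, 0), crop = c(0, 1000),
                       pair_average = TRUE, p2p_reject = NULL, design = NULL) {
  rec <- rereference(rec, ref_matrix)
  rec <- lowpass(rec, passband_hz, stopband_hz, design = design)
  rec <- downsample_avg(rec, ds_factor)
  ep <- extract_epochs(rec, tmin, tmax)
  ep <- baseline_correct(ep, baseline)
  if (!is.null(crop)) ep <- crop_epochs(ep, crop[1], crop[2])
  if (!is.null(p2p_reject)) ep <- reject_peak_to_peak(ep, p2p_reject)
  if (pair_average) ep <- average_adjacent_pairs(ep)
  ep$meta$pipeline <- list(ref = if (is.null(ref_matrix)) "common_average"
                                 else "user_matrix",
                           passband_hz = passband_hz,
                           stopband_hz = stopband_hz, ds_factor = ds_factor,
                           epoch_ms = c(tmin, tmax), baseline_ms = baseline,
                           crop_ms = crop, pair_average = pair_average,
                           p2p_reject = p2p_reject)
  ep
}

#' Pool epochs from several recordings into one labelled set
#'
#' Concatenates trials (user epochs keep label 1, imposter epochs 0) after
#' checking that sampling rate, window and montage agree.
#'
#' @param ... [eeg_epochs] objects.
#' @return A single [eeg_epochs].
#' @export
bind_epochs <- function(...) {
  eps <- list(...)
  stopifnot(length(eps) >= 1)
  ref <- eps[[1]]
  for (ep in eps[-1])
    if (ep$fs != ref$fs || ep$t0 != ref$t0 ||
        !identical(ep$channel_names, ref$channel_names) ||
        dim(ep$data)[3] != dim(ref$data)[3])
      stop("epoch sets are not compatible (fs/window/montage mismatch)")
  data <- do.call(abind3, lapply(eps, function(e) e$data))
  labels <- unlist(lapply(eps, function(e) e$labels))
  eeg_epochs(data, labels, ref$fs, ref$t0, ref$channel_names,
             meta = ref$meta)
}

# rbind for 3-d arrays along dim 1
abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  n <- sum(vapply(parts, function(p) dim(p)[1], 0))
  out <- array(0, c(n, d[2], d[3]))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}
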