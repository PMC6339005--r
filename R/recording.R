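#' Continuous multichannel EEG recording
#'
#' Lightweight container for a continuous EEG recording: a channels-by-samples
#' numeric matrix in microvolts, its sampling rate, channel names, and an event
#' table marking stimulus onsets.
#'
#' Event sample indices are 1-based positions into the columns of `data`
#' (on-disk formats use 0-based indices; the readers/writers convert).
#'
#' @param data numeric matrix, channels x samples, in microvolts (µV).
#' @param fs sampling rate in Hz.
#' @param channel_names character vector, one name per row of `data`.
#' @param events data.frame with columns `sample` (1-based onset index,
#'   strictly increasing) and `label` (`"self"` or `"nonself"`).
#' @param meta optional named list of provenance metadata (config echo, seed,
#'   processing log). Carried along by every pipeline stage.
#'
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_names, events = empty_events(),
                          meta = list()) {
  data <- as.matrix(data)
  stopifnot(is.numeric(data), is.numeric(fs), fs > 0)
  if (length(channel_names) != nrow(data))
    stop("channel_names length (", length(channel_names),
         ") does not match channel count (", nrow(data), ")")
  events <- as.data.frame(events)
  if (nrow(events)) {
    if (!all(c("sample", "label") %in% names(events)))
      stop("events must have columns 'sample' and 'label'")
    events$sample <- as.integer(events$sample)
    if (any(diff(events$sample) <= 0))
      stop("event sample indices must be strictly increasing")
    if (any(events$sample < 1L) || any(events$sample > ncol(data)))
      stop("event sample indices fall outside the recording")
    if (!all(events$label %in% c("self", "nonself")))
      stop("event labels must be 'self' or 'nonself'")
  }
  structure(
    list(data = data, fs = fs, channel_names = as.character(channel_names),
         events = events, meta = meta),
    class = "eeg_recording")
}

empty_events <- function() {
  data.frame(sample = integer(0), label = character(0),
             stringsAsFactors = FALSE)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$fs, " Hz (", round(ncol(x$data) / x$fs, 2), " s)\n",
      sep = "")
  cat("  channels: ", paste(x$channel_names, collapse = " "), "\n", sep = "")
  if (nrow(x$events)) {
    tab <- table(x$events$label)
    cat("  events:   ", nrow(x$events), " (",
        paste(names(tab), tab, sep = "=", collapse = ", "), ")\n", sep = "")
  } else cat("  events:   none\n")
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

n_channels <- function(rec) nrow(rec$data)

#' The 16-channel montage used by the RSVP authentication protocol
#'
#' Electrode labels (international 10-20 system) of the wet-electrode montage
#' the framework is designed around.
#'
#' @return Character vector of 16 channel names.
#' @export
default_montage <- function() {
  c("Fz", "Cz", "P3", "Pz", "P4", "Po7", "Oz", "Po8",
    "C3", "C4", "F3", "F4", "Af7", "Af8", "Cp5", "Cp6")
}

# ---- native array container: raw float64 + JSON sidecar --------------------

#' Read and write recordings in the native array container
#'
#' The native on-disk format is a raw little-endian float64 array (channel-major:
#' channel 1 samples, then channel 2, ...) with a JSON sidecar `<path>.json`
#' holding sampling rate, channel names, events (0-based sample indices) and
#' arbitrary metadata. This avoids the 16-bit quantisation of EDF mid-pipeline;
#' round-trips are bit-identical.
#'
#' @param rec an [eeg_recording].
#' @param path file path for the binary array; the sidecar is `<path>.json`.
#' @return `write_recording` returns `path` invisibly; `read_recording` returns
#'   an [eeg_recording].
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(rec$data)), con, size = 8, endian = "little")
  sidecar <- list(
    format = "rsvpauth-array-v1",
    n_channels = nrow(rec$data),
    n_samples = ncol(rec$data),
    fs = rec$fs,
    channel_names = rec$channel_names,
    events = list(sample0 = rec$events$sample - 1L,
                  label = rec$events$label),
    meta = rec$meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  nc <- sidecar$n_channels; ns <- sidecar$n_samples
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = nc * ns, size = 8, endian = "little")
  data <- t(matrix(x, nrow = ns, ncol = nc))
  ev <- if (length(sidecar$events$sample0))
    data.frame(sample = as.integer(sidecar$events$sample0) + 1L,
               label = as.character(sidecar$events$label),
               stringsAsFactors = FALSE)
  else empty_events()
  meta <- sidecar$meta
  if (is.null(meta)) meta <- list()
  eeg_recording(data, as.numeric(sidecar$fs), sidecar$channel_names, ev, meta)
}

# ---- EDF (European Data Format) export/import ------------------------------

#' Write a recording to EDF
#'
#' Minimal EDF (16-bit) writer: one data record per second, physical units µV.
#' Physical min/max are set symmetrically from the data range, so amplitudes
#' are quantised to 16 bits — use the native container ([write_recording]) for
#' lossless intermediate storage. Events are written to a companion
#' tab-separated file `<path>.events.tsv` with 0-based sample indices.
#'
#' @param rec an [eeg_recording]; `fs` must be a positive integer.
#' @param path output `.edf` path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF export requires an integer sampling rate")
  nc <- nrow(rec$data)
  spr <- as.integer(fs)                       # samples per record (1 s records)
  n_rec <- floor(ncol(rec$data) / spr)
  if (n_rec < 1) stop("recording shorter than one EDF data record (1 s)")
  used <- rec$data[, seq_len(n_rec * spr), drop = FALSE]
  phys_max <- max(1, ceiling(max(abs(used))))
  phys_min <- -phys_max
  dig_max <- 32767L; dig_min <- -32768L

  pad <- function(s, n) {
    s <- substr(as.character(s), 1, n)
    formatC(s, width = -n, flag = " ")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  header_bytes <- 256L + 256L * nc
  hdr <- paste0(
    pad("0", 8), pad("X X X X", 80), pad("Startdate X X X X", 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(header_bytes, 8), pad("", 44), pad(n_rec, 8), pad(1, 8), pad(nc, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste0(vapply(vals, pad, "", n = width), collapse = ""),
              con, eos = NULL)
  field(rec$channel_names, 16)                 # label
  field(rep("", nc), 80)                       # transducer
  field(rep("uV", nc), 8)                      # physical dimension
  field(rep(format(phys_min), nc), 8)
  field(rep(format(phys_max), nc), 8)
  field(rep(format(dig_min), nc), 8)
  field(rep(format(dig_max), nc), 8)
  field(rep("", nc), 80)                       # prefiltering
  field(rep(spr, nc), 8)
  field(rep("", nc), 32)                       # reserved
  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    block <- used[, idx, drop = FALSE]
    dig <- round((block - phys_min) * scale) + dig_min
    dig <- pmin(pmax(dig, dig_min), dig_max)
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }
  ev_path <- paste0(path, ".events.tsv")
  utils::write.table(
    data.frame(sample_index = rec$events$sample - 1L, label = rec$events$label),
    ev_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an EDF recording written by [write_edf]
#'
#' Supports the subset of EDF this package writes (equal samples-per-record on
#' every signal, no annotations channel). Events are restored from
#' `<path>.events.tsv` when present.
#'
#' @param path `.edf` path.
#' @return An [eeg_recording].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                        # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rd(8)                                        # record duration (1 s)
  nc <- as.integer(rd(4))
  rdf <- function(width) trimws(vapply(seq_len(nc), function(i) rd(width), ""))
  labels <- rdf(16); rdf(80); rdf(8)
  phys_min <- as.numeric(rdf(8)); phys_max <- as.numeric(rdf(8))
  dig_min <- as.numeric(rdf(8)); dig_max <- as.numeric(rdf(8))
  rdf(80)
  spr <- as.integer(rdf(8)); rdf(32)
  if (length(unique(spr)) != 1) stop("unequal samples-per-record not supported")
  spr <- spr[1]
  data <- matrix(0, nrow = nc, ncol = n_rec * spr)
  for (r in seq_len(n_rec)) {
    dig <- readBin(con, "integer", n = nc * spr, size = 2,
                   signed = TRUE, endian = "little")
    block <- matrix(dig, nrow = spr, ncol = nc)
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (ch in seq_len(nc))
      data[ch, idx] <- phys_min[ch] +
        (block[, ch] - dig_min[ch]) *
          (phys_max[ch] - phys_min[ch]) / (dig_max[ch] - dig_min[ch])
  }
  ev_path <- paste0(path, ".events.tsv")
  ev <- if (file.exists(ev_path)) {
    tab <- utils::read.table(ev_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    data.frame(sample = as.integer(tab$sample_index) + 1L,
               label = as.character(tab$label), stringsAsFactors = FALSE)
  } else empty_events()
  eeg_recording(data, spr, labels, ev)
}

#' Read and write epoch sets in the native array container
#'
#' Same raw-float64 + JSON-sidecar scheme as [write_recording], for
#' trials x channels x time epoch arrays with labels; round-trips are
#' bit-identical.
#'
#' @param ep an [eeg_epochs].
#' @param path file path for the binary array; the sidecar is `<path>.json`.
#' @return `write_epochs` returns `path` invisibly; `read_epochs` an
#'   [eeg_epochs].
#' @export
write_epochs <- function(ep, path) {
  stopifnot(inherits(ep, "eeg_epochs"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(ep$data), con, size = 8, endian = "little")
  sidecar <- list(format = "rsvpauth-epochs-v1", dim = dim(ep$data),
                  labels = ep$labels, fs = ep$fs, t0 = ep$t0,
                  channel_names = ep$channel_names, meta = ep$meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- as.integer(sidecar$dim)
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = prod(d), size = 8, endian = "little")
  meta <- sidecar$meta
  if (is.null(meta)) meta <- list()
  eeg_epochs(array(x, d), sidecar$labels, as.numeric(sidecar$fs),
             as.numeric(sidecar$t0), sidecar$channel_names, meta)
}
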