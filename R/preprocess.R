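#' Multichannel recording container
#'
#' @param data numeric matrix, channels x samples.
#' @param fs sampling rate in Hz.
#' @param labels ordered channel names, one per row of `data`.
#' @return An object of class `recording`: list with elements `data`, `fs`,
#'   `labels`.
#' @export
recording <- function(data, fs, labels = rownames(data)) {
  data <- as.matrix(data)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  if (length(labels) != nrow(data))
    stop("labels length (", length(labels), ") != channel count (",
         nrow(data), ")")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive scalar (Hz)")
  if (!all(is.finite(data)))
    stop("recording contains non-finite samples")
  structure(list(data = data, fs = fs, labels = as.character(labels)),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat("<recording> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$fs, " Hz (", round(ncol(x$data) / x$fs, 2),
      " s)\n", sep = "")
  invisible(x)
}

#' Frequency band specification
#'
#' @param name band name, e.g. `"alpha"`.
#' @param low,high band edges in Hz, `0 < low < high`.
#' @return An object of class `band_spec`.
#' @export
band_spec <- function(name, low, high) {
  if (!(low > 0 && high > low))
    stop("need 0 < low < high; got [", low, ", ", high, "]")
  structure(list(name = name, low = low, high = high), class = "band_spec")
}

#' The four classical EEG rhythms
#'
#' Delta 0.5-4, theta 4-8, alpha 8-13 and beta 13-30 Hz.
#'
#' @return Named list of [band_spec] objects.
#' @export
eeg_bands <- function() {
  list(delta = band_spec("delta", 0.5, 4),
       theta = band_spec("theta", 4, 8),
       alpha = band_spec("alpha", 8, 13),
       beta  = band_spec("beta", 13, 30))
}

#' Common average reference
#'
#' Subtracts the across-channel mean from every sample, so the channel sum
#' is zero at each time point. Idempotent.
#'
#' @param rec a [recording] with at least two channels.
#' @return The re-referenced [recording].
#' @export
average_reference <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  if (nrow(rec$data) < 2L)
    stop("average reference needs at least 2 channels")
  rec$data <- sweep(rec$data, 2L, colMeans(rec$data), "-")
  rec
}

# Forward-backward Butterworth on one channel with reflect padding.
# Padding length ~ 3 periods of the lowest passband frequency (capped at
# n-1) so the low-frequency edge transient decays inside the pad.
zero_phase_filter <- function(x, b_filt, pad_len) {
  n <- length(x)
  pad_len <- min(pad_len, n - 1L)
  if (pad_len > 0L) {
    head_ref <- 2 * x[1L] - x[(pad_len + 1L):2L]
    tail_ref <- 2 * x[n] - x[(n - 1L):(n - pad_len)]
    xp <- c(head_ref, x, tail_ref)
  } else xp <- x
  y <- signal::filtfilt(b_filt, xp)
  y[(pad_len + 1L):(pad_len + n)]
}

#' Zero-phase band-pass filtering
#'
#' 4th-order Butterworth band-pass applied forward and backward
#' (effective 8th order, zero net phase shift), with odd reflection padding
#' at both ends to suppress edge transients.
#'
#' @param rec a [recording].
#' @param band a [band_spec]; `high` must be below the Nyquist frequency.
#' @param order Butterworth order of the one-pass filter (default 4).
#' @return The band-limited [recording].
#' @export
bandpass_zero_phase <- function(rec, band, order = 4L) {
  stopifnot(inherits(rec, "recording"), inherits(band, "band_spec"))
  nyq <- rec$fs / 2
  if (band$high >= nyq)
    stop("band high edge (", band$high, " Hz) must be < Nyquist (", nyq,
         " Hz)")
  bf <- signal::butter(order, c(band$low, band$high) / nyq, type = "pass")
  pad_len <- as.integer(min(ceiling(3 * rec$fs / band$low),
                            ncol(rec$data) - 1L))
  rec$data <- t(apply(rec$data, 1L, zero_phase_filter, b_filt = bf,
                      pad_len = pad_len))
  rec
}

#' Decompose a recording into frequency bands
#'
#' @param rec a [recording].
#' @param bands list of [band_spec] objects (default the four classical
#'   rhythms of [eeg_bands()]).
#' @return Named list of band-limited [recording]s, same shape and labels
#'   as the input.
#' @export
decompose_bands <- function(rec, bands = eeg_bands()) {
  out <- lapply(bands, function(b) bandpass_zero_phase(rec, b))
  names(out) <- vapply(bands, function(b) b$name, character(1L))
  out
}

#' Broadband pre-filter and downsample for raw recordings
#'
#' The standard conditioning for recorded EEG: band-pass 0.3-30 Hz, then
#' integer-factor decimation to the target rate. Synthetic cohorts are
#' generated at the analysis rate directly, so this step is a pass-through
#' for them.
#'
#' @param rec a [recording].
#' @param low,high broadband pass edges in Hz.
#' @param fs_target target sampling rate; must divide `rec$fs`.
#' @return The conditioned [recording] at `fs_target`.
#' @export
broadband_condition <- function(rec, low = 0.3, high = 30,
                                fs_target = 200) {
  rec <- bandpass_zero_phase(rec, band_spec("broadband", low, high))
  if (fs_target < rec$fs) {
    fac <- rec$fs / fs_target
    if (abs(fac - round(fac)) > 1e-9)
      stop("fs_target must divide fs (", rec$fs, " -> ", fs_target, ")")
    keep <- seq(1L, ncol(rec$data), by = as.integer(round(fac)))
    rec$data <- rec$data[, keep, drop = FALSE]
    rec$fs <- fs_target
  }
  rec
}

#' Read / write a recording as a plain numeric matrix file
#'
#' Matrix files are whitespace-delimited text, one row per channel in the
#' documented montage order; channel labels live in a sidecar one-label-per-
#' line text file (or are taken from a montage).
#'
#' @param path matrix file path.
#' @param fs sampling rate of the stored data.
#' @param labels character vector of channel names, or a [montage].
#' @param rec a [recording] (for writing).
#' @return `read_recording_matrix()` returns a [recording];
#'   `write_recording_matrix()` returns `path` invisibly.
#' @export
read_recording_matrix <- function(path, fs, labels) {
  if (inherits(labels, "montage")) labels <- labels$label
  if (length(labels) == 1L && file.exists(labels))
    labels <- readLines(labels)
  m <- as.matrix(utils::read.table(path))
  dimnames(m) <- NULL
  recording(m, fs = fs, labels = labels)
}

#' @rdname read_recording_matrix
#' @export
write_recording_matrix <- function(rec, path) {
  utils::write.table(format(rec$data, digits = 10L), path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
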