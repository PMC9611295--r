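#' Sliding-window specification
#'
#' @param length_s window length in seconds (default 4).
#' @param step_s hop between window starts in seconds (default 2, i.e.
#'   50% overlap).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(length_s = 4, step_s = 2) {
  if (!(step_s > 0 && step_s <= length_s))
    stop("need 0 < step_s <= length_s")
  structure(list(length_s = length_s, step_s = step_s),
            class = "window_spec")
}

#' Number of sliding windows in a recording
#'
#' `floor((n_samples - length) / step) + 1` with length and step in
#' samples. A 400-s record at 200 Hz yields 199 windows of 4 s with 2-s
#' step.
#'
#' @param n_samples samples per channel.
#' @param fs sampling rate in Hz.
#' @param spec a [window_spec].
#' @return Integer window count.
#' @export
count_windows <- function(n_samples, fs, spec = window_spec()) {
  len <- round(spec$length_s * fs)
  step <- round(spec$step_s * fs)
  if (n_samples < len)
    stop("recording (", n_samples, " samples) shorter than one window (",
         len, " samples)")
  as.integer(floor((n_samples - len) / step) + 1L)
}

# Hilbert-transform frequency-domain weights for window length nt.
hilbert_weights <- function(nt) {
  h <- numeric(nt)
  if (nt %% 2L == 0L) {
    h[c(1L, nt / 2L + 1L)] <- 1
    h[2L:(nt / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((nt + 1L) / 2L)] <- 2
  }
  h
}

# Analytic signal of each row of a channels x samples matrix via FFT.
analytic_matrix <- function(x) {
  nt <- ncol(x)
  xf <- stats::mvfft(t(x)) * hilbert_weights(nt)
  t(stats::mvfft(xf, inverse = TRUE)) / nt
}

# Instantaneous phases of a channels x samples matrix, returned as a
# samples x channels matrix (contiguous per-channel columns for the C++
# PLI kernel). Arg() is scale-invariant, so the inverse FFT is left
# unnormalised.
phase_cols <- function(x) {
  nt <- ncol(x)
  xf <- stats::mvfft(t(x)) * hilbert_weights(nt)
  Arg(stats::mvfft(xf, inverse = TRUE))
}

#' Instantaneous phase of a signal window
#'
#' Analytic-signal (Hilbert-transform) phase, one value per sample in
#' `(-pi, pi]`.
#'
#' @param x numeric vector, a single-channel window (>= 2 samples).
#' @return Numeric vector of phases in radians.
#' @export
instantaneous_phase <- function(x) {
  if (length(x) < 2L) stop("window must have at least 2 samples")
  if (all(x == 0)) stop("phase undefined for an all-zero window")
  Arg(analytic_matrix(matrix(x, nrow = 1L))[1L, ])
}

#' Phase lag index of two signals
#'
#' `PLI = | mean_t sign(dphi(t)) |` where `dphi` is the instantaneous phase
#' difference wrapped to `(-pi, pi]`; samples with exactly zero phase
#' difference contribute 0. PLI is 0 for identical (or zero-lag coupled)
#' signals and 1 for a consistent nonzero lag; it is insensitive to
#' amplitude scaling.
#'
#' @param x,y numeric vectors of equal length (single-channel windows).
#' @return PLI value in `[0, 1]`.
#' @examples
#' t <- seq(0, 2, by = 0.005)
#' pli(cos(2 * pi * 5 * t), cos(2 * pi * 5 * t))          # 0
#' pli(cos(2 * pi * 5 * t), cos(2 * pi * 5 * t - pi / 2)) # ~1
#' @export
pli <- function(x, y) {
  if (length(x) != length(y))
    stop("signals must have equal length (", length(x), " vs ",
         length(y), ")")
  pli_matrix_cpp(phase_cols(rbind(x, y)))[1L, 2L]
}

#' Sliding-window PLI matrices of one band-limited recording
#'
#' Segments the recording with the given window specification, extracts the
#' analytic-signal phase within each window independently, and computes the
#' full symmetric PLI matrix per window.
#'
#' @param band_rec a band-limited [recording].
#' @param spec a [window_spec].
#' @return Numeric array `channels x channels x windows`; every slice is
#'   symmetric with zero diagonal and entries in `[0, 1]`. Channel labels
#'   are carried in the dimnames.
#' @export
window_pli_matrices <- function(band_rec, spec = window_spec()) {
  stopifnot(inherits(band_rec, "recording"))
  n <- nrow(band_rec$data)
  len <- round(spec$length_s * band_rec$fs)
  nw <- count_windows(ncol(band_rec$data), band_rec$fs, spec)
  step <- round(spec$step_s * band_rec$fs)
  out <- array(0, dim = c(n, n, nw),
               dimnames = list(band_rec$labels, band_rec$labels, NULL))
  for (w in seq_len(nw)) {
    idx <- (1L + (w - 1L) * step):((w - 1L) * step + len)
    out[, , w] <- pli_matrix_cpp(phase_cols(band_rec$data[, idx,
                                                          drop = FALSE]))
  }
  out
}

#' Per-band sliding-window connectivity of a recording
#'
#' Band-decomposes the recording and computes [window_pli_matrices()] for
#' every band.
#'
#' @param rec a [recording] (referenced, broadband-conditioned).
#' @param bands list of [band_spec]s (default [eeg_bands()]).
#' @param spec a [window_spec].
#' @return An object of class `connectivity_tensor`: named list of
#'   `channels x channels x windows` arrays, one per band, with attributes
#'   `labels` and `window_spec`.
#' @export
connectivity_tensor <- function(rec, bands = eeg_bands(),
                                spec = window_spec()) {
  band_recs <- decompose_bands(rec, bands)
  out <- lapply(band_recs, window_pli_matrices, spec = spec)
  structure(out, labels = rec$labels, window_spec = spec,
            class = "connectivity_tensor")
}

#' Window-averaged connectivity
#'
#' Element-wise mean of the per-window PLI matrices. Symmetry and the
#' `[0, 1]` range are preserved.
#'
#' @param x a `connectivity_tensor` or a single
#'   `channels x channels x windows` array.
#' @return A named list of `channels x channels` matrices (for a tensor) or
#'   a single matrix (for an array).
#' @export
mean_connectivity <- function(x) {
  avg1 <- function(a) {
    if (length(dim(a)) != 3L || dim(a)[3L] < 1L)
      stop("need at least one window")
    m <- rowMeans(a, dims = 2L)
    dimnames(m) <- dimnames(a)[1:2]
    m
  }
  if (inherits(x, "connectivity_tensor")) lapply(unclass(x), avg1)
  else avg1(x)
}
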