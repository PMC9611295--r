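#' Planted phase-coupled edge for the synthetic generator
#'
#' Describes one channel pair that receives a shared narrowband oscillator
#' in one frequency band, with condition-specific coupling strength. A
#' coupling of 0 means the two channels get fully independent narrowband
#' activity; 1 means both carry the same source (one copy phase-delayed by
#' pi/4), which drives the phase lag index of the pair toward 1.
#'
#' @param band band name, must match a band of the config.
#' @param a,b channel names (or indices into the montage).
#' @param coupling_a,coupling_b coupling in `[0, 1]` under condition A / B.
#' @return A `planted_edge` list.
#' @export
planted_edge <- function(band, a, b, coupling_a, coupling_b) {
  if (coupling_a < 0 || coupling_a > 1 || coupling_b < 0 || coupling_b > 1)
    stop("couplings must lie in [0, 1]")
  structure(list(band = band, a = a, b = b,
                 coupling = c(A = coupling_a, B = coupling_b)),
            class = "planted_edge")
}

#' Configuration of a synthetic EEG cohort
#'
#' Defines a two-condition cohort of 60-channel recordings: broadband 1/f
#' background activity plus planted band-specific phase coupling on chosen
#' channel pairs. Defaults emulate the acquisition this package targets:
#' 20 subjects, 400-s segments at 200 Hz, the four classical rhythms.
#'
#' @param n_subjects subjects per condition.
#' @param duration_s recording length in seconds.
#' @param fs sampling rate in Hz; `duration_s * fs` must be whole.
#' @param bands named list of [band_spec]s.
#' @param planted_edges list of [planted_edge]s.
#' @param noise_sd standard deviation of the 1/f background per channel.
#' @param osc_amplitude amplitude of a planted narrowband component
#'   relative to `noise_sd`; large enough that a fully coupled pair
#'   dominates the in-band background.
#' @param subject_jitter_sd per-subject Gaussian jitter applied to each
#'   coupling (clipped back to `[0, 1]`), creating between-subject variance.
#' @param seed master seed; identical configs with identical seeds
#'   reproduce bit-identical cohorts.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_subjects = 20L, duration_s = 400, fs = 200,
                             bands = eeg_bands(), planted_edges = list(),
                             noise_sd = 1, osc_amplitude = 2,
                             subject_jitter_sd = 0.05, seed = 1L) {
  nt <- duration_s * fs
  if (abs(nt - round(nt)) > 1e-9)
    stop("duration_s * fs must be a whole number of samples")
  band_names <- names(bands)
  for (pe in planted_edges) {
    if (!inherits(pe, "planted_edge")) stop("planted_edges must be a list of planted_edge objects")
    if (!pe$band %in% band_names)
      stop("planted edge band '", pe$band, "' not among config bands")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 duration_s = duration_s, fs = fs, bands = bands,
                 planted_edges = planted_edges, noise_sd = noise_sd,
                 osc_amplitude = osc_amplitude,
                 subject_jitter_sd = subject_jitter_sd,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Deterministic per-recording seed below 2^31, derived from the master
# seed, the condition and the subject index.
derive_seed <- function(master, condition, subject_index) {
  base <- (as.double(master) * 100003 + subject_index * 613 +
             ifelse(condition == "B", 299709, 0)) %% 2147483629
  as.integer(base) + 1L
}

# 1/f-amplitude (power slope -2) noise via spectral shaping of white
# noise; returned with unit standard deviation.
one_over_f_noise <- function(nt, fs) {
  w <- stats::rnorm(nt)
  f <- seq_len(nt) - 1L
  f <- pmin(f, nt - f) * fs / nt
  scale <- ifelse(f > 0, 1 / f, 0)
  x <- Re(stats::fft(stats::fft(w) * scale, inverse = TRUE)) / nt
  x / stats::sd(x)
}

# Unit-sd narrowband noise in a band.
narrowband_noise <- function(nt, fs, band) {
  bf <- signal::butter(4L, c(band$low, band$high) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(nt))
  x / stats::sd(x)
}

# Copy of x delayed by a constant phase angle (radians) via the analytic
# signal; unit sd.
phase_delayed <- function(x, angle) {
  y <- Re(analytic_matrix(matrix(x, nrow = 1L))[1L, ] * exp(-1i * angle))
  y / stats::sd(y)
}

#' Generate one synthetic recording
#'
#' Each channel is unit-variance 1/f background noise scaled by `noise_sd`.
#' For every planted edge in band b with (jittered) coupling c, the two
#' member channels additionally receive `osc_amplitude * noise_sd *
#' (c * shared + (1 - c) * own)`, where `shared` is a common narrowband
#' source (the second channel's copy delayed by a constant pi/4 phase) and
#' `own` is independent narrowband noise. The constant nonzero lag makes
#' the pair's phase-difference sign consistent, so PLI grows monotonically
#' with c while zero-lag (volume-conduction-like) coupling is never
#' planted.
#'
#' @param config a [synthetic_config].
#' @param condition `"A"` or `"B"`.
#' @param subject_index subject number in `1..n_subjects`.
#' @param mont the [montage] supplying channel count and labels.
#' @return A [recording], deterministic given
#'   `(config, condition, subject_index)`.
#' @export
generate_subject <- function(config, condition = c("A", "B"),
                             subject_index = 1L,
                             mont = default_montage()) {
  stopifnot(inherits(config, "synthetic_config"))
  condition <- match.arg(condition)
  if (subject_index < 1L || subject_index > config$n_subjects)
    stop("subject_index must be in 1..n_subjects")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, condition, subject_index))
  nt <- as.integer(round(config$duration_s * config$fs))
  n <- nrow(mont)
  dat <- matrix(0, n, nt)
  for (ch in seq_len(n))
    dat[ch, ] <- config$noise_sd * one_over_f_noise(nt, config$fs)
  amp <- config$osc_amplitude * config$noise_sd
  for (pe in config$planted_edges) {
    ia <- if (is.numeric(pe$a)) as.integer(pe$a) else match(pe$a, mont$label)
    ib <- if (is.numeric(pe$b)) as.integer(pe$b) else match(pe$b, mont$label)
    if (is.na(ia) || is.na(ib))
      stop("planted edge channel not in montage: ", pe$a, "-", pe$b)
    band <- config$bands[[pe$band]]
    cc <- pe$coupling[[condition]] +
      stats::rnorm(1L, 0, config$subject_jitter_sd)
    cc <- min(max(cc, 0), 1)
    shared <- narrowband_noise(nt, config$fs, band)
    lagged <- phase_delayed(shared, pi / 4)
    own_a <- narrowband_noise(nt, config$fs, band)
    own_b <- narrowband_noise(nt, config$fs, band)
    dat[ia, ] <- dat[ia, ] + amp * (cc * shared + (1 - cc) * own_a)
    dat[ib, ] <- dat[ib, ] + amp * (cc * lagged + (1 - cc) * own_b)
  }
  recording(dat, fs = config$fs, labels = mont$label)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a labelled two-condition cohort
#'
#' @param config a [synthetic_config].
#' @param mont the [montage].
#' @return An object of class `cohort`: list with `recordings` (named list
#'   of [recording]s, `n_subjects` per condition) and `manifest`
#'   (data.frame with columns `id`, `subject`, `condition`, `seed`).
#' @export
generate_cohort <- function(config, mont = default_montage()) {
  grid <- expand.grid(subject = seq_len(config$n_subjects),
                      condition = c("A", "B"),
                      stringsAsFactors = FALSE)
  ids <- sprintf("S%02d_%s", grid$subject, grid$condition)
  recs <- vector("list", nrow(grid))
  names(recs) <- ids
  for (k in seq_len(nrow(grid)))
    recs[[k]] <- generate_subject(config, grid$condition[k],
                                  grid$subject[k], mont)
  manifest <- data.frame(id = ids, subject = grid$subject,
                         condition = grid$condition,
                         seed = derive_seed(config$seed, grid$condition,
                                            grid$subject))
  structure(list(recordings = recs, manifest = manifest), class = "cohort")
}

#' Ground-truth differential edges of a synthetic config
#'
#' @param config a [synthetic_config].
#' @return Named list (one entry per band) of two-column character matrices
#'   listing the planted edges whose coupling differs between conditions.
#' @export
planted_truth <- function(config) {
  out <- lapply(names(config$bands), function(b) {
    keep <- Filter(function(pe) pe$band == b &&
                     pe$coupling[["A"]] != pe$coupling[["B"]],
                   config$planted_edges)
    if (!length(keep)) return(matrix(character(0), ncol = 2L,
                                     dimnames = list(NULL, c("a", "b"))))
    do.call(rbind, lapply(keep, function(pe)
      matrix(as.character(c(pe$a, pe$b)), ncol = 2L,
             dimnames = list(NULL, c("a", "b")))))
  })
  names(out) <- names(config$bands)
  out
}

#' Write a cohort as plain matrix files plus a manifest
#'
#' One whitespace-delimited matrix file per recording (rows = channels in
#' montage order) and a `manifest.csv` with columns `id`, `subject`,
#' `condition`, `path`, `seed`.
#'
#' @param coh a `cohort`.
#' @param dir output directory (created if missing).
#' @return The manifest data.frame, invisibly.
#' @export
write_cohort <- function(coh, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(coh$manifest$id, ".txt"))
  for (k in seq_along(coh$recordings))
    write_recording_matrix(coh$recordings[[k]], paths[k])
  manifest <- cbind(coh$manifest, path = paths)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
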