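#' Behavior motion motif
#'
#' A motif is the parametric motion signature of one behavior class used by
#' the synthetic generator: per-sensor oscillation amplitudes, a fundamental
#' frequency with a harmonic stack, additive Gaussian sensor noise, and a
#' static 12-channel baseline offset representing posture (gravity direction
#' on the accelerometer, heading on the magnetometer, attitude on the
#' rotation channels).
#'
#' @param class_id Integer behavior code in 0..4 (see [behavior_classes()]).
#' @param amplitude Length-4 non-negative vector of oscillation amplitudes in
#'   normalized units, one per sensor group (gyro, acc, mag, rot).
#' @param frequency Fundamental frequency in Hz; must lie strictly between 0
#'   and the Nyquist frequency (25 Hz at the default 50 Hz sampling rate).
#' @param harmonics Number of harmonics (integer >= 1); harmonic k enters
#'   with weight 1/k so the fundamental dominates the spectrum.
#' @param noise_sd Standard deviation of additive white Gaussian noise, in
#'   normalized units (>= 0).
#' @param offset Length-12 baseline offset, one value per channel in the
#'   canonical order of [cmpl_channels()].
#' @param amp_jitter Log-normal sd of the per-window action-intensity scale
#'   (one multiplicative draw per window; 0 disables).
#' @param offset_jitter Sd of the per-window posture perturbation added to
#'   `offset` (one draw per channel per window; 0 disables).
#' @param freq_jitter Log-normal sd of the per-window cadence factor applied
#'   to `frequency` (0 disables).
#' @param modes Optional list of 12-vectors: alternative posture offsets
#'   (e.g. lying on the left vs right side). Each window draws one mode
#'   uniformly in place of `offset`; `NULL` keeps the single posture.
#' @return An object of class `behavior_motif`.
#' @export
behavior_motif <- function(class_id, amplitude, frequency, harmonics = 1L,
                           noise_sd = 0.05, offset = rep(0, 12),
                           amp_jitter = 0, offset_jitter = 0, freq_jitter = 0,
                           modes = NULL) {
  class_id <- as.integer(class_id)
  if (is.na(class_id) || class_id < 0L || class_id > 4L) {
    stopf("`class_id` must be an integer in 0..4.")
  }
  if (length(amplitude) != 4L || any(!is.finite(amplitude)) || any(amplitude < 0)) {
    stopf("`amplitude` must be 4 non-negative finite values (gyro, acc, mag, rot).")
  }
  frequency <- check_number(frequency, "frequency", lower = 1e-6)
  if (frequency >= 25) stopf("`frequency` must be below the 25 Hz Nyquist limit.")
  harmonics <- as.integer(harmonics)
  if (harmonics < 1L) stopf("`harmonics` must be >= 1.")
  noise_sd <- check_number(noise_sd, "noise_sd", lower = 0)
  if (length(offset) != 12L || any(!is.finite(offset))) {
    stopf("`offset` must be 12 finite values.")
  }
  amp_jitter <- check_number(amp_jitter, "amp_jitter", lower = 0)
  offset_jitter <- check_number(offset_jitter, "offset_jitter", lower = 0)
  freq_jitter <- check_number(freq_jitter, "freq_jitter", lower = 0)
  if (!is.null(modes)) {
    if (!is.list(modes) || !all(vapply(modes, function(m) {
      length(m) == 12L && all(is.finite(m))
    }, logical(1)))) {
      stopf("`modes` must be a list of 12-vector posture offsets.")
    }
    modes <- lapply(modes, as.numeric)
  }
  structure(
    list(
      class_id = class_id,
      amplitude = as.numeric(amplitude),
      frequency = frequency,
      harmonics = harmonics,
      noise_sd = noise_sd,
      offset = as.numeric(offset),
      amp_jitter = amp_jitter,
      offset_jitter = offset_jitter,
      freq_jitter = freq_jitter,
      modes = modes
    ),
    class = "behavior_motif"
  )
}

#' @export
print.behavior_motif <- function(x, ...) {
  cls <- names(behavior_classes())[x$class_id + 1L]
  cat(sprintf(
    "<behavior_motif> class %d (%s): f0 = %g Hz, %d harmonic(s), noise sd %g\n",
    x$class_id, cls, x$frequency, x$harmonics, x$noise_sd
  ))
  invisible(x)
}

#' Default motion motifs for the five behavior classes
#'
#' Qualitative signatures: stand is low-amplitude slow drift in an upright
#' posture; walk has strong periodic gyro/acc content near 2 Hz with
#' harmonics; sit is moderate slow motion in a tilted posture; lying is
#' near-static with a distinct side-posture offset on the magnetometer and
#' rotation channels; eat has mid-frequency accelerometer bursts with the
#' head-down offset. Every window additionally draws its own action
#' intensity (log-normal amplitude scale), posture perturbation (offset
#' jitter) and cadence factor (frequency jitter), emulating within-class
#' variability across animals and episodes; without these the classes would
#' be trivially separable from a handful of examples. The training method
#' is agnostic to the exact shapes.
#'
#' @param noise_sd Optional common override of each motif's noise level.
#' @return A list of 5 `behavior_motif` objects, in class order 0..4.
#' @export
default_motifs <- function(noise_sd = NULL) {
  mode_pair <- function(base, d) list(base + d, base - d)
  m <- list(
    stand = behavior_motif(
      0L,
      amplitude = c(0.12, 0.10, 0.05, 0.08), frequency = 0.5, harmonics = 1L,
      noise_sd = 0.06,
      offset = 2 * c(0, 0, 0, 0, 0, 1.0, 0.3, 0.1, 0.4, 0, 0.1, 0),
      amp_jitter = 0.3, offset_jitter = 0.1, freq_jitter = 0.08,
      modes = mode_pair(2 * c(0, 0, 0, 0, 0, 1.0, 0.3, 0.1, 0.4, 0, 0.1, 0),
                        c(0, 0, 0, 0, 0.2, 0.1, 0.3, -0.2, 0.1, 0, 0.3, 0.2))
    ),
    walk = behavior_motif(
      1L,
      amplitude = c(0.6, 0.8, 0.2, 0.4), frequency = 2.0, harmonics = 3L,
      noise_sd = 0.10,
      offset = 2 * c(0, 0, 0, 0, 0.35, 0.9, 0.45, 0.15, 0.3, 0.15, 0.45, 0.1),
      amp_jitter = 0.3, offset_jitter = 0.1, freq_jitter = 0.08,
      modes = mode_pair(2 * c(0, 0, 0, 0, 0.35, 0.9, 0.45, 0.15, 0.3, 0.15, 0.45, 0.1),
                        c(0, 0, 0, 0, 0.25, -0.1, 0.2, 0.15, -0.2, 0.1, -0.35, 0.1))
    ),
    sit = behavior_motif(
      2L,
      amplitude = c(0.25, 0.20, 0.10, 0.30), frequency = 0.8, harmonics = 2L,
      noise_sd = 0.07,
      offset = 2 * c(0, 0, 0, 0, -0.4, 0.9, 0.2, 0.3, -0.3, 0.2, -0.5, 0),
      amp_jitter = 0.3, offset_jitter = 0.1, freq_jitter = 0.08,
      modes = mode_pair(2 * c(0, 0, 0, 0, -0.4, 0.9, 0.2, 0.3, -0.3, 0.2, -0.5, 0),
                        c(0, 0, 0, 0, 0.2, -0.15, 0.15, -0.2, 0.2, 0.1, 0.3, -0.1))
    ),
    lying = behavior_motif(
      3L,
      amplitude = c(0.06, 0.05, 0.08, 0.05), frequency = 0.3, harmonics = 1L,
      noise_sd = 0.05,
      offset = 2 * c(0, 0, 0, 0.9, 0.2, 0.2, 0.5, -0.2, 0.1, 1.2, 0.2, 0.3),
      amp_jitter = 0.3, offset_jitter = 0.1, freq_jitter = 0.08,
      modes = mode_pair(2 * c(0, 0, 0, 0.9, 0.2, 0.2, 0.5, -0.2, 0.1, 1.2, 0.2, 0.3),
                        c(0, 0, 0, 0.15, -0.25, 0.1, -0.4, 0.25, -0.1, -0.3, 0.15, -0.2))
    ),
    eat = behavior_motif(
      4L,
      amplitude = c(0.4, 0.6, 0.15, 0.3), frequency = 4.0, harmonics = 2L,
      noise_sd = 0.10,
      offset = 2 * c(0, 0, 0, 0.3, 0, 0.9, 0.1, 0.4, 0.2, 0, -0.8, 0.1),
      amp_jitter = 0.3, offset_jitter = 0.1, freq_jitter = 0.08,
      modes = mode_pair(2 * c(0, 0, 0, 0.3, 0, 0.9, 0.1, 0.4, 0.2, 0, -0.8, 0.1),
                        c(0, 0, 0, 0.2, -0.15, 0.1, 0.15, 0.2, -0.15, 0.1, -0.3, 0.2))
    )
  )
  if (!is.null(noise_sd)) {
    m <- lapply(m, function(x) {
      x$noise_sd <- check_number(noise_sd, "noise_sd", lower = 0)
      x
    })
  }
  m
}
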