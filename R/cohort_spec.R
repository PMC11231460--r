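#' Cohort specification for the synthetic fNIRS generator
#'
#' Describes the recording geometry and the class-difference structure of a
#' simulated two-class resting-state fNIRS cohort: 20 long + 2 short channels
#' sampled at 25 Hz for six minutes by default, with a controllable effect on
#' a chosen subset of (long) channels.
#'
#' @param n_per_class subjects per class (default 20, a balanced 40-subject
#'   cohort).
#' @param n_long_channels number of long-separation channels (default 20).
#' @param n_short_channels number of short-separation scalp channels
#'   (default 2); short channels carry only superficial systemic components.
#' @param fs sampling frequency in Hz (default 25).
#' @param duration_s recording length in seconds (default 360); `duration_s *
#'   fs` must be a whole number of samples.
#' @param effect_channels integer indices of the channels carrying the class
#'   difference (default the first five long channels).
#' @param effect_size dimensionless scaling of the class-dependent component:
#'   on effect channels the Mayer-wave amplitude of case subjects is scaled by
#'   `1 + effect_size` and its centre frequency shifted by
#'   `0.01 * effect_size` Hz. `effect_size = 0` makes the label independent of
#'   the signal distribution.
#' @param noise_sd standard deviation of the additive white measurement noise,
#'   in uM (default 0.1).
#' @param seed integer root seed; per-subject streams are derived from it so
#'   that adding subjects never perturbs earlier ones.
#'
#' @return an object of class `fnirs_cohort_spec`.
#' @seealso [signal_model()], [generate_cohort()]
#' @export
cohort_spec <- function(n_per_class = 20L,
                        n_long_channels = 20L,
                        n_short_channels = 2L,
                        fs = 25,
                        duration_s = 360,
                        effect_channels = 1:5,
                        effect_size = 2,
                        noise_sd = 0.1,
                        seed = 1L) {
  if (n_per_class < 1) stop("`n_per_class` must be >= 1")
  if (n_long_channels < 1 || n_short_channels < 0)
    stop("invalid channel counts")
  if (duration_s <= 0) stop("invalid spec: `duration_s` must be positive")
  if (fs <= 0) stop("invalid spec: `fs` must be positive")
  n_samples <- duration_s * fs
  if (abs(n_samples - round(n_samples)) > 1e-9)
    stop("invalid spec: `duration_s * fs` must be a whole number of samples")
  n_channels <- n_long_channels + n_short_channels
  effect_channels <- as.integer(effect_channels)
  if (length(effect_channels) &&
      (min(effect_channels) < 1 || max(effect_channels) > n_channels))
    stop("`effect_channels` out of channel range")
  structure(list(
    n_per_class = as.integer(n_per_class),
    n_long_channels = as.integer(n_long_channels),
    n_short_channels = as.integer(n_short_channels),
    n_channels = as.integer(n_channels),
    fs = fs,
    duration_s = duration_s,
    n_samples = as.integer(round(n_samples)),
    effect_channels = effect_channels,
    effect_size = effect_size,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "fnirs_cohort_spec")
}

#' Physiological signal model for the synthetic generator
#'
#' Oscillatory components of a resting-state hemodynamic trace: cardiac
#' pulsation (~1.1 Hz), respiration (~0.25 Hz), Mayer waves (~0.1 Hz) and a
#' slow vasomotor drift (<0.02 Hz). Amplitudes are oxyhemoglobin amplitudes in
#' uM; deoxyhemoglobin receives each component scaled by `hbr_ratio`
#' (anti-correlated, as in resting cortical physiology). `freq_jitter` is the
#' per-channel standard deviation of the component centre frequency, so that
#' channels are not phase-locked copies of one another.
#'
#' @param components data.frame with columns `name`, `freq_hz`, `amplitude`,
#'   `freq_jitter`. The default makes the Mayer wave the largest-amplitude
#'   component, so it is the dominant spectral peak of every channel.
#' @param hbr_ratio HbR/HbO component amplitude ratio (default -0.3).
#' @param spike_rate motion spikes per minute for [inject_artifacts()].
#' @param shift_rate baseline shifts per minute for [inject_artifacts()].
#' @param spike_amplitude spike height as a multiple of the channel sd.
#' @param shift_amplitude baseline step height as a multiple of the channel sd.
#' @param fs_check sampling frequency the model will be used at; all component
#'   frequencies must lie below `fs_check / 2`.
#'
#' @return an object of class `fnirs_signal_model`.
#' @export
signal_model <- function(components = NULL,
                         hbr_ratio = -0.3,
                         spike_rate = 0,
                         shift_rate = 0,
                         spike_amplitude = 10,
                         shift_amplitude = 5,
                         fs_check = 25) {
  if (is.null(components)) {
    components <- data.frame(
      name = c("cardiac", "respiratory", "mayer", "drift"),
      freq_hz = c(1.1, 0.25, 0.10, 0.012),
      amplitude = c(0.25, 0.15, 0.40, 0.20),
      freq_jitter = c(0.05, 0.02, 0.005, 0.001),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(c("name", "freq_hz", "amplitude", "freq_jitter") %in%
                  names(components)))
  if (any(components$freq_hz >= fs_check / 2))
    stop("aliasing error: component frequency at or above fs/2")
  if (spike_rate < 0 || shift_rate < 0) stop("artifact rates must be >= 0")
  structure(list(
    components = components,
    hbr_ratio = hbr_ratio,
    spike_rate = spike_rate,
    shift_rate = shift_rate,
    spike_amplitude = spike_amplitude,
    shift_amplitude = shift_amplitude
  ), class = "fnirs_signal_model")
}

#' @export
print.fnirs_cohort_spec <- function(x, ...) {
  cat("fNIRS synthetic cohort spec\n")
  cat(sprintf("  subjects: %d per class (%d total)\n",
              x$n_per_class, 2L * x$n_per_class))
  cat(sprintf("  channels: %d long + %d short = %d\n",
              x$n_long_channels, x$n_short_channels, x$n_channels))
  cat(sprintf("  sampling: %g Hz x %g s = %d samples\n",
              x$fs, x$duration_s, x$n_samples))
  cat(sprintf("  effect: size %g on channels %s\n", x$effect_size,
              paste(x$effect_channels, collapse = ",")))
  invisible(x)
}
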