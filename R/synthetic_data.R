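# Synthetic 14-channel EEG-like generator. Each command class is a set
# of sinusoidal tones (distinct frequencies below the 32 Hz feature
# ceiling, on a class-specific channel subset) plus Gaussian noise, so
# classes are separable in the spectral feature space and the whole
# pipeline can be exercised without headset hardware. Command classes
# carry more spectral power than the low-amplitude neutral class,
# mirroring how gesture-driven EEG fluctuates more than a resting pose.

#' Specification of one synthetic command class
#'
#' @param name class name (one of [command_classes]).
#' @param tone_freqs tone frequencies in Hz, each in `(0, 32)` so every
#'   tone falls inside the 64-bin (0–31.5 Hz) feature range.
#' @param tone_amps matching amplitudes (arbitrary amplifier units).
#' @param active_channels channel names carrying the tones; all other
#'   channels carry noise only.
#' @param noise_sd standard deviation of the additive Gaussian noise on
#'   every channel (default 0.05).
#' @return a `class_spec` list.
#' @export
class_spec <- function(name, tone_freqs, tone_amps,
                       active_channels = emotiv_channels,
                       noise_sd = 0.05) {
  if (any(tone_freqs <= 0 | tone_freqs >= 32))
    abort("tone frequencies must lie in (0, 32) Hz", "fnnbci_bad_frequency")
  if (length(tone_amps) != length(tone_freqs))
    abort("one amplitude per tone required", "fnnbci_bad_shape")
  if (noise_sd < 0) abort("noise_sd must be >= 0", "fnnbci_bad_noise")
  structure(list(name = name, tone_freqs = tone_freqs,
                 tone_amps = tone_amps,
                 active_channels = active_channels, noise_sd = noise_sd),
            class = "class_spec")
}

#' Default six-class tone specifications
#'
#' Neutral is a single low-amplitude 10 Hz tone on all channels; the
#' five command classes carry distinct higher-amplitude frequency pairs
#' on distinct frontal-to-parietal channel subsets, so each class owns
#' its spectral signature and commands exceed neutral in total power.
#' All frequencies are integer Hz, i.e. exactly on a 0.5 Hz analysis
#' bin.
#'
#' @param noise_sd Gaussian noise level shared by all classes
#'   (default 0.05).
#' @return named list of six [class_spec()] objects.
#' @export
default_class_specs <- function(noise_sd = 0.05) {
  specs <- list(
    class_spec("neutral", 10, 0.4, emotiv_channels, noise_sd),
    class_spec("forward", c(6, 21), c(1.5, 1.2),
               emotiv_channels[1:4], noise_sd),
    class_spec("backward", c(8, 25), c(1.5, 1.2),
               emotiv_channels[3:6], noise_sd),
    class_spec("left", c(12, 17), c(1.5, 1.2),
               emotiv_channels[5:8], noise_sd),
    class_spec("right", c(14, 27), c(1.5, 1.2),
               emotiv_channels[7:10], noise_sd),
    class_spec("switch_on", c(5, 29), c(1.5, 1.2),
               emotiv_channels[9:12], noise_sd))
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

#' Generate one synthetic labelled recording
#'
#' Active channels receive the sum of the class tones, each with a
#' random (seeded) phase; every channel additionally receives
#' independent Gaussian noise of the spec's standard deviation.
#'
#' @param spec a [class_spec()].
#' @param duration_s recording length in seconds (default 10, the
#'   per-class recording time of the experimental protocol).
#' @param sample_rate samples per second (default 128).
#' @param seed RNG seed; the recording is reproducible given the seed.
#' @return a labelled `eeg_recording` with the 14 default channels.
#' @export
generate_recording <- function(spec, duration_s = 10.0, sample_rate = 128,
                               seed = NULL) {
  n_exact <- duration_s * sample_rate
  N <- as.integer(round(n_exact))
  if (abs(n_exact - N) > 1e-9 || N < 1L)
    abort("duration_s * sample_rate must be a positive integer",
          "fnnbci_bad_duration")
  if (any(spec$tone_freqs >= 32))
    abort("tone frequency outside the 0-32 Hz feature range",
          "fnnbci_bad_frequency")
  if (!is.null(seed)) set.seed(seed)
  channels <- emotiv_channels
  t <- (seq_len(N) - 1L) / sample_rate
  data <- matrix(stats::rnorm(N * length(channels), sd = spec$noise_sd),
                 N, length(channels))
  phases <- stats::runif(length(spec$tone_freqs), 0, 2 * pi)
  tone <- rowSums(vapply(seq_along(spec$tone_freqs), function(i)
    spec$tone_amps[i] * sin(2 * pi * spec$tone_freqs[i] * t + phases[i]),
    numeric(N)))
  active <- match(spec$active_channels, channels)
  data[, active] <- data[, active] + tone
  recording(data, channels, sample_rate, label = spec$name)
}

#' Generate a labelled multi-class dataset
#'
#' One or more recordings per class, with per-recording seeds derived
#' deterministically from the dataset seed.
#'
#' @param n_per_class recordings per class (default 1).
#' @param specs list of [class_spec()]s (default [default_class_specs()]).
#' @param duration_s seconds per recording (default 10).
#' @param sample_rate samples per second (default 128).
#' @param seed dataset seed.
#' @return list of labelled `eeg_recording` objects, grouped by class.
#' @export
generate_dataset <- function(n_per_class = 1L,
                             specs = default_class_specs(),
                             duration_s = 10.0, sample_rate = 128,
                             seed = 1L) {
  if (n_per_class < 1L)
    abort("need at least one recording per class", "fnnbci_bad_config")
  recs <- list()
  idx <- 0L
  for (spec in specs) {
    for (k in seq_len(n_per_class)) {
      idx <- idx + 1L
      recs[[idx]] <- generate_recording(
        spec, duration_s, sample_rate,
        seed = as.integer((as.double(seed) * 7919 + idx) %% 2147483647))
    }
  }
  recs
}
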