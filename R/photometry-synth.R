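#' Photometry generator parameters
#'
#' The synthetic recording emulates a two-channel fiber-photometry setup: the
#' activity channel carries the indicator-convolved population rate plus a
#' shared motion artifact and noise; the reference channel carries only the
#' artifact (scaled by its own gain) and noise. Both are sampled at 130 Hz. An
#' optional exponential bleaching trend is added to both channels.
#'
#' @param fs_hz sampling rate.
#' @param tau_rise_s,tau_decay_s indicator kernel time constants (seconds).
#' @param signal_scale fluorescence units per (Hz of population rate), after
#'   kernel convolution.
#' @param artifact_amplitude standard deviation of the shared motion artifact
#'   (fluorescence units); the artifact itself is low-pass filtered noise.
#' @param artifact_cut_hz bandwidth of the motion artifact.
#' @param gain_activity,gain_reference artifact gain in each channel.
#' @param noise_sd independent white noise sd per channel.
#' @param baseline_f static fluorescence offset added to both channels (keeps
#'   dF/F baselines positive).
#' @param bleach_amplitude,bleach_tau_s exponential bleaching trend
#'   `amplitude * exp(-t/tau)` added to both channels (amplitude 0 = off).
#' @return a list of class `phot_params`.
#' @export
phot_params <- function(fs_hz = 130,
                        tau_rise_s = 0.05,
                        tau_decay_s = 0.5,
                        signal_scale = 1.0,
                        artifact_amplitude = 2.0,
                        artifact_cut_hz = 1.0,
                        gain_activity = 1.0,
                        gain_reference = 1.25,
                        noise_sd = 0.1,
                        baseline_f = 100,
                        bleach_amplitude = 0,
                        bleach_tau_s = 600) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(as.list(environment()), class = "phot_params")
}

#' Simulate a two-channel photometry recording with ground truth
#'
#' The population rate profile implied by the template and events is convolved
#' with a difference-of-exponentials indicator kernel (unit peak), scaled, and
#' mixed with a shared low-frequency motion artifact, per-channel white noise,
#' a static fluorescence offset, and an optional bleaching trend.
#'
#' @param events a `session_events` object.
#' @param template a [population_template()] giving the event modulation the
#'   fluorescence follows.
#' @param params a [phot_params()].
#' @param seed integer seed.
#' @return a list with `recording` (class `photometry_recording`: `activity`,
#'   `reference`, `fs_hz`, `events`) and `ground_truth` (class
#'   `photometry_ground_truth`: `true_signal`, `artifact`, `gains`,
#'   `noise_sd`).
#' @export
simulate_photometry <- function(events, template, params = phot_params(),
                                seed = 1L) {
  stopifnot(inherits(events, "session_events"),
            inherits(params, "phot_params"))
  with_seed(seed, {
    fs <- params$fs_hz
    dt <- 1 / fs
    n <- as.integer(floor(events$session_duration_s * fs))
    rate <- event_rate_profile(template, events, dt_s = dt)[seq_len(n)]

    # indicator kernel: (1 - exp(-t/tau_r)) * exp(-t/tau_d), normalized to peak 1
    tk <- seq(0, 6 * params$tau_decay_s, by = dt)
    kern <- (1 - exp(-tk / params$tau_rise_s)) * exp(-tk / params$tau_decay_s)
    kern <- kern / max(kern)
    sig <- stats::convolve(rate - template$tonic_rate_hz,
                           rev(kern), type = "open")[seq_len(n)] * dt
    true_signal <- params$signal_scale * sig

    artifact <- if (params$artifact_amplitude > 0) {
      raw <- stats::rnorm(n)
      bf <- signal::butter(2, min(0.99, params$artifact_cut_hz / (fs / 2)),
                           type = "low")
      a <- filtfilt_ss(bf$b, bf$a, raw)
      a <- a - mean(a)
      a * params$artifact_amplitude / stats::sd(a)
    } else {
      numeric(n)
    }

    t_grid <- (seq_len(n) - 1) * dt
    bleach <- params$bleach_amplitude * exp(-t_grid / params$bleach_tau_s)

    activity <- params$baseline_f + true_signal +
      params$gain_activity * artifact + bleach +
      stats::rnorm(n, 0, params$noise_sd)
    reference <- params$baseline_f + params$gain_reference * artifact + bleach +
      stats::rnorm(n, 0, params$noise_sd)

    recording <- structure(
      list(activity = activity, reference = reference, fs_hz = fs,
           events = events),
      class = "photometry_recording"
    )
    ground_truth <- structure(
      list(true_signal = true_signal, artifact = artifact,
           gains = c(activity = params$gain_activity,
                     reference = params$gain_reference),
           noise_sd = c(activity = params$noise_sd,
                        reference = params$noise_sd)),
      class = "photometry_ground_truth"
    )
    list(recording = recording, ground_truth = ground_truth)
  })
}
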