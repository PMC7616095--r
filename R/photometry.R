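#' Condition one photometry channel
#'
#' The acquisition filter chain applied to both channels: a 5-sample median
#' filter (despiking), a zero-phase second-order Butterworth low-pass at
#' `low_cut_hz`, and a zero-phase second-order Butterworth high-pass at
#' `high_cut_hz` correcting for photobleaching. The DC level removed by the
#' high-pass is kept as attribute `dc_offset` so the dF/F baseline can be
#' computed on a strictly positive signal.
#'
#' @param trace raw channel samples.
#' @param fs_hz sampling rate (must exceed twice `low_cut_hz`).
#' @param low_cut_hz low-pass cutoff (default 20 Hz).
#' @param high_cut_hz high-pass cutoff (default 0.001 Hz).
#' @param median_k median-filter kernel width (odd; 1 disables despiking).
#' @return conditioned trace with attribute `dc_offset` (mean level before
#'   high-pass).
#' @export
condition_channel <- function(trace, fs_hz = 130, low_cut_hz = 20,
                              high_cut_hz = 0.001, median_k = 5) {
  if (any(!is.finite(trace))) stop("non-finite samples in trace")
  if (fs_hz <= 2 * low_cut_hz) stop("sampling rate must exceed twice the low-pass cutoff")
  x <- if (median_k > 1) {
    stats::runmed(trace, k = median_k, endrule = "median")
  } else {
    trace
  }
  lp <- signal::butter(2, low_cut_hz / (fs_hz / 2), type = "low")
  x <- filtfilt_ss(lp$b, lp$a, as.numeric(x))
  dc <- mean(x)
  hp <- signal::butter(2, high_cut_hz / (fs_hz / 2), type = "high")
  y <- filtfilt_ss(hp$b, hp$a, x)
  attr(y, "dc_offset") <- dc
  y
}

#' Reference-channel motion correction
#'
#' Subtracts the best linear fit (ordinary least squares, with intercept) of
#' the reference channel from the activity channel. Whatever moves both
#' channels — motion of the fiber relative to tissue — is removed up to the
#' gain difference; a constant reference yields an intercept-only fit
#' (mean-centering) and a warning.
#'
#' @param activity conditioned activity-channel trace.
#' @param reference conditioned reference-channel trace.
#' @return corrected trace (activity minus fit) with attributes `slope` and
#'   `intercept`.
#' @export
motion_correct <- function(activity, reference) {
  if (length(activity) != length(reference)) stop("channel lengths differ")
  if (stats::sd(reference) == 0) {
    warning("constant reference channel; intercept-only correction")
    out <- activity - mean(activity)
    attr(out, "slope") <- 0
    attr(out, "intercept") <- mean(activity)
    return(out)
  }
  fit <- stats::lm.fit(cbind(1, reference), activity)
  out <- as.numeric(fit$residuals)
  attr(out, "slope") <- unname(fit$coefficients[2])
  attr(out, "intercept") <- unname(fit$coefficients[1])
  out
}

#' Fractional fluorescence change (dF/F)
#'
#' The baseline is a zero-phase second-order 0.001-Hz Butterworth low-pass of
#' the motion-corrected signal after restoring its pre-high-pass mean offset
#' (so the baseline is strictly positive where the raw fluorescence was);
#' dF/F is the corrected signal divided by that baseline.
#'
#' @param corrected motion-corrected trace (mean approximately zero).
#' @param dc_offset mean fluorescence level removed by the conditioning
#'   high-pass (attribute `dc_offset` of [condition_channel()]).
#' @param fs_hz sampling rate.
#' @param baseline_cut_hz baseline low-pass cutoff.
#' @return a `processed_trace`: `dff`, `baseline`, `corrected`.
#' @export
compute_dff <- function(corrected, dc_offset, fs_hz = 130,
                        baseline_cut_hz = 0.001) {
  lp <- signal::butter(2, baseline_cut_hz / (fs_hz / 2), type = "low")
  baseline <- filtfilt_ss(lp$b, lp$a, as.numeric(corrected) + dc_offset)
  if (any(baseline <= 0)) {
    stop("non-positive baseline at sample ", which(baseline <= 0)[1])
  }
  structure(list(dff = as.numeric(corrected) / baseline, baseline = baseline,
                 corrected = as.numeric(corrected)),
            class = "processed_trace")
}

#' Cue-aligned dF/F sweeps, normalized to the pre-cue second
#'
#' Extracts a window around every cue onset and subtracts, per sweep, the
#' mean of its 1-s pre-cue samples, so each sweep's pre-cue mean is exactly
#' zero. Trials whose window leaves the trace are dropped with a warning.
#'
#' @param dff dF/F samples (or a `processed_trace`).
#' @param events a `session_events`.
#' @param fs_hz sampling rate.
#' @param window window around cue onset, seconds.
#' @param norm_s pre-cue normalization span, seconds.
#' @return a `trial_sweeps`: `sweeps` (trials x samples), `time_s` (relative
#'   to cue), `trials` (retained trial indices).
#' @export
extract_sweeps <- function(dff, events, fs_hz = 130, window = c(-1, 4),
                           norm_s = 1) {
  if (inherits(dff, "processed_trace")) dff <- dff$dff
  n_samp <- round((window[2] - window[1]) * fs_hz)
  rel_idx <- round(window[1] * fs_hz) + seq_len(n_samp) - 1
  time_s <- rel_idx / fs_hz
  pre <- which(time_s >= -norm_s & time_s < 0)
  rows <- list()
  kept <- integer(0)
  for (k in seq_along(events$cue_onsets_s)) {
    idx <- round(events$cue_onsets_s[k] * fs_hz) + 1 + rel_idx
    if (idx[1] < 1 || idx[n_samp] > length(dff)) {
      warning("trial ", k, " window outside trace; dropped")
      next
    }
    sweep_k <- dff[idx]
    rows[[length(rows) + 1]] <- sweep_k - mean(sweep_k[pre])
    kept <- c(kept, k)
  }
  if (!length(rows)) stop("no trial window fits in the trace")
  structure(list(sweeps = do.call(rbind, rows), time_s = time_s,
                 trials = kept, fs_hz = fs_hz,
                 reward_delay_s = if (length(events$reward_times_s)) {
                   events$reward_times_s[1] - events$cue_onsets_s[1]
                 } else {
                   NA_real_
                 }),
            class = "trial_sweeps")
}

#' Mean peak dF/F change at reward
#'
#' Per-trial maximum of the normalized sweep within a post-reward window,
#' averaged over trials.
#'
#' @param sweeps a `trial_sweeps`.
#' @param window window relative to reward delivery, seconds.
#' @return mean peak dF/F (scalar).
#' @export
peak_reward_response <- function(sweeps, window = c(0, 1)) {
  stopifnot(inherits(sweeps, "trial_sweeps"))
  lo <- sweeps$reward_delay_s + window[1]
  hi <- sweeps$reward_delay_s + window[2]
  cols <- which(sweeps$time_s >= lo & sweeps$time_s < hi)
  if (!length(cols)) stop("empty post-reward window")
  mean(apply(sweeps$sweeps[, cols, drop = FALSE], 1, max))
}

#' Full photometry processing chain
#'
#' Conditioning of both channels, motion correction, dF/F, and sweep
#' extraction, in the acquisition order: median filter, low-pass, high-pass,
#' reference subtraction, baseline division, per-sweep normalization.
#'
#' @param recording a `photometry_recording`.
#' @param window sweep window around cue, seconds.
#' @return a list: `processed` (`processed_trace`), `sweeps`
#'   (`trial_sweeps`), `peak_reward_dff`.
#' @export
process_photometry <- function(recording, window = c(-1, 4)) {
  stopifnot(inherits(recording, "photometry_recording"))
  fs <- recording$fs_hz
  act <- condition_channel(recording$activity, fs)
  ref <- condition_channel(recording$reference, fs)
  corrected <- motion_correct(as.numeric(act), as.numeric(ref))
  processed <- compute_dff(corrected, attr(act, "dc_offset"), fs)
  sweeps <- extract_sweeps(processed, recording$events, fs, window)
  list(processed = processed, sweeps = sweeps,
       peak_reward_dff = peak_reward_response(sweeps))
}
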