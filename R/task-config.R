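#' Pavlovian task configuration
#'
#' Parameters of the head-fixed conditioning paradigm: a 1-s auditory cue
#' predicts reward at a fixed 2-s delay from cue onset, and consecutive trials
#' are separated by inter-trial intervals drawn from a flat-hazard (shifted,
#' truncated exponential) distribution on 4--10 s whose median is 5.4 s.
#'
#' @param n_trials number of cue/reward trials (default 100, one session).
#' @param cue_duration_s cue length in seconds.
#' @param cue_reward_delay_s delay from cue onset to reward delivery, seconds.
#' @param iti_support_s closed interval (seconds) the ITI is confined to.
#' @param iti_median_s target median of the ITI distribution; the exponential
#'   rate constant is calibrated by root finding so the truncated median equals
#'   this value. Ignored when `iti_rate_per_s` is given.
#' @param iti_rate_per_s optional explicit rate constant (1/s) of the
#'   underlying exponential.
#' @param session_padding_s event-free seconds at session start and end.
#' @param seed integer master seed.
#' @return an object of class `task_config`.
#' @examples
#' cfg <- task_config()
#' cfg$iti_rate_per_s
#' @export
task_config <- function(n_trials = 100,
                        cue_duration_s = 1.0,
                        cue_reward_delay_s = 2.0,
                        iti_support_s = c(4, 10),
                        iti_median_s = 5.4,
                        iti_rate_per_s = NULL,
                        session_padding_s = 10,
                        seed = 1L) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (cue_duration_s <= 0 || cue_reward_delay_s <= 0 || session_padding_s <= 0) {
    stop("all durations must be positive")
  }
  if (length(iti_support_s) != 2 || iti_support_s[1] >= iti_support_s[2]) {
    stop("iti_support_s must be an interval (lower < upper)")
  }
  if (is.null(iti_rate_per_s)) {
    iti_rate_per_s <- calibrate_iti_rate(iti_support_s[1], iti_support_s[2],
                                         iti_median_s)
  }
  if (iti_rate_per_s <= 0) stop("iti_rate_per_s must be positive")
  structure(
    list(n_trials = as.integer(n_trials),
         cue_duration_s = cue_duration_s,
         cue_reward_delay_s = cue_reward_delay_s,
         iti_support_s = iti_support_s,
         iti_median_s = iti_median_s,
         iti_rate_per_s = iti_rate_per_s,
         session_padding_s = session_padding_s,
         seed = as.integer(seed)),
    class = "task_config"
  )
}

#' Calibrate the ITI exponential rate to a target truncated median
#'
#' The ITI is `lower + E` with `E ~ Exp(rate)`, redrawn until the total is at
#' most `upper`. The median of that truncated distribution solves
#' `(1 - exp(-r (m - lower))) / (1 - exp(-r (upper - lower))) = 1/2`,
#' which this function inverts for `r` by bracketed root finding.
#'
#' @param lower,upper support bounds in seconds.
#' @param median_s target median in seconds; must lie strictly inside the
#'   lower half of the support for an exponential shape.
#' @return rate constant in 1/s.
#' @export
calibrate_iti_rate <- function(lower = 4, upper = 10, median_s = 5.4) {
  stopifnot(lower < median_s, median_s < upper)
  f <- function(r) {
    (1 - exp(-r * (median_s - lower))) / (1 - exp(-r * (upper - lower))) - 0.5
  }
  # r -> 0 gives uniform-like median at the support midpoint; large r pulls the
  # median toward `lower`, so a sign change exists whenever median < midpoint
  stats::uniroot(f, c(1e-6, 50), tol = 1e-12)$root
}

#' Behavioral bout parameters for the session generator
#'
#' Lick and movement bouts are generated directly at the event level (the
#' acquisition-side EMG/video scoring is out of scope): one anticipatory lick
#' bout per trial after cue onset, one consummatory bout after each reward, and
#' spontaneous movement bouts as a Poisson process confined to inter-trial
#' intervals.
#'
#' @param lick_latency_s latency from cue onset to anticipatory licking.
#' @param anticipatory_duration_s anticipatory bout length, seconds.
#' @param consummatory_latency_s latency from reward to consummatory licking.
#' @param consummatory_duration_s consummatory bout length, seconds.
#' @param movement_rate_per_s rate of spontaneous movement bout onsets within
#'   ITIs (Poisson process).
#' @param movement_duration_s movement bout length, seconds.
#' @param avoid_reward_window_s movement bouts are clipped so they do not enter
#'   this many seconds after each reward (set 0 to disable).
#' @return a list of class `behavior_params`.
#' @export
behavior_params <- function(lick_latency_s = 0.5,
                            anticipatory_duration_s = 1.5,
                            consummatory_latency_s = 0.1,
                            consummatory_duration_s = 2.5,
                            movement_rate_per_s = 0.06,
                            movement_duration_s = 1.5,
                            avoid_reward_window_s = 3.0) {
  p <- list(lick_latency_s = lick_latency_s,
            anticipatory_duration_s = anticipatory_duration_s,
            consummatory_latency_s = consummatory_latency_s,
            consummatory_duration_s = consummatory_duration_s,
            movement_rate_per_s = movement_rate_per_s,
            movement_duration_s = movement_duration_s,
            avoid_reward_window_s = avoid_reward_window_s)
  if (anticipatory_duration_s <= 0 || consummatory_duration_s <= 0 ||
      movement_duration_s <= 0) {
    stop("bout durations must be positive")
  }
  if (movement_rate_per_s < 0) stop("movement_rate_per_s must be >= 0")
  structure(p, class = "behavior_params")
}

#' Response template of a projection-defined dopamine population
#'
#' Firing is an inhomogeneous Poisson process: a tonic rate multiplied, during
#' each event window, by that event's gain (gain 1 = no modulation, gain < 1 a
#' firing decrease; overlapping modulations multiply). `pause_rate_per_min`
#' inserts complete firing cessations of `pause_duration_s`, emulating the
#' longer pauses of the accumbens-core population.
#'
#' The paper reports only qualitative response patterns per population, so the
#' default gains are generator choices encoding those orderings, not measured
#' values; see the package vignette.
#'
#' @param population one of `"DMS"`, `"DLS"`, `"VLS"`, `"NAcCore"`, or
#'   `"custom"`.
#' @param tonic_rate_hz baseline firing rate, spikes/s.
#' @param cue,reward,lick,movement per-event modulation, each a numeric vector
#'   `c(gain, latency_s, duration_s)`. For cue/reward the window is
#'   `[onset + latency, onset + latency + duration)`; for lick/movement the
#'   gain applies over each bout shifted by the latency (duration `NA` = full
#'   bout length).
#' @param pause_rate_per_min rate of inserted firing pauses.
#' @param pause_duration_s duration of each inserted pause.
#' @return an object of class `population_template`.
#' @examples
#' population_template("VLS")
#' @export
population_template <- function(population = c("custom", "DMS", "DLS", "VLS", "NAcCore"),
                                tonic_rate_hz = 6,
                                cue = c(gain = 1, latency_s = 0, duration_s = 0.25),
                                reward = c(gain = 1, latency_s = 0.04, duration_s = 0.2),
                                lick = c(gain = 1, latency_s = 0, duration_s = NA),
                                movement = c(gain = 1, latency_s = 0, duration_s = NA),
                                pause_rate_per_min = 0,
                                pause_duration_s = 0.5) {
  population <- match.arg(population)
  mods <- list(cue = cue, reward = reward, lick = lick, movement = movement)
  for (nm in names(mods)) {
    m <- unname(mods[[nm]])
    if (length(m) != 3) stop("modulation for ", nm, " must be (gain, latency_s, duration_s)")
    if (m[1] < 0) stop("gains must be >= 0")
    mods[[nm]] <- list(gain = m[1], latency_s = m[2], duration_s = m[3])
  }
  if (tonic_rate_hz < 0) stop("tonic_rate_hz must be >= 0")
  structure(
    c(list(population = population, tonic_rate_hz = tonic_rate_hz), mods,
      list(pause_rate_per_min = pause_rate_per_min,
           pause_duration_s = pause_duration_s)),
    class = "population_template"
  )
}

#' Default templates for the four projection-defined populations
#'
#' Encodes the qualitative response patterns of the four striatal projection
#' targets: DMS responds to cue but not reward; DLS responds to both and
#' multiplexes licking; VLS ignores the cue but shows a strong short-latency
#' reward response; NAc core has a lower tonic rate, delayed lick-locked
#' increases, and longer pauses. DMS and DLS decrease firing at movement.
#'
#' @param population population label.
#' @return a [population_template()].
#' @export
default_template <- function(population = c("DMS", "DLS", "VLS", "NAcCore")) {
  population <- match.arg(population)
  switch(population,
    DMS = population_template("DMS", tonic_rate_hz = 6,
      cue = c(2.6, 0.02, 0.20), reward = c(1.0, 0.04, 0.20),
      lick = c(1.0, 0, NA), movement = c(0.6, 0, NA)),
    DLS = population_template("DLS", tonic_rate_hz = 6,
      cue = c(2.2, 0.02, 0.20), reward = c(2.0, 0.04, 0.20),
      lick = c(1.4, 0, NA), movement = c(0.6, 0, NA)),
    VLS = population_template("VLS", tonic_rate_hz = 6,
      cue = c(1.0, 0, 0.25), reward = c(3.0, 0.04, 0.20),
      lick = c(1.0, 0, NA), movement = c(1.0, 0, NA)),
    NAcCore = population_template("NAcCore", tonic_rate_hz = 3.5,
      cue = c(1.8, 0.30, 0.30), reward = c(2.0, 0.35, 0.40),
      lick = c(1.5, 0.05, NA), movement = c(1.0, 0, NA),
      pause_rate_per_min = 2, pause_duration_s = 1.0)
  )
}
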