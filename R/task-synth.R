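#' Sample inter-trial intervals
#'
#' ITIs are `lower + E`, `E ~ Exp(rate)`, redrawn (rejection) until the total
#' is within the support. The flat hazard of the exponential keeps reward
#' expectation constant through the interval; truncation confines it to the
#' configured support. With the calibrated default rate the median is 5.4 s on
#' support 4--10 s.
#'
#' @param n number of draws.
#' @param config a [task_config()].
#' @return numeric vector of `n` ITIs in seconds.
#' @examples
#' cfg <- task_config(seed = 1)
#' set.seed(1)
#' range(sample_iti(1000, cfg))
#' @export
sample_iti <- function(n, config) {
  stopifnot(inherits(config, "task_config"))
  if (config$iti_rate_per_s <= 0) stop("iti_rate_per_s must be positive")
  lo <- config$iti_support_s[1]
  hi <- config$iti_support_s[2]
  out <- numeric(0)
  while (length(out) < n) {
    draw <- lo + stats::rexp(n - length(out), rate = config$iti_rate_per_s)
    out <- c(out, draw[draw <= hi])
  }
  out[seq_len(n)]
}

#' Construct a session event set
#'
#' Low-level constructor used by the generator and for hand-built sessions.
#' Bout tables are data frames with `onset_s`/`offset_s` columns; omitted
#' bouts default to empty.
#'
#' @param cue_onsets_s strictly ascending cue onset times, seconds.
#' @param reward_times_s reward delivery times, seconds.
#' @param lick_bouts,movement_bouts bout data frames.
#' @param session_duration_s total session length, seconds.
#' @return a `session_events` object.
#' @export
session_events <- function(cue_onsets_s, reward_times_s,
                           lick_bouts = NULL, movement_bouts = NULL,
                           session_duration_s) {
  empty <- data.frame(onset_s = numeric(0), offset_s = numeric(0))
  lick_bouts <- lick_bouts %||% empty
  movement_bouts <- movement_bouts %||% empty
  stopifnot(!is.unsorted(cue_onsets_s, strictly = TRUE),
            all(c(cue_onsets_s, reward_times_s) >= 0),
            all(c(cue_onsets_s, reward_times_s) <= session_duration_s))
  for (b in list(lick_bouts, movement_bouts)) {
    if (nrow(b)) stopifnot(all(b$offset_s > b$onset_s))
  }
  structure(
    list(cue_onsets_s = cue_onsets_s,
         reward_times_s = reward_times_s,
         lick_bouts = lick_bouts,
         movement_bouts = movement_bouts,
         session_duration_s = session_duration_s),
    class = "session_events"
  )
}

new_session_events <- session_events

#' Generate the event structure of one conditioning session
#'
#' Lays out `n_trials` cue/reward pairs separated by sampled ITIs (measured
#' from reward delivery to the next cue onset), adds one anticipatory lick
#' bout per trial and one consummatory bout per reward, and scatters movement
#' bouts through the ITIs as a Poisson process, optionally clipped away from
#' the post-reward consumption window.
#'
#' @param config a [task_config()].
#' @param behavior a [behavior_params()].
#' @param seed integer seed; defaults to the config seed.
#' @return a `session_events` object: ascending `cue_onsets_s`,
#'   `reward_times_s` at exactly the configured delay after each cue,
#'   `lick_bouts` and `movement_bouts` as data frames of `(onset_s, offset_s)`,
#'   and `session_duration_s`.
#' @examples
#' ev <- generate_session_events(task_config(n_trials = 5))
#' ev$reward_times_s - ev$cue_onsets_s
#' @export
generate_session_events <- function(config, behavior = behavior_params(),
                                    seed = config$seed) {
  stopifnot(inherits(config, "task_config"), inherits(behavior, "behavior_params"))
  with_seed(seed, {
    n <- config$n_trials
    itis <- sample_iti(n, config) # iti k separates reward k from cue k+1
    cue <- numeric(n)
    cue[1] <- config$session_padding_s
    if (n > 1) {
      for (k in 2:n) {
        cue[k] <- cue[k - 1] + config$cue_reward_delay_s + itis[k - 1]
      }
    }
    reward <- cue + config$cue_reward_delay_s
    duration <- reward[n] + itis[n] + config$session_padding_s

    lick_on <- c(cue + behavior$lick_latency_s,
                 reward + behavior$consummatory_latency_s)
    lick_off <- c(cue + behavior$lick_latency_s + behavior$anticipatory_duration_s,
                  reward + behavior$consummatory_latency_s +
                    behavior$consummatory_duration_s)
    ord <- order(lick_on)
    lick <- merge_bouts(data.frame(onset_s = lick_on[ord], offset_s = lick_off[ord]))

    # ITI spans available to spontaneous movement
    iti_start <- reward + behavior$avoid_reward_window_s
    iti_end <- c(cue[-1], duration)
    mv_on <- numeric(0)
    for (k in seq_len(n)) {
      span <- iti_end[k] - iti_start[k]
      if (span <= behavior$movement_duration_s) next
      n_mv <- stats::rpois(1, behavior$movement_rate_per_s * span)
      if (n_mv > 0) {
        on <- iti_start[k] +
          sort(stats::runif(n_mv, 0, span - behavior$movement_duration_s))
        mv_on <- c(mv_on, on)
      }
    }
    movement <- if (length(mv_on)) {
      merge_bouts(data.frame(onset_s = mv_on,
                             offset_s = mv_on + behavior$movement_duration_s))
    } else {
      data.frame(onset_s = numeric(0), offset_s = numeric(0))
    }
    new_session_events(cue, reward, lick, movement, duration)
  })
}

# collapse overlapping bouts of one kind into disjoint intervals
merge_bouts <- function(bouts) {
  if (nrow(bouts) < 2) return(bouts)
  stopifnot(all(bouts$offset_s > bouts$onset_s))
  on <- bouts$onset_s
  off <- bouts$offset_s
  keep_on <- on[1]
  keep_off <- off[1]
  for (i in 2:length(on)) {
    j <- length(keep_on)
    if (on[i] <= keep_off[j]) {
      keep_off[j] <- max(keep_off[j], off[i])
    } else {
      keep_on <- c(keep_on, on[i])
      keep_off <- c(keep_off, off[i])
    }
  }
  data.frame(onset_s = keep_on, offset_s = keep_off)
}

#' Piecewise-constant firing-rate profile implied by a template and events
#'
#' @param template a [population_template()].
#' @param events a `session_events` object.
#' @param dt_s grid resolution, seconds (default 1 ms).
#' @return numeric vector of rates (Hz) on the grid `[0, session_duration)`.
#' @keywords internal
event_rate_profile <- function(template, events, dt_s = 0.001) {
  n_bins <- ceiling(events$session_duration_s / dt_s)
  rate <- rep(template$tonic_rate_hz, n_bins)
  apply_gain <- function(rate, on, off, gain) {
    if (gain == 1) return(rate)
    i0 <- pmax(1L, as.integer(floor(on / dt_s)) + 1L)
    i1 <- pmin(n_bins, as.integer(ceiling(off / dt_s)))
    for (k in seq_along(i0)) {
      if (i1[k] >= i0[k]) rate[i0[k]:i1[k]] <- rate[i0[k]:i1[k]] * gain
    }
    rate
  }
  for (ev in c("cue", "reward")) {
    m <- template[[ev]]
    onsets <- if (ev == "cue") events$cue_onsets_s else events$reward_times_s
    rate <- apply_gain(rate, onsets + m$latency_s,
                       onsets + m$latency_s + m$duration_s, m$gain)
  }
  for (ev in c("lick", "movement")) {
    m <- template[[ev]]
    bouts <- if (ev == "lick") events$lick_bouts else events$movement_bouts
    if (nrow(bouts) == 0) next
    off <- if (is.na(m$duration_s)) bouts$offset_s + m$latency_s else
      bouts$onset_s + m$latency_s + m$duration_s
    rate <- apply_gain(rate, bouts$onset_s + m$latency_s, off, m$gain)
  }
  pmax(rate, 0)
}

#' Simulate a spike train from a population template
#'
#' Inhomogeneous Poisson process by thinning: candidate spikes are drawn
#' homogeneously at the profile maximum and retained with probability
#' `rate(t) / rate_max`, with the rate profile piecewise-constant at 1-ms
#' resolution. Inserted pauses (rate 0) are applied before thinning. An
#' optional absolute refractory period deletes spikes closer than
#' `refractory_s` to their predecessor.
#'
#' @param template a [population_template()].
#' @param events a `session_events` object.
#' @param seed integer seed.
#' @param refractory_s absolute refractory period, seconds (0 = off, default).
#' @param dt_s rate-grid resolution.
#' @return a `spike_train` object: strictly increasing `spike_times_s` plus
#'   `unit_id` (NA until assigned) and the generating template.
#' @export
simulate_spike_train <- function(template, events, seed = 1L,
                                 refractory_s = 0, dt_s = 0.001) {
  stopifnot(inherits(template, "population_template"),
            inherits(events, "session_events"))
  with_seed(seed, {
    rate <- event_rate_profile(template, events, dt_s)
    dur <- events$session_duration_s
    if (template$pause_rate_per_min > 0) {
      n_pause <- stats::rpois(1, template$pause_rate_per_min * dur / 60)
      if (n_pause > 0) {
        p_on <- stats::runif(n_pause, 0, dur - template$pause_duration_s)
        for (p in p_on) {
          i0 <- as.integer(floor(p / dt_s)) + 1L
          i1 <- min(length(rate),
                    as.integer(ceiling((p + template$pause_duration_s) / dt_s)))
          rate[i0:i1] <- 0
        }
      }
    }
    rmax <- max(rate)
    if (rmax <= 0) {
      times <- numeric(0)
    } else {
      n_cand <- stats::rpois(1, rmax * dur)
      cand <- sort(stats::runif(n_cand, 0, dur))
      idx <- pmin(length(rate), as.integer(floor(cand / dt_s)) + 1L)
      keep <- stats::runif(n_cand) < rate[idx] / rmax
      times <- cand[keep]
    }
    if (refractory_s > 0 && length(times) > 1) {
      kept <- times[1]
      for (t in times[-1]) {
        if (t - kept[length(kept)] >= refractory_s) kept <- c(kept, t)
      }
      times <- kept
    }
    structure(list(unit_id = NA_character_, spike_times_s = times,
                   template = template),
              class = "spike_train")
  })
}

#' Build a synthetic cohort of one population sharing a session
#'
#' One event structure is shared by `n_neurons` units, each simulated from the
#' population template with per-unit lognormal jitter on the tonic rate and on
#' the modulated gains (magnitude only: whether a parameter is encoded never
#' changes under jitter). The ground truth records, per unit, the set of
#' encoded parameters (template gain != 1) and the dominant one (largest
#' absolute log gain).
#'
#' @param population population label passed to [default_template()].
#' @param n_neurons number of units.
#' @param config a [task_config()].
#' @param behavior a [behavior_params()].
#' @param seed master seed; per-unit seeds are derived substreams.
#' @param rate_jitter_sd,gain_jitter_sd lognormal jitter (sd of log) applied to
#'   the tonic rate and to each non-unit gain.
#' @return a `synthetic_session`: `events`, `spike_trains` (list of
#'   `spike_train`), and `ground_truth` (data frame with `unit_id`,
#'   `population`, comma-separated `encoded`, `dominant`).
#' @export
build_population_session <- function(population, n_neurons,
                                     config = task_config(),
                                     behavior = behavior_params(),
                                     seed = config$seed,
                                     rate_jitter_sd = 0.10,
                                     gain_jitter_sd = 0.05) {
  if (n_neurons < 1) stop("n_neurons must be >= 1")
  base <- default_template(population)
  events <- generate_session_events(config, behavior,
                                    seed = derive_seed(seed, 0))
  trains <- vector("list", n_neurons)
  gt <- vector("list", n_neurons)
  for (i in seq_len(n_neurons)) {
    tpl <- base
    jit_seed <- derive_seed(seed, i, 1)
    with_seed(jit_seed, {
      tpl$tonic_rate_hz <- base$tonic_rate_hz *
        exp(stats::rnorm(1, 0, rate_jitter_sd))
      for (ev in c("cue", "reward", "lick", "movement")) {
        g <- base[[ev]]$gain
        if (g != 1 && g > 0) {
          tpl[[ev]]$gain <- exp(log(g) * exp(stats::rnorm(1, 0, gain_jitter_sd)))
        }
      }
    })
    tr <- simulate_spike_train(tpl, events, seed = derive_seed(seed, i, 2))
    tr$unit_id <- sprintf("%s_%03d", population, i)
    trains[[i]] <- tr
    gains <- vapply(c("cue", "reward", "lick", "movement"),
                    function(ev) base[[ev]]$gain, numeric(1))
    encoded <- names(gains)[gains != 1]
    dominant <- if (length(encoded)) {
      encoded[which.max(abs(log(gains[encoded])))]
    } else {
      "none"
    }
    gt[[i]] <- data.frame(unit_id = tr$unit_id, population = population,
                          encoded = paste(encoded, collapse = ","),
                          dominant = dominant)
  }
  structure(list(events = events,
                 spike_trains = trains,
                 ground_truth = do.call(rbind, gt),
                 seed = as.integer(seed)),
            class = "synthetic_session")
}
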