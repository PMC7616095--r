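# shared fixtures, all generated in code

# homogeneous Poisson spike train over [0, duration)
poisson_train <- function(rate_hz, duration_s, seed = 1) {
  set.seed(seed)
  n <- rpois(1, rate_hz * duration_s)
  structure(list(unit_id = "poisson", spike_times_s = sort(runif(n, 0, duration_s)),
                 template = NULL),
            class = "spike_train")
}

as_train <- function(times, id = "unit") {
  structure(list(unit_id = id, spike_times_s = sort(times), template = NULL),
            class = "spike_train")
}

# small session used by several suites (deterministic given seed)
quick_session <- function(n_trials = 30, seed = 11) {
  generate_session_events(task_config(n_trials = n_trials, seed = seed))
}

# constant-rate template with no event modulation
flat_template <- function(rate_hz = 10) {
  population_template(tonic_rate_hz = rate_hz)
}
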