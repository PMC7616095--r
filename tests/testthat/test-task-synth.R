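test_that("ITI sampler respects support, median calibration and determinism", {
  cfg <- task_config(seed = 1)
  set.seed(1)
  draws <- sample_iti(10000, cfg)
  expect_true(all(draws >= 4 & draws <= 10))

  set.seed(2)
  big <- sample_iti(100000, cfg)
  expect_lt(abs(median(big) - 5.4), 0.05)

  set.seed(3)
  a <- sample_iti(500, cfg)
  set.seed(3)
  b <- sample_iti(500, cfg)
  expect_identical(a, b)

  expect_error(task_config(iti_rate_per_s = -1), "positive")
})

test_that("calibrated ITI rate solves the truncated-median equation", {
  r <- calibrate_iti_rate(4, 10, 5.4)
  lhs <- (1 - exp(-r * 1.4)) / (1 - exp(-r * 6))
  expect_equal(lhs, 0.5, tolerance = 1e-9)
})

test_that("session events have the task structure", {
  cfg <- task_config(seed = 5)
  ev <- generate_session_events(cfg)
  expect_length(ev$reward_times_s, 100)
  expect_true(all(ev$reward_times_s - ev$cue_onsets_s == cfg$cue_reward_delay_s))
  itis <- ev$cue_onsets_s[-1] - ev$reward_times_s[-100]
  expect_true(all(itis >= 4 & itis <= 10))
  expect_true(all(ev$lick_bouts$offset_s > ev$lick_bouts$onset_s))
  expect_true(max(ev$movement_bouts$offset_s, 0) <= ev$session_duration_s)
})

test_that("anticipatory lick bout follows cue at the configured latency", {
  cfg <- task_config(n_trials = 3, seed = 2)
  bp <- behavior_params(lick_latency_s = 0.5, anticipatory_duration_s = 2.0,
                        movement_rate_per_s = 0)
  ev <- generate_session_events(cfg, bp)
  # consummatory bout (reward + 0.1) starts 2.1 s after cue, so the 2.5-s
  # anticipatory bout merges with it; the bout onset is still cue + 0.5
  expect_equal(ev$lick_bouts$onset_s[1], ev$cue_onsets_s[1] + 0.5)
  bp2 <- behavior_params(lick_latency_s = 0.5, anticipatory_duration_s = 1.2,
                         consummatory_latency_s = 0.2, movement_rate_per_s = 0)
  ev2 <- generate_session_events(cfg, bp2)
  expect_equal(ev2$lick_bouts$onset_s[1], ev2$cue_onsets_s[1] + 0.5)
  expect_equal(ev2$lick_bouts$offset_s[1], ev2$cue_onsets_s[1] + 1.7)
  expect_error(behavior_params(anticipatory_duration_s = -1), "positive")
})

test_that("spike simulation matches the configured intensity", {
  ev <- session_events(cue_onsets_s = 1, reward_times_s = 3,
                       session_duration_s = 100)
  silent <- simulate_spike_train(population_template(tonic_rate_hz = 0), ev, seed = 1)
  expect_length(silent$spike_times_s, 0)

  counts <- vapply(1:40, function(s) {
    length(simulate_spike_train(flat_template(10), ev, seed = s)$spike_times_s)
  }, numeric(1))
  # Poisson(1000): mean within 3 sd of the across-seed standard error
  expect_lt(abs(mean(counts) - 1000), 3 * sqrt(1000 / 40))
  expect_true(all(abs(counts - 1000) < 5 * sqrt(1000)))

  tr <- simulate_spike_train(flat_template(10), ev, seed = 7)
  expect_true(all(diff(tr$spike_times_s) > 0))
})

test_that("window spike counts are Poisson at the configured intensity", {
  ev <- session_events(cue_onsets_s = 1, reward_times_s = 3,
                       session_duration_s = 30)
  # counts in a fixed 10-s window over 200 seeds vs Poisson(50)
  counts <- vapply(1:200, function(s) {
    tr <- simulate_spike_train(flat_template(5), ev, seed = 100 + s)
    sum(tr$spike_times_s >= 10 & tr$spike_times_s < 20)
  }, numeric(1))
  brk <- c(-Inf, qpois(seq(0.1, 0.9, by = 0.1), 50), Inf)
  obs <- table(cut(counts, brk))
  expected <- diff(c(0, ppois(qpois(seq(0.1, 0.9, by = 0.1), 50), 50), 1)) * 200
  chi <- sum((as.numeric(obs) - expected)^2 / expected)
  expect_gt(pchisq(chi, df = length(expected) - 1, lower.tail = FALSE), 0.01)
})

test_that("VLS template modulates the reward window but not the cue window", {
  cfg <- task_config(n_trials = 60, seed = 9)
  ev <- generate_session_events(cfg, behavior_params(movement_rate_per_s = 0))
  tpl <- default_template("VLS")
  rates <- vapply(1:20, function(s) {
    tr <- simulate_spike_train(tpl, ev, seed = s)
    spikes <- tr$spike_times_s
    rw <- sum(findInterval(ev$reward_times_s + 0.24, spikes) -
                findInterval(ev$reward_times_s + 0.04, spikes)) / (60 * 0.2)
    cu <- sum(findInterval(ev$cue_onsets_s + 0.24, spikes) -
                findInterval(ev$cue_onsets_s, spikes)) / (60 * 0.24)
    c(rw, cu)
  }, numeric(2))
  expect_equal(mean(rates[1, ]) / tpl$tonic_rate_hz, 3, tolerance = 0.12)
  expect_equal(mean(rates[2, ]) / tpl$tonic_rate_hz, 1, tolerance = 0.12)
})

test_that("population sessions carry coherent ground truth", {
  ss <- build_population_session("DMS", 10, task_config(n_trials = 20, seed = 4))
  expect_length(ss$spike_trains, 10)
  expect_equal(nrow(ss$ground_truth), 10)
  expect_false(any(grepl("reward", ss$ground_truth$encoded)))

  ss2 <- build_population_session("DMS", 10, task_config(n_trials = 20, seed = 4))
  expect_identical(serialize(ss, NULL), serialize(ss2, NULL))

  expect_error(build_population_session("DMS", 0, task_config()), ">= 1")
})

test_that("synthetic photometry has the configured geometry", {
  ev <- session_events(cue_onsets_s = c(10, 20), reward_times_s = c(12, 22),
                       session_duration_s = 600)
  sim <- simulate_photometry(ev, flat_template(6), phot_params(), seed = 2)
  expect_length(sim$recording$activity, 600 * 130)
  expect_length(sim$recording$reference, 600 * 130)

  # artifact-free reference is pure noise around the static offset
  no_art <- simulate_photometry(ev, flat_template(6),
                                phot_params(artifact_amplitude = 0), seed = 3)
  expect_equal(mean(no_art$recording$reference), 100, tolerance = 0.01)

  # shared artifact dominating noise correlates the channels
  strong <- simulate_photometry(ev, flat_template(6),
                                phot_params(artifact_amplitude = 5,
                                            noise_sd = 0.05), seed = 4)
  expect_gt(cor(strong$recording$activity, strong$recording$reference), 0.5)
  expect_error(phot_params(noise_sd = -1), ">= 0")
})
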