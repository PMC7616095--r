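test_that("design matrix codes cue/reward bins and the 75% bout rule", {
  ev <- session_events(
    cue_onsets_s = 10, reward_times_s = 12,
    lick_bouts = data.frame(onset_s = 10.45, offset_s = 10.72),
    session_duration_s = 30
  )
  tr <- as_train(c(10.05, 10.3, 12.1))
  d <- build_design_matrix(tr, ev)

  at <- function(t) which(abs(d$bin_start_s - t) < 1e-9)
  expect_equal(d$cue[at(10.0)], 1)
  expect_equal(d$cue[at(10.2)], 1)
  expect_equal(d$cue[at(10.4)], 0)
  expect_equal(d$reward[at(12.0)], 1)
  expect_equal(d$reward[at(12.2)], 1)
  expect_equal(d$reward[at(12.4)], 0)
  # bout (10.45, 10.72): overlap 0.15 s (= 75%) with [10.4, 10.6) -> coded;
  # overlap 0.12 s (60%) with [10.6, 10.8) -> not coded
  expect_equal(d$lick[at(10.4)], 1)
  expect_equal(d$lick[at(10.6)], 0)
  expect_equal(d$count[at(10.0)], 1)
  expect_equal(d$count[at(10.2)], 1)

  expect_error(
    build_design_matrix(tr, session_events(
      cue_onsets_s = 10, reward_times_s = 12,
      lick_bouts = data.frame(onset_s = 29, offset_s = 31),
      session_duration_s = 30
    )),
    "bounds"
  )
})

test_that("the session is tiled by 200-ms bins with partial tails dropped", {
  ev <- quick_session(20)
  tr <- simulate_spike_train(flat_template(5), ev, seed = 3)
  d <- build_design_matrix(tr, ev)
  expect_true(all(abs(diff(d$bin_start_s[d$trial == 2]) - 0.2) < 1e-9))
  # bins within one trial are aligned to that trial's cue
  cue2 <- ev$cue_onsets_s[2]
  rel <- (d$bin_start_s[d$trial == 2] - cue2) / 0.2
  expect_true(all(abs(rel - round(rel)) < 1e-6))
  # total bin count is the tiled span over bin width, minus dropped tails
  spans <- diff(c(ev$cue_onsets_s - 1, ev$session_duration_s))
  expect_equal(nrow(d), sum(floor(spans / 0.2 + 1e-9)))
})

test_that("regressor coding is independent of bin order", {
  ev <- quick_session(5)
  tr <- simulate_spike_train(flat_template(5), ev, seed = 4)
  d <- build_design_matrix(tr, ev)
  perm <- sample(nrow(d))
  d2 <- build_design_matrix(tr, ev)[perm, ]
  expect_equal(d2[order(d2$bin_start_s), ]$cue, d[order(d$bin_start_s), ]$cue)
})

test_that("Poisson GLM recovers a known reward coefficient", {
  # counts ~ Pois(exp(log 2 + log 2 * reward)) per 200-ms bin
  set.seed(42)
  covered <- vapply(1:200, function(i) {
    reward <- rep(0L, 2000)
    reward[sample(2000, 150)] <- 1L
    d <- data.frame(count = rpois(2000, 2 * 2^reward),
                    cue = 0L, reward = reward, lick = 0L, movement = 0L)
    fit <- suppressWarnings(fit_poisson_encoding_glm(d))
    est <- fit$coefficients["reward"]
    se <- fit$se["reward"]
    est - 1.96 * se <= log(2) && est + 1.96 * se >= log(2)
  }, logical(1))
  expect_gte(mean(covered), 0.93)
})

test_that("null units reject each coefficient at the nominal rate", {
  set.seed(7)
  ev <- quick_session(10, seed = 30)
  tr <- simulate_spike_train(flat_template(6), ev, seed = 1)
  base <- build_design_matrix(tr, ev)
  rej <- matrix(NA, 400, 4)
  for (i in 1:400) {
    d <- base
    d$count <- rpois(nrow(d), 1.5) # no dependence on any regressor
    fit <- fit_poisson_encoding_glm(d)
    rej[i, ] <- fit$p_values[c("cue", "reward", "lick", "movement")] < 0.05
  }
  rates <- colMeans(rej)
  expect_true(all(rates > 0.02 & rates < 0.09))
})

test_that("well-specified units pass the deviance GOF about 95% of the time", {
  # the chi-square reference for the residual deviance holds in the
  # moderate-count regime; low-count bins make it anticonservative
  set.seed(8)
  gof <- vapply(1:200, function(i) {
    reward <- rep(0L, 1000)
    reward[sample(1000, 80)] <- 1L
    d <- data.frame(count = rpois(1000, 20 * 1.5^reward),
                    cue = 0L, reward = reward, lick = 0L, movement = 0L)
    suppressWarnings(fit_poisson_encoding_glm(d))$gof_p
  }, numeric(1))
  expect_lt(abs(mean(gof < 0.05) - 0.05), 0.05)
})

test_that("coefficient bias shrinks as trials increase", {
  est_bias <- vapply(c(50, 200), function(n_trials) {
    set.seed(n_trials)
    errs <- vapply(1:40, function(i) {
      reward <- rep(0L, n_trials * 10)
      reward[sample(n_trials * 10, n_trials)] <- 1L
      d <- data.frame(count = rpois(n_trials * 10, 2 * 2^reward),
                      cue = 0L, reward = reward, lick = 0L, movement = 0L)
      suppressWarnings(fit_poisson_encoding_glm(d))$coefficients["reward"] - log(2)
    }, numeric(1))
    abs(mean(errs))
  }, numeric(1))
  expect_lt(est_bias[2], est_bias[1] + 0.02)
  expect_lt(est_bias[2], 0.05)
})

test_that("saturated hand design has zero residual deviance", {
  d <- data.frame(count = c(2L, 4L), cue = c(0L, 1L), reward = 0L,
                  lick = 0L, movement = 0L)
  fit <- suppressWarnings(fit_poisson_encoding_glm(d))
  expect_equal(fit$deviance, 0, tolerance = 1e-8)
  expect_error(fit_poisson_encoding_glm(
    data.frame(count = 0L, cue = 0L, reward = 0L, lick = 0L, movement = 0L)
  ), "all-zero")
})

test_that("classification picks significant set and dominant by |beta|", {
  fake <- structure(list(
    coefficients = c("(Intercept)" = 1, cue = 0.2, reward = -0.5,
                     lick = 0.1, movement = 0.0),
    p_values = c("(Intercept)" = 0, cue = 0.01, reward = 0.001,
                 lick = 0.3, movement = 0.9),
    converged = TRUE
  ), class = "encoding_fit")
  cl <- classify_encoding(fake)
  expect_setequal(cl$significant, c("cue", "reward"))
  expect_equal(cl$dominant, "reward")
  expect_equal(cl$multiplexing, 2L)

  fake$p_values[2:5] <- 0.5
  expect_equal(classify_encoding(fake)$dominant, "none")
})

test_that("DMS cohort never classifies reward as encoded", {
  ss <- build_population_session("DMS", 10, task_config(n_trials = 60, seed = 15))
  hits <- vapply(ss$spike_trains, function(tr) {
    fit <- fit_poisson_encoding_glm(build_design_matrix(tr, ss$events))
    "reward" %in% classify_encoding(fit)$significant
  }, logical(1))
  expect_gte(mean(!hits), 0.9)
})

test_that("event-window rates and shuffle test behave under null and signal", {
  ev <- quick_session(40, seed = 33)
  empty <- as_train(numeric(0))
  expect_equal(event_window_rate(empty, ev, "cue", seed = 1)$rate_hz, 0)

  # null calibration: p below 0.05 about 5% of the time
  ps <- vapply(1:60, function(s) {
    tr <- simulate_spike_train(flat_template(10), ev, seed = 200 + s)
    r <- event_window_rate(tr, ev, "cue", n_shuffles = 500, seed = s)
    r$shuffle_p
  }, numeric(1))
  expect_lt(mean(ps < 0.05), 0.15)
  r10 <- event_window_rate(simulate_spike_train(flat_template(10), ev, seed = 3),
                           ev, "cue", seed = 5)
  expect_equal(r10$rate_hz, 10, tolerance = 0.25)

  # power: a reward-gain-3 template is detected in nearly every seed
  tpl <- default_template("VLS")
  sig <- vapply(1:20, function(s) {
    tr <- simulate_spike_train(tpl, ev, seed = 300 + s)
    event_window_rate(tr, ev, "reward", c(0.04, 0.24),
                      n_shuffles = 500, seed = s)$shuffle_p < 0.05
  }, logical(1))
  expect_gte(mean(sig), 0.95)
})
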