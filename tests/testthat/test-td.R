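test_that("TD error and asymmetric update match their definitions", {
  expect_equal(td_error(2, 0, 1, 5), 3)
  expect_equal(td_error(4, 5, 0.9, 0), 1) # terminal state
  expect_equal(td_error(3 + 0.9 * 7, 3, 0.9, 7), 0) # fixed point

  expect_equal(apply_update(2, 3, 0.5, 0.25), 3.5)
  expect_equal(apply_update(2, -2, 0.5, 0.25), 1.5)
  expect_equal(apply_update(2, 0, 0.5, 0.25), 2)
  expect_error(apply_update(1, 1, 0, 0.5))
})

test_that("Gaussian expectile oracle has its symmetry properties", {
  expect_equal(expectile_gaussian(0.5, 5, 5), 5, tolerance = 1e-8)
  e <- expectile_gaussian(c(0.2, 0.8), 0, 2)
  expect_equal(e[1], -e[2], tolerance = 1e-8)
  expect_error(expectile_gaussian(0.3, 0, -1))

  # brute-force check: decaying-rate asymmetric updates converge to it
  set.seed(1)
  for (tau in c(0.25, 0.7)) {
    reps <- vapply(1:20, function(r) {
      v <- 0
      for (k in 1:20000) {
        d <- rnorm(1, 2, 3) - v
        a <- 5 / (100 + k)
        v <- v + a * d * if (d > 0) tau else (1 - tau)
      }
      v
    }, numeric(1))
    oracle <- expectile_gaussian(tau, 2, 3)
    expect_lt(abs(mean(reps) - oracle), 3 * sd(reps) / sqrt(20) + 0.02)
  }
})

test_that("balanced agents converge to the training mean", {
  cfg <- td_config(seed = 11)
  ag <- make_td_agent(cfg)
  ag$alpha_minus <- ag$alpha_plus
  ag <- train_agent(ag, cfg, seed = 42)
  expect_equal(mean(ag$value_estimate), 5, tolerance = 0.15)
})

test_that("converged values equal the tau-expectile of the reward distribution", {
  cfg <- td_config(n_neurons = 40, seed = 12)
  for (tau in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    # modest rates keep the constant-step stationary bias small
    ag <- make_td_agent(cfg, alpha_plus = 0.12 * tau, alpha_minus = 0.12 * (1 - tau))
    ag <- train_agent(ag, cfg, seed = 100 + round(100 * tau))
    expect_equal(mean(ag$value_estimate),
                 expectile_gaussian(tau, cfg$reward_mean, cfg$reward_sd),
                 tolerance = 0.25)
  }
})

test_that("converged value is strictly increasing in tau", {
  cfg <- td_config(n_neurons = 30, seed = 13)
  taus <- c(0.2, 0.4, 0.6, 0.8)
  vals <- vapply(taus, function(tau) {
    ag <- make_td_agent(cfg, alpha_plus = 0.1 * tau, alpha_minus = 0.1 * (1 - tau))
    mean(train_agent(ag, cfg, seed = 500 + round(10 * tau))$value_estimate)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("value propagates down the chain as gamma^k", {
  cfg <- td_config(gamma = 0.8, n_neurons = 20, seed = 14)
  ag <- make_td_agent(cfg, alpha_plus = 0.1, alpha_minus = 0.1)
  ag <- train_agent(ag, cfg, seed = 3)
  v <- rowMeans(ag$state_value_estimate)
  for (k in 1:(cfg$n_states - 1)) {
    expect_equal(v[cfg$n_states - k], 0.8^k * v[cfg$n_states],
                 tolerance = 0.02 * max(1, abs(v[cfg$n_states])))
  }
})

test_that("degenerate zero-spread rewards give exact convergence", {
  cfg <- td_config(reward_sd = 0, n_neurons = 10,
                   n_training_trials = 3000, seed = 15)
  ag <- make_td_agent(cfg) # arbitrary asymmetries
  ag <- train_agent(ag, cfg, seed = 4)
  expect_equal(unname(ag$value_estimate), rep(5, 10), tolerance = 1e-6)
  ev <- evaluate_agent(ag, cfg, n_test = 50, seed = 5)
  expect_true(all(is.finite(ev$mse_per_cell)))
})

test_that("training diverging values errors out", {
  cfg <- td_config(value_bound = 1e-8, seed = 16)
  ag <- make_td_agent(cfg)
  expect_error(train_agent(ag, cfg, seed = 1), "diverged")
})

test_that("activity distributions integrate to 1 and sample faithfully", {
  set.seed(2)
  x <- rnorm(300, 1, 2)
  act <- estimate_activity_distribution(x)
  area <- sum(act$y) * diff(act$x[1:2])
  expect_equal(area, 1, tolerance = 1e-3)
  draws <- sample_activity(act, 1e5, seed = 3)
  se <- sqrt(var(x) / 1e5)
  expect_lt(abs(mean(draws) - mean(x)), 3 * se + 0.02)

  expect_warning(deg <- estimate_activity_distribution(rep(2, 10)), "degenerate")
  d2 <- sample_activity(deg, 100, seed = 4)
  expect_lt(max(abs(d2 - 2)), 10 * deg$bw)
  expect_error(estimate_activity_distribution(1:3), "at least 5")
})

test_that("grid fit recovers symmetric and shifted target structure", {
  cfg <- td_config(seed = 17)
  set.seed(5)
  z <- rnorm(150)
  sym <- estimate_activity_distribution(c(z, -z))
  fit <- fit_learning_rates(sym, cfg, seed = 6)
  expect_lt(abs(mean(fit$asymmetry) - 0.5), 0.05)
  expect_true(all(fit$asymmetry > 0 & fit$asymmetry < 1))

  # strictly positive targets: values sit below the mean, asymmetry < 0.5
  pos <- estimate_activity_distribution(abs(z) + 0.5)
  fit_pos <- fit_learning_rates(pos, cfg, seed = 7)
  expect_true(all(fit_pos$asymmetry < 0.5))

  # a degenerate zero target lands on balanced rates up to grid resolution
  deg <- suppressWarnings(estimate_activity_distribution(rep(0, 10)))
  fit0 <- fit_learning_rates(deg, td_config(n_neurons = 5, seed = 18), seed = 8)
  expect_equal(unname(fit0$asymmetry), rep(0.5, 5), tolerance = 0.02)
})

test_that("fit direction is confirmed by simulating the fitted rates", {
  cfg <- td_config(n_neurons = 12, seed = 19)
  set.seed(9)
  pos <- estimate_activity_distribution(abs(rnorm(100)) + 0.5)
  fit <- fit_learning_rates(pos, cfg, seed = 10)
  ag <- make_td_agent(cfg, alpha_plus = fit$alpha_plus,
                      alpha_minus = fit$alpha_minus)
  ag <- train_agent(ag, cfg, seed = 11)
  # persistent positive reward-state errors mean values below the mean reward
  expect_lt(mean(ag$value_estimate), cfg$reward_mean)
})

test_that("evaluation computes per-cell MSE and bias direction", {
  cfg <- td_config(n_neurons = 2, seed = 20)
  ag <- make_td_agent(cfg, alpha_plus = 0.1, alpha_minus = 0.1)
  ag$trained <- TRUE
  ag$value_estimate <- c(5, 5)
  y <- c(4, 6)
  mse <- vapply(ag$value_estimate, function(v) mean((y - v)^2), numeric(1))
  expect_equal(mse, c(1, 1)) # frozen arithmetic of the definition

  ev <- evaluate_agent(ag, cfg, n_test = 2000, seed = 21)
  expect_true(all(ev$mse_per_cell >= 0))
  # identical predictions and targets give zero error
  ag$value_estimate <- ev$test_rewards[1]
  ev2 <- evaluate_agent(ag, cfg, n_test = 1, seed = 21)
  expect_equal(ev2$mse_per_cell[1], 0, tolerance = 1e-20)

  expect_error(evaluate_agent(make_td_agent(cfg), cfg), "trained")
})

test_that("projection agents are built per population plus unified", {
  cfg <- td_config(n_neurons = 20, n_training_trials = 2000, seed = 22)
  set.seed(12)
  samples <- list(A = rnorm(30, 1), B = rnorm(30, 0.5),
                  C = rnorm(30, 1.5), D = rnorm(30, 0.8))
  agents <- build_projection_agents(samples, cfg, seed = 23)
  expect_setequal(names(agents), c("A", "B", "C", "D", "unified"))
  for (ag in agents) {
    expect_length(ag$value_estimate, 20)
    expect_equal(nrow(ag$fit), 20)
  }
  expect_error(build_projection_agents(list(), cfg), "at least one")
  expect_error(build_projection_agents(list(rnorm(10)), cfg), "named")
})

test_that("identical population samples give exchangeable asymmetries", {
  cfg <- td_config(n_neurons = 25, n_training_trials = 500, seed = 24)
  set.seed(13)
  x <- rnorm(60, 0.5)
  ok <- vapply(1:10, function(r) {
    agents <- build_projection_agents(list(A = x, B = x), cfg,
                                      seed = derive_seed(24, r))
    suppressWarnings(wilcox.test(agents$A$fit$asymmetry,
                                 agents$B$fit$asymmetry)$p.value) > 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("agents fit to positive activity underestimate large test rewards", {
  cfg <- td_config(n_neurons = 30, seed = 25)
  set.seed(14)
  pos <- estimate_activity_distribution(abs(rnorm(100)) + 0.3)
  fit <- fit_learning_rates(pos, cfg, seed = 15)
  ag <- train_agent(make_td_agent(cfg, fit$alpha_plus, fit$alpha_minus),
                    cfg, seed = 16)
  ev <- evaluate_agent(ag, cfg, n_test = 500, seed = 17)
  expect_lt(mean(ev$predictions), cfg$reward_mean)
  expect_lt(ev$bias, 0)
})
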