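#' Distributional TD model configuration
#'
#' The environment is a deterministic chain of `n_states` states traversed
#' once per episode; at the reward state (the terminal state by default) the
#' agent receives a reward drawn from a Gaussian training distribution,
#' mean `reward_mean` and standard deviation `reward_sd`. Each simulated
#' neuron carries its own pair of learning rates (alpha+ applied to positive
#' TD errors, alpha- to negative ones), so its value estimate converges to the
#' tau-expectile of the reward distribution with
#' `tau = alpha+ / (alpha+ + alpha-)`.
#'
#' @param gamma discount factor in (0, 1].
#' @param n_states number of chain states.
#' @param reward_state index of the rewarded (terminal) state.
#' @param reward_mean,reward_sd training reward distribution parameters
#'   (Gaussian; sd interpretation of the dispersion parameter).
#' @param test_range test rewards are uniform on this interval.
#' @param n_neurons simulated neurons per agent.
#' @param n_training_trials training episodes.
#' @param grid learning-rate grid for fitting (values in (0, 1]).
#' @param tail_window episodes over which the converged value is averaged
#'   (tail averaging of the constant-step-size iterates).
#' @param value_bound divergence guard on |V|.
#' @param seed integer seed.
#' @return a `td_config`.
#' @export
td_config <- function(gamma = 0.9,
                      n_states = 5,
                      reward_state = n_states,
                      reward_mean = 5,
                      reward_sd = 5,
                      test_range = c(0, 20),
                      n_neurons = 50,
                      n_training_trials = 10000,
                      grid = seq(0.01, 1, by = 0.01),
                      tail_window = 500,
                      value_bound = 1e6,
                      seed = 1L) {
  if (gamma <= 0 || gamma > 1) stop("gamma must be in (0, 1]")
  if (any(grid <= 0 | grid > 1)) stop("grid values must be in (0, 1]")
  if (n_neurons < 1) stop("n_neurons must be >= 1")
  if (reward_state < 1 || reward_state > n_states) stop("invalid reward_state")
  if (reward_sd < 0) stop("reward_sd must be >= 0")
  structure(as.list(environment()), class = "td_config")
}

#' Temporal-difference error
#'
#' `delta = r + gamma * v_next - v`: the difference between the received
#' reward plus the discounted bootstrapped estimate of the next state's value
#' and the current state-value prediction. Vectorized over neurons.
#'
#' @param v current state value(s).
#' @param r reward(s).
#' @param gamma discount factor.
#' @param v_next next-state value(s) (0 at the terminal state).
#' @return TD error(s).
#' @examples
#' td_error(2, 0, 1, 5) # 3
#' @export
td_error <- function(v, r, gamma, v_next) {
  r + gamma * v_next - v
}

#' Asymmetric value update
#'
#' Positive TD errors are scaled by `alpha_plus`, negative ones by
#' `alpha_minus`; a zero error leaves the value unchanged. The asymmetry
#' `tau = alpha_plus / (alpha_plus + alpha_minus)` determines the expectile
#' the value converges to.
#'
#' @param v current value(s).
#' @param delta TD error(s).
#' @param alpha_plus,alpha_minus learning rates in (0, 1].
#' @return updated value(s).
#' @examples
#' apply_update(2, 3, 0.5, 0.1) # 3.5
#' @export
apply_update <- function(v, delta, alpha_plus, alpha_minus) {
  stopifnot(all(alpha_plus > 0 & alpha_plus <= 1),
            all(alpha_minus > 0 & alpha_minus <= 1))
  v + ifelse(delta > 0, alpha_plus, ifelse(delta < 0, alpha_minus, 0)) * delta
}

#' Create a TD agent
#'
#' @param config a [td_config()].
#' @param alpha_plus,alpha_minus per-neuron learning rates (length
#'   `n_neurons`, recycled); by default drawn uniform on (0, 1) from the
#'   config seed.
#' @param label population label for the agent.
#' @return a `td_agent`: value matrix `V` (states x neurons, zeros),
#'   `alpha_plus`, `alpha_minus`, `tau`, `label`, `trained = FALSE`.
#' @export
make_td_agent <- function(config, alpha_plus = NULL, alpha_minus = NULL,
                          label = "agent") {
  stopifnot(inherits(config, "td_config"))
  n <- config$n_neurons
  if (is.null(alpha_plus) || is.null(alpha_minus)) {
    draws <- with_seed(derive_seed(config$seed, 101), stats::runif(2 * n))
    if (is.null(alpha_plus)) alpha_plus <- draws[seq_len(n)]
    if (is.null(alpha_minus)) alpha_minus <- draws[n + seq_len(n)]
  }
  alpha_plus <- rep_len(alpha_plus, n)
  alpha_minus <- rep_len(alpha_minus, n)
  stopifnot(all(alpha_plus > 0 & alpha_plus <= 1),
            all(alpha_minus > 0 & alpha_minus <= 1))
  structure(list(V = matrix(0, config$n_states, n),
                 alpha_plus = alpha_plus, alpha_minus = alpha_minus,
                 tau = alpha_plus / (alpha_plus + alpha_minus),
                 label = label, trained = FALSE,
                 value_estimate = NULL),
            class = "td_agent")
}

#' Train a TD agent on the deterministic chain
#'
#' Each episode traverses the chain once; non-terminal transitions carry no
#' reward, the terminal (reward) state delivers a per-neuron Gaussian reward
#' draw. All neurons update in parallel with their own asymmetric learning
#' rates. The converged value reported per neuron (`value_estimate`) is the
#' mean of the reward-state value over the final `tail_window` episodes —
#' the tail average of the constant-step-size iterates, whose expectation is
#' the tau-expectile of the training reward distribution.
#'
#' @param agent a `td_agent`.
#' @param config a [td_config()].
#' @param seed integer seed for the reward draws.
#' @param keep_trace record per-episode reward-state values and TD errors.
#' @return the trained agent, with `value_estimate` (per neuron, reward
#'   state), `state_value_estimate` (states x neurons, tail-averaged) and,
#'   when `keep_trace`, a `trace` data frame (`episode`, per-episode mean
#'   reward, mean reward-state delta and value).
#' @export
train_agent <- function(agent, config, seed = config$seed, keep_trace = FALSE) {
  stopifnot(inherits(agent, "td_agent"), inherits(config, "td_config"))
  V <- agent$V
  ap <- agent$alpha_plus
  am <- agent$alpha_minus
  ns <- config$n_states
  rs <- config$reward_state
  gamma <- config$gamma
  n <- length(ap)
  n_ep <- config$n_training_trials
  tw <- min(config$tail_window, n_ep)
  tail_sum <- matrix(0, ns, n)
  tr_r <- tr_d <- tr_v <- if (keep_trace) numeric(n_ep) else NULL
  with_seed(seed, {
    for (ep in seq_len(n_ep)) {
      for (t in seq_len(ns)) {
        if (t == rs) {
          r <- stats::rnorm(n, config$reward_mean, config$reward_sd)
          v_next <- 0 # terminal: no bootstrap beyond the rewarded state
        } else {
          r <- 0
          v_next <- V[t + 1, ]
        }
        delta <- td_error(V[t, ], r, gamma, v_next)
        V[t, ] <- V[t, ] + ifelse(delta > 0, ap, am) * delta
        if (t == rs) {
          if (keep_trace) {
            tr_r[ep] <- mean(r)
            tr_d[ep] <- mean(delta)
            tr_v[ep] <- mean(V[t, ])
          }
        }
      }
      if (max(abs(V)) > config$value_bound) stop("value estimates diverged")
      if (ep > n_ep - tw) tail_sum <- tail_sum + V
    }
  })
  agent$V <- V
  agent$state_value_estimate <- tail_sum / tw
  agent$value_estimate <- agent$state_value_estimate[rs, ]
  agent$trained <- TRUE
  if (keep_trace) {
    agent$trace <- data.frame(episode = seq_len(n_ep), mean_reward = tr_r,
                              mean_delta = tr_d, mean_value = tr_v)
  }
  agent
}

# closed-form E[(X - e)+] for X ~ N(mu, sigma)
gaussian_upper_partial <- function(e, mu, sigma) {
  z <- (e - mu) / sigma
  (mu - e) * stats::pnorm(z, lower.tail = FALSE) + sigma * stats::dnorm(z)
}

#' Gaussian expectile (independent oracle)
#'
#' The tau-expectile of `N(mu, sigma)` is the root of
#' `tau * E[(X - e)+] = (1 - tau) * E[(e - X)+]`, solved by bracketed root
#' finding on closed-form partial expectations. This is the stationary point
#' of the asymmetric TD update and serves as its independent check.
#'
#' @param tau asymmetry in (0, 1).
#' @param mu,sigma Gaussian parameters (`sigma > 0`).
#' @return the expectile (scalar; vectorized over `tau`).
#' @examples
#' expectile_gaussian(0.5, 5, 5) # 5
#' @export
expectile_gaussian <- function(tau, mu = 0, sigma = 1) {
  stopifnot(all(tau > 0 & tau < 1), sigma > 0)
  vapply(tau, function(tt) {
    f <- function(e) {
      up <- gaussian_upper_partial(e, mu, sigma)
      lo <- up + e - mu # E[(e - X)+] = e - mu + E[(X - e)+]
      tt * up - (1 - tt) * lo
    }
    stats::uniroot(f, c(mu - 12 * sigma, mu + 12 * sigma), tol = 1e-10)$root
  }, numeric(1))
}

#' Stationary reward-state TD error of a learning-rate pair
#'
#' At stationarity the reward-state value sits at the tau-expectile of the
#' training distribution, so the expected TD error there is
#' `mu - e_tau`. Used by the grid-search fit in place of re-simulating each
#' grid point.
#'
#' @param tau asymmetry value(s) in (0, 1).
#' @param config a [td_config()].
#' @return expected stationary TD error(s).
#' @export
stationary_reward_delta <- function(tau, config) {
  config$reward_mean - expectile_gaussian(tau, config$reward_mean,
                                          config$reward_sd)
}

#' Kernel-density model of a population's reward-window activity
#'
#' Gaussian-kernel density estimate (Silverman bandwidth) of standardized
#' reward responses, with a sampler for drawing fit targets. A zero-variance
#' sample is flagged degenerate and given a nominal bandwidth.
#'
#' @param responses numeric sample (>= 5 values).
#' @param label population label.
#' @return an `activity_distribution`: `sample`, `bw`, `x`/`y` density grid,
#'   `degenerate` flag, `label`.
#' @export
estimate_activity_distribution <- function(responses, label = "pooled") {
  if (length(responses) < 5) stop("at least 5 responses required")
  degenerate <- stats::sd(responses) == 0
  bw <- if (degenerate) {
    warning("zero-variance responses; degenerate activity distribution")
    max(abs(responses[1]) * 1e-3, 1e-6)
  } else {
    stats::bw.nrd0(responses)
  }
  d <- stats::density(responses, bw = bw, n = 512,
                      from = min(responses) - 4 * bw,
                      to = max(responses) + 4 * bw)
  structure(list(sample = responses, bw = bw, x = d$x, y = d$y,
                 degenerate = degenerate, label = label),
            class = "activity_distribution")
}

#' Draw from an activity distribution
#'
#' Samples the KDE: a resampled data point plus Gaussian kernel noise of the
#' estimated bandwidth.
#'
#' @param dist an `activity_distribution`.
#' @param n number of draws.
#' @param seed integer seed.
#' @return numeric vector of `n` draws.
#' @export
sample_activity <- function(dist, n, seed = 1L) {
  stopifnot(inherits(dist, "activity_distribution"))
  with_seed(seed, {
    sample(dist$sample, n, replace = TRUE) + stats::rnorm(n, 0, dist$bw)
  })
}

#' Fit per-neuron learning rates by grid search
#'
#' For each neuron one target TD error is drawn from the activity
#' distribution; over all `(alpha+, alpha-)` grid pairs the stationary
#' reward-state TD error (from the expectile relation) is compared to the
#' target in squared difference and the minimizing pair selected, ties broken
#' toward the smaller `alpha+ + alpha-`. A symmetric zero-mean target
#' distribution therefore yields mean asymmetry 0.5; strictly positive
#' targets (persistent positive reward-state errors, i.e. values below the
#' training mean) yield asymmetries below 0.5.
#'
#' @param activity an `activity_distribution`.
#' @param config a [td_config()].
#' @param seed integer seed for the target draws.
#' @return a `fit_result` data frame: per neuron `alpha_plus`, `alpha_minus`,
#'   `asymmetry`, `loss`, `target`.
#' @export
fit_learning_rates <- function(activity, config, seed = config$seed) {
  stopifnot(inherits(activity, "activity_distribution"),
            inherits(config, "td_config"))
  g <- config$grid
  if (!length(g)) stop("empty learning-rate grid")
  pairs <- expand.grid(alpha_plus = g, alpha_minus = g)
  tau_pair <- pairs$alpha_plus / (pairs$alpha_plus + pairs$alpha_minus)
  tau_unique <- sort(unique(tau_pair))
  delta_unique <- stationary_reward_delta(tau_unique, config)
  delta_pair <- delta_unique[match(tau_pair, tau_unique)]
  if (any(!is.finite(delta_pair))) stop("non-finite stationary TD errors on the grid")
  rate_sum <- pairs$alpha_plus + pairs$alpha_minus

  targets <- sample_activity(activity, config$n_neurons,
                             seed = derive_seed(seed, 7))
  rows <- lapply(seq_len(config$n_neurons), function(i) {
    loss <- (delta_pair - targets[i])^2
    best <- which(loss <= min(loss) + 1e-12)
    pick <- best[which.min(rate_sum[best])]
    data.frame(neuron = i,
               alpha_plus = pairs$alpha_plus[pick],
               alpha_minus = pairs$alpha_minus[pick],
               asymmetry = tau_pair[pick],
               loss = loss[pick],
               target = targets[i])
  })
  out <- do.call(rbind, rows)
  class(out) <- c("fit_result", class(out))
  out
}

#' Evaluate a trained agent on test rewards
#'
#' Test rewards are drawn uniform over the configured range; predictions are
#' the converged per-neuron reward-state values (no learning during test).
#' Per-cell mean squared error over the test rewards, per-agent mean MSE, and
#' the sign of the prediction bias.
#'
#' @param agent a trained `td_agent`.
#' @param config a [td_config()].
#' @param n_test number of test rewards.
#' @param seed integer seed.
#' @return an `evaluation_result`: `test_rewards`, `predictions` (per
#'   neuron), `mse_per_cell`, `mean_mse`, `bias` (mean prediction minus mean
#'   test reward).
#' @export
evaluate_agent <- function(agent, config, n_test = 200, seed = config$seed) {
  stopifnot(inherits(agent, "td_agent"))
  if (!isTRUE(agent$trained)) stop("agent must be trained before evaluation")
  y <- with_seed(derive_seed(seed, 13), {
    stats::runif(n_test, config$test_range[1], config$test_range[2])
  })
  yhat <- agent$value_estimate
  mse <- vapply(yhat, function(v) mean((y - v)^2), numeric(1))
  structure(list(test_rewards = y, predictions = yhat, mse_per_cell = mse,
                 mean_mse = mean(mse), bias = mean(yhat) - mean(y),
                 label = agent$label),
            class = "evaluation_result")
}

#' Build, fit and train projection-defined agents
#'
#' One agent per population activity sample plus a unified agent fit to the
#' pooled sample. Each agent's learning rates come from the grid-search fit
#' to its population's activity distribution; each is then trained on the
#' common environment.
#'
#' @param samples named list of numeric activity samples (one per
#'   population).
#' @param config a [td_config()].
#' @param seed master seed.
#' @return named list of trained `td_agent`s (populations plus
#'   `"unified"`), each with its `fit` attached.
#' @export
build_projection_agents <- function(samples, config = td_config(),
                                    seed = config$seed) {
  if (!length(samples)) stop("at least one population sample required")
  if (is.null(names(samples)) || any(!nzchar(names(samples)))) {
    stop("samples must be a named list")
  }
  samples <- c(samples, list(unified = unlist(samples, use.names = FALSE)))
  agents <- list()
  for (i in seq_along(samples)) {
    nm <- names(samples)[i]
    act <- estimate_activity_distribution(samples[[i]], label = nm)
    fit <- fit_learning_rates(act, config, seed = derive_seed(seed, 31, i))
    agent <- make_td_agent(config, alpha_plus = fit$alpha_plus,
                           alpha_minus = fit$alpha_minus, label = nm)
    agent <- train_agent(agent, config, seed = derive_seed(seed, 37, i))
    agent$fit <- fit
    agents[[nm]] <- agent
  }
  agents
}

#' Standardized reward-window responses of a cohort
#'
#' Maps firing to the dimensionless TD-error scale of the model fit: each
#' unit's mean rate in the reward window (40--240 ms by default) minus its
#' pre-cue baseline rate, divided by the pooled standard deviation of those
#' baseline-subtracted responses across all units supplied.
#'
#' @param sessions named list of `synthetic_session`s (one per population).
#' @param window reward-aligned window, seconds.
#' @param baseline_s pre-cue baseline span, seconds.
#' @return named list of numeric response vectors on a common scale.
#' @export
reward_window_responses <- function(sessions, window = c(0.04, 0.24),
                                    baseline_s = 1) {
  raw <- lapply(sessions, function(ss) {
    vapply(ss$spike_trains, function(tr) {
      spikes <- sort(tr$spike_times_s)
      count_in <- function(starts, width) {
        sum(findInterval(starts + width, spikes) - findInterval(starts, spikes)) /
          (length(starts) * width)
      }
      rw <- count_in(ss$events$reward_times_s + window[1], diff(window))
      bl <- count_in(ss$events$cue_onsets_s - baseline_s, baseline_s)
      rw - bl
    }, numeric(1))
  })
  pooled_sd <- stats::sd(unlist(raw, use.names = FALSE))
  if (!is.finite(pooled_sd) || pooled_sd == 0) pooled_sd <- 1
  lapply(raw, function(x) x / pooled_sd)
}
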