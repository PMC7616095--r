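#' Build the Poisson-GLM design matrix for one unit
#'
#' The whole session, ITIs included, is tiled with 200-ms spike-count bins
#' aligned per trial to cue onset: each trial's bins run from 1 s before its
#' cue to 1 s before the next cue (session end for the last trial), a trailing
#' partial bin being dropped. Binary regressors: `cue` and `reward` are 1 for
#' the two bins covering 0--400 ms from the respective onset; `lick` and
#' `movement` are 1 where the bin overlaps a bout by at least 75% of the bin
#' length. Several regressors may be active in the same bin.
#'
#' @param train a `spike_train`.
#' @param events a `session_events`.
#' @param bin_s bin width, seconds.
#' @param event_code_s event-positive span from onset (default 0.4 s).
#' @param overlap_frac minimum bout overlap fraction for lick/movement coding.
#' @return a `design_matrix`: data frame with `trial`, `bin_start_s`, `count`,
#'   and 0/1 columns `cue`, `reward`, `lick`, `movement`.
#' @export
build_design_matrix <- function(train, events, bin_s = 0.2,
                                event_code_s = 0.4, overlap_frac = 0.75) {
  stopifnot(inherits(events, "session_events"))
  check_bouts <- function(b) {
    if (nrow(b) && (min(b$onset_s) < 0 ||
                    max(b$offset_s) > events$session_duration_s)) {
      stop("bouts outside session bounds")
    }
  }
  check_bouts(events$lick_bouts)
  check_bouts(events$movement_bouts)

  cues <- events$cue_onsets_s
  rewards <- events$reward_times_s
  n <- length(cues)
  seg_start <- cues - 1
  seg_end <- c(cues[-1] - 1, events$session_duration_s)

  starts <- trial <- list()
  for (k in seq_len(n)) {
    nb <- floor((seg_end[k] - seg_start[k]) / bin_s + 1e-9) # drop partial tail
    if (nb < 1) next
    starts[[k]] <- seg_start[k] + bin_s * (seq_len(nb) - 1)
    trial[[k]] <- rep(k, nb)
  }
  bin_start <- unlist(starts)
  trial <- unlist(trial)
  spikes <- sort(train$spike_times_s)
  count <- findInterval(bin_start + bin_s - 1e-12, spikes) -
    findInterval(bin_start - 1e-12, spikes)

  code_onset <- function(onsets) {
    on <- onsets[trial] # bins are trial-aligned, so compare within trial
    as.integer(bin_start - on >= -1e-9 & bin_start - on < event_code_s - 1e-9)
  }
  overlap_with <- function(bouts) {
    if (!nrow(bouts)) return(integer(length(bin_start)))
    ov <- numeric(length(bin_start))
    for (j in seq_len(nrow(bouts))) {
      o <- pmin(bin_start + bin_s, bouts$offset_s[j]) -
        pmax(bin_start, bouts$onset_s[j])
      ov <- ov + pmax(o, 0) # bouts of one kind are disjoint, sums are exact
    }
    as.integer(ov >= overlap_frac * bin_s - 1e-9)
  }

  d <- data.frame(trial = trial, bin_start_s = bin_start, count = count,
                  cue = code_onset(cues), reward = code_onset(rewards),
                  lick = overlap_with(events$lick_bouts),
                  movement = overlap_with(events$movement_bouts))
  class(d) <- c("design_matrix", class(d))
  d
}

#' Fit the Poisson encoding GLM of one unit
#'
#' Maximum-likelihood Poisson regression (log link) of per-bin spike counts on
#' the four binary regressors plus an intercept, with per-coefficient Wald
#' p-values and a deviance goodness-of-fit p from the chi-square distribution
#' of the residual deviance.
#'
#' @param design a [build_design_matrix()] result (or any data frame with a
#'   `count` column and the four regressors).
#' @return an `encoding_fit`: `coefficients`, `se`, `p_values` (named vectors
#'   incl. intercept), `deviance`, `df_residual`, `gof_p`, `converged`, and
#'   the fitted `glm` object.
#' @export
fit_poisson_encoding_glm <- function(design) {
  if (all(design$count == 0)) stop("all-zero counts: unit has no spikes in any bin")
  fit <- stats::glm(count ~ cue + reward + lick + movement,
                    family = stats::poisson(), data = design)
  sm <- summary(fit)
  co <- sm$coefficients
  aliased <- sm$aliased
  if (any(aliased)) warning("rank-deficient design; aliased: ",
                            paste(names(aliased)[aliased], collapse = ", "))
  structure(
    list(coefficients = co[, "Estimate"],
         se = co[, "Std. Error"],
         p_values = co[, "Pr(>|z|)"],
         deviance = fit$deviance,
         df_residual = fit$df.residual,
         gof_p = stats::pchisq(fit$deviance, fit$df.residual,
                               lower.tail = FALSE),
         converged = fit$converged,
         glm = fit),
    class = "encoding_fit"
  )
}

#' Classify which parameters a unit encodes
#'
#' A unit is responsive to a parameter when its Wald p-value is below `alpha`
#' (no multiple-testing correction, per the analysis the model reproduces);
#' the dominant parameter is the significant one with the largest absolute
#' coefficient, increases and decreases counting alike.
#'
#' @param fit an `encoding_fit`.
#' @param alpha significance level.
#' @return an `encoding_classification`: `significant` (character vector),
#'   `dominant` (or `"none"`), `multiplexing` count.
#' @export
classify_encoding <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "encoding_fit"))
  if (!isTRUE(fit$converged)) warning("classifying a non-converged fit")
  params <- c("cue", "reward", "lick", "movement")
  p <- fit$p_values[params]
  beta <- fit$coefficients[params]
  sig <- params[!is.na(p) & p < alpha]
  dominant <- if (length(sig)) sig[which.max(abs(beta[sig]))] else "none"
  structure(list(significant = sig, dominant = dominant,
                 multiplexing = length(sig)),
            class = "encoding_classification")
}

#' Mean event-window firing rate with a shuffled-baseline p-value
#'
#' Mean rate across trials in a fixed window after cue or reward, compared to
#' a null distribution built by placing the same set of windows at random
#' positions inside the inter-trial intervals (excluding the first second
#' after each reward). Two-sided percentile p-value.
#'
#' @param train a `spike_train`.
#' @param events a `session_events`.
#' @param align `"cue"` or `"reward"`.
#' @param window window relative to the aligning event, seconds (defaults to
#'   the 0--240 ms cue window; use `c(0.04, 0.24)` for the reward window).
#' @param n_shuffles number of shuffled placements (>= 100).
#' @param exclude_post_reward_s post-reward seconds excluded from shuffles.
#' @param seed integer seed for the shuffle placement.
#' @return a list: `rate_hz`, `shuffle_p`, `null_rates_hz`.
#' @export
event_window_rate <- function(train, events, align = c("cue", "reward"),
                              window = c(0, 0.24), n_shuffles = 1000,
                              exclude_post_reward_s = 1, seed = 1L) {
  align <- match.arg(align)
  if (n_shuffles < 100) stop("n_shuffles must be >= 100")
  onsets <- if (align == "cue") events$cue_onsets_s else events$reward_times_s
  width <- diff(window)
  stopifnot(width > 0)
  spikes <- sort(train$spike_times_s)
  rate_in <- function(starts) {
    hi <- findInterval(starts + width, spikes)
    lo <- findInterval(starts, spikes)
    mean(hi - lo) / width
  }
  obs <- rate_in(onsets + window[1])

  seg_lo <- events$reward_times_s + exclude_post_reward_s
  seg_hi <- c(events$cue_onsets_s[-1], events$session_duration_s)
  len <- pmax(seg_hi - seg_lo - width, 0)
  if (sum(len) <= 0) stop("shuffle window longer than every inter-trial interval")
  null_rates <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      seg <- sample.int(length(len), length(onsets), replace = TRUE,
                        prob = len)
      rate_in(seg_lo[seg] + stats::runif(length(onsets)) * len[seg])
    }, numeric(1))
  })
  p_hi <- (1 + sum(null_rates >= obs)) / (n_shuffles + 1)
  p_lo <- (1 + sum(null_rates <= obs)) / (n_shuffles + 1)
  list(rate_hz = obs, shuffle_p = min(1, 2 * min(p_hi, p_lo)),
       null_rates_hz = null_rates)
}
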