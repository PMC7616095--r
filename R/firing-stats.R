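#' CV2 firing-regularity index
#'
#' Mean over adjacent interval pairs of `2|ISI[n+1] - ISI[n]| / (ISI[n+1] +
#' ISI[n])`: 0 for perfectly regular firing, approximately 1 for a Poisson
#' process, up to 2. Scale-invariant.
#'
#' @param isis inter-spike intervals in seconds (all positive).
#' @return mean CV2 (scalar).
#' @examples
#' compute_cv2(c(1, 3)) # 1
#' @export
compute_cv2 <- function(isis) {
  if (length(isis) < 2) stop("CV2 needs at least two inter-spike intervals")
  if (any(isis <= 0)) stop("inter-spike intervals must be positive")
  a <- isis[-length(isis)]
  b <- isis[-1]
  mean(2 * abs(b - a) / (b + a))
}

# Robust-surprise detection of outlier ISI strings on one tail.
#
# Null model: a robust exponential matched to the median ISI (rate =
# log(2)/median, re-estimated excluding already-detected strings, so bursts
# or pauses do not contaminate the tonic estimate). Candidate seeds are
# single ISIs, or adjacent pairs, whose one-sided tail probability under
# that null is below alpha. Around each seed the most surprising substring
# within +/- `span` intervals is found; a string's surprise is the exact
# gamma tail probability of its summed length (-log10), the sufficient
# statistic for a uniform rate change over the string. Retention uses a
# Bonferroni-corrected threshold, -log10(alpha / n_substrings_searched),
# accounting for the per-seed selection. Overlapping strings are pruned,
# most surprising first.
rgs_detect <- function(isis, alpha, tail = c("short", "long"), min_isis,
                       span = 4, max_iter = 3) {
  tail <- match.arg(tail)
  if (length(isis) < 10) stop("at least 10 inter-spike intervals required")
  if (any(isis <= 0)) stop("inter-spike intervals must be positive")
  n <- length(isis)
  lower <- tail == "short"
  thresh <- -log10(alpha) + log10((span + 1)^2)
  cs <- c(0, cumsum(isis))
  empty <- data.frame(start_isi = integer(0), n_isis = integer(0),
                      n_spikes = integer(0), surprise = numeric(0))
  mask <- rep(TRUE, n)
  out <- list()
  for (it in seq_len(max_iter)) {
    med <- stats::median(isis[mask])
    if (!is.finite(med) || med <= 0) break
    rate <- log(2) / med
    surprise <- function(i, j) {
      -stats::pgamma(cs[j + 1] - cs[i], shape = j - i + 1, rate = rate,
                     lower.tail = lower, log.p = TRUE) / log(10)
    }
    p1 <- stats::pexp(isis, rate, lower.tail = lower)
    p2 <- stats::pgamma(isis[-n] + isis[-1], shape = 2, rate = rate,
                        lower.tail = lower)
    seeds <- sort(unique(c(which(p1 < alpha), which(p2 < alpha))))
    strings <- list()
    for (s in seeds) {
      best <- NULL
      bs <- -Inf
      for (i in max(1, s - span):s) {
        for (j in s:min(n, s + span)) {
          if (j - i + 1 < min_isis) next
          S <- surprise(i, j)
          if (S > bs) {
            bs <- S
            best <- c(i, j)
          }
        }
      }
      if (!is.null(best) && bs >= thresh) {
        strings[[length(strings) + 1]] <- c(i = best[1], j = best[2], s = bs)
      }
    }
    newmask <- rep(TRUE, n)
    if (length(strings)) {
      m <- do.call(rbind, strings)
      for (r in seq_len(nrow(m))) newmask[m[r, "i"]:m[r, "j"]] <- FALSE
    }
    out <- strings
    if (identical(newmask, mask)) break
    mask <- newmask
  }
  if (!length(out)) return(empty)
  m <- unique(do.call(rbind, out))
  m <- m[order(-m[, "s"]), , drop = FALSE]
  taken <- rep(FALSE, n)
  keep <- logical(nrow(m))
  for (r in seq_len(nrow(m))) {
    sp <- m[r, "i"]:m[r, "j"]
    if (!any(taken[sp])) {
      taken[sp] <- TRUE
      keep[r] <- TRUE
    }
  }
  m <- m[keep, , drop = FALSE]
  m <- m[order(m[, "i"]), , drop = FALSE]
  data.frame(start_isi = as.integer(m[, "i"]),
             n_isis = as.integer(m[, "j"] - m[, "i"] + 1),
             n_spikes = as.integer(m[, "j"] - m[, "i"] + 2),
             surprise = m[, "s"])
}

#' Burst detection by robust surprise on inter-spike intervals
#'
#' Detects strings of unusually short intervals against a robust,
#' median-matched exponential null: candidate strings are seeded by
#' individually (or pairwise) sub-`alpha` intervals, scored by the exact
#' gamma tail probability of their summed length, and retained at a
#' selection-corrected significance threshold. A burst spans at least three
#' spikes. Detection is invariant to uniform time rescaling.
#'
#' @param isis inter-spike intervals, seconds (>= 10).
#' @param alpha detection level.
#' @param span search half-width (in intervals) around each seed.
#' @return data frame `start_isi`, `n_isis`, `n_spikes`, `surprise`
#'   (non-overlapping; a burst spans spikes `start_isi ... start_isi +
#'   n_isis` of the interval sequence).
#' @export
detect_bursts_rgs <- function(isis, alpha = 0.05, span = 4) {
  rgs_detect(isis, alpha, tail = "short", min_isis = 2, span = span)
}

#' Pause detection by robust surprise on inter-spike intervals
#'
#' Mirror image of [detect_bursts_rgs()] on the long-interval tail; a pause
#' is a string of one or more significantly long intervals.
#'
#' @inheritParams detect_bursts_rgs
#' @return data frame as in [detect_bursts_rgs()] plus `duration_s`, the
#'   summed length of the pause intervals.
#' @export
detect_pauses_rgs <- function(isis, alpha = 0.05, span = 4) {
  out <- rgs_detect(isis, alpha, tail = "long", min_isis = 1, span = span)
  out$duration_s <- vapply(seq_len(nrow(out)), function(r) {
    sum(isis[out$start_isi[r]:(out$start_isi[r] + out$n_isis[r] - 1)])
  }, numeric(1))
  out
}

# ITI spans "outside of engagement": from `post_reward_s` after each reward to
# `pre_cue_s` before the next cue (session end after the last trial)
iti_spans <- function(events, post_reward_s = 3, pre_cue_s = 1) {
  lo <- events$reward_times_s + post_reward_s
  hi <- c(events$cue_onsets_s[-1] - pre_cue_s, events$session_duration_s)
  ok <- hi > lo
  data.frame(start_s = lo[ok], end_s = hi[ok])
}

#' Tonic firing summary over the inter-trial intervals
#'
#' Statistics restricted to task-disengaged epochs: each ITI minus the first
#' `post_reward_s` seconds after reward (consummatory licking) and the final
#' `pre_cue_s` second before the next cue. ISI-based measures (CV2, bursts,
#' pauses) use only intervals between spikes falling in the same epoch.
#'
#' @param train a `spike_train`.
#' @param events a `session_events`.
#' @param post_reward_s,pre_cue_s engagement margins trimmed from each ITI.
#' @param alpha detection level for bursts and pauses.
#' @return a `firing_summary`: `iti_rate_hz`, `mean_cv2` (NA with
#'   `cv2_defined = FALSE` when too few intervals), `burst_fraction` (of ITI
#'   spikes), `n_pauses`, `median_pause_s`.
#' @export
iti_firing_summary <- function(train, events, post_reward_s = 3,
                               pre_cue_s = 1, alpha = 0.05) {
  spans <- iti_spans(events, post_reward_s, pre_cue_s)
  total <- sum(spans$end_s - spans$start_s)
  if (total <= 0) stop("inter-trial intervals have zero usable duration")
  spikes <- sort(train$spike_times_s)
  isis <- list()
  n_spikes <- 0
  for (r in seq_len(nrow(spans))) {
    s <- spikes[spikes >= spans$start_s[r] & spikes < spans$end_s[r]]
    n_spikes <- n_spikes + length(s)
    if (length(s) > 1) isis[[length(isis) + 1]] <- diff(s)
  }
  isis <- unlist(isis) %||% numeric(0)
  rate <- n_spikes / total
  cv2_defined <- length(isis) >= 2
  cv2 <- if (cv2_defined) compute_cv2(isis) else NA_real_
  if (length(isis) >= 10) {
    bursts <- detect_bursts_rgs(isis, alpha)
    pauses <- detect_pauses_rgs(isis, alpha)
    burst_fraction <- sum(bursts$n_spikes) / max(n_spikes, 1)
    n_pauses <- nrow(pauses)
    median_pause <- if (n_pauses) stats::median(pauses$duration_s) else NA_real_
  } else {
    burst_fraction <- NA_real_
    n_pauses <- NA_integer_
    median_pause <- NA_real_
  }
  structure(list(iti_rate_hz = rate, mean_cv2 = cv2, cv2_defined = cv2_defined,
                 burst_fraction = burst_fraction, n_pauses = n_pauses,
                 median_pause_s = median_pause),
            class = "firing_summary")
}
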