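#' Five-tap Gaussian smoothing kernel
#'
#' The PSTH smoother: a Gaussian of 70-ms full width at half maximum sampled
#' at the 40-ms bin spacing, truncated to 5 taps and renormalized to unit sum
#' (so constant inputs pass unchanged).
#'
#' @param fwhm_s full width at half maximum, seconds.
#' @param bin_s bin width, seconds.
#' @param n_taps number of taps (odd).
#' @return numeric vector of `n_taps` weights summing to 1.
#' @export
gaussian_taps <- function(fwhm_s = 0.070, bin_s = 0.040, n_taps = 5) {
  stopifnot(n_taps %% 2 == 1)
  sigma_bins <- (fwhm_s / (2 * sqrt(2 * log(2)))) / bin_s
  half <- (n_taps - 1) / 2
  w <- stats::dnorm(seq(-half, half), 0, sigma_bins)
  w / sum(w)
}

# convolve each row with a unit-sum kernel; edge taps renormalized over the
# in-range portion so constants stay constant at the borders too
smooth_rows <- function(m, kernel) {
  half <- (length(kernel) - 1) / 2
  nb <- ncol(m)
  out <- matrix(0, nrow(m), nb)
  for (j in seq_len(nb)) {
    idx <- (j - half):(j + half)
    ok <- idx >= 1 & idx <= nb
    w <- kernel[ok] / sum(kernel[ok])
    out[, j] <- m[, idx[ok], drop = FALSE] %*% w
  }
  out
}

#' Event-aligned, z-scored, smoothed peri-stimulus time histogram
#'
#' Spike counts in 40-ms bins over a window around each cue, converted to
#' rates, z-scored against the mean and standard deviation of the pooled 1-s
#' pre-cue baseline bins of all trials, and smoothed with the 5-tap Gaussian
#' kernel. Baseline z has pooled mean 0 by construction (assessed on the
#' unsmoothed matrix).
#'
#' @param train a `spike_train`.
#' @param events a `session_events`.
#' @param window alignment window in seconds relative to cue onset.
#' @param bin_s bin width (default 40 ms).
#' @param baseline_s length of the pre-cue baseline, seconds.
#' @param kernel smoothing kernel (unit sum).
#' @return a `psth` object: `bin_edges_s`, `bin_centers_s`, `rate` (trials x
#'   bins, Hz), `z_raw` and `z` (smoothed) matrices, `mean_z`,
#'   `baseline_mean_hz`, `baseline_sd_hz`, and `silent` flag. For a silent
#'   unit (zero baseline SD) the z fields are `NULL` and `silent` is `TRUE`.
#' @export
compute_psth <- function(train, events, window = c(-1, 4), bin_s = 0.040,
                         baseline_s = 1, kernel = gaussian_taps(bin_s = bin_s)) {
  stopifnot(inherits(events, "session_events"), window[1] < window[2])
  cues <- events$cue_onsets_s
  if (length(cues) < 1) stop("at least one trial required")
  n_bins <- round((window[2] - window[1]) / bin_s)
  edges <- window[1] + bin_s * (0:n_bins)
  spikes <- train$spike_times_s
  rate <- matrix(0, length(cues), n_bins)
  for (k in seq_along(cues)) {
    rel <- spikes[spikes >= cues[k] + edges[1] &
                  spikes < cues[k] + edges[n_bins + 1]] - cues[k]
    if (length(rel)) {
      counts <- tabulate(findInterval(rel, edges), nbins = n_bins)
      rate[k, ] <- counts / bin_s
    }
  }
  base_cols <- which(edges[-length(edges)] >= -baseline_s - 1e-9 &
                     edges[-1] <= 1e-9)
  base_vals <- rate[, base_cols]
  b_mean <- mean(base_vals)
  b_sd <- stats::sd(as.numeric(base_vals))
  centers <- edges[-length(edges)] + bin_s / 2
  if (!is.finite(b_sd) || b_sd == 0) {
    return(structure(list(bin_edges_s = edges, bin_centers_s = centers,
                          rate = rate, z_raw = NULL, z = NULL, mean_z = NULL,
                          baseline_mean_hz = b_mean, baseline_sd_hz = b_sd,
                          kernel = kernel, silent = TRUE),
                     class = "psth"))
  }
  z_raw <- (rate - b_mean) / b_sd
  z <- smooth_rows(z_raw, kernel)
  structure(list(bin_edges_s = edges, bin_centers_s = centers, rate = rate,
                 z_raw = z_raw, z = z, mean_z = colMeans(z),
                 baseline_mean_hz = b_mean, baseline_sd_hz = b_sd,
                 kernel = kernel, silent = FALSE),
            class = "psth")
}

#' Stack the mean PSTHs of a cohort into a units-by-bins matrix
#'
#' Silent units (zero baseline SD) are dropped with a warning; the result is
#' the input to [extract_pcs()] and hierarchical clustering.
#'
#' @param trains list of `spike_train` objects.
#' @param events shared `session_events`.
#' @param ... passed to [compute_psth()].
#' @return a matrix (units x bins) of smoothed mean z, with unit ids as row
#'   names and an attribute `bin_centers_s`.
#' @export
psth_matrix <- function(trains, events, ...) {
  rows <- list()
  centers <- NULL
  for (tr in trains) {
    p <- compute_psth(tr, events, ...)
    if (p$silent) {
      warning("unit ", tr$unit_id, " is silent in the baseline; excluded")
      next
    }
    rows[[tr$unit_id %||% as.character(length(rows) + 1)]] <- p$mean_z
    centers <- p$bin_centers_s
  }
  if (!length(rows)) stop("no non-silent units")
  m <- do.call(rbind, rows)
  attr(m, "bin_centers_s") <- centers
  m
}
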