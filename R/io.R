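#' Write session events to CSV
#'
#' Long format: one row per event, columns `event_type` (cue, reward, lick,
#' movement), `onset_s`, `offset_s` (equal to onset for point events).
#'
#' @param events a `session_events`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_session_events_csv <- function(events, path) {
  stopifnot(inherits(events, "session_events"))
  rows <- rbind(
    data.frame(event_type = "cue", onset_s = events$cue_onsets_s,
               offset_s = events$cue_onsets_s),
    data.frame(event_type = "reward", onset_s = events$reward_times_s,
               offset_s = events$reward_times_s),
    if (nrow(events$lick_bouts)) {
      data.frame(event_type = "lick", onset_s = events$lick_bouts$onset_s,
                 offset_s = events$lick_bouts$offset_s)
    },
    if (nrow(events$movement_bouts)) {
      data.frame(event_type = "movement",
                 onset_s = events$movement_bouts$onset_s,
                 offset_s = events$movement_bouts$offset_s)
    }
  )
  utils::write.csv(rows[order(rows$onset_s), ], path, row.names = FALSE)
  invisible(path)
}

#' Read session events from CSV
#'
#' Inverse of [write_session_events_csv()]; the session duration is taken
#' from `duration_s` when present, else the last event offset.
#'
#' @param path CSV file.
#' @param session_duration_s optional explicit duration.
#' @return a `session_events`.
#' @export
read_session_events_csv <- function(path, session_duration_s = NULL) {
  d <- utils::read.csv(path)
  pick <- function(type) d[d$event_type == type, , drop = FALSE]
  lick <- pick("lick")
  mv <- pick("movement")
  new_session_events(
    cue_onsets_s = sort(pick("cue")$onset_s),
    reward_times_s = sort(pick("reward")$onset_s),
    lick_bouts = data.frame(onset_s = lick$onset_s, offset_s = lick$offset_s),
    movement_bouts = data.frame(onset_s = mv$onset_s, offset_s = mv$offset_s),
    session_duration_s = session_duration_s %||% max(d$offset_s)
  )
}

#' Write spike trains to CSV
#'
#' One row per spike: `unit_id`, `spike_time_s`, plus the ground-truth
#' columns when a `synthetic_session` is given.
#'
#' @param trains list of `spike_train`s or a `synthetic_session`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spike_trains_csv <- function(trains, path) {
  if (inherits(trains, "synthetic_session")) trains <- trains$spike_trains
  rows <- lapply(trains, function(tr) {
    if (!length(tr$spike_times_s)) return(NULL)
    data.frame(unit_id = tr$unit_id, spike_time_s = tr$spike_times_s)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write a photometry recording to CSV
#'
#' Columns `time_s`, `activity`, `reference`; the sampling rate is implied by
#' the time column.
#'
#' @param recording a `photometry_recording`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_photometry_csv <- function(recording, path) {
  stopifnot(inherits(recording, "photometry_recording"))
  n <- length(recording$activity)
  utils::write.csv(
    data.frame(time_s = (seq_len(n) - 1) / recording$fs_hz,
               activity = recording$activity,
               reference = recording$reference),
    path, row.names = FALSE
  )
  invisible(path)
}

#' Write an encoding results table
#'
#' One row per unit: coefficients, p-values, significance flags, dominant
#' parameter, goodness of fit.
#'
#' @param fits named list of `encoding_fit`s.
#' @param classifications matching list of `encoding_classification`s.
#' @param path output file.
#' @return the table, invisibly (also written to `path` when non-NULL).
#' @export
write_encoding_csv <- function(fits, classifications, path = NULL) {
  params <- c("cue", "reward", "lick", "movement")
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    cl <- classifications[[i]]
    r <- data.frame(unit_id = names(fits)[i] %||% as.character(i),
                    intercept = unname(f$coefficients["(Intercept)"]),
                    gof_p = f$gof_p, dominant = cl$dominant,
                    multiplexing = cl$multiplexing)
    for (p in params) {
      r[[paste0("beta_", p)]] <- unname(f$coefficients[p])
      r[[paste0("p_", p)]] <- unname(f$p_values[p])
      r[[paste0("sig_", p)]] <- p %in% cl$significant
    }
    r
  })
  tab <- do.call(rbind, rows)
  if (!is.null(path)) utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
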