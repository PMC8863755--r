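#' Cleaning parameters
#'
#' Three rules take an exported stream from raw to analysis-ready. Double
#' counts: when the same event is documented twice within a few milliseconds
#' it is certainly a double-count, so only the earlier record survives;
#' `epsilon_ms` (default 100 ms, generous against tens of milliseconds of OS
#' scheduling jitter) bounds "a few milliseconds". Idle episodes: a single
#' app foregrounded for multiple hours — e.g. a clock app on a device whose
#' screen stays on while charging — is flagged, not deleted, when longer than
#' `idle_threshold_ms` (default 3 h). Unpaired screen-ons: a session whose
#' screen-off was never logged is closed at the next device shutdown/boot
#' (`repair_policy = "close_at_shutdown"`) or dropped
#' (`"drop_unmatched"`).
#'
#' @param epsilon_ms Duplicate window, ms (> 0; default 100).
#' @param idle_threshold_ms Longest plausible continuous foreground, ms
#'   (default 3 hours).
#' @param repair_policy `"close_at_shutdown"` or `"drop_unmatched"`.
#' @return A `cleaning_params` object.
#' @export
cleaning_params <- function(epsilon_ms = 100,
                            idle_threshold_ms = 3 * MS_PER_HOUR,
                            repair_policy = c(
                              "close_at_shutdown",
                              "drop_unmatched"
                            )) {
  stopifnot(epsilon_ms > 0, idle_threshold_ms > 0)
  structure(
    list(
      epsilon_ms = epsilon_ms,
      idle_threshold_ms = idle_threshold_ms,
      repair_policy = match.arg(repair_policy)
    ),
    class = "cleaning_params"
  )
}

#' Remove double-counted events
#'
#' Within the sub-sequence of events sharing a type and app, any run whose
#' successive gaps are all at most `epsilon_ms` is collapsed to its earliest
#' member (the rule chains: three copies 5 ms apart collapse to one). Events
#' of distinct types or apps are never merged, and the rule is idempotent:
#' surviving same-kind events are more than `epsilon_ms` apart.
#'
#' @param events A validated `event_stream`.
#' @param params A [cleaning_params()].
#' @return A list with `events` (the deduplicated stream) and `removed_count`.
#' @export
#' @examples
#' s <- validate_stream(event_stream(c(1000, 1003), c("SCREEN_ON", "SCREEN_ON")))
#' dedupe(s)$removed_count
dedupe <- function(events, params = cleaning_params()) {
  events <- ensure_validated(events)
  n <- nrow(events)
  if (n == 0) {
    return(list(events = events, removed_count = 0L))
  }
  key <- paste(events$type, events$app_id, sep = "\r")
  remove <- logical(n)
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) < 2) next
    gaps <- diff(events$timestamp_ms[idx])
    remove[idx[-1]] <- gaps <= params$epsilon_ms
  }
  out <- new_event_stream(events[!remove, ],
    validated = TRUE,
    rejected = rejected_rows(events)
  )
  list(events = out, removed_count = sum(remove))
}

#' Flag idle foreground episodes
#'
#' Derives maximal single-app foreground episodes (the duration of each event
#' must be established before idleness can be judged) and flags — without
#' deleting — those longer than the idle threshold, which are most plausibly
#' a device left on rather than active use.
#'
#' @param events A validated `event_stream`.
#' @param params A [cleaning_params()].
#' @return A tibble of flagged episodes: `app_id`, `start_ms`, `end_ms`,
#'   `duration_ms`.
#' @export
flag_idle <- function(events, params = cleaning_params()) {
  eps <- app_episodes(events)
  out <- eps[eps$end_ms - eps$start_ms > params$idle_threshold_ms, ]
  out$duration_ms <- out$end_ms - out$start_ms
  out
}

#' Maximal single-app foreground episodes
#'
#' Each `APP_FOREGROUND` opens an episode that closes at the next
#' `APP_FOREGROUND`, an `APP_BACKGROUND` of the same app, a `SCREEN_OFF`, or
#' a `DEVICE_SHUTDOWN`; consecutive foregrounds of the same app merge into
#' one episode. An episode still open at the end of the stream closes at the
#' final event's timestamp.
#'
#' @param events A validated `event_stream`.
#' @return A tibble `app_id`, `start_ms`, `end_ms`.
#' @export
app_episodes <- function(events) {
  events <- ensure_validated(events)
  relevant <- events[events$type %in% c(
    "APP_FOREGROUND", "APP_BACKGROUND",
    "SCREEN_OFF", "DEVICE_SHUTDOWN"
  ), ]
  n <- nrow(relevant)
  out_app <- character(0)
  out_start <- numeric(0)
  out_end <- numeric(0)
  cur_app <- NA_character_
  cur_start <- NA_real_
  close_at <- function(ts) {
    if (!is.na(cur_app) && ts > cur_start) {
      out_app <<- c(out_app, cur_app)
      out_start <<- c(out_start, cur_start)
      out_end <<- c(out_end, ts)
    }
    cur_app <<- NA_character_
  }
  for (i in seq_len(n)) {
    ty <- relevant$type[i]
    ts <- relevant$timestamp_ms[i]
    if (ty == "APP_FOREGROUND") {
      app <- relevant$app_id[i]
      if (!is.na(cur_app) && cur_app == app) next # same app, episode continues
      close_at(ts)
      cur_app <- app
      cur_start <- ts
    } else if (ty == "APP_BACKGROUND") {
      if (!is.na(cur_app) && cur_app == relevant$app_id[i]) close_at(ts)
    } else {
      close_at(ts)
    }
  }
  if (!is.na(cur_app) && nrow(events) > 0) {
    close_at(max(events$timestamp_ms))
  }
  tibble(app_id = out_app, start_ms = out_start, end_ms = out_end)
}

#' Repair unpaired screen sessions
#'
#' A stream interrupted by crashes, dropouts, or power loss can contain a
#' `SCREEN_ON` with no `SCREEN_OFF` before the next `SCREEN_ON` (or the end
#' of the stream), or a `SCREEN_OFF` with no open session. Restart events are
#' always documented, so under `close_at_shutdown` an open session is closed
#' by inserting a `SCREEN_OFF` at the next `DEVICE_SHUTDOWN`/`DEVICE_BOOT`
#' before the next `SCREEN_ON`; with no such anchor (or under
#' `drop_unmatched`) the orphan `SCREEN_ON` is dropped. Orphan `SCREEN_OFF`s
#' are always dropped. After repair, screen-ons and screen-offs strictly
#' alternate.
#'
#' @param events A deduplicated, validated `event_stream`.
#' @param params A [cleaning_params()]; `repair_policy` selects the rule.
#' @return A list with `events` (repaired stream) and `repairs` (tibble
#'   `action`, `timestamp_ms`: one row per inserted or dropped event;
#'   actions are `closed_at_shutdown`, `dropped_screen_on`,
#'   `dropped_screen_off`).
#' @export
repair_sessions <- function(events, params = cleaning_params()) {
  events <- ensure_validated(events)
  df <- as_tibble(events)
  idx <- which(df$type %in% c(
    "SCREEN_ON", "SCREEN_OFF",
    "DEVICE_SHUTDOWN", "DEVICE_BOOT"
  ))
  types <- df$type[idx]
  ts <- df$timestamp_ms[idx]

  drop_rows <- integer(0)
  insert_ts <- numeric(0)
  repairs <- list()
  note <- function(action, at) {
    repairs[[length(repairs) + 1]] <<- tibble(
      action = action,
      timestamp_ms = at
    )
  }

  open_i <- NA_integer_ # position (within idx) of the currently open SCREEN_ON
  anchor <- NA_real_ # first shutdown/boot since the open SCREEN_ON
  close_open <- function() {
    if (is.na(open_i)) {
      return()
    }
    if (params$repair_policy == "close_at_shutdown" && !is.na(anchor)) {
      insert_ts <<- c(insert_ts, anchor)
      note("closed_at_shutdown", anchor)
    } else {
      drop_rows <<- c(drop_rows, idx[open_i])
      note("dropped_screen_on", ts[open_i])
    }
    open_i <<- NA_integer_
    anchor <<- NA_real_
  }

  for (i in seq_along(idx)) {
    switch(types[i],
      SCREEN_ON = {
        close_open() # previous ON had no OFF
        open_i <- i
        anchor <- NA_real_
      },
      SCREEN_OFF = {
        if (is.na(open_i)) {
          drop_rows <- c(drop_rows, idx[i])
          note("dropped_screen_off", ts[i])
        } else {
          open_i <- NA_integer_
          anchor <- NA_real_
        }
      },
      {
        if (!is.na(open_i) && is.na(anchor)) anchor <- ts[i]
      }
    )
  }
  close_open() # trailing unpaired ON

  if (length(drop_rows) > 0) df <- df[-drop_rows, ]
  if (length(insert_ts) > 0) {
    df <- bind_rows(df, tibble(
      timestamp_ms = insert_ts, type = "SCREEN_OFF",
      app_id = NA_character_, source = "continuous"
    ))
  }
  out <- suppressWarnings(validate_stream(df))
  list(
    events = out,
    repairs = if (length(repairs) > 0) {
      bind_rows(repairs)
    } else {
      tibble(action = character(), timestamp_ms = numeric())
    }
  )
}
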