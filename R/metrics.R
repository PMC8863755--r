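#' Pair screen-on/off events into usage sessions
#'
#' Total smartphone time is computed by comparing UNIX timestamps between a
#' screen-on event and the following screen-off event; each such pair is one
#' session (one *pickup*). Intervals are half-open `[start, end)`. The input
#' must alternate strictly on/off — run [repair_sessions()] first on streams
#' that do not (this function checks and directs you there). Sessions
#' crossing an hour/day/week boundary are split later, at aggregation time
#' (see [usage_summary()]), never here.
#'
#' @param events A cleaned, repaired, validated `event_stream`.
#' @return A tibble of sessions: `start_ms`, `end_ms`, `duration_ms`,
#'   `trigger` (all `"unknown"` until [classify_triggers()] runs),
#'   `trigger_app`.
#' @export
#' @examples
#' s <- validate_stream(event_stream(c(1000, 61000), c("SCREEN_ON", "SCREEN_OFF")))
#' sessionize(s)$duration_ms
sessionize <- function(events) {
  events <- ensure_validated(events)
  scr <- events[events$type %in% c("SCREEN_ON", "SCREEN_OFF"), ]
  n <- nrow(scr)
  if (n == 0) {
    return(tibble(
      start_ms = numeric(), end_ms = numeric(), duration_ms = numeric(),
      trigger = character(), trigger_app = character()
    ))
  }
  expected <- rep(c("SCREEN_ON", "SCREEN_OFF"), length.out = n)
  if (n %% 2 != 0 || !identical(scr$type, expected)) {
    abort(paste(
      "screen events do not alternate ON/OFF;",
      "run repair_sessions() before sessionize()"
    ))
  }
  on_ts <- scr$timestamp_ms[seq(1, n, by = 2)]
  off_ts <- scr$timestamp_ms[seq(2, n, by = 2)]
  if (any(off_ts <= on_ts)) {
    abort("found a session with non-positive duration; input is corrupt")
  }
  tibble(
    start_ms = on_ts, end_ms = off_ts, duration_ms = off_ts - on_ts,
    trigger = "unknown", trigger_app = NA_character_
  )
}

#' Foreground app intervals of a stream
#'
#' Converts foreground events into explicit intervals: each `APP_FOREGROUND`
#' opens an interval that ends at the next `APP_FOREGROUND`, a `SCREEN_OFF`
#' (or shutdown), an `APP_BACKGROUND` of the same app, or the end of `span`.
#'
#' @param events A validated `event_stream`.
#' @param span Optional `c(start_ms, end_ms)` to clip to.
#' @return A tibble `app_id`, `start_ms`, `end_ms`.
#' @export
app_intervals <- function(events, span = NULL) {
  eps <- app_episodes(events)
  if (!is.null(span)) {
    stopifnot(length(span) == 2, span[2] > span[1])
    eps$start_ms <- pmax(eps$start_ms, span[1])
    eps$end_ms <- pmin(eps$end_ms, span[2])
    eps <- eps[eps$end_ms > eps$start_ms, ]
  }
  eps
}

#' Total foreground time per app
#'
#' Sums, independently per app, the time differences between consecutive
#' foreground events — i.e. the lengths of the foreground intervals of
#' [app_intervals()]. Idle-flagged episodes (see [flag_idle()]) can be
#' excluded, which subtracts their overlap from the affected apps.
#'
#' @param events A validated `event_stream`.
#' @param span Optional `c(start_ms, end_ms)` analysis window.
#' @param exclude Optional tibble of episodes to exclude (`app_id`,
#'   `start_ms`, `end_ms`), typically [flag_idle()] output.
#' @return A tibble `app_id`, `duration_ms`, sorted by decreasing duration.
#' @export
per_app_durations <- function(events, span = NULL, exclude = NULL) {
  ivs <- app_intervals(events, span)
  if (nrow(ivs) == 0) {
    return(tibble(app_id = character(), duration_ms = numeric()))
  }
  if (!is.null(exclude) && nrow(exclude) > 0) {
    for (i in seq_len(nrow(exclude))) {
      same <- ivs$app_id == exclude$app_id[i]
      cut <- pmin(ivs$end_ms, exclude$end_ms[i]) -
        pmax(ivs$start_ms, exclude$start_ms[i])
      overlap <- same & cut > 0
      ivs$end_ms[overlap] <- ivs$end_ms[overlap] - cut[overlap]
    }
    ivs <- ivs[ivs$end_ms > ivs$start_ms, ]
  }
  out <- ivs |>
    mutate(duration_ms = .data$end_ms - .data$start_ms) |>
    group_by(.data$app_id) |>
    summarise(duration_ms = sum(.data$duration_ms)) |>
    arrange(dplyr::desc(.data$duration_ms))
  out
}

#' Windowed usage summary
#'
#' Splits sessions (and, when supplied, per-app foreground intervals) at
#' hour, day, or week boundaries and totals them per window, in local time
#' expressed as a fixed offset from UTC. A *pickup* is a session start and is
#' counted in the window containing the start only; a session spanning a
#' boundary contributes its duration to each window it touches. Weeks start
#' on Monday, local time.
#'
#' @param sessions Output of [sessionize()] (non-overlapping sessions).
#' @param intervals Optional [app_intervals()] output for per-app breakdowns.
#' @param granularity `"hour"`, `"day"`, or `"week"`.
#' @param tz_offset_min Local-time offset from UTC in minutes (default 0).
#' @return A `usage_summary`: list with `granularity`, `tz_offset_min`,
#'   `windows` (tibble `window_start_ms`, `window_label`, `total_use_ms`,
#'   `pickup_count`) and `per_app` (tibble `window_start_ms`, `app_id`,
#'   `duration_ms`; empty if `intervals` is `NULL`). Windows with no usage
#'   between the first and last active window are present with zeros.
#' @export
usage_summary <- function(sessions, intervals = NULL,
                          granularity = c("day", "hour", "week"),
                          tz_offset_min = 0) {
  granularity <- match.arg(granularity)
  if (nrow(sessions) > 0) {
    o <- order(sessions$start_ms)
    if (any(sessions$end_ms[o][-nrow(sessions)] > sessions$start_ms[o][-1])) {
      abort("sessions overlap; sessionize() output expected")
    }
  }
  off <- tz_offset_min * MS_PER_MIN

  pieces <- split_at_boundaries(
    sessions$start_ms, sessions$end_ms, granularity, off
  )
  starts_w <- window_start(sessions$start_ms, granularity, off)

  if (nrow(pieces) == 0) {
    windows <- tibble(
      window_start_ms = numeric(), window_label = character(),
      total_use_ms = numeric(), pickup_count = integer()
    )
  } else {
    use <- pieces |>
      group_by(window_start_ms = .data$window) |>
      summarise(total_use_ms = sum(.data$end - .data$start))
    width <- window_width_ms(granularity)
    grid <- seq(min(use$window_start_ms), max(use$window_start_ms), by = width)
    total <- use$total_use_ms[match(grid, use$window_start_ms)]
    total[is.na(total)] <- 0
    pickup <- vapply(
      grid, function(g) sum(starts_w == g), integer(1)
    )
    windows <- tibble(
      window_start_ms = grid,
      window_label = format_window(grid, granularity, off),
      total_use_ms = total,
      pickup_count = pickup
    )
  }

  per_app <- tibble(
    window_start_ms = numeric(), app_id = character(),
    duration_ms = numeric()
  )
  if (!is.null(intervals) && nrow(intervals) > 0) {
    ap <- split_at_boundaries(
      intervals$start_ms, intervals$end_ms,
      granularity, off, id = intervals$app_id
    )
    per_app <- ap |>
      group_by(window_start_ms = .data$window, app_id = .data$id) |>
      summarise(duration_ms = sum(.data$end - .data$start), .groups = "drop") |>
      arrange(.data$window_start_ms, dplyr::desc(.data$duration_ms))
  }

  structure(
    list(
      granularity = granularity, tz_offset_min = tz_offset_min,
      windows = windows, per_app = per_app
    ),
    class = "usage_summary"
  )
}

window_width_ms <- function(granularity) {
  switch(granularity,
    hour = MS_PER_HOUR,
    day = MS_PER_DAY,
    week = 7 * MS_PER_DAY
  )
}

# start (in UTC ms) of the local-time window containing each timestamp
window_start <- function(ts, granularity, offset_ms) {
  local <- ts + offset_ms
  w <- window_width_ms(granularity)
  if (granularity == "week") {
    day <- floor(local / MS_PER_DAY)
    monday <- day - ((day + EPOCH_MONDAY_SHIFT) %% 7)
    monday * MS_PER_DAY - offset_ms
  } else {
    floor(local / w) * w - offset_ms
  }
}

# split [start, end) intervals at window boundaries
split_at_boundaries <- function(start, end, granularity, offset_ms, id = NULL) {
  if (length(start) == 0) {
    return(tibble(
      window = numeric(), start = numeric(), end = numeric(),
      id = character()
    ))
  }
  w <- window_width_ms(granularity)
  if (is.null(id)) id <- rep(NA_character_, length(start))
  acc_s <- vector("list", length(start))
  acc_e <- vector("list", length(start))
  acc_id <- vector("list", length(start))
  for (i in seq_along(start)) {
    first <- window_start(start[i], granularity, offset_ms)
    inner <- if (first + w < end[i]) seq(first + w, end[i] - 1, by = w) else numeric(0)
    bounds <- c(start[i], inner, end[i])
    acc_s[[i]] <- bounds[-length(bounds)]
    acc_e[[i]] <- bounds[-1]
    acc_id[[i]] <- rep(id[i], length(bounds) - 1)
  }
  s <- unlist(acc_s)
  tibble(
    window = window_start(s, granularity, offset_ms),
    start = s, end = unlist(acc_e), id = unlist(acc_id)
  )
}

format_window <- function(ms, granularity, offset_ms) {
  t <- as.POSIXct((ms + offset_ms) / 1000, origin = "1970-01-01", tz = "UTC")
  fmt <- switch(granularity,
    hour = "%Y-%m-%d %H:00",
    day = "%Y-%m-%d",
    week = "%Y-%m-%d (wk)"
  )
  format(t, fmt)
}

#' Parameters for notification-trigger attribution
#'
#' @param tau_ms Maximum notification-to-pickup latency for a session to be
#'   attributed to a notification (default 30 000 ms). The distinction being
#'   drawn is between interactions directed by the individual and usage
#'   driven by a notification.
#' @return A `trigger_params` object.
#' @export
trigger_params <- function(tau_ms = 30000) {
  stopifnot(tau_ms > 0)
  structure(list(tau_ms = tau_ms), class = "trigger_params")
}

#' Label sessions as notification-driven or self-initiated
#'
#' A session is attributed to a notification when some `NOTIFICATION_POSTED`
#' falls in `(start - tau_ms, start]` *and* the session's first foreground
#' app is the notifying app (the most recent such notification wins);
#' otherwise it is self-initiated. If the stream contains no notification
#' events at all — e.g. notification tracking was disabled — every label is
#' `"unknown"`.
#'
#' @param sessions [sessionize()] output.
#' @param events The validated `event_stream` the sessions came from.
#' @param params A [trigger_params()].
#' @return `sessions` with `trigger` and `trigger_app` filled in.
#' @export
classify_triggers <- function(sessions, events, params = trigger_params()) {
  events <- ensure_validated(events)
  notifs <- events[events$type == "NOTIFICATION_POSTED", ]
  if (nrow(notifs) == 0) {
    sessions$trigger <- "unknown"
    sessions$trigger_app <- NA_character_
    return(sessions)
  }
  fg <- events[events$type == "APP_FOREGROUND", ]
  fg_ts <- fg$timestamp_ms
  nt_ts <- notifs$timestamp_ms
  n <- nrow(sessions)
  trigger <- rep("self", n)
  trigger_app <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    s <- sessions$start_ms[i]
    fi <- findInterval(s - 0.5, fg_ts) + 1
    if (fi > length(fg_ts) || fg_ts[fi] >= sessions$end_ms[i]) next
    first_app <- fg$app_id[fi]
    lo <- findInterval(s - params$tau_ms, nt_ts) + 1
    hi <- findInterval(s, nt_ts)
    if (lo > hi) next
    hit <- which(notifs$app_id[lo:hi] == first_app)
    if (length(hit) > 0) {
      trigger[i] <- "notification"
      trigger_app[i] <- first_app
    }
  }
  sessions$trigger <- trigger
  sessions$trigger_app <- trigger_app
  sessions
}
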