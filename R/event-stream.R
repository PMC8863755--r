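#' The closed vocabulary of loggable device events
#'
#' Every interaction a passive usage logger can record is one of these event
#' types. Screen and power events describe the device as a whole; the
#' app-scoped types (see [app_event_types()]) additionally carry the package
#' identifier of the app involved. `CONFIG_CHANGE` and `FLUSH_TO_DISK` are
#' operating-system housekeeping records that participants have no control
#' over but that retrospective extractions routinely contain.
#'
#' @return Character vector of the event-type names, in canonical order (used
#'   as the tie-break when sorting simultaneous events).
#' @export
#' @examples
#' event_types()
event_types <- function() {
  c(
    "SCREEN_ON", "SCREEN_OFF",
    "APP_FOREGROUND", "APP_BACKGROUND", "USER_INTERACTION",
    "APP_INSTALLED", "APP_UNINSTALLED",
    "NOTIFICATION_POSTED", "NOTIFICATION_REMOVED",
    "DEVICE_BOOT", "DEVICE_SHUTDOWN",
    "CONFIG_CHANGE", "FLUSH_TO_DISK"
  )
}

#' @rdname event_types
#' @details `app_event_types()` returns the subset of types that must carry an
#'   `app_id`; all other types must not.
#' @export
app_event_types <- function() {
  c(
    "APP_FOREGROUND", "APP_BACKGROUND", "APP_INSTALLED", "APP_UNINSTALLED",
    "NOTIFICATION_POSTED", "NOTIFICATION_REMOVED"
  )
}

event_sources <- function() c("continuous", "past")

#' Construct an event stream
#'
#' An event stream is a tibble with one row per logged device interaction and
#' columns `timestamp_ms` (UNIX epoch milliseconds, stored as doubles because
#' millisecond timestamps exceed 32-bit integer range), `type` (one of
#' [event_types()]), `app_id` (reverse-domain package name, `NA` for
#' device-level events), and `source` (`"continuous"` for prospectively logged
#' events, `"past"` for events recovered from the operating system's
#' retrospective usage database).
#'
#' @param timestamp_ms Numeric vector of UNIX millisecond timestamps.
#' @param type Character vector of event types.
#' @param app_id Character vector of package identifiers (`NA` where absent).
#' @param source `"continuous"` or `"past"`, recycled to length.
#' @return A tibble of class `event_stream` (not yet validated; see
#'   [validate_stream()]).
#' @seealso [validate_stream()], [filter_event_types()], [merge_sources()]
#' @export
#' @examples
#' event_stream(c(1e12, 1e12 + 5000), c("SCREEN_ON", "SCREEN_OFF"))
event_stream <- function(timestamp_ms = numeric(), type = character(),
                         app_id = NA_character_, source = "continuous") {
  n <- max(length(timestamp_ms), length(type))
  df <- tibble(
    timestamp_ms = as.numeric(timestamp_ms),
    type = as.character(type),
    app_id = rep_len(as.character(app_id), n),
    source = rep_len(as.character(source), n)
  )
  new_event_stream(df)
}

new_event_stream <- function(df, validated = FALSE, rejected = NULL) {
  stopifnot(is.data.frame(df))
  df <- as_tibble(df)
  class(df) <- unique(c("event_stream", class(df)))
  attr(df, "validated") <- isTRUE(validated)
  attr(df, "rejected") <- rejected %||% empty_rejects()
  df
}

empty_rejects <- function() {
  tibble(
    row = integer(), timestamp_ms = numeric(), type = character(),
    app_id = character(), reason = character()
  )
}

#' Coerce a data frame to an event stream
#'
#' Missing `app_id`/`source` columns are filled with `NA` and `"continuous"`.
#'
#' @param x A data frame with at least `timestamp_ms` and `type` columns, or
#'   an existing `event_stream`.
#' @return An (unvalidated) `event_stream`.
#' @export
as_event_stream <- function(x) {
  if (inherits(x, "event_stream")) {
    return(x)
  }
  if (!is.data.frame(x)) {
    abort("`x` must be a data frame with `timestamp_ms` and `type` columns.")
  }
  missing_cols <- setdiff(c("timestamp_ms", "type"), names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  x <- as_tibble(x)
  if (!"app_id" %in% names(x)) x$app_id <- NA_character_
  if (!"source" %in% names(x)) x$source <- "continuous"
  new_event_stream(x[, c("timestamp_ms", "type", "app_id", "source")])
}

#' Has a stream been through validation?
#'
#' @param x An `event_stream`.
#' @return `TRUE` if `x` is the output of [validate_stream()].
#' @export
is_validated <- function(x) isTRUE(attr(x, "validated"))

#' Rows rejected during validation or parsing
#'
#' @param x An `event_stream` (or other object carrying a rejection record).
#' @return A tibble with one row per rejected input row and a `reason` column.
#' @export
rejected_rows <- function(x) attr(x, "rejected") %||% empty_rejects()

#' Validate and canonically order an event stream
#'
#' Checks every row against the event-stream invariants, drops rows that
#' cannot be repaired, and returns the surviving events in canonical order:
#' sorted by timestamp, ties broken by source (`continuous` before `past`)
#' and then by event-type order, with the original order preserved among
#' remaining ties (stable sort).
#'
#' Row-level rules:
#' * the timestamp must be a finite positive integer number of milliseconds
#'   (rejected otherwise);
#' * the event type must be a member of [event_types()] (rejected otherwise);
#' * app-scoped types (see [app_event_types()]) must carry an `app_id`
#'   (rejected with reason `"missing app_id"` otherwise);
#' * device-level types must not carry an `app_id`; these rows are kept but
#'   the stray `app_id` is cleared, with a warning.
#'
#' Rejected rows are reported via a warning and retained, with reasons, in
#' the attribute returned by [rejected_rows()]. An empty input yields an
#' empty validated stream, not an error. The operation is idempotent.
#'
#' @param events An `event_stream` or coercible data frame.
#' @return A validated `event_stream` ([is_validated()] is `TRUE`).
#' @export
#' @examples
#' s <- event_stream(c(5, 3), c("SCREEN_OFF", "SCREEN_ON"))
#' validate_stream(s)$timestamp_ms
validate_stream <- function(events) {
  events <- as_event_stream(events)
  if (nrow(events) == 0) {
    return(new_event_stream(events, validated = TRUE))
  }

  ts <- suppressWarnings(as.numeric(events$timestamp_ms))
  type <- as.character(events$type)
  app <- as.character(events$app_id)
  src <- as.character(events$source)
  app[!is.na(app) & app == ""] <- NA_character_
  src[is.na(src) | !(src %in% event_sources())] <- "continuous"

  reason <- rep(NA_character_, length(ts))
  bad_ts <- !is.finite(ts) | ts != trunc(ts)
  reason[bad_ts] <- "non-integer timestamp"
  nonpos <- !bad_ts & ts <= 0
  reason[nonpos] <- "non-positive timestamp"
  unknown <- is.na(reason) & !(type %in% event_types())
  reason[unknown] <- "unknown event type"
  needs_app <- type %in% app_event_types()
  missing_app <- is.na(reason) & needs_app & is.na(app)
  reason[missing_app] <- "missing app_id"

  stray <- is.na(reason) & !needs_app & !is.na(app)
  if (any(stray)) {
    warn(sprintf(
      "%d device-level event(s) carried an app_id; cleared.", sum(stray)
    ))
    app[stray] <- NA_character_
  }

  bad <- !is.na(reason)
  rejected <- tibble(
    row = which(bad), timestamp_ms = events$timestamp_ms[bad],
    type = type[bad], app_id = app[bad], reason = reason[bad]
  )
  if (nrow(rejected) > 0) {
    warn(sprintf(
      "rejected %d malformed event row(s); see rejected_rows().",
      nrow(rejected)
    ))
  }

  keep <- !bad
  out <- tibble(
    timestamp_ms = ts[keep], type = type[keep],
    app_id = app[keep], source = src[keep]
  )
  ord <- order(out$timestamp_ms,
    match(out$source, event_sources()),
    match(out$type, event_types()),
    method = "radix"
  )
  new_event_stream(out[ord, ], validated = TRUE, rejected = rejected)
}

#' Keep only the event types a research question needs
#'
#' Event selection is the first processing decision: only the types relevant
#' to the analysis are retained, in their original order.
#'
#' @param events An `event_stream`.
#' @param keep Non-empty character vector of [event_types()] members.
#' @return The filtered stream; validation status is preserved.
#' @export
filter_event_types <- function(events, keep) {
  events <- as_event_stream(events)
  if (length(keep) == 0) {
    abort("`keep` must name at least one event type.")
  }
  bad <- setdiff(keep, event_types())
  if (length(bad) > 0) {
    abort(paste0("unknown event type(s): ", paste(bad, collapse = ", ")))
  }
  out <- events[events$type %in% keep, ]
  new_event_stream(out,
    validated = is_validated(events),
    rejected = rejected_rows(events)
  )
}

#' Merge continuous and retrospective views of the same device
#'
#' Continuous logging and the operating system's retrospective usage database
#' observe the same underlying behavior by different mechanisms, so a study
#' that collects both can use the retrospective ("past") view to fill gaps
#' where continuous logging was paused. All continuous events are kept. A past
#' event is considered a duplicate observation — and dropped — when a
#' continuous event of the same type and app lies within `window_ms` of it;
#' the two records come from the same device clock, so no drift allowance is
#' needed beyond scheduling jitter. Past events with no continuous
#' counterpart (before logging started, or inside a logging dropout) are
#' retained with their `past` provenance.
#'
#' If the merged stream contains two consecutive screen-on events from
#' different sources further apart than `window_ms` (contradictory screen
#' state), a warning is raised and both are kept.
#'
#' @param continuous,past Validated `event_stream`s.
#' @param window_ms Coincidence window for cross-source duplicates (default
#'   1000 ms).
#' @return A validated merged `event_stream`; row count never exceeds the sum
#'   of the two inputs.
#' @export
merge_sources <- function(continuous, past, window_ms = 1000) {
  continuous <- ensure_validated(continuous)
  past <- ensure_validated(past)
  if (nrow(continuous) > 0) continuous$source <- "continuous"
  if (nrow(past) > 0) past$source <- "past"

  drop <- rep(FALSE, nrow(past))
  if (nrow(past) > 0 && nrow(continuous) > 0) {
    key_c <- paste(continuous$type, continuous$app_id, sep = "\r")
    key_p <- paste(past$type, past$app_id, sep = "\r")
    for (k in unique(key_p)) {
      c_ts <- sort(continuous$timestamp_ms[key_c == k])
      if (length(c_ts) == 0) next
      idx <- which(key_p == k)
      p_ts <- past$timestamp_ms[idx]
      pos <- findInterval(p_ts, c_ts)
      lo <- pmax(pos, 1L)
      hi <- pmin(pos + 1L, length(c_ts))
      nearest <- pmin(abs(p_ts - c_ts[lo]), abs(p_ts - c_ts[hi]))
      drop[idx] <- nearest <= window_ms
    }
  }

  merged <- bind_rows(as_tibble(continuous), as_tibble(past)[!drop, ])
  out <- suppressWarnings(validate_stream(merged))

  scr <- out[out$type %in% c("SCREEN_ON", "SCREEN_OFF"), ]
  if (nrow(scr) >= 2) {
    i <- seq_len(nrow(scr) - 1)
    contradictory <- scr$type[i] == "SCREEN_ON" &
      scr$type[i + 1] == "SCREEN_ON" &
      scr$source[i] != scr$source[i + 1] &
      (scr$timestamp_ms[i + 1] - scr$timestamp_ms[i]) > window_ms
    if (any(contradictory)) {
      warn(sprintf(
        "%d contradictory cross-source screen-on pair(s) kept.",
        sum(contradictory)
      ))
    }
  }
  out
}

ensure_validated <- function(events) {
  events <- as_event_stream(events)
  if (is_validated(events)) events else validate_stream(events)
}
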