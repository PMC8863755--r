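#' Parameters for logging artifacts
#'
#' Real exports contain recording artifacts that a clean generative model does
#' not: retrospective extractions double-count events within a few
#' milliseconds; a device charging overnight with its screen set to stay on
#' shows a clock app foregrounded for many hours; devices restart; and
#' continuous logging pauses when the app is killed or permissions revoked.
#' [inject_artifacts()] adds these to a simulated stream without touching the
#' ground truth, and records exactly what it injected so cleaning rules can be
#' tested against a known answer.
#'
#' @param duplicate_prob Probability each event is double-logged.
#' @param duplicate_gap_ms Maximum gap between an event and its duplicate
#'   (must be <= 10 ms; duplicates land "within a few milliseconds").
#' @param clock_on_prob Per-night probability that the clock app stays
#'   foregrounded across the night window while charging.
#' @param restart_rate Device restarts per day.
#' @param dropout_windows List of `c(start_ms, end_ms)` intervals where
#'   continuous logging was paused (events inside are deleted).
#' @param clock_app Package id used for clock-on nights.
#' @param night_window `c(start_hour, end_hour)` of the charging night.
#' @return An `artifact_params` object.
#' @export
artifact_params <- function(duplicate_prob = 0.02, duplicate_gap_ms = 10,
                            clock_on_prob = 0.1, restart_rate = 0.05,
                            dropout_windows = list(),
                            clock_app = "com.google.android.deskclock",
                            night_window = c(1, 7)) {
  stopifnot(
    duplicate_prob >= 0, duplicate_prob <= 1,
    clock_on_prob >= 0, clock_on_prob <= 1,
    duplicate_gap_ms >= 1, duplicate_gap_ms <= 10,
    restart_rate >= 0, is.list(dropout_windows)
  )
  structure(
    list(
      duplicate_prob = duplicate_prob,
      duplicate_gap_ms = as.integer(duplicate_gap_ms),
      clock_on_prob = clock_on_prob,
      restart_rate = restart_rate,
      dropout_windows = dropout_windows,
      clock_app = clock_app,
      night_window = night_window
    ),
    class = "artifact_params"
  )
}

#' Inject recording artifacts into a simulated stream
#'
#' Applies, in order: device restarts (a `DEVICE_SHUTDOWN`/`DEVICE_BOOT` pair
#' placed in an inter-session gap), clock-on nights (a
#' `SCREEN_ON`/`APP_FOREGROUND(clock)`/`SCREEN_OFF` episode spanning the night
#' window, skipped if a real session would collide), logging dropouts (events
#' inside each window deleted), and double-logging (each surviving event
#' duplicated with probability `duplicate_prob` at a gap of at most
#' `duplicate_gap_ms`). Ground truth is deliberately left unchanged.
#'
#' The returned stream carries an `artifacts` attribute (see
#' [injected_artifacts()]) listing every duplicate, clock episode, restart,
#' and deleted event.
#'
#' @param events Validated `event_stream` from [simulate_usage_log()].
#' @param truth The matching ground truth (used to avoid colliding with real
#'   sessions); may be `NULL`, in which case restarts and clock nights are
#'   placed blindly.
#' @param params An [artifact_params()].
#' @param seed RNG seed.
#' @return A validated `event_stream` with artifacts, plus the `artifacts`
#'   attribute.
#' @export
inject_artifacts <- function(events, truth = NULL,
                             params = artifact_params(), seed = 1L) {
  events <- ensure_validated(events)
  if (!inherits(params, "artifact_params")) {
    abort("`params` must be an artifact_params object")
  }
  withr::with_seed(seed, inject_impl(events, truth, params))
}

inject_impl <- function(events, truth, p) {
  ev <- as_tibble(events)
  if (nrow(ev) == 0) {
    return(new_event_stream(ev, validated = TRUE))
  }
  t0 <- min(ev$timestamp_ms)
  t1 <- max(ev$timestamp_ms)
  sessions <- if (!is.null(truth)) truth$sessions else empty_sessions()

  # --- device restarts, placed in gaps between sessions -------------------
  restarts <- tibble(shutdown_ms = numeric(), boot_ms = numeric())
  n_days <- max((t1 - t0) / MS_PER_DAY, 1)
  n_restart <- rpois(1, p$restart_rate * n_days)
  if (n_restart > 0) {
    gap_start <- c(t0, sessions$end_ms) + 60 * MS_PER_SEC
    gap_end <- c(sessions$start_ms, t1) - 60 * MS_PER_SEC
    ok <- gap_end - gap_start > 5 * MS_PER_MIN
    gs <- gap_start[ok]
    ge <- gap_end[ok]
    if (length(gs) > 0) {
      pick <- sample.int(length(gs), min(n_restart, length(gs)))
      at <- round(gs[pick] + runif(length(pick)) * (ge[pick] - gs[pick] -
        30 * MS_PER_SEC))
      restarts <- tibble(shutdown_ms = at, boot_ms = at + 30 * MS_PER_SEC)
    }
  }

  # --- clock-on charging nights ------------------------------------------
  clock_eps <- tibble(app_id = character(), start_ms = numeric(), end_ms = numeric())
  if (p$clock_on_prob > 0) {
    day0 <- floor(t0 / MS_PER_DAY) * MS_PER_DAY
    nights <- seq(day0, t1, by = MS_PER_DAY)
    lit <- nights[runif(length(nights)) < p$clock_on_prob]
    for (d in lit) {
      s <- round(d + p$night_window[1] * MS_PER_HOUR +
        runif(1) * 30 * MS_PER_MIN)
      e <- round(d + p$night_window[2] * MS_PER_HOUR -
        runif(1) * 10 * MS_PER_MIN)
      if (e - s < MS_PER_HOUR || s < t0 || e > t1) next
      busy <- nrow(sessions) > 0 &&
        any(sessions$start_ms < e + 2000 & sessions$end_ms > s - 2000)
      busy <- busy || (nrow(restarts) > 0 &&
        any(restarts$shutdown_ms < e + 2000 & restarts$boot_ms > s - 2000))
      if (busy) next
      clock_eps <- bind_rows(clock_eps, tibble(
        app_id = p$clock_app, start_ms = s, end_ms = e
      ))
    }
  }

  extra <- bind_rows(
    tibble(
      timestamp_ms = restarts$shutdown_ms, type = "DEVICE_SHUTDOWN",
      app_id = NA_character_
    ),
    tibble(
      timestamp_ms = restarts$boot_ms, type = "DEVICE_BOOT",
      app_id = NA_character_
    ),
    tibble(
      timestamp_ms = clock_eps$start_ms, type = "SCREEN_ON",
      app_id = NA_character_
    ),
    tibble(
      timestamp_ms = clock_eps$start_ms, type = "APP_FOREGROUND",
      app_id = clock_eps$app_id
    ),
    tibble(
      timestamp_ms = clock_eps$end_ms, type = "SCREEN_OFF",
      app_id = NA_character_
    )
  )
  if (nrow(extra) > 0) {
    extra$source <- "continuous"
    ev <- bind_rows(ev, extra)
  }

  # --- dropouts: continuous logging paused -------------------------------
  dropped <- ev[0, ]
  if (length(p$dropout_windows) > 0) {
    inside <- rep(FALSE, nrow(ev))
    for (w in p$dropout_windows) {
      inside <- inside | (ev$timestamp_ms >= w[1] & ev$timestamp_ms < w[2] &
        ev$source == "continuous")
    }
    dropped <- ev[inside, ]
    ev <- ev[!inside, ]
  }

  # --- double-logging ----------------------------------------------------
  dup_flag <- runif(nrow(ev)) < p$duplicate_prob
  duplicates <- ev[dup_flag, ]
  if (nrow(duplicates) > 0) {
    gaps <- sample.int(p$duplicate_gap_ms, nrow(duplicates), replace = TRUE)
    dup_record <- tibble(
      timestamp_ms = duplicates$timestamp_ms,
      type = duplicates$type, app_id = duplicates$app_id,
      dup_ms = duplicates$timestamp_ms + gaps
    )
    duplicates$timestamp_ms <- dup_record$dup_ms
    ev <- bind_rows(ev, duplicates)
  } else {
    dup_record <- tibble(
      timestamp_ms = numeric(), type = character(),
      app_id = character(), dup_ms = numeric()
    )
  }

  out <- suppressWarnings(validate_stream(ev))
  attr(out, "artifacts") <- list(
    duplicates = dup_record,
    clock_episodes = clock_eps,
    restarts = restarts,
    dropped = as_tibble(dropped),
    dropout_windows = p$dropout_windows
  )
  out
}

#' What did inject_artifacts add?
#'
#' @param events A stream returned by [inject_artifacts()].
#' @return A list with tibbles `duplicates`, `clock_episodes`, `restarts`,
#'   `dropped`, and the `dropout_windows` used.
#' @export
injected_artifacts <- function(events) attr(events, "artifacts")

#' Event types present in a retrospective (past-usage) extraction
#'
#' The operating system's own usage database records screen and app
#' transitions, power events, and system housekeeping — but not notifications.
#'
#' @return Character vector of event types.
#' @export
past_view_types <- function() {
  c(
    "SCREEN_ON", "SCREEN_OFF", "APP_FOREGROUND", "APP_BACKGROUND",
    "DEVICE_BOOT", "DEVICE_SHUTDOWN", "CONFIG_CHANGE", "FLUSH_TO_DISK"
  )
}

#' Derive the retrospective view of a simulated stream
#'
#' The operating system retains a limited trailing history of usage events —
#' typically several days, varying between devices — which a logger can query
#' at export time without having observed the period prospectively. This
#' derives that view from a full stream: only the trailing `retention_days`
#' survive, only the types the OS database stores (see [past_view_types()])
#' are kept, and the result is relabeled `source = "past"`. Idempotent.
#'
#' @param events A validated `event_stream`.
#' @param retention_days Trailing window length in days (default 5, the span
#'   generally considered representative of typical use).
#' @param keep_types Event types the retrospective database records.
#' @return A validated `event_stream` with `source == "past"`.
#' @export
derive_past_view <- function(events, retention_days = 5,
                             keep_types = past_view_types()) {
  if (!is.numeric(retention_days) || retention_days <= 0) {
    abort("`retention_days` must be a positive number")
  }
  events <- ensure_validated(events)
  if (nrow(events) == 0) {
    return(events)
  }
  cutoff <- max(events$timestamp_ms) - retention_days * MS_PER_DAY
  out <- events[events$timestamp_ms >= cutoff & events$type %in% keep_types, ]
  out$source <- "past"
  new_event_stream(out, validated = TRUE)
}
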