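PROTOCOL_PROBE_APP <- "com.example.probe"
PROTOCOL_INSTALL_APP <- "com.example.installee"

#' Define a prompted-action validation protocol
#'
#' Timestamp accuracy of a passive logger is validated by running a companion
#' oracle app that performs (or prompts the user to perform) a fixed sequence
#' of actions at known times and records when each occurred. The default
#' protocol mirrors standard practice: 20 screen on/offs (alternating, so 10
#' of each), two identical app installations and two uninstalls, 10
#' notifications pushed and removed, and a new app opened 20 times.
#'
#' The logger's record of each action differs from the prompted time by
#' scheduling jitter. The jitter model is per event type, Gaussian with a
#' `bias_ms` and `sd_ms`, and deliberately sign-unrestricted: because the
#' kernel queues the log record and the action itself independently, an event
#' can be recorded *before* it visibly occurs.
#'
#' @param n_screen_toggles Total screen on/off actions (alternating; default
#'   20).
#' @param n_installs,n_uninstalls App (un)installations (default 2 each).
#' @param n_notifications Notifications pushed and subsequently removed
#'   (default 10; contributes one `NOTIFICATION_POSTED` and one
#'   `NOTIFICATION_REMOVED` action each).
#' @param n_app_opens Times the probe app is opened (default 20).
#' @param gap_s Mean inter-action gap, seconds (default 5).
#' @param gap_jitter_s Half-width of the uniform jitter on the gap.
#' @param jitter Per-type jitter model, a tibble with columns `type`,
#'   `bias_ms`, `sd_ms`; types not listed fall back to `default_bias_ms` /
#'   `default_sd_ms`.
#' @param default_bias_ms,default_sd_ms Fallback jitter (0 and 500 ms).
#' @param start_ms Protocol start time, UNIX ms.
#' @return A `validation_protocol` object.
#' @seealso [simulate_validation_protocol()], [align_events()],
#'   [verify_counts()]
#' @export
validation_protocol <- function(n_screen_toggles = 20, n_installs = 2,
                                n_uninstalls = 2, n_notifications = 10,
                                n_app_opens = 20, gap_s = 5,
                                gap_jitter_s = 2, jitter = NULL,
                                default_bias_ms = 0, default_sd_ms = 500,
                                start_ms = 1704067200000) {
  counts <- c(n_screen_toggles, n_installs, n_uninstalls, n_notifications, n_app_opens)
  if (any(counts < 0)) abort("protocol counts must be >= 0")
  stopifnot(gap_s > 0, gap_jitter_s >= 0, gap_jitter_s < gap_s, default_sd_ms >= 0)
  if (!is.null(jitter)) {
    stopifnot(
      is.data.frame(jitter),
      all(c("type", "bias_ms", "sd_ms") %in% names(jitter))
    )
  }
  structure(
    list(
      n_screen_toggles = as.integer(n_screen_toggles),
      n_installs = as.integer(n_installs),
      n_uninstalls = as.integer(n_uninstalls),
      n_notifications = as.integer(n_notifications),
      n_app_opens = as.integer(n_app_opens),
      gap_s = gap_s, gap_jitter_s = gap_jitter_s,
      jitter = jitter,
      default_bias_ms = default_bias_ms, default_sd_ms = default_sd_ms,
      start_ms = as.numeric(start_ms)
    ),
    class = "validation_protocol"
  )
}

# the ordered action list of a protocol, without times
protocol_action_table <- function(protocol) {
  p <- protocol
  on_off <- rep(c("SCREEN_ON", "SCREEN_OFF"), length.out = p$n_screen_toggles)
  notif <- rep(
    c("NOTIFICATION_POSTED", "NOTIFICATION_REMOVED"),
    p$n_notifications
  )
  type <- c(
    on_off,
    rep("APP_INSTALLED", p$n_installs),
    rep("APP_UNINSTALLED", p$n_uninstalls),
    notif,
    rep("APP_FOREGROUND", p$n_app_opens)
  )
  app <- ifelse(
    type %in% c("APP_INSTALLED", "APP_UNINSTALLED"), PROTOCOL_INSTALL_APP,
    ifelse(type %in% app_event_types(), PROTOCOL_PROBE_APP, NA_character_)
  )
  tibble(action = seq_along(type), type = type, app_id = app)
}

#' Expected event counts of a protocol
#'
#' @param protocol A [validation_protocol()].
#' @return Tibble with columns `type` and `expected`.
#' @export
protocol_expected_counts <- function(protocol) {
  acts <- protocol_action_table(protocol)
  out <- as_tibble(as.data.frame(table(type = acts$type),
    stringsAsFactors = FALSE
  ))
  names(out) <- c("type", "expected")
  out$expected <- as.integer(out$expected)
  out
}

#' Replay a validation protocol through a simulated logger
#'
#' Emits the protocol's actions in order, separated by the protocol's
#' inter-action gaps, and produces the logger's view of them: one recorded
#' event per prompted action, displaced by a per-type Gaussian jitter draw
#' (which may be negative — the logger can time-stamp an event before the
#' action visibly happens). Prompt/record correspondence is recoverable by
#' order within each event type.
#'
#' @param protocol A [validation_protocol()].
#' @param seed RNG seed.
#' @return A list with `prompted` (tibble `action`, `type`, `app_id`,
#'   `prompted_ms`) and `recorded` (validated `event_stream`).
#' @export
#' @examples
#' rep <- simulate_validation_protocol(validation_protocol(), seed = 1)
#' table(rep$recorded$type)
simulate_validation_protocol <- function(protocol = validation_protocol(),
                                         seed = 1L) {
  if (!inherits(protocol, "validation_protocol")) {
    abort("`protocol` must be a validation_protocol object")
  }
  acts <- protocol_action_table(protocol)
  n <- nrow(acts)
  if (n == 0) {
    return(list(
      prompted = cbind(acts, tibble(prompted_ms = numeric())),
      recorded = validate_stream(event_stream())
    ))
  }
  withr::with_seed(seed, {
    gaps <- runif(
      n, (protocol$gap_s - protocol$gap_jitter_s) * MS_PER_SEC,
      (protocol$gap_s + protocol$gap_jitter_s) * MS_PER_SEC
    )
    prompted_ms <- round(protocol$start_ms + cumsum(gaps))
    bias <- jitter_lookup(protocol, acts$type, "bias_ms")
    sdv <- jitter_lookup(protocol, acts$type, "sd_ms")
    recorded_ms <- round(prompted_ms + rnorm(n, bias, sdv))
  })
  prompted <- acts
  prompted$prompted_ms <- prompted_ms
  recorded <- validate_stream(event_stream(
    recorded_ms, acts$type,
    app_id = acts$app_id, source = "continuous"
  ))
  list(prompted = prompted, recorded = recorded)
}

jitter_lookup <- function(protocol, types, col) {
  default <- if (col == "bias_ms") {
    protocol$default_bias_ms
  } else {
    protocol$default_sd_ms
  }
  out <- rep(default, length(types))
  if (!is.null(protocol$jitter)) {
    i <- match(types, protocol$jitter$type)
    hit <- !is.na(i)
    out[hit] <- protocol$jitter[[col]][i[hit]]
  }
  out
}
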