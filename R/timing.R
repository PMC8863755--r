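DISCREPANCY_ROW_ORDER <- c(
  "SCREEN_OFF", "SCREEN_ON", "APP_FOREGROUND",
  "NOTIFICATION_POSTED", "NOTIFICATION_REMOVED",
  "APP_INSTALLED", "APP_UNINSTALLED"
)

DISCREPANCY_LABELS <- c(
  SCREEN_OFF = "Screen off", SCREEN_ON = "Screen on",
  APP_FOREGROUND = "App opened",
  NOTIFICATION_POSTED = "Notification generated",
  NOTIFICATION_REMOVED = "Notification removed",
  APP_INSTALLED = "App installed", APP_UNINSTALLED = "App uninstalled"
)

#' Align prompted actions with recorded events
#'
#' Matches the oracle's prompted actions to the logger's recorded events.
#' Because a correctly functioning logger detects all actions in the order
#' they occur, alignment is order-based within each event type: the k-th
#' prompted action of a type pairs with the k-th recorded event of that type.
#' Prompted actions beyond the recorded count are reported as misses; surplus
#' recorded events (more recorded than prompted) are reported and a warning
#' raised, with alignment still order-based. The difference is signed as
#' recorded minus prompted, so a negative discrepancy means the logger
#' time-stamped the event before the oracle says it happened.
#'
#' @param prompted Tibble of prompted actions (`type`, `prompted_ms`), as in
#'   [simulate_validation_protocol()]'s `prompted`.
#' @param recorded The logger's `event_stream`.
#' @param method `"order"` (default) or `"nearest"`; nearest-neighbor
#'   matching is offered for streams with missed detections, pairing each
#'   prompted action greedily with the closest unused recorded event of its
#'   type.
#' @return A list with `pairs` (tibble `event_type`, `prompted_ms`,
#'   `recorded_ms`, `diff_ms`), `misses`, and `surplus`.
#' @export
align_events <- function(prompted, recorded, method = c("order", "nearest")) {
  method <- match.arg(method)
  recorded <- ensure_validated(recorded)
  stopifnot(all(c("type", "prompted_ms") %in% names(prompted)))

  pairs <- list()
  misses <- list()
  surplus <- list()
  for (ty in unique(prompted$type)) {
    p_ts <- prompted$prompted_ms[prompted$type == ty]
    r_ts <- recorded$timestamp_ms[recorded$type == ty]
    if (method == "order") {
      k <- min(length(p_ts), length(r_ts))
      if (k > 0) {
        pairs[[ty]] <- tibble(
          event_type = ty, prompted_ms = p_ts[seq_len(k)],
          recorded_ms = r_ts[seq_len(k)]
        )
      }
      if (length(p_ts) > k) {
        misses[[ty]] <- tibble(event_type = ty, prompted_ms = p_ts[-seq_len(k)])
      }
      if (length(r_ts) > k) {
        surplus[[ty]] <- tibble(event_type = ty, recorded_ms = r_ts[-seq_len(k)])
      }
    } else {
      # globally greedy: closest prompted/recorded pairs claim each other first
      cand <- expand.grid(j = seq_along(p_ts), r = seq_along(r_ts))
      cand <- cand[order(abs(r_ts[cand$r] - p_ts[cand$j])), ]
      used <- logical(length(r_ts))
      rec <- rep(NA_real_, length(p_ts))
      for (row in seq_len(nrow(cand))) {
        j <- cand$j[row]
        r <- cand$r[row]
        if (used[r] || !is.na(rec[j])) next
        used[r] <- TRUE
        rec[j] <- r_ts[r]
      }
      hit <- !is.na(rec)
      if (any(hit)) {
        pairs[[ty]] <- tibble(
          event_type = ty, prompted_ms = p_ts[hit], recorded_ms = rec[hit]
        )
      }
      if (any(!hit)) {
        misses[[ty]] <- tibble(event_type = ty, prompted_ms = p_ts[!hit])
      }
      if (any(!used)) {
        surplus[[ty]] <- tibble(event_type = ty, recorded_ms = r_ts[!used])
      }
    }
  }
  pairs <- bind_rows(c(
    list(tibble(
      event_type = character(),
      prompted_ms = numeric(), recorded_ms = numeric()
    )),
    unname(pairs)
  ))
  pairs$diff_ms <- pairs$recorded_ms - pairs$prompted_ms
  misses <- bind_rows(c(
    list(tibble(event_type = character(), prompted_ms = numeric())),
    unname(misses)
  ))
  surplus <- bind_rows(c(
    list(tibble(event_type = character(), recorded_ms = numeric())),
    unname(surplus)
  ))
  if (nrow(surplus) > 0) {
    warn(sprintf(
      "%d recorded event(s) beyond the prompted counts", nrow(surplus)
    ))
  }
  list(pairs = pairs, misses = misses, surplus = surplus)
}

#' Per-event-type discrepancy statistics
#'
#' Summarizes logger-minus-oracle timestamp differences per event type: the
#' number of matched pairs, the mean difference, and the sample standard
#' deviation (n - 1 denominator; `NA` when a type has a single pair). Rows
#' are ordered the way timing-validation tables are conventionally laid out
#' (screen off/on, app opened, notifications, installs), with a
#' human-readable `event` label.
#'
#' @param pairs The `pairs` tibble from [align_events()] (or the list it
#'   returns).
#' @return A `discrepancy_report` tibble: `event_type`, `event`, `n`,
#'   `mean_ms`, `sd_ms`.
#' @export
#' @examples
#' p <- tibble::tibble(
#'   event_type = "SCREEN_ON",
#'   prompted_ms = c(0, 0), recorded_ms = c(10, -10), diff_ms = c(10, -10)
#' )
#' discrepancy_stats(p)
discrepancy_stats <- function(pairs) {
  if (is.list(pairs) && !is.data.frame(pairs) && !is.null(pairs$pairs)) {
    pairs <- pairs$pairs
  }
  stopifnot(all(c("event_type", "diff_ms") %in% names(pairs)))
  if (nrow(pairs) == 0) {
    abort("no matched pairs to summarize")
  }
  out <- pairs |>
    group_by(event_type = .data$event_type) |>
    summarise(
      n = dplyr::n(),
      mean_ms = mean(.data$diff_ms),
      sd_ms = if (dplyr::n() > 1) sd(.data$diff_ms) else NA_real_
    )
  ord <- match(out$event_type, DISCREPANCY_ROW_ORDER)
  ord[is.na(ord)] <- length(DISCREPANCY_ROW_ORDER) + seq_len(sum(is.na(ord)))
  out <- out[order(ord), ]
  out$event <- unname(DISCREPANCY_LABELS[out$event_type])
  out$event[is.na(out$event)] <- out$event_type[is.na(out$event)]
  out <- out[, c("event_type", "event", "n", "mean_ms", "sd_ms")]
  class(out) <- c("discrepancy_report", class(out))
  out
}

#' Check recorded counts against a protocol's expectations
#'
#' @param recorded The logger's `event_stream` from a protocol run.
#' @param protocol The [validation_protocol()] that was executed.
#' @return A tibble `type`, `expected`, `observed`, `pass`.
#' @export
verify_counts <- function(recorded, protocol) {
  recorded <- ensure_validated(recorded)
  exp <- protocol_expected_counts(protocol)
  obs <- vapply(
    exp$type, function(ty) sum(recorded$type == ty), integer(1)
  )
  tibble(
    type = exp$type, expected = exp$expected, observed = unname(obs),
    pass = exp$expected == unname(obs)
  )
}
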