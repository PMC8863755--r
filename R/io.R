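#' Write an event stream as the canonical CSV schema
#'
#' The plain-text interchange schema is a three-column CSV with header
#' `timestamp,event,app`: the UNIX millisecond timestamp as an integer, the
#' event-type name, and the package id (empty when absent). Fields containing
#' commas or quotes are quoted per RFC 4180. The `source` label is not part
#' of the file; [read_log_csv()] reattaches one.
#'
#' @param events A validated `event_stream`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_log_csv <- function(events, path) {
  events <- ensure_validated(events)
  df <- tibble(
    timestamp = sprintf("%.0f", events$timestamp_ms),
    event = events$type,
    app = events$app_id
  )
  readr::write_csv(df, path, na = "")
  invisible(path)
}

#' Read the canonical CSV schema back into an event stream
#'
#' Rows with unknown event labels or malformed timestamps are rejected
#' individually (with reasons, via [rejected_rows()]) rather than failing the
#' whole file; a file whose header is not `timestamp,event,app` is a format
#' error.
#'
#' @param path CSV file path.
#' @param source Source label to attach (`"continuous"` or `"past"`).
#' @return A validated `event_stream`.
#' @export
read_log_csv <- function(path, source = "continuous") {
  df <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE
  )
  log_table_to_stream(df, source)
}

log_table_to_stream <- function(df, source = "continuous") {
  if (!identical(names(df)[seq_len(min(3, ncol(df)))], c("timestamp", "event", "app"))) {
    abort("not an event-log CSV: expected header 'timestamp,event,app'")
  }
  app <- as.character(df$app)
  app[!is.na(app) & app == ""] <- NA_character_
  stream <- tibble(
    timestamp_ms = suppressWarnings(as.numeric(df$timestamp)),
    type = as.character(df$event),
    app_id = app,
    source = source
  )
  validate_stream(stream)
}

stream_to_log_table <- function(events) {
  tibble(
    timestamp = sprintf("%.0f", events$timestamp_ms),
    event = events$type,
    app = events$app_id
  )
}
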