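# shorthand: a validated stream from vectors
vs <- function(ts, type, app = NA_character_, source = "continuous") {
  validate_stream(event_stream(ts, type, app_id = app, source = source))
}

# sorted multiset signature of a stream's content (ignores validation attrs)
stream_key <- function(s, with_source = TRUE) {
  d <- as.data.frame(s)
  cols <- c("timestamp_ms", "type", "app_id", if (with_source) "source")
  sort(do.call(paste, c(d[cols], sep = "\r")))
}

expect_same_events <- function(a, b, with_source = TRUE) {
  expect_identical(stream_key(a, with_source), stream_key(b, with_source))
}

# a randomized study configuration (uses the ambient RNG)
random_config <- function() {
  srcs <- sample(c("contextual", "continuous", "past"), sample(1:3, 1))
  phases <- lapply(srcs, function(s) {
    switch(s,
      contextual = phase_contextual(),
      continuous = phase_continuous(
        track_screen = runif(1) < 0.5,
        track_apps = runif(1) < 0.5,
        track_installs = runif(1) < 0.5,
        track_notifications = runif(1) < 0.5
      ),
      past = phase_past(retention_days = sample(1:14, 1))
    )
  })
  study_config(phases)
}

# a small random (but valid) event table for round-trip tests
random_small_stream <- function(n = 20) {
  types <- sample(event_types(), n, replace = TRUE)
  app <- ifelse(
    types %in% app_event_types(),
    sample(c("com.a.one", "com.b,two", "com.c.three"), n, replace = TRUE),
    NA_character_
  )
  vs(sort(sample(1e12 + 1:1e6, n)), types, app)
}
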