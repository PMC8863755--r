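test_that("validate_stream sorts by timestamp and is idempotent", {
  s <- event_stream(c(5, 3), c("SCREEN_OFF", "SCREEN_ON"))
  v <- validate_stream(s)
  expect_equal(v$timestamp_ms, c(3, 5))
  expect_true(is_validated(v))

  sorted <- vs(c(1, 2, 3), c("SCREEN_ON", "SCREEN_OFF", "SCREEN_ON"))
  again <- validate_stream(sorted)
  expect_identical(as.data.frame(again), as.data.frame(sorted))

  # ties: continuous before past, then event-type order
  tied <- event_stream(
    c(10, 10, 10),
    c("APP_FOREGROUND", "SCREEN_ON", "SCREEN_ON"),
    app_id = c("com.a", NA, NA),
    source = c("continuous", "past", "continuous")
  )
  v2 <- validate_stream(tied)
  expect_equal(v2$type, c("SCREEN_ON", "APP_FOREGROUND", "SCREEN_ON"))
  expect_equal(v2$source, c("continuous", "continuous", "past"))
})

test_that("validate_stream rejects malformed rows with reasons", {
  df <- tibble::tibble(
    timestamp_ms = c(100, -5, 7.5, 200, 300, 400),
    type = c(
      "SCREEN_ON", "SCREEN_ON", "SCREEN_OFF", "WIBBLE",
      "APP_FOREGROUND", "APP_FOREGROUND"
    ),
    app_id = c(NA, NA, NA, NA, NA, "com.a")
  )
  expect_warning(v <- validate_stream(df), "rejected 4")
  expect_equal(nrow(v), 2)
  rej <- rejected_rows(v)
  expect_setequal(
    rej$reason,
    c(
      "non-positive timestamp", "non-integer timestamp",
      "unknown event type", "missing app_id"
    )
  )

  # stray app_id on a device-level event is cleared, not rejected
  expect_warning(
    v2 <- validate_stream(event_stream(1, "SCREEN_ON", app_id = "com.a")),
    "cleared"
  )
  expect_true(is.na(v2$app_id))

  # empty input is an empty validated stream, not an error
  e <- validate_stream(event_stream())
  expect_equal(nrow(e), 0)
  expect_true(is_validated(e))
})

test_that("filter_event_types keeps order and obeys set semantics", {
  s <- vs(
    1:5, c(
      "SCREEN_ON", "FLUSH_TO_DISK", "SCREEN_ON",
      "FLUSH_TO_DISK", "SCREEN_ON"
    )
  )
  expect_equal(nrow(filter_event_types(s, "SCREEN_ON")), 3)
  expect_identical(
    as.data.frame(filter_event_types(s, event_types())),
    as.data.frame(s)
  )
  expect_equal(nrow(filter_event_types(s, "DEVICE_BOOT")), 0)
  expect_error(filter_event_types(s, character()), "at least one")
  expect_error(filter_event_types(s, "NOT_A_TYPE"), "unknown")
})

test_that("filtering commutes with validation", {
  raw <- event_stream(
    c(9, 2, 5, 5), c("SCREEN_ON", "FLUSH_TO_DISK", "SCREEN_OFF", "SCREEN_ON")
  )
  keep <- c("SCREEN_ON", "SCREEN_OFF")
  a <- validate_stream(filter_event_types(raw, keep))
  b <- filter_event_types(validate_stream(raw), keep)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("merge_sources drops coincident past duplicates and fills gaps", {
  cont <- vs(1000, "SCREEN_ON")
  past <- vs(1000, "SCREEN_ON", source = "past")
  m <- merge_sources(cont, past)
  expect_equal(nrow(m), 1)
  expect_equal(m$source, "continuous")

  # a past-only day before continuous logging starts is fully retained
  day <- 86400000
  past2 <- vs(c(1, 2, 3) * 1000, c("SCREEN_ON", "SCREEN_OFF", "SCREEN_ON"),
    source = "past"
  )
  cont2 <- vs(day + c(1, 2) * 1000, c("SCREEN_OFF", "SCREEN_ON"))
  m2 <- suppressWarnings(merge_sources(cont2, past2))
  expect_equal(sum(m2$source == "past"), 3)
  expect_lte(nrow(m2), nrow(cont2) + nrow(past2))
})

test_that("merging simulator-derived views recovers the truth multiset", {
  sim <- simulate_usage_log(behavior_params(n_days = 7), seed = 21)
  full <- sim$events
  t1 <- max(full$timestamp_ms)
  cont <- validate_stream(full[full$timestamp_ms >= t1 - 3 * 86400000, ])
  past <- derive_past_view(full, retention_days = 5)
  merged <- suppressWarnings(merge_sources(cont, past))

  expected <- as.data.frame(past)
  expected <- expected[expected$timestamp_ms < min(cont$timestamp_ms), ]
  expected <- validate_stream(rbind(as.data.frame(cont), expected))
  expect_same_events(merged, expected)
})

test_that("config payloads round-trip exactly over randomized configs", {
  withr::with_seed(404, {
    for (i in 1:100) {
      cfg <- random_config()
      expect_identical(decode_config(encode_config(cfg)), cfg)
    }
  })
})

test_that("config codec preserves phase order and reports schema errors", {
  cfg <- study_config(phase_past(3), phase_continuous(), phase_contextual())
  back <- decode_config(encode_config(cfg))
  expect_equal(
    vapply(back$phases, function(p) p$source, character(1)),
    c("past", "continuous", "contextual")
  )

  expect_error(decode_config("phonelog-config/1\nfoo=1\n"), "phases")
  expect_error(decode_config("not a payload"), "payload")
  expect_error(
    decode_config("phonelog-config/1\nphases=2\nphase.1.source=past\n"),
    "phase.2.source"
  )

  # unknown keys are ignored with a warning (forward compatibility)
  payload <- paste0(encode_config(study_config(phase_contextual())), "zzz=1\n")
  expect_warning(got <- decode_config(payload), "zzz")
  expect_identical(got, study_config(phase_contextual()))
})

test_that("duplicate sources require the explicit flag", {
  expect_error(study_config(phase_past(1), phase_past(2)), "duplicate")
  cfg <- study_config(phase_past(1), phase_past(2),
    allow_duplicate_sources = TRUE
  )
  expect_identical(decode_config(encode_config(cfg)), cfg)
})
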