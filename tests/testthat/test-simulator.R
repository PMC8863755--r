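test_that("zero pickup and notification rates leave only the boot event", {
  p <- behavior_params(
    n_days = 3, daily_pickup_rate = 0,
    notification_rate = 0
  )
  sim <- simulate_usage_log(p, seed = 1)
  expect_equal(nrow(sim$events), 1)
  expect_equal(sim$events$type, "DEVICE_BOOT")
  expect_equal(sim$events$timestamp_ms, p$start_ms)
  expect_equal(nrow(sim$truth$sessions), 0)
})

test_that("simulation is reproducible for a seed and sensitive to it", {
  p <- behavior_params(n_days = 3)
  a <- simulate_usage_log(p, seed = 5)
  b <- simulate_usage_log(p, seed = 5)
  c <- simulate_usage_log(p, seed = 6)
  expect_identical(as.data.frame(a$events), as.data.frame(b$events))
  expect_identical(a$truth, b$truth)
  expect_false(identical(as.data.frame(a$events), as.data.frame(c$events)))
})

test_that("ground truth is internally consistent and mirrored by events", {
  sim <- simulate_usage_log(behavior_params(n_days = 5), seed = 9)
  tr <- sim$truth
  # sessions are ordered and non-overlapping
  expect_true(all(diff(tr$sessions$start_ms) > 0))
  expect_true(all(tr$sessions$end_ms[-nrow(tr$sessions)] <=
    tr$sessions$start_ms[-1]))
  # app intervals tile each session exactly
  by_session <- split(tr$app_intervals, tr$app_intervals$session_id)
  for (s in seq_len(nrow(tr$sessions))) {
    iv <- by_session[[as.character(s)]]
    expect_equal(iv$start_ms[1], tr$sessions$start_ms[s])
    expect_equal(iv$end_ms[nrow(iv)], tr$sessions$end_ms[s])
    if (nrow(iv) > 1) expect_equal(iv$start_ms[-1], iv$end_ms[-nrow(iv)])
    expect_equal(
      sum(iv$end_ms - iv$start_ms),
      tr$sessions$end_ms[s] - tr$sessions$start_ms[s]
    )
  }
  # every session appears as a SCREEN_ON/SCREEN_OFF pair at exactly its bounds
  on_ts <- sim$events$timestamp_ms[sim$events$type == "SCREEN_ON"]
  off_ts <- sim$events$timestamp_ms[sim$events$type == "SCREEN_OFF"]
  expect_equal(on_ts, tr$sessions$start_ms)
  expect_equal(off_ts, tr$sessions$end_ms)
})

test_that("default calibration recovers the pickup rate", {
  p <- behavior_params(n_days = 30)
  sim <- simulate_usage_log(p, seed = 17)
  daily <- nrow(sim$truth$sessions) / p$n_days
  se <- sqrt(p$daily_pickup_rate / p$n_days)
  expect_lt(abs(daily - p$daily_pickup_rate), 3 * se)
  # no pickups inside the sleep window
  hrs <- ((sim$truth$sessions$start_ms - p$start_ms) %% 86400000) / 3600000
  expect_false(any(hrs >= p$sleep_window[1] & hrs < p$sleep_window[2]))
})

test_that("notification-triggered sessions have a preceding posted event", {
  sim <- simulate_usage_log(behavior_params(n_days = 5), seed = 4)
  tr <- sim$truth$sessions
  trig <- tr[tr$trigger == "notification", ]
  expect_gt(nrow(trig), 0)
  posted <- sim$events[sim$events$type == "NOTIFICATION_POSTED", ]
  for (i in seq_len(nrow(trig))) {
    hit <- posted$app_id == trig$trigger_app[i] &
      posted$timestamp_ms < trig$start_ms[i] &
      posted$timestamp_ms > trig$start_ms[i] - 121000
    expect_true(any(hit))
  }
})

test_that("artifact injection at zero rates is the identity", {
  sim <- simulate_usage_log(behavior_params(n_days = 3), seed = 2)
  p0 <- artifact_params(
    duplicate_prob = 0, clock_on_prob = 0,
    restart_rate = 0
  )
  out <- inject_artifacts(sim$events, sim$truth, p0, seed = 1)
  cols <- c("timestamp_ms", "type", "app_id", "source")
  expect_identical(
    as.data.frame(out)[cols],
    as.data.frame(sim$events)[cols]
  )
})

test_that("duplicate_prob = 1 doubles the stream within the gap bound", {
  sim <- simulate_usage_log(behavior_params(n_days = 2), seed = 3)
  p1 <- artifact_params(
    duplicate_prob = 1, clock_on_prob = 0,
    restart_rate = 0
  )
  out <- inject_artifacts(sim$events, sim$truth, p1, seed = 1)
  expect_equal(nrow(out), 2 * nrow(sim$events))
  dup <- injected_artifacts(out)$duplicates
  expect_equal(nrow(dup), nrow(sim$events))
  gaps <- dup$dup_ms - dup$timestamp_ms
  expect_true(all(gaps >= 1 & gaps <= 10))
})

test_that("past view windows, filters types, and is idempotent", {
  sim <- simulate_usage_log(behavior_params(n_days = 14), seed = 8)
  pv <- derive_past_view(sim$events)
  t1 <- max(sim$events$timestamp_ms)
  expect_gte(min(pv$timestamp_ms), t1 - 5 * 86400000)
  expect_true(all(pv$type %in% past_view_types()))
  expect_false(any(grepl("NOTIFICATION", pv$type)))
  expect_true(all(pv$source == "past"))
  expect_identical(
    as.data.frame(derive_past_view(pv)),
    as.data.frame(pv)
  )

  # retention beyond the stream span degenerates to a type filter
  all_kept <- derive_past_view(sim$events, retention_days = 100)
  expect_same_events(
    all_kept,
    {
      f <- filter_event_types(sim$events, past_view_types())
      f$source <- "past"
      f
    }
  )
  expect_error(derive_past_view(sim$events, retention_days = 0), "positive")
})

test_that("protocol replay emits the protocol's actions with jitter", {
  proto <- validation_protocol()
  rep <- simulate_validation_protocol(proto, seed = 1)
  counts <- table(rep$recorded$type)
  expect_equal(unname(counts[["NOTIFICATION_POSTED"]]), 10)
  expect_equal(unname(counts[["NOTIFICATION_REMOVED"]]), 10)
  expect_equal(unname(counts[["APP_INSTALLED"]]), 2)
  expect_equal(unname(counts[["APP_UNINSTALLED"]]), 2)
  expect_equal(unname(counts[["APP_FOREGROUND"]]), 20)
  expect_equal(unname(counts[["SCREEN_ON"]]), 10)
  expect_equal(unname(counts[["SCREEN_OFF"]]), 10)

  # screen prompts alternate on/off
  scr <- rep$prompted$type[rep$prompted$type %in% c("SCREEN_ON", "SCREEN_OFF")]
  expect_equal(scr, rep(c("SCREEN_ON", "SCREEN_OFF"), 10))

  # zero jitter: recorded equals prompted exactly
  z <- validation_protocol(default_sd_ms = 0)
  rz <- simulate_validation_protocol(z, seed = 2)
  expect_equal(
    sort(rz$recorded$timestamp_ms),
    sort(rz$prompted$prompted_ms)
  )
})

test_that("context snapshots respect the permission containment invariant", {
  one <- behavior_params(
    n_days = 1,
    app_repertoire = tibble::tibble(app_id = "com.a", weight = 1)
  )
  snap <- simulate_context(one, seed = 1)
  expect_equal(nrow(snap$entries), 1)
  expect_false(anyDuplicated(snap$entries$app_id) > 0)

  p <- behavior_params(n_days = 1)
  for (seed in 1:100) {
    s <- simulate_context(p, seed = seed)
    ok <- mapply(
      function(g, r) all(g %in% r),
      s$entries$permissions_granted, s$entries$permissions_requested
    )
    expect_true(all(ok))
  }

  empty_vocab <- simulate_context(p, seed = 1, vocabulary = character())
  expect_true(all(lengths(empty_vocab$entries$permissions_requested) == 0))
  expect_true(all(lengths(empty_vocab$entries$permissions_granted) == 0))
})
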