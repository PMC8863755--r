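test_that("sessionize pairs on/off events and enforces its contract", {
  s <- vs(c(1000, 61000), c("SCREEN_ON", "SCREEN_OFF"))
  ses <- sessionize(s)
  expect_equal(ses$duration_ms, 60000)
  expect_equal(ses$trigger, "unknown")

  expect_equal(nrow(sessionize(vs(numeric(), character()))), 0)

  bad <- vs(c(1000, 2000), c("SCREEN_ON", "SCREEN_ON"))
  expect_error(sessionize(bad), "repair_sessions")
})

test_that("sessionize reproduces simulator ground truth exactly", {
  sim <- simulate_usage_log(behavior_params(n_days = 10), seed = 14)
  ses <- sessionize(sim$events)
  expect_equal(ses$start_ms, sim$truth$sessions$start_ms)
  expect_equal(ses$end_ms, sim$truth$sessions$end_ms)
})

test_that("per-app durations follow the consecutive-difference rule", {
  s <- vs(
    c(0, 0, 10000, 25000) + 1000,
    c("SCREEN_ON", "APP_FOREGROUND", "APP_FOREGROUND", "SCREEN_OFF"),
    app = c(NA, "com.a", "com.b", NA)
  )
  d <- per_app_durations(s)
  expect_equal(d$duration_ms[d$app_id == "com.a"], 10000)
  expect_equal(d$duration_ms[d$app_id == "com.b"], 15000)

  expect_equal(nrow(per_app_durations(vs(c(1, 2), c("SCREEN_ON", "SCREEN_OFF")))), 0)

  # an APP_BACKGROUND of the current app closes its interval early
  s2 <- vs(
    c(1000, 1000, 5000, 9000),
    c("SCREEN_ON", "APP_FOREGROUND", "APP_BACKGROUND", "SCREEN_OFF"),
    app = c(NA, "com.a", "com.a", NA)
  )
  expect_equal(per_app_durations(s2)$duration_ms, 4000)
})

test_that("per-app durations match ground-truth interval sums", {
  sim <- simulate_usage_log(behavior_params(n_days = 10), seed = 14)
  got <- per_app_durations(sim$events)
  iv <- sim$truth$app_intervals
  want <- tapply(iv$end_ms - iv$start_ms, iv$app_id, sum)
  expect_setequal(got$app_id, names(want))
  expect_equal(
    got$duration_ms[match(names(want), got$app_id)],
    unname(as.numeric(want))
  )
})

test_that("idle exclusion subtracts flagged episodes from app totals", {
  day <- 1.7e12
  s <- vs(
    c(day, day, day + 7 * 3600e3),
    c("SCREEN_ON", "APP_FOREGROUND", "SCREEN_OFF"),
    app = c(NA, "com.clock", NA)
  )
  fl <- flag_idle(s)
  with_idle <- per_app_durations(s)
  without <- per_app_durations(s, exclude = fl)
  expect_equal(with_idle$duration_ms, 7 * 3600e3)
  expect_equal(nrow(without), 0)
})

test_that("a session crossing midnight splits between days, one pickup", {
  day2 <- 1704153600000 # 2024-01-02 00:00 UTC
  ses <- sessionize(vs(
    c(day2 - 30 * 60e3, day2 + 30 * 60e3),
    c("SCREEN_ON", "SCREEN_OFF")
  ))
  su <- usage_summary(ses, granularity = "day")
  expect_equal(nrow(su$windows), 2)
  expect_equal(su$windows$total_use_ms, c(30 * 60e3, 30 * 60e3))
  expect_equal(su$windows$pickup_count, c(1L, 0L))

  # with a +60 min local offset the whole session lands in the second day
  su2 <- usage_summary(ses, granularity = "day", tz_offset_min = 60)
  expect_equal(nrow(su2$windows), 1)
  expect_equal(su2$windows$total_use_ms, 60 * 60e3)
})

test_that("windowed totals conserve total usage at every granularity", {
  sim <- simulate_usage_log(behavior_params(n_days = 10), seed = 14)
  ses <- sessionize(sim$events)
  total <- sum(ses$duration_ms)
  for (g in c("hour", "day", "week")) {
    su <- usage_summary(ses, granularity = g)
    width <- switch(g, hour = 3600e3, day = 86400e3, week = 7 * 86400e3)
    expect_equal(sum(su$windows$total_use_ms), total)
    expect_true(all(su$windows$total_use_ms <= width))
    expect_equal(sum(su$windows$pickup_count), nrow(ses))
  }

  empty <- usage_summary(ses[0, ], granularity = "day")
  expect_equal(nrow(empty$windows), 0)
})

test_that("per-app window breakdown conserves app totals", {
  sim <- simulate_usage_log(behavior_params(n_days = 5), seed = 19)
  ses <- sessionize(sim$events)
  iv <- app_intervals(sim$events)
  su <- usage_summary(ses, intervals = iv, granularity = "day")
  per_app_total <- tapply(su$per_app$duration_ms, su$per_app$app_id, sum)
  want <- per_app_durations(sim$events)
  expect_equal(
    unname(as.numeric(per_app_total[want$app_id])),
    want$duration_ms
  )
  # within every window, app time cannot exceed screen-on time
  merged <- merge(
    aggregate(duration_ms ~ window_start_ms, su$per_app, sum),
    su$windows
  )
  expect_true(all(merged$duration_ms <= merged$total_use_ms))
})

test_that("trigger classification follows the latency-and-first-app rule", {
  base <- 1.7e12
  s <- vs(
    c(base, base + 5000, base + 5000, base + 60000),
    c("NOTIFICATION_POSTED", "SCREEN_ON", "APP_FOREGROUND", "SCREEN_OFF"),
    app = c("com.x", NA, "com.x", NA)
  )
  ses <- classify_triggers(sessionize(s), s)
  expect_equal(ses$trigger, "notification")
  expect_equal(ses$trigger_app, "com.x")

  # same notification, different first app: self-initiated
  s2 <- vs(
    c(base, base + 5000, base + 5000, base + 60000),
    c("NOTIFICATION_POSTED", "SCREEN_ON", "APP_FOREGROUND", "SCREEN_OFF"),
    app = c("com.x", NA, "com.y", NA)
  )
  expect_equal(classify_triggers(sessionize(s2), s2)$trigger, "self")

  # notification older than tau: self-initiated
  s3 <- vs(
    c(base, base + 50000, base + 50000, base + 90000),
    c("NOTIFICATION_POSTED", "SCREEN_ON", "APP_FOREGROUND", "SCREEN_OFF"),
    app = c("com.x", NA, "com.x", NA)
  )
  expect_equal(classify_triggers(sessionize(s3), s3)$trigger, "self")

  # no notification events at all: labels unknown
  s4 <- vs(c(base, base + 1000), c("SCREEN_ON", "SCREEN_OFF"))
  expect_equal(classify_triggers(sessionize(s4), s4)$trigger, "unknown")
})

test_that("trigger labels recover simulator ground truth at >= 95%", {
  sim <- simulate_usage_log(behavior_params(n_days = 20), seed = 27)
  ses <- classify_triggers(sessionize(sim$events), sim$events)
  acc <- mean(ses$trigger == sim$truth$sessions$trigger)
  expect_gte(acc, 0.95)
})

test_that("metrics agree between continuous and merged views on covered windows", {
  sim <- simulate_usage_log(behavior_params(n_days = 7), seed = 21)
  full <- sim$events
  t1 <- max(full$timestamp_ms)
  cont <- validate_stream(full[full$timestamp_ms >= t1 - 3 * 86400000, ])
  merged <- suppressWarnings(merge_sources(cont, derive_past_view(full, 5)))

  span <- c(min(cont$timestamp_ms), t1 + 1)
  in_span <- function(ses) ses[ses$start_ms >= span[1], ]
  a <- in_span(sessionize(repair_sessions(cont)$events))
  b <- in_span(sessionize(repair_sessions(merged)$events))
  expect_equal(a$start_ms, b$start_ms)
  expect_equal(a$end_ms, b$end_ms)
})
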