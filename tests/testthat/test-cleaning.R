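test_that("dedupe collapses millisecond double-counts and nothing else", {
  s <- vs(c(1000, 1003), c("SCREEN_ON", "SCREEN_ON"))
  d <- dedupe(s)
  expect_equal(nrow(d$events), 1)
  expect_equal(d$events$timestamp_ms, 1000)
  expect_equal(d$removed_count, 1)

  far <- vs(c(1000, 6000), c("SCREEN_ON", "SCREEN_ON"))
  expect_equal(dedupe(far)$removed_count, 0)

  # the rule chains within a run
  run <- vs(c(1000, 1005, 1010, 1200), rep("SCREEN_ON", 4))
  d2 <- dedupe(run)
  expect_equal(d2$events$timestamp_ms, c(1000, 1200))

  # distinct types or apps are never merged, even at identical times
  mixed <- vs(
    c(1000, 1000, 1001, 1001),
    c("SCREEN_ON", "APP_FOREGROUND", "APP_FOREGROUND", "NOTIFICATION_POSTED"),
    app = c(NA, "com.a", "com.b", "com.a")
  )
  expect_equal(dedupe(mixed)$removed_count, 0)
})

test_that("dedupe is idempotent and conserves counts", {
  withr::with_seed(31, {
    for (i in 1:20) {
      n <- 40
      ts <- sort(1e9 + cumsum(sample(c(1:5, 1000, 5000), n, replace = TRUE)))
      ty <- sample(c("SCREEN_ON", "SCREEN_OFF", "FLUSH_TO_DISK"), n, TRUE)
      s <- vs(ts, ty)
      d1 <- dedupe(s)
      expect_equal(nrow(s) - nrow(d1$events), d1$removed_count)
      d2 <- dedupe(d1$events)
      expect_equal(d2$removed_count, 0)
      expect_identical(as.data.frame(d2$events), as.data.frame(d1$events))
    }
  })
})

test_that("dedupe removes exactly the injected duplicates (simulator oracle)", {
  sim <- simulate_usage_log(behavior_params(n_days = 10), seed = 23)
  art <- inject_artifacts(
    sim$events, sim$truth,
    artifact_params(duplicate_prob = 0.05, clock_on_prob = 0.2),
    seed = 6
  )
  dup <- injected_artifacts(art)$duplicates
  d <- dedupe(art)
  expect_equal(d$removed_count, nrow(dup))
  # output + duplicates reassembles the artifact stream as a multiset
  reassembled <- rbind(
    as.data.frame(d$events)[c("timestamp_ms", "type", "app_id")],
    data.frame(
      timestamp_ms = dup$dup_ms, type = dup$type, app_id = dup$app_id
    )
  )
  key <- function(d) sort(paste(d$timestamp_ms, d$type, d$app_id))
  expect_identical(
    key(reassembled),
    key(as.data.frame(art)[c("timestamp_ms", "type", "app_id")])
  )
})

test_that("flag_idle flags exactly the long single-app episodes", {
  day <- 1.7e12
  s <- vs(
    c(day, day, day + 7 * 3600e3, day + 8 * 3600e3, day + 8 * 3600e3 + 60e3,
      day + 8 * 3600e3 + 120e3),
    c("SCREEN_ON", "APP_FOREGROUND", "SCREEN_OFF", "SCREEN_ON",
      "APP_FOREGROUND", "SCREEN_OFF"),
    app = c(NA, "com.clock", NA, NA, "com.mail", NA)
  )
  fl <- flag_idle(s)
  expect_equal(nrow(fl), 1)
  expect_equal(fl$app_id, "com.clock")
  expect_equal(fl$duration_ms, 7 * 3600e3)

  short <- vs(c(1000, 1000, 500000), c("SCREEN_ON", "APP_FOREGROUND", "SCREEN_OFF"),
    app = c(NA, "com.a", NA)
  )
  expect_equal(nrow(flag_idle(short)), 0)
})

test_that("flag_idle recovers injected clock-on nights (simulator oracle)", {
  sim <- simulate_usage_log(behavior_params(n_days = 15), seed = 33)
  art <- inject_artifacts(
    sim$events, sim$truth,
    artifact_params(duplicate_prob = 0, clock_on_prob = 0.5, restart_rate = 0),
    seed = 2
  )
  eps <- injected_artifacts(art)$clock_episodes
  expect_gt(nrow(eps), 0)
  fl <- flag_idle(art)
  expect_equal(nrow(fl), nrow(eps))
  expect_equal(sort(fl$start_ms), sort(eps$start_ms))
})

test_that("repair closes open sessions at shutdown or drops them", {
  s <- vs(
    c(1000, 5000, 6000, 9000, 12000),
    c("SCREEN_ON", "DEVICE_SHUTDOWN", "DEVICE_BOOT", "SCREEN_ON", "SCREEN_OFF")
  )
  r <- repair_sessions(s)
  expect_equal(r$repairs$action, "closed_at_shutdown")
  ses <- sessionize(r$events)
  expect_equal(ses$start_ms, c(1000, 9000))
  expect_equal(ses$end_ms, c(5000, 12000))

  rd <- repair_sessions(s, cleaning_params(repair_policy = "drop_unmatched"))
  expect_equal(rd$repairs$action, "dropped_screen_on")
  expect_equal(nrow(sessionize(rd$events)), 1)

  # orphan screen-off (its on was lost) is dropped
  s2 <- vs(c(1000, 2000, 3000), c("SCREEN_OFF", "SCREEN_ON", "SCREEN_OFF"))
  r2 <- repair_sessions(s2)
  expect_equal(r2$repairs$action, "dropped_screen_off")

  paired <- vs(c(1, 2, 3, 4) * 1000, rep(c("SCREEN_ON", "SCREEN_OFF"), 2))
  expect_equal(nrow(repair_sessions(paired)$repairs), 0)
})

test_that("repair restores strict alternation after logging dropouts", {
  sim <- simulate_usage_log(behavior_params(n_days = 5), seed = 3)
  t0 <- min(sim$events$timestamp_ms)
  win <- c(t0 + 2.55 * 86400000, t0 + 2.65 * 86400000)
  art <- inject_artifacts(
    sim$events, sim$truth,
    artifact_params(
      duplicate_prob = 0, clock_on_prob = 0, restart_rate = 0,
      dropout_windows = list(win)
    ),
    seed = 2
  )
  r <- repair_sessions(art, cleaning_params(repair_policy = "drop_unmatched"))
  scr <- r$events$type[r$events$type %in% c("SCREEN_ON", "SCREEN_OFF")]
  expect_identical(
    scr, rep(c("SCREEN_ON", "SCREEN_OFF"), length.out = length(scr))
  )

  # bookkeeping: clipped sessions are repaired/dropped, engulfed ones vanish
  tr <- sim$truth$sessions
  on_in <- tr$start_ms >= win[1] & tr$start_ms < win[2]
  off_in <- tr$end_ms >= win[1] & tr$end_ms < win[2]
  expect_equal(nrow(r$repairs), sum(xor(on_in, off_in)))
  expect_equal(
    nrow(sessionize(r$events)),
    nrow(tr) - sum(on_in & off_in) - sum(on_in & !off_in) -
      sum(!on_in & off_in)
  )
})

test_that("all three cleaning rules are identities on artifact-free output", {
  sim <- simulate_usage_log(behavior_params(n_days = 8), seed = 41)
  d <- dedupe(sim$events)
  expect_equal(d$removed_count, 0)
  expect_equal(nrow(flag_idle(sim$events)), 0)
  r <- repair_sessions(sim$events)
  expect_equal(nrow(r$repairs), 0)
  expect_identical(as.data.frame(r$events), as.data.frame(sim$events))
})
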