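#' Default app repertoire for the simulator
#'
#' Twelve common Android packages with Zipf-like popularity weights. The last
#' entry is a clock app, which also serves as the default app for simulated
#' screen-left-on charging artifacts.
#'
#' @return A tibble with columns `app_id` and `weight` (normalized at use).
#' @export
default_app_repertoire <- function() {
  tibble(
    app_id = c(
      "com.whatsapp", "com.instagram.android", "com.google.android.youtube",
      "com.zhiliaoapp.musically", "com.android.chrome", "com.facebook.katana",
      "com.google.android.gm", "com.spotify.music", "com.reddit.frontpage",
      "com.google.android.apps.maps", "com.android.vending",
      "com.google.android.deskclock"
    ),
    weight = 1 / seq_len(12)
  )
}

#' Default circadian weighting of pickup intensity
#'
#' Hourly weights (hour 0-23, local device time) for the inhomogeneous Poisson
#' pickup process: near-zero overnight, a morning rise, and an evening peak —
#' the usual diurnal shape of smartphone use. Weights are normalized to sum
#' to one; hours inside the sleep window are additionally zeroed at
#' simulation time.
#'
#' @return Numeric vector of 24 non-negative weights summing to 1.
#' @export
default_circadian_weights <- function() {
  w <- c(
    0.6, 0.2, 0.1, 0.1, 0.1, 0.2, 0.8, 2.0,
    3.0, 3.2, 3.0, 3.2, 3.6, 3.2, 3.0, 3.0,
    3.2, 3.6, 4.0, 4.6, 4.6, 3.8, 2.4, 1.2
  )
  w / sum(w)
}

default_permission_vocabulary <- function() {
  c(
    "CAMERA", "ACCESS_FINE_LOCATION", "READ_CONTACTS", "RECORD_AUDIO",
    "POST_NOTIFICATIONS", "READ_SMS", "INTERNET", "READ_EXTERNAL_STORAGE",
    "ACTIVITY_RECOGNITION", "CALL_PHONE"
  )
}

#' Behavioral parameters for the usage simulator
#'
#' These parameters define the generative model of device use: pickups arise
#' from an inhomogeneous Poisson process whose daily intensity integrates to
#' `daily_pickup_rate` (default 80/day — members of the general population
#' interact with their phones on the order of 80 times a day), modulated
#' across the day by `circadian_weights` and silenced inside `sleep_window`.
#' Session lengths are log-normal in seconds; within a session the foreground
#' app switches as a Markov chain with per-minute hazard `switch_hazard`.
#' A fraction `notif_response_prob` of pickups are notification-driven: a
#' notification from a repertoire app precedes the screen-on by an
#' exponential latency and that app is opened first. Apps additionally post
#' ambient (unanswered) notifications at `notification_rate` per app per day.
#' An optional fixed `alarm_time` adds one clock-app pickup at the same time
#' every day, the regular daily marker typical of alarm-clock use.
#'
#' @param n_days Number of simulated days (> 0).
#' @param daily_pickup_rate Expected pickups per day (default 80).
#' @param circadian_weights 24 non-negative hourly weights (normalized).
#' @param sleep_window `c(start_hour, end_hour)` of near-zero activity
#'   (default 1-7 am).
#' @param session_duration_meanlog,session_duration_sdlog Log-normal
#'   parameters of session duration in seconds (default median 90 s).
#' @param app_repertoire Tibble of `app_id`, `weight`.
#' @param switch_hazard Per-minute probability-rate of an in-session app
#'   switch.
#' @param notification_rate Ambient notifications per app per day.
#' @param notif_response_prob Fraction of pickups that are
#'   notification-triggered.
#' @param notif_response_latency_s Mean of the exponential notification-to-
#'   pickup latency, seconds.
#' @param alarm_time Clock-app alarm hour (e.g. `7.5` for 07:30), or `NULL`.
#' @param start_ms Simulation origin, UNIX ms (default 2024-01-01 00:00 UTC,
#'   a Monday, so weekly windows align with the simulation start).
#' @param seed Default RNG seed used by [simulate_usage_log()].
#' @return A `behavior_params` object (validated list).
#' @export
behavior_params <- function(n_days = 30,
                            daily_pickup_rate = 80,
                            circadian_weights = default_circadian_weights(),
                            sleep_window = c(1, 7),
                            session_duration_meanlog = log(90),
                            session_duration_sdlog = 1.1,
                            app_repertoire = default_app_repertoire(),
                            switch_hazard = 0.35,
                            notification_rate = 1.5,
                            notif_response_prob = 0.25,
                            notif_response_latency_s = 5,
                            alarm_time = NULL,
                            start_ms = 1704067200000,
                            seed = 1L) {
  if (!is.numeric(n_days) || n_days <= 0) {
    abort("`n_days` must be a positive number")
  }
  stopifnot(
    daily_pickup_rate >= 0, notification_rate >= 0,
    notif_response_prob >= 0, notif_response_prob <= 1,
    notif_response_latency_s >= 0, switch_hazard >= 0,
    length(circadian_weights) == 24, all(circadian_weights >= 0),
    sum(circadian_weights) > 0,
    length(sleep_window) == 2,
    is.data.frame(app_repertoire), nrow(app_repertoire) > 0,
    all(c("app_id", "weight") %in% names(app_repertoire)),
    all(app_repertoire$weight >= 0), sum(app_repertoire$weight) > 0,
    start_ms > 0
  )
  structure(
    list(
      n_days = as.integer(n_days),
      daily_pickup_rate = daily_pickup_rate,
      circadian_weights = circadian_weights / sum(circadian_weights),
      sleep_window = sleep_window,
      session_duration_meanlog = session_duration_meanlog,
      session_duration_sdlog = session_duration_sdlog,
      app_repertoire = as_tibble(app_repertoire),
      switch_hazard = switch_hazard,
      notification_rate = notification_rate,
      notif_response_prob = notif_response_prob,
      notif_response_latency_s = notif_response_latency_s,
      alarm_time = alarm_time,
      start_ms = as.numeric(start_ms),
      seed = as.integer(seed)
    ),
    class = "behavior_params"
  )
}

#' Simulate a continuous usage log with known ground truth
#'
#' Generates the event stream a passive logger would record from a device
#' used according to `params`, together with the ground truth that downstream
#' cleaning and metric code can be tested against. The stream starts with a
#' `DEVICE_BOOT`; each pickup emits `SCREEN_ON`, an `APP_FOREGROUND` chain,
#' and `SCREEN_OFF`; notification-triggered pickups are preceded by a
#' `NOTIFICATION_POSTED` from the app that is then opened first (its
#' `NOTIFICATION_REMOVED` follows shortly after the screen-on); ambient
#' notifications post and are later removed without a pickup. Identical
#' output is guaranteed for identical `(params, seed)`.
#'
#' By construction no two events of the same type and app fall within one
#' second of each other, so on artifact-free output the cleaning rules of
#' [dedupe()], [flag_idle()], and [repair_sessions()] are identities.
#'
#' @param params A [behavior_params()] object.
#' @param seed RNG seed (defaults to `params$seed`).
#' @return A list with elements `events` (validated `event_stream`, source
#'   `"continuous"`) and `truth` (list with tibbles `sessions` — `session_id`,
#'   `start_ms`, `end_ms`, `trigger`, `trigger_app`, and `app_intervals` —
#'   `session_id`, `app_id`, `start_ms`, `end_ms`, tiling each session).
#' @export
#' @examples
#' sim <- simulate_usage_log(behavior_params(n_days = 2), seed = 7)
#' nrow(sim$truth$sessions)
simulate_usage_log <- function(params = behavior_params(),
                               seed = params$seed) {
  if (!inherits(params, "behavior_params")) {
    abort("`params` must be a behavior_params object")
  }
  withr::with_seed(seed, sim_usage_impl(params))
}

sim_usage_impl <- function(p) {
  end_ms <- p$start_ms + p$n_days * MS_PER_DAY
  w <- p$circadian_weights
  hours <- 0:23
  asleep <- in_hour_window(hours, p$sleep_window)
  w[asleep] <- 0
  if (sum(w) == 0) abort("circadian weights are zero everywhere outside sleep")
  w <- w / sum(w)

  # piecewise-constant inhomogeneous Poisson process, hour resolution
  lam <- rep(p$daily_pickup_rate * w, p$n_days)
  cell_start <- p$start_ms + (seq_along(lam) - 1) * MS_PER_HOUR
  counts <- rpois(length(lam), lam)
  starts <- rep(cell_start, counts) + runif(sum(counts)) * MS_PER_HOUR

  if (!is.null(p$alarm_time)) {
    alarm <- p$start_ms + (seq_len(p$n_days) - 1) * MS_PER_DAY +
      p$alarm_time * MS_PER_HOUR + abs(rnorm(p$n_days, 0, 60 * MS_PER_SEC))
    starts <- c(starts, alarm)
    alarm_flag <- c(
      rep(FALSE, sum(counts)),
      rep(TRUE, p$n_days)
    )[order(starts)]
  } else {
    alarm_flag <- rep(FALSE, sum(counts))[order(starts)]
  }
  starts <- sort(starts)
  starts <- round(starts)

  # enforce a minimum inter-pickup spacing so sessions cannot collide
  keep <- greedy_spacing(starts, 2000)
  starts <- starts[keep]
  alarm_flag <- alarm_flag[keep]
  n <- length(starts)

  if (n == 0) {
    events <- validate_stream(event_stream(
      p$start_ms, "DEVICE_BOOT",
      source = "continuous"
    ))
    truth <- list(sessions = empty_sessions(), app_intervals = empty_intervals())
    return(list(events = events, truth = truth))
  }

  dur <- round(rlnorm(n, p$session_duration_meanlog, p$session_duration_sdlog) *
    MS_PER_SEC)
  dur <- pmin(pmax(dur, 1000), 4 * MS_PER_HOUR)
  gap_cap <- c(diff(starts), end_ms - starts[n]) - 1000
  dur <- pmin(dur, pmax(gap_cap, 1000))
  ends <- starts + dur

  # notification-triggered pickups
  apps <- p$app_repertoire$app_id
  wts <- p$app_repertoire$weight / sum(p$app_repertoire$weight)
  trig <- runif(n) < p$notif_response_prob & !alarm_flag
  latency <- round(pmin(
    pmax(rexp(n, 1 / max(p$notif_response_latency_s, 0.001)) * MS_PER_SEC, 500),
    120 * MS_PER_SEC
  ))
  notif_ts <- starts - latency
  prev_end <- c(p$start_ms, ends[-n])
  # a triggering notification must fall after the previous session ended
  trig <- trig & notif_ts > prev_end + 500
  trig_app <- rep(NA_character_, n)
  trig_app[trig] <- sample(apps, sum(trig), replace = TRUE, prob = wts)

  # app interval chains per session
  first_app <- ifelse(trig, trig_app,
    if (!is.null(p$alarm_time)) {
      ifelse(alarm_flag, apps[length(apps)],
        sample(apps, n, replace = TRUE, prob = wts)
      )
    } else {
      sample(apps, n, replace = TRUE, prob = wts)
    }
  )
  intervals <- vector("list", n)
  for (i in seq_len(n)) {
    cuts <- numeric(0)
    if (p$switch_hazard > 0 && dur[i] > 2000 && length(apps) > 1) {
      t <- 0
      repeat {
        t <- t + max(rexp(1, p$switch_hazard / 60) * MS_PER_SEC, 1000)
        if (t >= dur[i] - 1000) break
        cuts <- c(cuts, round(t))
      }
    }
    bounds <- c(0, cuts, dur[i])
    k <- length(bounds) - 1
    chain <- character(k)
    chain[1] <- first_app[i]
    if (k > 1) {
      for (j in 2:k) {
        others <- apps != chain[j - 1]
        chain[j] <- sample(apps[others], 1, prob = wts[others])
      }
    }
    intervals[[i]] <- tibble(
      session_id = i, app_id = chain,
      start_ms = starts[i] + bounds[-length(bounds)],
      end_ms = starts[i] + bounds[-1]
    )
  }
  app_intervals <- bind_rows(intervals)

  sessions <- tibble(
    session_id = seq_len(n), start_ms = starts, end_ms = ends,
    trigger = ifelse(trig, "notification", "self"), trigger_app = trig_app
  )

  # ambient (unanswered) notifications, spaced away from answered ones
  answered <- tibble(
    app_id = trig_app[trig],
    posted_ms = notif_ts[trig],
    removed_ms = starts[trig] + 2000
  )
  amb <- ambient_notifications(p, end_ms, answered)

  ev <- bind_rows(
    tibble(
      timestamp_ms = p$start_ms, type = "DEVICE_BOOT",
      app_id = NA_character_
    ),
    tibble(timestamp_ms = starts, type = "SCREEN_ON", app_id = NA_character_),
    tibble(timestamp_ms = ends, type = "SCREEN_OFF", app_id = NA_character_),
    tibble(
      timestamp_ms = app_intervals$start_ms, type = "APP_FOREGROUND",
      app_id = app_intervals$app_id
    ),
    tibble(
      timestamp_ms = notif_ts[trig], type = "NOTIFICATION_POSTED",
      app_id = trig_app[trig]
    ),
    tibble(
      timestamp_ms = starts[trig] + 2000, type = "NOTIFICATION_REMOVED",
      app_id = trig_app[trig]
    ),
    amb
  )
  ev$source <- "continuous"
  events <- validate_stream(ev)

  list(
    events = events,
    truth = list(sessions = sessions, app_intervals = app_intervals)
  )
}

# ambient notifications that never trigger a pickup; each POSTED/REMOVED is
# kept at least 1 s from any same-app event of the same type so that
# millisecond-window deduplication can never touch legitimate events
ambient_notifications <- function(p, end_ms, answered) {
  empty <- tibble(
    timestamp_ms = numeric(), type = character(),
    app_id = character()
  )
  if (p$notification_rate <= 0) {
    return(empty)
  }
  apps <- p$app_repertoire$app_id
  out <- vector("list", length(apps))
  span <- end_ms - p$start_ms
  for (a in seq_along(apps)) {
    m <- rpois(1, p$notification_rate * p$n_days)
    if (m == 0) next
    posted <- round(p$start_ms + runif(m) * span)
    ans <- answered[answered$app_id == apps[a], ]
    posted <- enforce_group_gap(posted, ans$posted_ms, 1000)
    if (length(posted) == 0) next
    removed <- round(posted + pmax(rexp(length(posted), 1 / 1800) *
      MS_PER_SEC, 1000))
    ok <- removed < end_ms
    removed <- enforce_group_gap(removed[ok], ans$removed_ms, 1000)
    out[[a]] <- bind_rows(
      tibble(
        timestamp_ms = posted, type = "NOTIFICATION_POSTED",
        app_id = apps[a]
      ),
      tibble(
        timestamp_ms = removed, type = "NOTIFICATION_REMOVED",
        app_id = apps[a]
      )
    )
  }
  bind_rows(out, empty)
}

# greedily keep elements of a sorted vector at least `gap` apart
greedy_spacing <- function(x, gap) {
  n <- length(x)
  keep <- logical(n)
  last <- -Inf
  for (i in seq_len(n)) {
    if (x[i] - last >= gap) {
      keep[i] <- TRUE
      last <- x[i]
    }
  }
  keep
}

# drop elements of `x` closer than `gap` to any element of `fixed` or to an
# earlier kept element of `x`
enforce_group_gap <- function(x, fixed, gap) {
  x <- sort(x)
  kept <- numeric(0)
  for (v in x) {
    if (length(fixed) > 0 && any(abs(fixed - v) < gap)) next
    if (length(kept) > 0 && v - kept[length(kept)] < gap) next
    kept <- c(kept, v)
  }
  kept
}

in_hour_window <- function(h, window) {
  if (window[1] <= window[2]) {
    h >= window[1] & h < window[2]
  } else {
    h >= window[1] | h < window[2]
  }
}

empty_sessions <- function() {
  tibble(
    session_id = integer(), start_ms = numeric(), end_ms = numeric(),
    trigger = character(), trigger_app = character()
  )
}

empty_intervals <- function() {
  tibble(
    session_id = integer(), app_id = character(),
    start_ms = numeric(), end_ms = numeric()
  )
}

#' Simulate a contextual snapshot of installed apps and permissions
#'
#' One entry per repertoire app, with a random subset of a fixed permission
#' vocabulary requested and a random subset of the requested permissions
#' granted — the granted set is always contained in the requested set.
#'
#' @param params A [behavior_params()] (supplies the app repertoire and the
#'   snapshot timestamp).
#' @param seed RNG seed.
#' @param vocabulary Permission vocabulary to draw from.
#' @param p_requested,p_granted Per-permission inclusion probabilities.
#' @return A `context_snapshot`: list with `captured_at_ms` and an `entries`
#'   tibble (`app_id`, list-columns `permissions_requested`,
#'   `permissions_granted`).
#' @export
simulate_context <- function(params = behavior_params(), seed = params$seed,
                             vocabulary = default_permission_vocabulary(),
                             p_requested = 0.5, p_granted = 0.6) {
  apps <- params$app_repertoire$app_id
  if (length(apps) == 0) abort("app repertoire is empty")
  withr::with_seed(seed, {
    req <- lapply(apps, function(a) {
      vocabulary[runif(length(vocabulary)) < p_requested]
    })
    gr <- lapply(req, function(r) r[runif(length(r)) < p_granted])
  })
  structure(
    list(
      captured_at_ms = params$start_ms,
      entries = tibble(
        app_id = apps,
        permissions_requested = req,
        permissions_granted = gr
      )
    ),
    class = "context_snapshot"
  )
}
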