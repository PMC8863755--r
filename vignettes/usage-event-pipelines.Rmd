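---
title: "From raw event streams to usage metrics: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw event streams to usage metrics: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phonelogr)
```

Passive smartphone logging apps record a time-stamped event for every
interaction a participant has with their device — screens turning on and
off, apps moving to the foreground, notifications arriving — and export the
result as tables of `(timestamp, event type, app)`. Turning those exports
into research variables (total screen time, pickups, per-app durations,
notification-driven sessions) involves a chain of decisions that are rarely
written down. This vignette documents the chain as phonelogr implements it:
the generative model behind the simulator, the cleaning rules, the metric
definitions, the secure-export format, and the timestamp-validation
harness, together with the reasoning behind every tunable default.

## The event model

All modules share one vocabulary (`event_types()`): screen and power events
describe the device, app-scoped events (`app_event_types()`) additionally
carry a reverse-domain package id, and `CONFIG_CHANGE` / `FLUSH_TO_DISK`
are operating-system housekeeping that retrospective extractions contain
whether you want them or not. Timestamps are integer UNIX *milliseconds*
stored as doubles: millisecond resolution is what loggers emit and what
timing validation reports, and doubles represent integers exactly far
beyond any plausible epoch value, while 32-bit integers overflow in 1970.

`validate_stream()` is the single gate into the package: it rejects
malformed rows individually (keeping the reasons retrievable via
`rejected_rows()`), clears stray app ids from device-level events, and
sorts stably by timestamp with ties broken by source (`continuous` before
`past`) and then event-type order. Everything downstream assumes — and the
tests assert — that this operation is idempotent.

Two views of the same device can be merged (`merge_sources()`): continuous
logging observes prospectively, while the operating system's own usage
database can be queried retrospectively and is immune to logging dropouts.
A past event is treated as a duplicate observation when a continuous event
of the same type and app lies within `window_ms` (default 1000 ms) of it.
Both records come from the *same* device clock, so no drift model is
needed; the window only absorbs scheduling jitter. Past events with no
continuous counterpart are kept — that is the point of collecting both.
Where the two sources contradict each other (two screen-ons from different
sources with nothing in between), both are kept under a warning rather than
silently resolved; there is no principled way to decide which record is
wrong.

## The behavioral simulator

No public event-level corpus exists for this data class, so the package
ships a generative simulator whose output is the test oracle for every
downstream stage. The model, chosen to be the simplest thing that
reproduces the gross structure of real usage:

* **Pickups** follow an inhomogeneous Poisson process whose daily intensity
  integrates to `daily_pickup_rate` (default **80/day**, the rate at which
  members of the general population interact with their phones), shaped
  across the day by 24 hourly `circadian_weights` (near-zero overnight,
  morning rise, evening peak) and zeroed inside `sleep_window` (default
  01:00–07:00). The process is sampled at hourly resolution: counts are
  Poisson per hour-of-day cell, positions uniform within the hour.
* **Session durations** are log-normal in seconds (default median 90 s,
  `sdlog` 1.1), right-skewed as usage durations are: many glances, few long
  sessions. Durations are clamped to at least 1 s and at most 4 h and
  truncated so sessions never collide.
* **Within a session** the foreground app switches as a Markov chain:
  exponential holding times with per-minute hazard `switch_hazard`
  (default 0.35), next app drawn from the Zipf-weighted repertoire
  excluding the current one. The resulting intervals tile the session
  exactly, which is what lets per-app duration tests demand equality, not
  approximation.
* **Notifications** play two roles. A fraction `notif_response_prob`
  (default 0.25) of pickups is *notification-driven*: a
  `NOTIFICATION_POSTED` from a repertoire app precedes the screen-on by an
  exponential latency (mean 5 s) and that app is opened first. The
  remaining, ambient notifications arrive at `notification_rate` per app
  per day (default 1.5) and are later removed without a pickup. The
  parameter is defined at the pickup level — not as a per-notification
  response probability — so that the total pickup intensity stays exactly
  `daily_pickup_rate` regardless of notification traffic.
* An optional `alarm_time` adds one clock-app pickup at the same time every
  day, the regular daily marker characteristic of alarm-clock use. It is
  off by default because it is a feature of some participants, not all.

Ground truth (`truth$sessions`, `truth$app_intervals`) is recorded as the
stream is built, never re-derived from it.

One deliberately engineered property: the generator keeps any two events of
the same type and app at least one second apart (pickups at least two
seconds apart, app switches at least one second). Real behavior has no
reason to produce same-kind events within milliseconds — that is precisely
why millisecond coincidence identifies double-counts — and enforcing it
makes the cleaning rules provable identities on artifact-free output.

What the simulator does **not** emulate, and what passing tests therefore
do not show: weekday/weekend structure, behavioral reactivity to being
observed, content or typing, device clock adjustments (NTP steps, DST — all
times are a fixed offset from UTC), or between-participant heterogeneity.
Tests passing on this generator demonstrate that the pipeline inverts a
*known* data-generating process, not that the model is a complete account
of human usage.

### Artifacts

`inject_artifacts()` adds what real exports contain and clean models do
not, recording exactly what it injected (`injected_artifacts()`) so
cleaning can be tested against a known answer:

* **Double counts**: each event duplicated with probability
  `duplicate_prob` at a gap of 1–10 ms — the retrospective database's
  double-count signature.
* **Clock-on nights**: with per-night probability `clock_on_prob`, a
  screen-on/clock-foreground/screen-off episode spans the night window,
  emulating a charging device whose screen stays on. Nights where a real
  session would collide are skipped so ground truth stays exact.
* **Restarts**: shutdown/boot pairs placed in inter-session gaps (devices
  mostly restart while idle; placing them mid-session would contradict the
  recorded sessions the truth tables describe).
* **Dropouts**: windows where continuous events are deleted outright — the
  app was killed or permissions revoked.

### The retrospective view and the validation protocol

`derive_past_view()` models the OS usage database: only the trailing
`retention_days` (default 5 — five days of retrospective data is generally
held sufficient to represent typical use) of the types that database stores
survive; notifications are absent from it by construction.

`simulate_validation_protocol()` replays the standard timestamp-validation
procedure: 20 alternating screen on/offs, two app installs and two
uninstalls, 10 notifications pushed and removed, a probe app opened 20
times, separated by ~5 s gaps (the protocol itself does not prescribe a
gap; 5 s is this package's choice, long enough that order-based alignment
is unambiguous at realistic jitter). The logger's record of each action is
displaced by per-type Gaussian jitter, default bias 0 and **sd 500 ms,
sign-unrestricted**: because the kernel queues the log record and the
action's execution independently, a logger can time-stamp an event a moment
*before* it visibly happens, and observed discrepancies on real devices are
of millisecond-to-second order in both directions.

## Cleaning rules

* **Dedupe** (`epsilon_ms`, default 100 ms): within the sub-sequence of
  events sharing a type and app, any run whose successive gaps are all at
  most epsilon collapses to its earliest member. The window is generous
  relative to the few-millisecond double-count signature because OS
  scheduling jitter reaches tens of milliseconds. Chaining is applied
  within the same-kind subsequence rather than between physically adjacent
  rows: an unrelated event of another type can land between an original
  and its duplicate without hiding the duplication. Events of distinct
  types or apps are never merged at any distance.
* **Idle flagging** (`idle_threshold_ms`, default 3 h): maximal single-app
  foreground episodes longer than the threshold are *flagged, not
  deleted* — whether a seven-hour overnight clock episode is an artifact
  or the phenomenon of interest depends on the research question, so the
  decision is left to the analyst (`per_app_durations(exclude = )`).
  Episode derivation requires event durations, which is why flagging runs
  after streams are validated and ordered.
* **Session repair** (`repair_policy`): restarts are always documented, so
  an open session interrupted by power loss can be closed at the next
  shutdown/boot (`close_at_shutdown`, the default — it preserves real
  usage time) or dropped (`drop_unmatched`, the conservative choice when
  dropouts make the shutdown anchor unreliable). Orphan screen-offs are
  always dropped. After repair, on/off events strictly alternate, which is
  the precondition `sessionize()` enforces.

## Metrics

Sessions are half-open `[start, end)` intervals; a **pickup** is a session
start. Windowed summaries (`usage_summary()`) split sessions at hour, day,
or week boundaries — weeks start Monday — in local time expressed as a
fixed minute offset from UTC (default 0; a full tz database adds DST
semantics the underlying data cannot disambiguate). A boundary-crossing
session contributes duration to every window it touches but its pickup is
counted once, in the start window, keeping the pickup total equal to the
session count. These conventions make the conservation identities exact:
hourly, daily, and weekly totals each sum to total session time, and daily
totals can never exceed 24 h.

Per-app durations follow the consecutive-difference rule: each foreground
interval ends at the next foreground event, a same-app background event, a
screen-off/shutdown, or the window edge, and durations are summed per app.
Within a session, per-app time can never exceed session duration, with
equality when foreground coverage is gapless (as in the simulator).

A session is classified **notification-driven** when a
`NOTIFICATION_POSTED` falls within `tau_ms` (default 30 s) before the
screen-on *and* the session's first foreground app is the notifying app.
The response-latency literature motivates a short window; 30 s is this
package's default, not an empirical constant, and misattribution from a
coincidental same-app notification in the window is possible — on
simulated data at default rates it stays below 5%. Streams with no
notification events yield `unknown` labels rather than a confident
`self`.

## Secure export

Exports are password-protected. Passwords come from *user-generated
randomness*: the millisecond timestamps of a participant's consent-dialog
taps are shuffled, one is drawn, and that value seeds a character generator
emitting 16 characters (configurable, minimum 8) from a 74-character
alphabet with at least one uppercase, lowercase, digit, and symbol
guaranteed. The charset size and length are this package's policy — varied
characters resist brute force, and not deriving from words resists
dictionary attacks.

The container itself is a deliberately simple text document: a `key: value`
header and a base64 body. The payload (CSV text) is encrypted with
**AES-256** in CBC mode under a key stretched from the password with
bcrypt-pbkdf (16 rounds, 16-byte random salt) and authenticated with
HMAC-SHA256 over IV and ciphertext, encrypt-then-MAC — a wrong password or
a flipped bit fails the MAC check before any decryption output exists. The
contract is the lossless round trip and the 256-bit key, both asserted in
tests via the container metadata and tamper tests; the wrapper format is
not the point and is documented precisely so other tools can read it.

## Timestamp validation

`align_events()` pairs prompted with recorded events order-preservingly
within each type — justified when the logger detects all actions in the
order they occur, which the protocol's generous gaps make overwhelmingly
likely — with a nearest-neighbor option for streams with missed
detections. `discrepancy_stats()` reports per type the pair count, mean
difference, and **sample** standard deviation (n − 1; reported as `NA` for
a single pair), signed recorded-minus-prompted so negative means the
logger ran ahead of the oracle. The row order mirrors the conventional
layout of timing-validation tables. Absolute millisecond values measured
on physical devices are hardware- and scheduler-dependent and are out of
scope here; what the harness demonstrates is that injected jitter is
recovered within sampling error.

## Problem sizes and tolerances in the test suite

The suite simulates 2–20 days for unit tests, 30 days for calibration
checks (the pickup-rate test asserts the observed mean within three
standard errors of 80/day), and 60 days for the end-to-end
cleaning/metrics inversion; randomized round-trip properties (config
codec, CSV, encryption) run 100 cases each under fixed seeds. Oracle
comparisons are exact equalities — the generator's spacing guarantees make
that possible — and only genuinely stochastic recoveries (rate, jitter
bias) use sampling-error bounds.

## Known limitations

* The simulator's behavioral realism is limited as listed above; defaults
  are calibrated to one headline rate, not fitted to any dataset.
* `merge_sources()` matches duplicates per event kind within a window; it
  does not attempt global sequence alignment, so a past record whose
  timestamp differs from its continuous counterpart by more than the
  window appears twice.
* Trigger classification is heuristic; it has no access to whether the
  participant actually saw the notification.
* The encrypted container is a package-defined format, not an encrypted
  PDF; tooling expecting the PDF dialect of on-device exports needs the
  dialect documented above.
* Windowing supports fixed UTC offsets only; studies spanning DST
  transitions should window in UTC and shift afterwards.
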