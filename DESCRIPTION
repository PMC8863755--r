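Package: phonelogr
Title: Simulate, Secure, Clean, and Summarize Smartphone Usage Event Logs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for working with smartphone usage event logs of the kind
    produced by passive logging apps in digital-phenotyping research: a
    behaviorally structured simulator of screen, app, and notification event
    streams with known ground truth; an encrypted export container with
    consent-tap password generation; event-stream cleaning (duplicate removal,
    idle-episode flagging, screen-session repair); sessionization and usage
    metrics (pickups, per-app durations, hourly/daily/weekly summaries,
    notification-triggered session classification); a harness for validating
    logger timestamps against a prompted-action oracle; and standard
    visualizations (per-app totals, daily usage barcode, colored app timeline).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    openssl,
    readr,
    rlang,
    tibble,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
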