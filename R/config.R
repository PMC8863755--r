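#' Describe a study's data-collection phases
#'
#' A study configuration is an ordered list of collection phases, each drawing
#' on one of three data sources: a one-off `contextual` snapshot of installed
#' apps and permissions, prospective `continuous` logging, or a retrospective
#' `past`-usage extraction from the operating system's own database. The order
#' of phases matters (e.g., retrospectively querying a period that was also
#' logged continuously, to back-fill dropouts) and is preserved through the
#' payload codec ([encode_config()] / [decode_config()]).
#'
#' @param ... Phase records created by [phase_contextual()],
#'   [phase_continuous()], or [phase_past()] (or a single list of them).
#' @param allow_duplicate_sources Permit the same source to appear in more
#'   than one phase (default `FALSE`).
#' @return A `study_config` object.
#' @export
#' @examples
#' study_config(phase_past(retention_days = 5), phase_continuous())
study_config <- function(..., allow_duplicate_sources = FALSE) {
  phases <- list(...)
  if (length(phases) == 1 && !inherits(phases[[1]], "phonelog_phase") &&
    is.list(phases[[1]])) {
    phases <- phases[[1]]
  }
  if (length(phases) == 0) {
    abort("a study configuration needs at least one phase")
  }
  for (p in phases) {
    if (!inherits(p, "phonelog_phase")) {
      abort("every phase must be built with phase_contextual/continuous/past()")
    }
  }
  sources <- vapply(phases, function(p) p$source, character(1))
  if (!allow_duplicate_sources && anyDuplicated(sources)) {
    abort("duplicate phase sources; set allow_duplicate_sources = TRUE to permit")
  }
  structure(
    list(
      phases = unname(phases),
      allow_duplicate_sources = isTRUE(allow_duplicate_sources)
    ),
    class = "study_config"
  )
}

new_phase <- function(source, options) {
  structure(list(source = source, options = options),
    class = "phonelog_phase"
  )
}

#' @rdname study_config
#' @export
phase_contextual <- function() new_phase("contextual", list())

#' @rdname study_config
#' @param track_screen,track_apps,track_installs,track_notifications Which
#'   event families continuous logging should record. Device restarts are
#'   always documented regardless of these switches.
#' @export
phase_continuous <- function(track_screen = TRUE, track_apps = TRUE,
                             track_installs = TRUE,
                             track_notifications = TRUE) {
  new_phase("continuous", list(
    track_screen = isTRUE(track_screen),
    track_apps = isTRUE(track_apps),
    track_installs = isTRUE(track_installs),
    track_notifications = isTRUE(track_notifications)
  ))
}

#' @rdname study_config
#' @param retention_days How many trailing days of retrospective usage to
#'   extract (default 5; five days of retrospective data is generally
#'   sufficient to represent typical smartphone use).
#' @export
phase_past <- function(retention_days = 5) {
  if (!is.numeric(retention_days) || retention_days <= 0) {
    abort("`retention_days` must be a positive number")
  }
  new_phase("past", list(retention_days = as.numeric(retention_days)))
}

CONFIG_MAGIC <- "phonelog-config/1"

#' Encode a study configuration as a QR-compatible text payload
#'
#' The payload is a short, self-delimiting UTF-8 key-value document (one
#' `key=value` pair per line, first line a format tag). It carries every field
#' of the configuration and is small enough to render as a QR code with any
#' generator, which is how a logging app on a participant's device would be
#' configured without manual input.
#'
#' @param config A [study_config()].
#' @return A single string, the payload text.
#' @seealso [decode_config()], its exact inverse.
#' @export
#' @examples
#' cat(encode_config(study_config(phase_continuous())))
encode_config <- function(config) {
  if (!inherits(config, "study_config")) {
    abort("`config` must be a study_config")
  }
  lines <- c(
    CONFIG_MAGIC,
    paste0(
      "allow_duplicate_sources=",
      encode_value(config$allow_duplicate_sources)
    ),
    paste0("phases=", length(config$phases))
  )
  for (i in seq_along(config$phases)) {
    p <- config$phases[[i]]
    lines <- c(lines, sprintf("phase.%d.source=%s", i, p$source))
    for (key in names(p$options)) {
      lines <- c(lines, sprintf(
        "phase.%d.%s=%s", i, key, encode_value(p$options[[key]])
      ))
    }
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

encode_value <- function(v) {
  if (is.logical(v)) {
    if (v) "true" else "false"
  } else if (is.numeric(v)) {
    format(v, digits = 15, scientific = FALSE)
  } else {
    as.character(v)
  }
}

#' Decode a configuration payload
#'
#' Exact inverse of [encode_config()]. Unknown keys are ignored with a
#' warning (so older readers tolerate payloads from newer writers); missing
#' required fields raise an error naming the field.
#'
#' @param payload Payload text as produced by [encode_config()].
#' @return A [study_config()].
#' @export
decode_config <- function(payload) {
  lines <- strsplit(paste(payload, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0 || trimws(lines[1]) != CONFIG_MAGIC) {
    abort(paste0("not a configuration payload (expected '", CONFIG_MAGIC, "')"))
  }
  body <- lines[-1]
  eq <- regexpr("=", body, fixed = TRUE)
  if (any(eq < 0)) {
    abort("malformed payload line (expected key=value)")
  }
  keys <- substr(body, 1, eq - 1)
  vals <- substr(body, eq + 1, nchar(body))
  kv <- function(key) {
    i <- which(keys == key)
    if (length(i) == 0) NULL else vals[i[1]]
  }

  n_str <- kv("phases")
  if (is.null(n_str)) abort("configuration payload missing field: phases")
  n <- suppressWarnings(as.integer(n_str))
  if (is.na(n) || n < 1) abort("configuration field 'phases' must be >= 1")

  known_opts <- list(
    contextual = character(),
    continuous = c(
      "track_screen", "track_apps", "track_installs",
      "track_notifications"
    ),
    past = "retention_days"
  )

  recognized <- c("phases", "allow_duplicate_sources")
  phases <- vector("list", n)
  for (i in seq_len(n)) {
    src_key <- sprintf("phase.%d.source", i)
    src <- kv(src_key)
    if (is.null(src)) {
      abort(paste0("configuration payload missing field: ", src_key))
    }
    if (!src %in% names(known_opts)) {
      abort(paste0("unknown phase source: ", src))
    }
    recognized <- c(
      recognized, src_key,
      sprintf("phase.%d.%s", i, known_opts[[src]])
    )
    get_opt <- function(name, default, parse) {
      raw <- kv(sprintf("phase.%d.%s", i, name))
      if (is.null(raw)) default else parse(raw)
    }
    phases[[i]] <- switch(src,
      contextual = phase_contextual(),
      continuous = phase_continuous(
        track_screen = get_opt("track_screen", TRUE, parse_bool),
        track_apps = get_opt("track_apps", TRUE, parse_bool),
        track_installs = get_opt("track_installs", TRUE, parse_bool),
        track_notifications = get_opt("track_notifications", TRUE, parse_bool)
      ),
      past = phase_past(
        retention_days = get_opt("retention_days", 5, as.numeric)
      )
    )
  }

  unknown <- setdiff(keys, recognized)
  if (length(unknown) > 0) {
    warn(paste0(
      "ignoring unknown payload key(s): ", paste(unknown, collapse = ", ")
    ))
  }

  allow <- kv("allow_duplicate_sources")
  study_config(phases,
    allow_duplicate_sources = if (is.null(allow)) FALSE else parse_bool(allow)
  )
}

parse_bool <- function(x) tolower(trimws(x)) %in% c("true", "1", "yes")
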