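PASSWORD_CLASSES <- list(
  upper = strsplit("ABCDEFGHIJKLMNOPQRSTUVWXYZ", "")[[1]],
  lower = strsplit("abcdefghijklmnopqrstuvwxyz", "")[[1]],
  digit = strsplit("0123456789", "")[[1]],
  symbol = strsplit("!#$%&*+-=?@^", "")[[1]]
)

#' Generate an export password from consent-tap timestamps
#'
#' Participant-chosen passwords are weak, so export passwords are generated
#' automatically from *user-generated randomness*: the UNIX-millisecond
#' timestamps at which the participant tapped through the consent dialogs.
#' The tap list is shuffled, one value is drawn at random, and that value
#' seeds a character generator which emits `length` characters drawn from a
#' 74-character alphabet of uppercase, lowercase, digits, and symbols, with at
#' least one character from each class (a varied alphabet resists brute-force
#' search; not deriving from dictionary words resists dictionary attacks).
#'
#' The result is fully determined by `(taps, length, rng_seed)`; with a
#' single tap the selection is forced and the password depends only on that
#' timestamp and the requested length.
#'
#' @param taps Numeric vector of consent-tap timestamps (UNIX ms), non-empty.
#' @param length Password length, at least 8 (default 16).
#' @param rng_seed Seed for the shuffle-and-draw step. `NULL` uses the
#'   ambient RNG state (non-reproducible, as on a device).
#' @return A single string of `length` characters.
#' @export
#' @examples
#' generate_password(c(1.7e12, 1.7e12 + 804, 1.7e12 + 2377), rng_seed = 42)
generate_password <- function(taps, length = 16, rng_seed = NULL) {
  if (length(taps) == 0 || any(is.na(taps))) {
    abort("consent-tap log is empty: collect taps before generating a password")
  }
  if (!is.numeric(length) || length < 8) {
    abort("`length` must be at least 8")
  }
  length <- as.integer(length)
  if (any(taps <= 0)) abort("tap timestamps must be positive")
  draw <- function() {
    shuffled <- as.numeric(taps)[sample.int(length(taps))]
    shuffled[sample.int(length(shuffled), 1)]
  }
  chosen <- if (is.null(rng_seed)) draw() else withr::with_seed(rng_seed, draw())

  char_seed <- as.integer(chosen %% 2147483629)
  withr::with_seed(char_seed, {
    alphabet <- unlist(PASSWORD_CLASSES, use.names = FALSE)
    chars <- c(
      vapply(PASSWORD_CLASSES, function(cl) sample(cl, 1), character(1)),
      sample(alphabet, length - 4, replace = TRUE)
    )
    paste(sample(chars), collapse = "")
  })
}

EXPORT_MAGIC <- "PHONELOG-ENC/1"
KDF_ROUNDS <- 16L
PAYLOAD_KINDS <- c("continuous", "past", "usage", "context", "crash")

# password key stretch (bcrypt_pbkdf); 32-byte (256-bit) cipher key plus a
# separate MAC key derived from it
derive_keys <- function(password, salt, rounds = KDF_ROUNDS) {
  k <- openssl::bcrypt_pbkdf(password, salt, rounds = rounds, size = 32L)
  list(
    enc = k,
    mac = openssl::sha256(c(k, charToRaw("mac")))
  )
}

#' Encrypt a data table into a password-protected export container
#'
#' Data leaves the device only inside an encrypted container. The payload
#' (the table, serialized as CSV text) is encrypted with AES-256 in CBC mode
#' under a key stretched from the password with the salted bcrypt-pbkdf key
#' derivation, and authenticated with HMAC-SHA256 (encrypt-then-MAC), so a wrong
#' password fails cleanly with no partial plaintext. The container itself is
#' a small plain-text document: a key-value header plus a base64 body.
#'
#' @param table The payload: an `event_stream` (serialized to the canonical
#'   `timestamp,event,app` schema) or any data frame.
#' @param password Non-empty password string (see [generate_password()]).
#' @param payload_kind One of `"continuous"`, `"past"`, `"usage"`,
#'   `"context"`, `"crash"`; stored in the clear so readers can dispatch.
#' @return An `encrypted_export` object; `x$key_bits` reports the cipher key
#'   length (256).
#' @seealso [decrypt_export()], [write_export()], [read_export()]
#' @export
encrypt_export <- function(table, password, payload_kind = "continuous") {
  if (!is.character(password) || length(password) != 1 || !nzchar(password)) {
    abort("`password` must be a non-empty string")
  }
  payload_kind <- match.arg(payload_kind, PAYLOAD_KINDS)
  if (inherits(table, "event_stream")) {
    table <- stream_to_log_table(ensure_validated(table))
  }
  if (!is.data.frame(table)) abort("`table` must be a data frame")
  payload <- readr::format_csv(table, na = "")

  salt <- openssl::rand_bytes(16)
  iv <- openssl::rand_bytes(16)
  keys <- derive_keys(password, salt)
  ct <- openssl::aes_cbc_encrypt(charToRaw(payload), key = keys$enc, iv = iv)
  mac <- openssl::sha256(c(iv, ct), key = keys$mac)

  structure(
    list(
      magic = EXPORT_MAGIC,
      payload_kind = payload_kind,
      cipher = "AES-256-CBC",
      key_bits = 256L,
      kdf = "bcrypt-pbkdf",
      kdf_rounds = KDF_ROUNDS,
      salt = salt, iv = iv, mac = as.raw(mac), ciphertext = ct
    ),
    class = "encrypted_export"
  )
}

#' Decrypt an export container
#'
#' Verifies the authentication tag before decrypting: a wrong password or a
#' tampered container raises an authentication error and yields no partial
#' data. The decrypted payload is parsed back into a table; containers of
#' kind `"crash"` are parsed as crash reports (see [parse_crash_report()]),
#' event kinds (`"continuous"`, `"past"`, `"usage"`) as validated event
#' streams, and anything else as a plain tibble.
#'
#' @param container An `encrypted_export` (or a path readable by
#'   [read_export()]).
#' @param password The password the container was encrypted under.
#' @return The payload table (see Details).
#' @export
decrypt_export <- function(container, password) {
  if (is.character(container) && length(container) == 1) {
    container <- read_export(container)
  }
  if (!inherits(container, "encrypted_export")) {
    abort("`container` must be an encrypted_export or a path to one")
  }
  keys <- derive_keys(password, container$salt,
    rounds = container$kdf_rounds
  )
  mac <- openssl::sha256(c(container$iv, container$ciphertext), key = keys$mac)
  if (!identical(as.raw(mac), as.raw(container$mac))) {
    abort("authentication failed: wrong password or corrupted container")
  }
  payload <- rawToChar(openssl::aes_cbc_decrypt(container$ciphertext,
    key = keys$enc, iv = container$iv
  ))
  df <- readr::read_csv(payload,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE
  )
  kind <- container$payload_kind
  if (kind == "crash") {
    parse_crash_report(df)
  } else if (kind %in% c("continuous", "past") &&
    identical(names(df)[seq_len(min(3, ncol(df)))], c("timestamp", "event", "app"))) {
    log_table_to_stream(df, source = kind)
  } else {
    df
  }
}

#' Write / read an export container as a text file
#'
#' The on-disk form is line-oriented text: `key: value` header lines, a blank
#' line, then the base64-encoded ciphertext.
#'
#' @param container An `encrypted_export`.
#' @param path File path.
#' @return `write_export()` returns `path` invisibly; `read_export()` returns
#'   the `encrypted_export`.
#' @export
write_export <- function(container, path) {
  stopifnot(inherits(container, "encrypted_export"))
  b64 <- function(r) openssl::base64_encode(r)
  lines <- c(
    container$magic,
    paste0("payload_kind: ", container$payload_kind),
    paste0("cipher: ", container$cipher),
    paste0("key_bits: ", container$key_bits),
    paste0("kdf: ", container$kdf),
    paste0("kdf_rounds: ", container$kdf_rounds),
    paste0("salt: ", b64(container$salt)),
    paste0("iv: ", b64(container$iv)),
    paste0("mac: ", b64(container$mac)),
    "",
    chunk_string(b64(container$ciphertext), 76)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_export
#' @export
read_export <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 10 || lines[1] != EXPORT_MAGIC) {
    abort("not an export container (bad magic line)")
  }
  blank <- which(lines == "")[1]
  if (is.na(blank)) abort("corrupted container: missing body separator")
  hdr <- lines[2:(blank - 1)]
  sep <- regexpr(": ", hdr, fixed = TRUE)
  if (any(sep < 0)) abort("corrupted container: malformed header line")
  keys <- substr(hdr, 1, sep - 1)
  vals <- substr(hdr, sep + 2, nchar(hdr))
  get <- function(k) {
    i <- which(keys == k)
    if (length(i) == 0) abort(paste0("corrupted container: missing ", k))
    vals[i[1]]
  }
  structure(
    list(
      magic = EXPORT_MAGIC,
      payload_kind = get("payload_kind"),
      cipher = get("cipher"),
      key_bits = as.integer(get("key_bits")),
      kdf = get("kdf"),
      kdf_rounds = as.integer(get("kdf_rounds")),
      salt = openssl::base64_decode(get("salt")),
      iv = openssl::base64_decode(get("iv")),
      mac = openssl::base64_decode(get("mac")),
      ciphertext = openssl::base64_decode(
        paste(lines[(blank + 1):length(lines)], collapse = "")
      )
    ),
    class = "encrypted_export"
  )
}

chunk_string <- function(x, width) {
  if (nchar(x) == 0) {
    return(character(0))
  }
  starts <- seq(1, nchar(x), by = width)
  substring(x, starts, pmin(starts + width - 1, nchar(x)))
}

#' Parse a crash-report payload
#'
#' Crash reports travel in the same export container as raw data; each row
#' records the device manufacturer and model, the section of code where the
#' error occurred, and a timestamp. Malformed rows are rejected with reasons
#' (see [rejected_rows()]).
#'
#' @param rows A data frame with columns `manufacturer`, `model`,
#'   `code_location`, `timestamp` (UNIX ms).
#' @return A tibble of class `crash_report`, one row per valid report.
#' @export
parse_crash_report <- function(rows) {
  rows <- as_tibble(rows)
  required <- c("manufacturer", "model", "code_location", "timestamp")
  missing_cols <- setdiff(required, names(rows))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "crash payload missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(rows) == 0) {
    out <- tibble(
      manufacturer = character(), model = character(),
      code_location = character(), timestamp_ms = numeric()
    )
    class(out) <- c("crash_report", class(out))
    attr(out, "rejected") <- empty_rejects()
    return(out)
  }
  ts <- suppressWarnings(as.numeric(rows$timestamp))
  reason <- rep(NA_character_, nrow(rows))
  reason[!is.finite(ts) | ts <= 0] <- "missing or invalid timestamp"
  for (col in c("manufacturer", "model", "code_location")) {
    blank <- is.na(rows[[col]]) | !nzchar(trimws(as.character(rows[[col]])))
    reason[is.na(reason) & blank] <- paste0("missing ", col)
  }
  bad <- !is.na(reason)
  if (any(bad)) {
    warn(sprintf("rejected %d malformed crash-report row(s)", sum(bad)))
  }
  out <- tibble(
    manufacturer = as.character(rows$manufacturer)[!bad],
    model = as.character(rows$model)[!bad],
    code_location = as.character(rows$code_location)[!bad],
    timestamp_ms = ts[!bad]
  )
  class(out) <- c("crash_report", class(out))
  attr(out, "rejected") <- tibble(
    row = which(bad), timestamp_ms = ts[bad],
    type = NA_character_, app_id = NA_character_, reason = reason[bad]
  )
  out
}
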