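#' @keywords internal
"_PACKAGE"

# Classed conditions used across the package -----------------------------

pb_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "pb_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

pb_validation_error <- function(field, rule) {
  pb_stop("pb_validation_error",
          sprintf("configuration invalid: field '%s' violates rule: %s", field, rule),
          field = field, rule = rule)
}

pb_syntax_error <- function(msg) pb_stop("pb_syntax_error", msg)
pb_auth_error <- function(msg, ...) pb_stop("pb_authorization_error", msg, ...)
pb_state_error <- function(msg) pb_stop("pb_state_error", msg)
pb_duplicate_error <- function(msg, ticket = NULL)
  pb_stop("pb_duplicate_error", msg, ticket = ticket)
pb_notfound_error <- function(msg) pb_stop("pb_notfound_error", msg)
pb_usage_error <- function(msg) pb_stop("pb_usage_error", msg)
pb_io_error <- function(msg) pb_stop("pb_io_error", msg)
pb_audit_error <- function(msg) pb_stop("pb_audit_error", msg)
pb_unreachable_error <- function(msg) pb_stop("pb_endpoint_unreachable", msg)
pb_crypto_error <- function(msg) pb_stop("pb_crypto_auth_error", msg)

# Virtual clock -----------------------------------------------------------

#' Create an injectable clock
#'
#' All time-dependent components (scheduler windows, rate buckets, project
#' expiration, audit timestamps) read time through a clock object so tests
#' and simulations can run on virtual time. A clock created with a start
#' instant is virtual and only moves when advanced; a clock created without
#' one reads the system time.
#'
#' @param start optional `POSIXct` (or string parseable as UTC time). When
#'   given, the clock is virtual and starts frozen at this instant.
#' @return an environment with class `pb_clock`.
#' @export
new_clock <- function(start = NULL) {
  clk <- new.env(parent = emptyenv())
  if (is.null(start)) {
    clk$virtual <- FALSE
  } else {
    clk$virtual <- TRUE
    clk$now <- as_utc(start)
  }
  class(clk) <- "pb_clock"
  clk
}

#' @rdname new_clock
#' @param clock a `pb_clock`
#' @export
clock_now <- function(clock) {
  if (clock$virtual) clock$now else as_utc(Sys.time())
}

#' @rdname new_clock
#' @param seconds how far to advance a virtual clock
#' @export
clock_advance <- function(clock, seconds) {
  stopifnot(clock$virtual)
  clock$now <- clock$now + seconds
  invisible(clock$now)
}

as_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  as.POSIXct(x, tz = "UTC")
}

# Deterministic counter-based uniform deviates, independent of R's global
# RNG stream (used by mock-archive behaviors so package code never disturbs
# user-visible randomness).
hash_unif <- function(seed, counter) {
  h <- digest::digest(list(seed, counter), algo = "xxhash32", serialize = TRUE)
  strtoi(substr(h, 1, 7), base = 16L) / 16^7  # 28 bits, avoids int overflow
}

`%||%` <- function(a, b) if (is.null(a)) b else a

uint32_be <- function(n) {
  as.raw(c(bitwAnd(bitwShiftR(n, 24), 255L), bitwAnd(bitwShiftR(n, 16), 255L),
           bitwAnd(bitwShiftR(n, 8), 255L), bitwAnd(n, 255L)))
}

read_uint32_be <- function(r) {
  sum(as.integer(r) * c(2^24, 2^16, 2^8, 1))
}
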