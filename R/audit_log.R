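# Append-only audit trail.
#
# Contract: write-ahead with fail-closed semantics. Every access-relevant
# operation records its audit event durably BEFORE talking to an archive or
# returning a result; if the audit store cannot be written the triggering
# operation itself fails and no archive traffic occurs. Records are
# immutable once written; sequence numbers are strictly increasing with no
# gaps. The store is a tab-separated text file (one row per event) so
# administrators can review it with ordinary tools.

AUDIT_ACTIONS <- c("PATIENT_QUERY", "STUDY_QUERY", "RETRIEVE_REQUEST",
                   "RETRIEVE_COMPLETE", "RETRIEVE_FAIL", "CACHE_DOWNLOAD",
                   "CACHE_DELETE", "CACHE_FORWARD", "ACCESS_DENIED")

AUDIT_COLS <- c("seq", "timestamp", "user", "project_id", "endpoint_id",
                "action", "detail")

#' Open (or create) an audit log
#'
#' @param path file path of the tab-separated audit store
#' @return an `audit_log` handle
#' @export
new_audit_log <- function(path) {
  log <- new.env(parent = emptyenv())
  log$path <- path
  if (file.exists(path)) {
    ev <- audit_query(structure(log, class = "audit_log"))
    log$seq <- if (nrow(ev)) max(ev$seq) else 0L
  } else {
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    ok <- tryCatch({
      con <- file(path, open = "wt")
      writeLines(paste(AUDIT_COLS, collapse = "\t"), con)
      close(con)
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) pb_audit_error(sprintf("cannot create audit store at '%s'", path))
    log$seq <- 0L
  }
  class(log) <- "audit_log"
  log
}

#' Record one audit event (write-ahead, fail-closed)
#'
#' Appends the event durably and returns it. Callers must invoke this
#' before performing the action it describes; any failure to append is
#' raised as an audit error which the caller propagates, aborting the
#' action (fail-closed).
#'
#' @param log an `audit_log`
#' @param user,project_id actor and project charged
#' @param action one of the audit action codes (see Details)
#' @param detail free-form structured text (MRNs, accession numbers, UIDs,
#'   counts, reasons); newlines and tabs are escaped
#' @param endpoint_id optional archive endpoint involved
#' @param timestamp event time (UTC); defaults to the system clock
#' @details Actions: `r paste(AUDIT_ACTIONS, collapse = ", ")`.
#' @return the recorded event as a one-row data frame
#' @export
audit_record <- function(log, user, project_id, action, detail = "",
                         endpoint_id = NA_character_, timestamp = Sys.time()) {
  if (!action %in% AUDIT_ACTIONS)
    pb_stop("pb_bad_action", sprintf("unknown audit action '%s'", action))
  stopifnot(nzchar(user), nzchar(project_id))
  seq <- log$seq + 1L
  ts <- format(as_utc(timestamp), "%Y-%m-%dT%H:%M:%OS3Z")
  esc <- function(x) gsub("[\t\n\r]", " ", x)
  line <- paste(seq, ts, esc(user), esc(project_id),
                ifelse(is.na(endpoint_id), "-", esc(endpoint_id)),
                action, esc(detail), sep = "\t")
  ok <- tryCatch({
    con <- file(log$path, open = "at")
    on.exit(close(con), add = TRUE)
    writeLines(line, con)
    flush(con)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !audit_tail_is(log$path, seq))
    pb_audit_error(sprintf("audit store '%s' is not writable; action aborted",
                           log$path))
  log$seq <- seq
  data.frame(seq = seq, timestamp = ts, user = user, project_id = project_id,
             endpoint_id = endpoint_id, action = action, detail = detail,
             stringsAsFactors = FALSE)
}

# Durability check: the last line on disk must be the record just written
# (catches read-only files where open() silently succeeds).
audit_tail_is <- function(path, seq) {
  lines <- tryCatch(readLines(path, warn = FALSE), error = function(e) character(0))
  if (length(lines) < 2) return(FALSE)
  startsWith(lines[length(lines)], paste0(seq, "\t"))
}

#' Query the audit trail
#'
#' Returns all and only the matching events, in sequence order.
#'
#' @param log an `audit_log`
#' @param project_id,user,action optional equality filters
#' @param from,to optional UTC time range (inclusive)
#' @return a data frame with columns seq, timestamp, user, project_id,
#'   endpoint_id, action, detail
#' @export
audit_query <- function(log, project_id = NULL, user = NULL, action = NULL,
                        from = NULL, to = NULL) {
  empty <- data.frame(seq = integer(0), timestamp = character(0),
                      user = character(0), project_id = character(0),
                      endpoint_id = character(0), action = character(0),
                      detail = character(0), stringsAsFactors = FALSE)
  if (!file.exists(log$path)) return(empty)
  lines <- readLines(log$path, warn = FALSE)
  if (length(lines) < 2) return(empty)
  parts <- strsplit(lines[-1], "\t", fixed = TRUE)
  ev <- as.data.frame(do.call(rbind, lapply(parts, function(p) {
    length(p) <- 7L
    p
  })), stringsAsFactors = FALSE)
  names(ev) <- AUDIT_COLS
  ev$seq <- as.integer(ev$seq)
  ev$detail[is.na(ev$detail)] <- ""
  if (!is.null(project_id)) ev <- ev[ev$project_id %in% project_id, ]
  if (!is.null(user)) ev <- ev[ev$user %in% user, ]
  if (!is.null(action)) ev <- ev[ev$action %in% action, ]
  if (!is.null(from) || !is.null(to)) {
    t <- as.POSIXct(ev$timestamp, format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC")
    if (!is.null(from)) ev <- ev[t >= as_utc(from), , drop = FALSE]
    t <- as.POSIXct(ev$timestamp, format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC")
    if (!is.null(to)) ev <- ev[t <= as_utc(to), , drop = FALSE]
  }
  ev[order(ev$seq), , drop = FALSE]
}
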