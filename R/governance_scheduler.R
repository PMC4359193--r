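# Fair, rate- and window-governed retrieval scheduling.
#
# One FIFO queue per project; dispatch walks the project ring round-robin
# from a persistent cursor so every project is served fairly. Each archive
# endpoint carries a governance policy: time-of-day access windows with a
# studies-per-minute/hour rate, and a concurrency cap on active moves.
# The rate limiter is the sliding-window form of a token bucket: a
# dispatch is permitted only when fewer than rate_count dispatches
# happened in the trailing rate period, so the bound holds in EVERY
# sliding window, not merely in aligned ones. Crossing into a different
# access window clears the history (each window governs its own rate).

REQUEST_STATES <- c("SCHEDULED", "PROCESSING", "COMPLETED", "FAILED")

#' Look up the governance window in force at an instant
#'
#' Windows are half-open `[start, end)` in minutes of the service-local
#' day and start-inclusive, so a boundary instant belongs to the window it
#' opens. Returns the containing window, or `"blocked"` when no window
#' contains the instant (outside all windows means no archive access) or
#' the containing window has `rate_count` 0.
#'
#' @param policy a `governance_policy`
#' @param now a `POSIXct`
#' @param tz service time zone in which clinical "nights and weekends"
#'   are meant
#' @return the `access_window`, or the string `"blocked"`
#' @export
current_rate <- function(policy, now, tz = "UTC") {
  lt <- as.POSIXlt(as_utc(now), tz = tz)
  dow <- DAY_NAMES[((lt$wday + 6L) %% 7L) + 1L]   # wday: 0=Sun -> Mon-first
  minute <- lt$hour * 60L + lt$min + lt$sec / 60
  for (w in policy$windows)
    if (dow %in% w$days && minute >= w$start && minute < w$end)
      return(w)
  "blocked"
}

window_key <- function(w) paste(paste(w$days, collapse = ""), w$start, w$end)
rate_period_secs <- function(w) if (w$rate_period == "hour") 3600 else 60

#' Create a scheduler
#'
#' @param config a `system_config` (supplies per-endpoint policies and the
#'   project ring)
#' @param audit an `audit_log`; submission, completion, failure and
#'   dispatch-time denials are all recorded through it (write-ahead)
#' @param clock a [new_clock()]; virtual clocks make window/rate behavior
#'   fully deterministic in tests
#' @param usage_fn `function(project_id) -> used bytes`, consulted at
#'   dispatch time for the cache-quota gate; defaults to zero usage
#' @param store_path optional JSON file backing the request store: the
#'   request log, queues and round-robin cursor survive service restarts.
#'   A request that was in flight (PROCESSING) when the service stopped is
#'   reloaded as FAILED with reason "service restart".
#' @return a `scheduler` handle
#' @export
new_scheduler <- function(config, audit, clock = new_clock(),
                          usage_fn = function(project_id) 0,
                          store_path = NULL) {
  s <- new.env(parent = emptyenv())
  s$config <- config
  s$audit <- audit
  s$clock <- clock
  s$usage_fn <- usage_fn
  s$project_ring <- sort(unname(vapply(config$projects, `[[`, "", "id")))
  s$queues <- stats::setNames(
    replicate(length(s$project_ring), character(0), simplify = FALSE),
    s$project_ring)
  s$cursor <- if (length(s$project_ring)) s$project_ring[1] else NA_character_
  s$requests <- list()        # ticket id -> retrieval_request
  s$active <- list()          # endpoint id -> count of PROCESSING
  s$dispatch_hist <- list()   # endpoint id -> list(times=POSIXct, key=window key)
  s$ticket_n <- 0L
  s$store_path <- store_path
  s$dirty <- FALSE
  s$last_save <- 0
  class(s) <- "scheduler"
  if (!is.null(store_path) && file.exists(store_path)) sched_load(s)
  s
}

# -- request-store persistence (the durable "Request Log") ----------------

ts_chr <- function(t) if (is.null(t)) NA_character_ else
  format(as_utc(t), "%Y-%m-%dT%H:%M:%OS3Z")
ts_parse <- function(x) if (is.na(x)) NULL else
  as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC")

# Saves are debounced (at most ~2 writes/second under bulk mutation) and
# marked dirty otherwise; sched_flush() writes out pending state and is
# called at broker operation boundaries.
sched_save <- function(s, force = FALSE) {
  if (is.null(s$store_path)) return(invisible(s))
  now_wall <- as.numeric(Sys.time())
  if (!force && now_wall - s$last_save < 0.5) {
    s$dirty <- TRUE
    return(invisible(s))
  }
  s$last_save <- now_wall
  s$dirty <- FALSE
  doc <- list(
    cursor = s$cursor, ticket_n = s$ticket_n,
    queues = s$queues,
    requests = lapply(unname(s$requests), function(r) list(
      id = r$id, project_id = r$project_id, user = r$user,
      endpoint_id = r$endpoint_id, study_ref = r$study_ref,
      state = r$state, submitted_at = ts_chr(r$submitted_at),
      started_at = ts_chr(r$started_at), finished_at = ts_chr(r$finished_at),
      failure_reason = r$failure_reason)))
  dir.create(dirname(s$store_path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(doc, s$store_path, auto_unbox = TRUE, null = "null")
  invisible(s)
}

#' Flush pending request-store state to disk
#'
#' @param sched a `scheduler`
#' @export
sched_flush <- function(sched) {
  if (isTRUE(sched$dirty)) sched_save(sched, force = TRUE)
  invisible(sched)
}

sched_load <- function(s) {
  doc <- jsonlite::read_json(s$store_path)
  s$cursor <- doc$cursor %||% s$cursor
  s$ticket_n <- as.integer(doc$ticket_n %||% 0L)
  for (pid in names(s$queues))
    s$queues[[pid]] <- as.character(unlist(doc$queues[[pid]]))
  for (r in doc$requests) {
    req <- structure(list(
      id = r$id, project_id = r$project_id, user = r$user,
      endpoint_id = r$endpoint_id,
      study_ref = r$study_ref, state = r$state,
      submitted_at = ts_parse(r$submitted_at %||% NA_character_),
      started_at = ts_parse(r$started_at %||% NA_character_),
      finished_at = ts_parse(r$finished_at %||% NA_character_),
      failure_reason = r$failure_reason), class = "retrieval_request")
    if (identical(req$state, "PROCESSING")) {
      req$state <- "FAILED"
      req$finished_at <- clock_now(s$clock)
      req$failure_reason <- "service restart"
    }
    s$requests[[req$id]] <- req
  }
  invisible(s)
}

#' Submit a retrieval request (one request = one study)
#'
#' Authorization is checked here and re-checked at dispatch. A duplicate
#' (project, StudyInstanceUID) with a live ticket is refused.
#'
#' @param sched a `scheduler`
#' @param project a `project`
#' @param user submitting member
#' @param endpoint the `pacs_endpoint` holding the study
#' @param study_ref list with `study_instance_uid`, `accession_number`,
#'   `canonical_mrn`
#' @return the new `retrieval_request` (state SCHEDULED)
#' @export
submit_request <- function(sched, project, user, endpoint, study_ref) {
  now <- clock_now(sched$clock)
  dec <- authorize_study_retrieval(
    user, project, list(canonical_mrn = study_ref$canonical_mrn), now,
    tz = sched$config$timezone)
  if (!dec$allowed) {
    audit_record(sched$audit, user, project$id, "ACCESS_DENIED",
                 sprintf("retrieval of study %s denied: %s",
                         study_ref$study_instance_uid, dec$reason),
                 endpoint_id = endpoint$id, timestamp = now)
    pb_auth_error(sprintf("retrieval not authorized: %s", dec$reason),
                  reason = dec$reason)
  }
  dup <- Filter(function(r)
    r$project_id == project$id &&
      r$study_ref$study_instance_uid == study_ref$study_instance_uid &&
      r$state %in% c("SCHEDULED", "PROCESSING"),
    sched$requests)
  if (length(dup) > 0)
    pb_duplicate_error(sprintf(
      "study %s already has live ticket %s for project %s",
      study_ref$study_instance_uid, dup[[1]]$id, project$id),
      ticket = dup[[1]]$id)
  sched$ticket_n <- sched$ticket_n + 1L
  req <- structure(list(
    id = sprintf("T%06d", sched$ticket_n),
    project_id = project$id, user = user, endpoint_id = endpoint$id,
    study_ref = study_ref, state = "SCHEDULED",
    submitted_at = now, started_at = NULL, finished_at = NULL,
    failure_reason = NULL), class = "retrieval_request")
  audit_record(sched$audit, user, project$id, "RETRIEVE_REQUEST",
               sprintf("ticket %s study %s accession %s mrn %s", req$id,
                       study_ref$study_instance_uid,
                       study_ref$accession_number %||% "-",
                       study_ref$canonical_mrn),
               endpoint_id = endpoint$id, timestamp = now)
  sched$requests[[req$id]] <- req
  sched$queues[[project$id]] <- c(sched$queues[[project$id]], req$id)
  sched_save(sched)
  req
}

# prune dispatch history to the trailing period; returns count inside it
rate_used <- function(sched, eid, w, now) {
  h <- sched$dispatch_hist[[eid]]
  key <- window_key(w)
  if (is.null(h) || !identical(h$key, key)) {
    sched$dispatch_hist[[eid]] <- list(times = as_utc(now)[0], key = key)
    return(0L)
  }
  keep <- h$times > now - rate_period_secs(w)
  sched$dispatch_hist[[eid]]$times <- h$times[keep]
  sum(keep)
}

#' Dispatch the next retrieval request, if governance permits
#'
#' Walks the project ring from the cursor and pops the head of the first
#' queue whose request passes every gate: project still active (a queued
#' request whose project expired is failed and audited, never sent),
#' endpoint inside an open window with spare rate, concurrency below the
#' cap, and project cache under quota. Returns `NULL` when nothing may be
#' dispatched now. On success the request enters PROCESSING and the cursor
#' advances past the chosen project.
#'
#' @param sched a `scheduler`
#' @param now optional override of the scheduler clock
#' @return the dispatched `retrieval_request`, or `NULL`
#' @export
next_dispatch <- function(sched, now = clock_now(sched$clock)) {
  ring <- sched$project_ring
  if (length(ring) == 0) return(NULL)
  start <- match(sched$cursor, ring)
  if (is.na(start)) start <- 1L
  tz <- sched$config$timezone
  for (off in seq_along(ring) - 1L) {
    pid <- ring[((start - 1L + off) %% length(ring)) + 1L]
    repeat {
      q <- sched$queues[[pid]]
      if (length(q) == 0) break
      req <- sched$requests[[q[1]]]
      project <- sched$config$projects[[pid]]
      # dispatch-time re-authorization: expiry stops queued work
      if (!project_is_active(project, now, tz)) {
        audit_record(sched$audit, req$user, pid, "ACCESS_DENIED",
                     sprintf("ticket %s not dispatched: project expired", req$id),
                     endpoint_id = req$endpoint_id, timestamp = now)
        req$state <- "FAILED"
        req$finished_at <- now
        req$failure_reason <- "project expired before dispatch"
        sched$requests[[req$id]] <- req
        sched$queues[[pid]] <- q[-1]
        audit_record(sched$audit, req$user, pid, "RETRIEVE_FAIL",
                     sprintf("ticket %s: %s", req$id, req$failure_reason),
                     endpoint_id = req$endpoint_id, timestamp = now)
        sched_save(sched)
        next
      }
      eid <- req$endpoint_id
      policy <- sched$config$policies[[eid]]
      w <- current_rate(policy, now, tz)
      if (identical(w, "blocked") || w$rate_count == 0L) break
      if (policy$max_concurrent == 0L ||
          (sched$active[[eid]] %||% 0L) >= policy$max_concurrent) break
      if (rate_used(sched, eid, w, now) >= w$rate_count) break
      if (sched$usage_fn(pid) >= project$cache_quota_bytes) break
      # all gates passed: dispatch
      sched$queues[[pid]] <- q[-1]
      req$state <- "PROCESSING"
      req$started_at <- now
      sched$requests[[req$id]] <- req
      sched$active[[eid]] <- (sched$active[[eid]] %||% 0L) + 1L
      sched$dispatch_hist[[eid]]$times <-
        c(sched$dispatch_hist[[eid]]$times, as_utc(now))
      sched$cursor <- ring[(match(pid, ring) %% length(ring)) + 1L]
      sched_save(sched)
      return(req)
    }
  }
  NULL
}

#' Record the outcome of a dispatched retrieval
#'
#' Legal transitions: PROCESSING -> COMPLETED, PROCESSING -> FAILED (with
#' a reason). Anything else is a state error. Frees the endpoint
#' concurrency slot and audits the outcome.
#'
#' @param sched a `scheduler`
#' @param request the `retrieval_request` (or its ticket id)
#' @param outcome `"COMPLETED"` or `"FAILED"`
#' @param now optional override of the scheduler clock
#' @param failure_reason required when outcome is FAILED
#' @return the updated request
#' @export
transition <- function(sched, request, outcome,
                       now = clock_now(sched$clock), failure_reason = NULL) {
  id <- if (is.character(request)) request else request$id
  req <- sched$requests[[id]]
  if (is.null(req)) pb_notfound_error(sprintf("no such ticket '%s'", id))
  if (!outcome %in% c("COMPLETED", "FAILED"))
    pb_state_error(sprintf("invalid outcome '%s'", outcome))
  if (req$state != "PROCESSING")
    pb_state_error(sprintf("illegal transition %s -> %s for ticket %s",
                           req$state, outcome, id))
  if (outcome == "FAILED" && is.null(failure_reason))
    pb_state_error("FAILED outcome requires a failure_reason")
  audit_record(sched$audit, req$user, req$project_id,
               if (outcome == "COMPLETED") "RETRIEVE_COMPLETE" else "RETRIEVE_FAIL",
               sprintf("ticket %s study %s%s", id,
                       req$study_ref$study_instance_uid,
                       if (is.null(failure_reason)) ""
                       else paste0(": ", failure_reason)),
               endpoint_id = req$endpoint_id, timestamp = now)
  req$state <- outcome
  req$finished_at <- now
  req$failure_reason <- failure_reason
  sched$requests[[id]] <- req
  sched$active[[req$endpoint_id]] <-
    max(0L, (sched$active[[req$endpoint_id]] %||% 1L) - 1L)
  sched_save(sched)
  req
}

#' The request log (Tab-5 view)
#'
#' @param sched a `scheduler`
#' @param project_id,user,state optional filters
#' @return a data frame, one row per request, submission order
#' @export
request_log <- function(sched, project_id = NULL, user = NULL, state = NULL) {
  reqs <- sched$requests
  df <- do.call(rbind, lapply(reqs, function(r) data.frame(
    id = r$id, project_id = r$project_id, user = r$user,
    endpoint_id = r$endpoint_id,
    study_instance_uid = r$study_ref$study_instance_uid,
    accession_number = r$study_ref$accession_number %||% NA_character_,
    state = r$state,
    submitted_at = format(r$submitted_at, "%Y-%m-%dT%H:%M:%SZ"),
    failure_reason = r$failure_reason %||% NA_character_,
    stringsAsFactors = FALSE)))
  if (is.null(df)) df <- data.frame(
    id = character(0), project_id = character(0), user = character(0),
    endpoint_id = character(0), study_instance_uid = character(0),
    accession_number = character(0), state = character(0),
    submitted_at = character(0), failure_reason = character(0),
    stringsAsFactors = FALSE)
  if (!is.null(project_id)) df <- df[df$project_id %in% project_id, ]
  if (!is.null(user)) df <- df[df$user %in% user, ]
  if (!is.null(state)) df <- df[df$state %in% state, ]
  df <- df[order(df$id), , drop = FALSE]
  rownames(df) <- NULL
  df
}
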