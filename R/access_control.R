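# IRB-scoped access control: allowlist filtering, membership, expiration.
# Enforcement happens before any archive traffic is generated, and again at
# dispatch time (a project expiring while requests sit queued stops them).

#' Is a project currently active?
#'
#' A project with an expiration date is active through the whole of that
#' calendar date (inclusive-end convention, matching how IRB approval
#' periods are stated); access stops at the first instant of the following
#' day in the configured service time zone. A project without an
#' expiration never expires.
#'
#' @param project a `project` from the configuration
#' @param now a `POSIXct` instant
#' @param tz service time zone used to turn `now` into a calendar date
#' @return `TRUE` if the project may generate archive traffic at `now`
#' @export
project_is_active <- function(project, now, tz = "UTC") {
  if (is.null(project$expiration)) return(TRUE)
  as.Date(format(as_utc(now), tz = tz)) <= project$expiration
}

access_decision <- function(allowed, filtered, denied, reason) {
  structure(list(allowed = allowed,
                 filtered_mrns = filtered,
                 denied_mrns = denied,
                 reason = reason),
            class = "access_decision")
}

#' Authorize a patient-level query
#'
#' Filters the requested MRNs against the project allowlist. Denial is a
#' value, never an error, so every refusal can be audited. A mixed query
#' proceeds for the on-list subset; the off-list subset is reported in
#' `denied_mrns`.
#'
#' @param user username issuing the query
#' @param project the project the query is charged to
#' @param mrns canonical MRNs requested
#' @param now current instant
#' @param tz service time zone
#' @return an `access_decision` with fields `allowed`, `filtered_mrns`,
#'   `denied_mrns` and `reason` (one of OK, PROJECT_EXPIRED, NOT_MEMBER,
#'   EMPTY_AFTER_FILTER)
#' @export
authorize_patient_query <- function(user, project, mrns, now, tz = "UTC") {
  stopifnot(length(mrns) > 0)
  if (!user %in% project$members)
    return(access_decision(FALSE, character(0), mrns, "NOT_MEMBER"))
  if (!project_is_active(project, now, tz))
    return(access_decision(FALSE, character(0), mrns, "PROJECT_EXPIRED"))
  keep <- mrns[mrns %in% project$allowlist]
  deny <- mrns[!mrns %in% project$allowlist]
  if (length(keep) == 0)
    return(access_decision(FALSE, character(0), deny, "EMPTY_AFTER_FILTER"))
  access_decision(TRUE, keep, deny, "OK")
}

#' Authorize retrieval of one study
#'
#' Closes the loophole of retrieving a study whose patient is off-list:
#' allowed only when the project is active, the user is a member, and the
#' study's canonical MRN is on the allowlist.
#'
#' @param study a study record carrying `canonical_mrn`
#' @inheritParams authorize_patient_query
#' @export
authorize_study_retrieval <- function(user, project, study, now, tz = "UTC") {
  mrn <- study$canonical_mrn
  stopifnot(is.character(mrn), nzchar(mrn))
  if (!user %in% project$members)
    return(access_decision(FALSE, character(0), mrn, "NOT_MEMBER"))
  if (!project_is_active(project, now, tz))
    return(access_decision(FALSE, character(0), mrn, "PROJECT_EXPIRED"))
  if (!mrn %in% project$allowlist)
    return(access_decision(FALSE, character(0), mrn, "EMPTY_AFTER_FILTER"))
  access_decision(TRUE, mrn, character(0), "OK")
}
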