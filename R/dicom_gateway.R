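# Gateway between the broker and the archives: patient/study queries,
# governed study retrieval into staging, instance reception, C-STORE
# forwarding, and faceted filtering of result tables.
#
# Audit discipline: the audit event for a query is written BEFORE the
# archive sees any traffic (write-ahead, fail-closed), so an unwritable
# audit store stops the query and the archive observes nothing.

#' Build a faceted filter
#'
#' A filter is a conjunction over columns; each column predicate is either
#' a range over ordered values (dates, numbers) or a value set with
#' checkbox semantics (a multi-valued cell such as `"CT\\MR"` passes when
#' ANY of its values is in the set). A row survives iff it passes every
#' column predicate.
#'
#' @param ... per-column predicates created with [facet_range()] and
#'   [facet_set()]
#' @return a `facet_filter`
#' @examples
#' facet_filter(facet_range("study_date", "2009-01-01", "2012-01-01"),
#'              facet_set("modalities", c("MR", "US")))
#' @export
facet_filter <- function(...) {
  preds <- list(...)
  stopifnot(all(vapply(preds, inherits, TRUE, "facet_predicate")))
  structure(stats::setNames(preds, vapply(preds, `[[`, "", "column")),
            class = "facet_filter")
}

#' @rdname facet_filter
#' @param column column name the predicate applies to
#' @param min,max inclusive range bounds (either may be `NULL` for open)
#' @export
facet_range <- function(column, min = NULL, max = NULL) {
  structure(list(column = column, kind = "range", min = min, max = max),
            class = "facet_predicate")
}

#' @rdname facet_filter
#' @param values the checked set
#' @export
facet_set <- function(column, values) {
  structure(list(column = column, kind = "set", values = values),
            class = "facet_predicate")
}

#' Apply a faceted filter to a result table
#'
#' Row order is preserved; an empty or `NULL` filter is the identity.
#' Predicates naming columns absent from `rows` are ignored.
#'
#' @param rows a data frame of patient/study/cache/request rows
#' @param filter a [facet_filter()]
#' @return the surviving rows
#' @export
apply_facets <- function(rows, filter = NULL) {
  if (is.null(filter) || length(filter) == 0 || nrow(rows) == 0) return(rows)
  keep <- rep(TRUE, nrow(rows))
  for (p in filter) {
    if (!p$column %in% names(rows)) next
    col <- rows[[p$column]]
    pass <- if (p$kind == "set") {
      vapply(strsplit(as.character(col), "\\", fixed = TRUE),
             function(v) any(v %in% p$values), logical(1))
    } else {
      compare_range(col, p$min, p$max)
    }
    pass[is.na(pass)] <- FALSE
    keep <- keep & pass
  }
  out <- rows[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Range predicates compare numerically when the whole column parses as
# numbers (instance counts, byte sizes) and lexicographically otherwise
# (ISO dates, identifiers — both order correctly as strings).
compare_range <- function(col, lo, hi) {
  n <- suppressWarnings(as.numeric(col))
  if (!anyNA(n) && (is.null(lo) || !is.na(suppressWarnings(as.numeric(lo))))) {
    ok <- rep(TRUE, length(col))
    if (!is.null(lo)) ok <- ok & n >= as.numeric(lo)
    if (!is.null(hi)) ok <- ok & n <= as.numeric(hi)
    return(ok)
  }
  ok <- rep(TRUE, length(col))
  if (!is.null(lo)) ok <- ok & as.character(col) >= as.character(lo)
  if (!is.null(hi)) ok <- ok & as.character(col) <= as.character(hi)
  ok
}

#' Query an archive for patients
#'
#' Issues one patient-level query per authorized MRN (no wildcards) and
#' returns only patients that have at least one study. The PATIENT_QUERY
#' audit event is written before the archive is contacted.
#'
#' @param pacs the archive handle (a `mock_pacs` in tests)
#' @param endpoint the `pacs_endpoint` being queried
#' @param mrns canonical MRNs from an allowed access decision
#' @param filter optional [facet_filter()]
#' @param audit an `audit_log`
#' @param user,project_id actor attribution for the audit trail
#' @param now timestamp
#' @return data frame of patient rows: canonical_mrn, patient_name,
#'   birth_date, source_endpoint_id
#' @export
find_patients <- function(pacs, endpoint, mrns, filter = NULL,
                          audit, user, project_id, now = Sys.time()) {
  stopifnot(length(mrns) > 0)
  audit_record(audit, user, project_id, "PATIENT_QUERY",
               sprintf("mrns: %s", paste(mrns, collapse = ",")),
               endpoint_id = endpoint$id, timestamp = now)
  rows <- do.call(rbind, lapply(mrns, function(m)
    pacs_find(pacs, "PATIENT", "mrn", m)))
  rows <- unique(rows)
  if (nrow(rows) == 0)
    return(data.frame(canonical_mrn = character(0), patient_name = character(0),
                      birth_date = character(0),
                      source_endpoint_id = character(0),
                      stringsAsFactors = FALSE))
  out <- data.frame(canonical_mrn = rows$mrn, patient_name = rows$patient_name,
                    birth_date = rows$birth_date,
                    source_endpoint_id = endpoint$id, stringsAsFactors = FALSE)
  apply_facets(out, filter)
}

#' Query an archive for studies
#'
#' Keyed either by canonical MRNs (already authorized) or by accession
#' numbers (each resolved to its patient, who must be on the allowlist
#' before any result is released). Per patient, at most
#' `max_studies_per_patient` studies are returned, most recent StudyDate
#' first (ties by StudyInstanceUID), with `truncated_flag` set when the
#' limit clipped results.
#'
#' @param pacs archive handle
#' @param endpoint the `pacs_endpoint`
#' @param mrns,accessions exactly one must be given
#' @param filter optional [facet_filter()]
#' @param policy the endpoint's `governance_policy` (supplies the
#'   per-patient limit)
#' @param project the querying `project` (allowlist for accession-keyed
#'   lookups)
#' @param audit,user,now audit attribution
#' @return data frame of study rows (canonical_mrn, accession_number,
#'   study_instance_uid, study_date, modalities, study_description,
#'   institution, source_endpoint_id, n_instances, truncated_flag)
#' @export
find_studies <- function(pacs, endpoint, mrns = NULL, accessions = NULL,
                         filter = NULL, policy, project,
                         audit, user, now = Sys.time()) {
  if (is.null(mrns) == is.null(accessions))
    pb_usage_error("exactly one of mrns/accessions must be supplied")
  key_type <- if (is.null(mrns)) "accession" else "mrn"
  keys <- if (is.null(mrns)) accessions else mrns
  audit_record(audit, user, project$id, "STUDY_QUERY",
               sprintf("%s: %s", key_type, paste(keys, collapse = ",")),
               endpoint_id = endpoint$id, timestamp = now)
  rows <- do.call(rbind, lapply(keys, function(k)
    pacs_find(pacs, "STUDY", key_type, k)))
  rows <- unique(rows)
  if (key_type == "accession" && nrow(rows) > 0) {
    off <- unique(rows$mrn[!rows$mrn %in% project$allowlist])
    if (length(off) > 0) {
      audit_record(audit, user, project$id, "ACCESS_DENIED",
                   sprintf("accession lookup resolved to off-list mrn(s): %s",
                           paste(off, collapse = ",")),
                   endpoint_id = endpoint$id, timestamp = now)
      pb_auth_error("accession number resolves to a patient outside the project allowlist")
    }
  }
  empty <- data.frame(canonical_mrn = character(0), accession_number = character(0),
                      study_instance_uid = character(0), study_date = character(0),
                      modalities = character(0), study_description = character(0),
                      institution = character(0), source_endpoint_id = character(0),
                      n_instances = integer(0), truncated_flag = logical(0),
                      stringsAsFactors = FALSE)
  if (nrow(rows) == 0) return(empty)
  out <- data.frame(canonical_mrn = rows$mrn,
                    accession_number = rows$accession_number,
                    study_instance_uid = rows$study_instance_uid,
                    study_date = rows$study_date,
                    modalities = rows$modalities,
                    study_description = rows$study_description,
                    institution = rows$institution,
                    source_endpoint_id = endpoint$id,
                    n_instances = rows$n_instances,
                    truncated_flag = FALSE, stringsAsFactors = FALSE)
  limit <- policy$max_studies_per_patient
  if (!is.null(limit)) {
    pieces <- lapply(split(out, out$canonical_mrn), function(g) {
      g <- g[order(-xtfrm(g$study_date), g$study_instance_uid), , drop = FALSE]
      if (nrow(g) > limit) {
        g <- g[seq_len(limit), , drop = FALSE]
        g$truncated_flag <- TRUE
      }
      g
    })
    out <- do.call(rbind, pieces)
    rownames(out) <- NULL
  }
  apply_facets(out, filter)
}

#' Retrieve one dispatched study into staging
#'
#' Issues a study move addressed to the broker's own storage
#' application-entity. Success requires zero failed sub-operations and at
#' least one received instance; anything else is a failure with a reason
#' for the request log.
#'
#' @param pacs archive handle
#' @param request a `retrieval_request` in PROCESSING
#' @param broker_aet the broker's registered AE title
#' @param context passed to the storage receiver (project/ticket
#'   attribution)
#' @return the move outcome list (`status`, `completed`, `failed`,
#'   `reason`, `delay_seconds`)
#' @export
retrieve_study <- function(pacs, request, broker_aet, context = list()) {
  if (request$state != "PROCESSING")
    pb_state_error("retrieve_study requires a PROCESSING request")
  pacs_move(pacs, request$study_ref$study_instance_uid, broker_aet,
            context = c(context, list(ticket = request$id,
                                      project_id = request$project_id)))
}

#' Storage receiver: accept one instance into staging
#'
#' The broker's storage service. An instance is accepted only when an
#' active PROCESSING request matches its StudyInstanceUID; it is then
#' persisted as a Part-10 file in the owning project's staging area
#' (duplicate SOPInstanceUIDs overwrite idempotently). Unsolicited
#' instances are rejected and audited.
#'
#' @param staging_root staging directory root
#' @param sched the `scheduler` (source of active-request truth)
#' @param audit an `audit_log`
#' @param instance_bytes raw Part-10 bytes as received
#' @param context sender context (must name the ticket)
#' @return the staged file path, invisibly
#' @export
receive_instance <- function(staging_root, sched, audit, instance_bytes, context) {
  tmp <- tempfile(fileext = ".dcm")
  writeBin(instance_bytes, tmp)
  hdr <- dcm_read(tmp, c("StudyInstanceUID", "SOPInstanceUID"))
  live <- Filter(function(r) r$state == "PROCESSING" &&
                   r$study_ref$study_instance_uid == hdr$StudyInstanceUID,
                 sched$requests)
  if (length(live) == 0) {
    unlink(tmp)
    audit_record(audit, context$user %||% "-unknown-",
                 context$project_id %||% "-unknown-", "ACCESS_DENIED",
                 sprintf("unsolicited instance %s rejected (no active request)",
                         hdr$SOPInstanceUID))
    pb_stop("pb_unsolicited_instance",
            sprintf("no active request for study %s", hdr$StudyInstanceUID))
  }
  req <- live[[1]]
  dest <- file.path(staging_root, req$project_id, hdr$StudyInstanceUID)
  dir.create(dest, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dest, paste0(hdr$SOPInstanceUID, ".dcm"))
  file.rename(tmp, path) || {
    file.copy(tmp, path, overwrite = TRUE); unlink(tmp)
  }
  invisible(path)
}

#' Forward a cached study to another DICOM destination
#'
#' Sends every instance of the entry via store operations to the
#' destination AE (another archive, a research system, a workstation).
#' The cache is never modified.
#'
#' @param cr the `cache_repo`
#' @param project owning `project`
#' @param study_uid StudyInstanceUID of the cached entry
#' @param user acting member
#' @param dest_aet destination AE title
#' @param registry the AE registry holding the destination's receiver
#' @param now timestamp
#' @return data frame: one row per instance with `sop_uid` and `stored`
#' @export
forward_study <- function(cr, project, study_uid, user, dest_aet, registry,
                          now = Sys.time()) {
  if (!user %in% project$members)
    pb_auth_error(sprintf("user '%s' is not a member of project %s",
                          user, project$id))
  e <- get_entry(cr, project$id, study_uid)
  audit_record(cr$audit, user, project$id, "CACHE_FORWARD",
               sprintf("study %s to AE %s", study_uid, dest_aet),
               timestamp = now)
  if (!exists(dest_aet, envir = registry, inherits = FALSE))
    pb_unreachable_error(sprintf("destination AE '%s' unreachable", dest_aet))
  receiver <- get(dest_aet, envir = registry)
  rows <- lapply(e$file_layout, function(fl) {
    ok <- tryCatch({
      receiver(readBin(fl$file, "raw", n = file.size(fl$file)),
               list(study_uid = study_uid, sop_uid = fl$sop_uid))
      TRUE
    }, error = function(err) FALSE)
    data.frame(sop_uid = fl$sop_uid, stored = ok, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
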