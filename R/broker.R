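# The broker service: one object wiring configuration, access control,
# audit, scheduler, gateway, cache and archive connections together. This
# is what the CLI drives and what end-to-end tests exercise.

BROKER_AET <- "RESEARCH_BROKER"

#' Start a broker service
#'
#' Opens the audit store, the cache repository and the scheduler, and
#' connects the configured archive endpoints. An endpoint whose `host` has
#' the form `mock:<fixture.yaml>` is served by an in-process mock archive
#' generated deterministically from that fixture specification; tests may
#' also attach a mock directly with [broker_attach_pacs()].
#'
#' @param config a `system_config` from [load_config()]
#' @param clock a [new_clock()] (virtual in tests/simulations)
#' @return a `broker` handle
#' @export
broker_new <- function(config, clock = new_clock()) {
  b <- new.env(parent = emptyenv())
  b$config <- config
  b$clock <- clock
  b$aet <- BROKER_AET
  b$audit <- new_audit_log(config$audit_store)
  b$cache <- new_cache_repo(config$cache_root, b$audit)
  b$staging <- file.path(config$cache_root, "staging")
  dir.create(b$staging, recursive = TRUE, showWarnings = FALSE)
  b$registry <- new.env(parent = emptyenv())
  b$sched <- new_scheduler(config, b$audit, clock,
                           usage_fn = function(pid)
                             cache_usage(b$cache, config$projects[[pid]])$used_bytes,
                           store_path = file.path(config$cache_root, "state",
                                                  "requests.json"))
  assign(b$aet, function(bytes, context)
    receive_instance(b$staging, b$sched, b$audit, bytes, context),
    envir = b$registry)
  b$pacs <- list()
  for (e in config$endpoints)
    if (startsWith(e$host, "mock:"))
      broker_attach_pacs(b, e$id,
                         mock_pacs_from_fixture(sub("^mock:", "", e$host),
                                                ae_registry = b$registry))
  class(b) <- "broker"
  b
}

#' Attach an archive connection to an endpoint id
#'
#' @param b a `broker`
#' @param endpoint_id configured endpoint the handle serves
#' @param pacs the archive handle (a `mock_pacs`)
#' @export
broker_attach_pacs <- function(b, endpoint_id, pacs) {
  stopifnot(endpoint_id %in% names(b$config$endpoints))
  pacs$registry <- b$registry
  b$pacs[[endpoint_id]] <- pacs
  invisible(b)
}

#' Instantiate a mock archive from a fixture specification file
#'
#' The fixture file is YAML with a `behavior` mapping (see
#' [mock_behavior()]) and a `studies` list of [synthetic_study_spec()]
#' fields. Identical files always produce identical archives.
#'
#' @param path fixture YAML
#' @param ae_registry registry the archive resolves move destinations in
#' @return a `mock_pacs`
#' @export
mock_pacs_from_fixture <- function(path, ae_registry = new.env(parent = emptyenv())) {
  doc <- yaml::yaml.load_file(path)
  studies <- lapply(doc$studies, function(s)
    generate_study(do.call(synthetic_study_spec, s)))
  beh <- do.call(mock_behavior, doc$behavior %||% list())
  serve_mock_pacs(studies, beh, ae_registry)
}

broker_pacs <- function(b, endpoint_id) {
  p <- b$pacs[[endpoint_id]]
  if (is.null(p))
    pb_unreachable_error(sprintf("endpoint '%s' has no archive connection",
                                 endpoint_id))
  p
}

broker_project <- function(b, project_id) {
  p <- b$config$projects[[project_id]]
  if (is.null(p)) pb_notfound_error(sprintf("unknown project '%s'", project_id))
  p
}

# Allowlists are stored in the endpoint-independent default canonical form;
# an endpoint's own rule (e.g. zero-padding) may map into a different
# canonical space. For endpoint-bound authorization the allowlist is viewed
# through that endpoint's rule — normalization is idempotent, so entries
# already in endpoint form are unchanged.
project_for_endpoint <- function(project, endpoint) {
  project$allowlist <- unique(normalize_mrn(project$allowlist,
                                            endpoint$mrn_rule))
  project
}

# audits each denied-MRN set exactly once, as the access module requires
audit_denials <- function(b, user, project_id, endpoint_id, dec, what, now) {
  if (length(dec$denied_mrns) > 0)
    audit_record(b$audit, user, project_id, "ACCESS_DENIED",
                 sprintf("%s denied (%s): %s", what, dec$reason,
                         paste(dec$denied_mrns, collapse = ",")),
                 endpoint_id = endpoint_id, timestamp = now)
  invisible(dec)
}

#' Search an archive for patients on behalf of a project
#'
#' Raw MRNs are normalized with the endpoint's format rule, filtered
#' against the project allowlist (off-list identifiers are denied,
#' audited, and never reach the archive), and the surviving set is
#' queried.
#'
#' @param b a `broker`
#' @param project_id,user acting project and member
#' @param endpoint_id archive to query
#' @param mrns raw MRNs as supplied by the user
#' @param filter optional [facet_filter()]
#' @return list with the access `decision` and the `patients` data frame
#' @export
broker_find_patients <- function(b, project_id, user, endpoint_id, mrns,
                                 filter = NULL) {
  now <- clock_now(b$clock)
  ep <- b$config$endpoints[[endpoint_id]]
  project <- project_for_endpoint(broker_project(b, project_id), ep)
  canon <- unique(normalize_mrn(mrns, ep$mrn_rule))
  dec <- authorize_patient_query(user, project, canon, now,
                                 tz = b$config$timezone)
  audit_denials(b, user, project_id, endpoint_id, dec, "patient query", now)
  if (!dec$allowed)
    return(list(decision = dec, patients = data.frame(
      canonical_mrn = character(0), patient_name = character(0),
      birth_date = character(0), source_endpoint_id = character(0),
      stringsAsFactors = FALSE)))
  pats <- find_patients(broker_pacs(b, endpoint_id), ep, dec$filtered_mrns,
                        filter, b$audit, user, project_id, now = now)
  list(decision = dec, patients = pats)
}

#' Search an archive for studies on behalf of a project
#'
#' MRN-keyed searches are allowlist-filtered before the archive sees
#' them; accession-keyed searches resolve to a patient inside the gateway
#' and fail (audited) when that patient is off-list.
#'
#' @inheritParams broker_find_patients
#' @param accessions accession numbers (alternative to `mrns`)
#' @return list with the `decision` (MRN-keyed only) and `studies`
#' @export
broker_find_studies <- function(b, project_id, user, endpoint_id,
                                mrns = NULL, accessions = NULL, filter = NULL) {
  now <- clock_now(b$clock)
  ep <- b$config$endpoints[[endpoint_id]]
  project <- project_for_endpoint(broker_project(b, project_id), ep)
  policy <- b$config$policies[[endpoint_id]]
  dec <- NULL
  if (!is.null(mrns)) {
    canon <- unique(normalize_mrn(mrns, ep$mrn_rule))
    dec <- authorize_patient_query(user, project, canon, now,
                                   tz = b$config$timezone)
    audit_denials(b, user, project_id, endpoint_id, dec, "study query", now)
    if (!dec$allowed)
      return(list(decision = dec, studies = NULL))
    mrns <- dec$filtered_mrns
  } else {
    if (!user %in% project$members) pb_auth_error("not a project member")
    if (!project_is_active(project, now, b$config$timezone)) {
      audit_record(b$audit, user, project_id, "ACCESS_DENIED",
                   "study query denied (PROJECT_EXPIRED)",
                   endpoint_id = endpoint_id, timestamp = now)
      pb_auth_error("project expired")
    }
  }
  st <- find_studies(broker_pacs(b, endpoint_id), ep, mrns = mrns,
                     accessions = accessions, filter = filter,
                     policy = policy, project = project,
                     audit = b$audit, user = user, now = now)
  list(decision = dec, studies = st)
}

#' Submit a retrieval request for one study
#'
#' @param b a `broker`
#' @param project_id,user acting project and member
#' @param endpoint_id archive holding the study
#' @param study one row of a [broker_find_studies()] result (or a list
#'   with canonical_mrn, accession_number, study_instance_uid)
#' @return the `retrieval_request` ticket
#' @export
broker_request <- function(b, project_id, user, endpoint_id, study) {
  ep <- b$config$endpoints[[endpoint_id]]
  req <- submit_request(b$sched,
                        project_for_endpoint(broker_project(b, project_id), ep),
                        user, ep,
                        list(study_instance_uid = study$study_instance_uid,
                             accession_number = study$accession_number,
                             canonical_mrn = study$canonical_mrn))
  sched_flush(b$sched)
  req
}

#' Run the dispatch/retrieve/admit loop
#'
#' Pumps the scheduler: each step dispatches the next permissible request,
#' performs the study move into staging, admits the study into the
#' project cache on success and records the outcome. Stops when
#' governance permits no further dispatch (advance the virtual clock and
#' pump again to continue).
#'
#' @param b a `broker`
#' @param max_steps safety bound on dispatches in this call
#' @return number of requests dispatched, invisibly
#' @export
broker_pump <- function(b, max_steps = 1000L) {
  n <- 0L
  on.exit(sched_flush(b$sched))
  while (n < max_steps) {
    req <- next_dispatch(b$sched)
    if (is.null(req)) break
    n <- n + 1L
    pacs <- tryCatch(broker_pacs(b, req$endpoint_id), error = function(e) NULL)
    outcome <- if (is.null(pacs))
      list(status = "FAILED", reason = "endpoint unreachable")
    else tryCatch(
      retrieve_study(pacs, req, b$aet,
                     context = list(user = req$user,
                                    project_id = req$project_id)),
      error = function(e) list(status = "FAILED",
                               reason = conditionMessage(e)))
    if (identical(outcome$status, "COMPLETED")) {
      staged <- file.path(b$staging, req$project_id,
                          req$study_ref$study_instance_uid)
      admitted <- tryCatch({
        admit_study(b$cache, broker_project(b, req$project_id), staged,
                    now = clock_now(b$clock))
        TRUE
      }, error = function(e) {
        outcome$reason <<- conditionMessage(e)
        FALSE
      })
      if (admitted) transition(b$sched, req, "COMPLETED")
      else transition(b$sched, req, "FAILED",
                      failure_reason = outcome$reason %||% "cache admission failed")
    } else {
      transition(b$sched, req, "FAILED",
                 failure_reason = outcome$reason %||% "move failed")
    }
  }
  invisible(n)
}

#' @rdname broker_pump
#' @details `broker_run_until_idle()` alternates pumping with advancing a
#'   virtual clock, until every queue is empty or `max_virtual_seconds`
#'   of simulated time have elapsed.
#' @param step_seconds virtual seconds advanced between pump rounds
#' @param max_virtual_seconds simulation budget
#' @export
broker_run_until_idle <- function(b, step_seconds = 1,
                                  max_virtual_seconds = 7 * 86400) {
  stopifnot(b$clock$virtual)
  elapsed <- 0
  repeat {
    broker_pump(b)
    if (all(vapply(b$sched$queues, length, 0L) == 0)) break
    if (elapsed >= max_virtual_seconds) break
    clock_advance(b$clock, step_seconds)
    elapsed <- elapsed + step_seconds
  }
  invisible(b)
}

#' Download a cached study to local storage
#' @inheritParams broker_request
#' @param study_uid cached StudyInstanceUID
#' @param destination target directory
#' @param encrypt,passphrase encrypted export controls
#' @export
broker_download <- function(b, project_id, user, study_uid, destination,
                            encrypt = FALSE, passphrase = NULL) {
  export_study(b$cache, broker_project(b, project_id), study_uid, user,
               destination, encrypt = encrypt, passphrase = passphrase,
               now = clock_now(b$clock))
}

#' Delete a cached study
#' @inheritParams broker_download
#' @export
broker_delete <- function(b, project_id, user, study_uid) {
  delete_study(b$cache, broker_project(b, project_id), study_uid, user,
               now = clock_now(b$clock))
}

#' Forward a cached study to another DICOM destination
#' @inheritParams broker_download
#' @param dest_aet destination AE title (must be registered)
#' @export
broker_forward <- function(b, project_id, user, study_uid, dest_aet) {
  forward_study(b$cache, broker_project(b, project_id), study_uid, user,
                dest_aet, b$registry, now = clock_now(b$clock))
}
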