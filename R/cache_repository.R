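# Per-project, quota-limited image repository.
#
# Layout on disk: <root>/cache/<project_id>/<study_uid>/<files>. Quota is
# enforced as a dispatch gate (see the scheduler) plus truthful overflow
# accounting here: a study's size is unknown before it arrives, so an
# admission may push a project over quota; the project is then blocked
# from further dispatch until the user deletes entries.

#' Open a cache repository rooted at a directory
#'
#' @param root cache root directory (created if needed)
#' @param audit an `audit_log` for download/delete/forward events
#' @return a `cache_repo` handle
#' @export
new_cache_repo <- function(root, audit) {
  cr <- new.env(parent = emptyenv())
  cr$root <- root
  cr$audit <- audit
  cr$entries <- list()   # "<project>|<study_uid>" -> cache_entry
  dir.create(file.path(root, "cache"), recursive = TRUE, showWarnings = FALSE)
  class(cr) <- "cache_repo"
  # rebuild the index from the on-disk tree, so a repo (and its usage
  # accounting) survives service restarts; the directory is the truth
  for (pid in list.dirs(file.path(root, "cache"), recursive = FALSE,
                        full.names = FALSE))
    for (sdir in list.dirs(file.path(root, "cache", pid), recursive = FALSE))
      tryCatch({
        e <- entry_from_dir(pid, sdir)
        cr$entries[[entry_key(pid, e$study_instance_uid)]] <- e
      }, error = function(err) NULL)
  cr
}

entry_from_dir <- function(project_id, dir, now = file.mtime(dir)) {
  files <- list.files(dir, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) == 0) pb_stop("pb_empty_study", "no instances")
  info <- lapply(files, function(f)
    dcm_read(f, c("StudyInstanceUID", "SOPInstanceUID", "SeriesNumber",
                  "InstanceNumber", "AccessionNumber", "PatientID",
                  "Modality", "StudyDate")))
  ord <- order(as.integer(vapply(info, `[[`, "", "SeriesNumber")),
               as.integer(vapply(info, `[[`, "", "InstanceNumber")),
               vapply(info, `[[`, "", "SOPInstanceUID"))
  layout <- lapply(ord, function(i)
    list(sop_uid = info[[i]]$SOPInstanceUID,
         series_number = as.integer(info[[i]]$SeriesNumber),
         instance_number = as.integer(info[[i]]$InstanceNumber),
         file = files[i], bytes = file.size(files[i])))
  structure(list(
    project_id = project_id,
    study_instance_uid = info[[1]]$StudyInstanceUID,
    accession_number = info[[1]]$AccessionNumber,
    canonical_mrn = info[[1]]$PatientID,
    modalities = paste(sort(unique(vapply(info, `[[`, "", "Modality"))),
                       collapse = "\\"),
    study_date = info[[1]]$StudyDate,
    instance_count = length(files),
    total_bytes = sum(file.size(files)),
    admitted_at = as_utc(now), file_layout = layout),
    class = "cache_entry")
}

entry_key <- function(project_id, study_uid) paste(project_id, study_uid, sep = "|")

#' Admit a staged study into a project's cache
#'
#' Atomically moves all staged instance files for one study into the
#' project cache and records a `cache_entry`. All files must share one
#' StudyInstanceUID; the file layout is ordered by (SeriesNumber,
#' InstanceNumber, SOPInstanceUID). Admission proceeds even when it
#' overflows the quota — gating happens at dispatch time.
#'
#' @param cr a `cache_repo`
#' @param project the owning `project`
#' @param staging_dir directory containing the staged Part-10 files
#' @param now admission timestamp
#' @return the new `cache_entry`
#' @export
admit_study <- function(cr, project, staging_dir, now = Sys.time()) {
  files <- list.files(staging_dir, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) == 0)
    pb_stop("pb_empty_study", "staging area holds no instances")
  info <- lapply(files, function(f)
    dcm_read(f, c("StudyInstanceUID", "SOPInstanceUID", "SeriesNumber",
                  "InstanceNumber", "AccessionNumber", "PatientID",
                  "Modality", "StudyDate")))
  uids <- unique(vapply(info, `[[`, "", "StudyInstanceUID"))
  if (length(uids) != 1)
    pb_stop("pb_staging_corruption",
            sprintf("staging area mixes %d StudyInstanceUIDs", length(uids)))
  ord <- order(as.integer(vapply(info, `[[`, "", "SeriesNumber")),
               as.integer(vapply(info, `[[`, "", "InstanceNumber")),
               vapply(info, `[[`, "", "SOPInstanceUID"))
  dest <- file.path(cr$root, "cache", project$id, uids)
  dir.create(dest, recursive = TRUE, showWarnings = FALSE)
  layout <- vector("list", length(ord))
  total <- 0
  for (k in seq_along(ord)) {
    i <- ord[k]
    to <- file.path(dest, basename(files[i]))
    if (!file.rename(files[i], to)) {
      file.copy(files[i], to, overwrite = TRUE)
      unlink(files[i])
    }
    sz <- file.size(to)
    total <- total + sz
    layout[[k]] <- list(sop_uid = info[[i]]$SOPInstanceUID,
                        series_number = as.integer(info[[i]]$SeriesNumber),
                        instance_number = as.integer(info[[i]]$InstanceNumber),
                        file = to, bytes = sz)
  }
  entry <- structure(list(
    project_id = project$id, study_instance_uid = uids,
    accession_number = info[[1]]$AccessionNumber,
    canonical_mrn = info[[1]]$PatientID,
    modalities = paste(sort(unique(vapply(info, `[[`, "", "Modality"))),
                       collapse = "\\"),
    study_date = info[[1]]$StudyDate,
    instance_count = length(files), total_bytes = total,
    admitted_at = as_utc(now), file_layout = layout),
    class = "cache_entry")
  cr$entries[[entry_key(project$id, uids)]] <- entry
  unlink(staging_dir, recursive = TRUE)
  entry
}

#' Report a project's cache usage
#'
#' `used_bytes` is reported truthfully even when above quota (overflow
#' from an in-flight admission).
#'
#' @param cr a `cache_repo`
#' @param project a `project` (supplies the quota)
#' @return a `cache_usage` list: project_id, used_bytes, quota_bytes, entries
#' @export
cache_usage <- function(cr, project) {
  mine <- Filter(function(e) e$project_id == project$id, cr$entries)
  structure(list(project_id = project$id,
                 used_bytes = sum(vapply(mine, `[[`, 0, "total_bytes")),
                 quota_bytes = project$cache_quota_bytes,
                 entries = length(mine)),
            class = "cache_usage")
}

#' List a project's cache entries
#'
#' Entries are returned newest-admitted first, optionally facet-filtered
#' with the same conjunction-of-disjunctions semantics as search results.
#'
#' @param cr a `cache_repo`
#' @param project a `project`
#' @param filter optional [facet_filter()] over columns
#'   study_instance_uid, accession_number, canonical_mrn, modalities,
#'   study_date, instance_count, total_bytes
#' @return a data frame, one row per entry
#' @export
list_entries <- function(cr, project, filter = NULL) {
  mine <- Filter(function(e) e$project_id == project$id, cr$entries)
  df <- do.call(rbind, lapply(mine, function(e) data.frame(
    study_instance_uid = e$study_instance_uid,
    accession_number = e$accession_number,
    canonical_mrn = e$canonical_mrn,
    modalities = e$modalities,
    study_date = as.character(as.Date(e$study_date, format = "%Y%m%d")),
    instance_count = e$instance_count,
    total_bytes = e$total_bytes,
    admitted_at = format(e$admitted_at, "%Y-%m-%dT%H:%M:%OS3Z"),
    stringsAsFactors = FALSE)))
  if (is.null(df)) return(data.frame(
    study_instance_uid = character(0), accession_number = character(0),
    canonical_mrn = character(0), modalities = character(0),
    study_date = character(0), instance_count = integer(0),
    total_bytes = numeric(0), admitted_at = character(0),
    stringsAsFactors = FALSE))
  rownames(df) <- NULL
  df <- df[order(df$admitted_at, df$study_instance_uid,
                 decreasing = TRUE), , drop = FALSE]
  if (!is.null(filter)) df <- apply_facets(df, filter)
  rownames(df) <- NULL
  df
}

get_entry <- function(cr, project_id, study_uid) {
  e <- cr$entries[[entry_key(project_id, study_uid)]]
  if (is.null(e))
    pb_notfound_error(sprintf("no cache entry for study %s in project %s",
                              study_uid, project_id))
  e
}

#' Delete a cached study
#'
#' Removes the entry's files, decrements usage and audits CACHE_DELETE.
#' Deleting is the only way a project over quota becomes dispatchable
#' again.
#'
#' @param cr a `cache_repo`
#' @param project the owning `project`
#' @param study_uid StudyInstanceUID of the entry
#' @param user acting member
#' @param now timestamp
#' @return the updated `cache_usage`
#' @export
delete_study <- function(cr, project, study_uid, user, now = Sys.time()) {
  if (!user %in% project$members)
    pb_auth_error(sprintf("user '%s' is not a member of project %s",
                          user, project$id))
  e <- get_entry(cr, project$id, study_uid)
  audit_record(cr$audit, user, project$id, "CACHE_DELETE",
               sprintf("study %s (%d instances, %.0f bytes)",
                       study_uid, e$instance_count, e$total_bytes),
               timestamp = now)
  unlink(dirname(e$file_layout[[1]]$file), recursive = TRUE)
  cr$entries[[entry_key(project$id, study_uid)]] <- NULL
  cache_usage(cr, project)
}

#' Export a cached study to local storage
#'
#' Plaintext mode copies the Part-10 files byte-identically under a
#' `<mrn>/<study_uid>/<series>/<instance>.dcm` tree. Encrypted mode
#' delegates to the crypto store: only ciphertext containers with
#' obfuscated names reach the destination. Either way the download is
#' audited with its date and time.
#'
#' @param cr a `cache_repo`
#' @param project the owning `project`
#' @param study_uid StudyInstanceUID of the entry
#' @param user acting member
#' @param destination target directory
#' @param encrypt encrypt the export
#' @param passphrase required iff `encrypt`
#' @param now timestamp
#' @return an export manifest: data frame of written files (plaintext) or
#'   the `obfuscation_manifest` (encrypted)
#' @export
export_study <- function(cr, project, study_uid, user, destination,
                         encrypt = FALSE, passphrase = NULL, now = Sys.time()) {
  if (!user %in% project$members)
    pb_auth_error(sprintf("user '%s' is not a member of project %s",
                          user, project$id))
  if (encrypt && (is.null(passphrase) || !nzchar(passphrase)))
    pb_usage_error("encrypted export requires a passphrase")
  e <- get_entry(cr, project$id, study_uid)
  audit_record(cr$audit, user, project$id, "CACHE_DOWNLOAD",
               sprintf("study %s to local storage (%s)", study_uid,
                       if (encrypt) "encrypted" else "plaintext"),
               timestamp = now)
  if (encrypt)
    return(export_encrypted(e, destination, passphrase))
  rows <- lapply(e$file_layout, function(fl) {
    dest <- file.path(destination, e$canonical_mrn, e$study_instance_uid,
                      fl$series_number)
    dir.create(dest, recursive = TRUE, showWarnings = FALSE)
    to <- file.path(dest, sprintf("%06d.dcm", fl$instance_number))
    if (!file.copy(fl$file, to, overwrite = TRUE))
      pb_io_error(sprintf("cannot write '%s'", to))
    data.frame(source = fl$file, destination = to,
               bytes = file.size(to), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
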