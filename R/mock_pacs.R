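# Synthetic DICOM fixtures and a configurable mock archive.
#
# The generator emits standards-valid secondary-capture studies whose
# identifiers are deterministic functions of a seed, so a spec generated
# twice is byte-identical. The mock archive indexes generated studies and
# answers patient/study queries and study moves the way a clinical PACS
# would, while recording every query it sees — tests use that record to
# prove the broker never leaks an off-list MRN onto the wire.

#' Describe one synthetic study
#'
#' @param seed integer controlling every identifier and pixel byte
#' @param canonical_mrn patient identifier in canonical form
#' @param accession_number examination identifier
#' @param study_date ISO date string
#' @param n_series,instances_per_series study shape (both >= 1)
#' @param modality DICOM modality code (e.g. MR, CT, US)
#' @param pixel_dims edge length of the square 8-bit image (default 32)
#' @param patient_name,birth_date,study_description,institution optional
#'   demographic/context attributes
#' @param target_bytes optional approximate on-disk size per instance; the
#'   excess over the natural size is carried in a trailing padding element
#'   so quota accounting can be exercised at realistic scales without
#'   realistic files
#' @return a `synthetic_study_spec`
#' @export
synthetic_study_spec <- function(seed, canonical_mrn, accession_number,
                                 study_date, n_series = 1L,
                                 instances_per_series = 1L, modality = "MR",
                                 pixel_dims = 32L,
                                 patient_name = NULL, birth_date = "19700101",
                                 study_description = "SYNTHETIC STUDY",
                                 institution = "Mock General Hospital",
                                 target_bytes = NULL) {
  stopifnot(n_series >= 1, instances_per_series >= 1, pixel_dims >= 1)
  structure(list(seed = as.integer(seed), canonical_mrn = canonical_mrn,
                 accession_number = accession_number, study_date = study_date,
                 n_series = as.integer(n_series),
                 instances_per_series = as.integer(instances_per_series),
                 modality = modality, pixel_dims = as.integer(pixel_dims),
                 patient_name = patient_name %||%
                   paste0("SYNTH^", toupper(canonical_mrn)),
                 birth_date = birth_date,
                 study_description = study_description,
                 institution = institution,
                 target_bytes = target_bytes),
            class = "synthetic_study_spec")
}

# deterministic pixel bytes: SHA-256 counter stream keyed by identifiers
det_bytes <- function(n, ...) {
  key <- paste(c(...), collapse = "|")
  blocks <- ceiling(n / 32)
  out <- vector("list", blocks)
  for (b in seq_len(blocks))
    out[[b]] <- openssl::sha256(charToRaw(paste0(key, "#", b)))
  head(do.call(c, lapply(out, as.raw)), n)
}

#' Generate one synthetic study as Part-10 files
#'
#' Writes `n_series * instances_per_series` DICOM files into `dir`.
#' All UIDs derive from the spec's seed, so regeneration is byte-identical.
#'
#' @param spec a [synthetic_study_spec()]
#' @param dir output directory (created if needed)
#' @return a `synthetic_study` list: `spec`, `study_uid`, `files`
#'   (in (SeriesNumber, InstanceNumber) order) and per-instance `meta`
#' @export
generate_study <- function(spec, dir = tempfile("study")) {
  stopifnot(inherits(spec, "synthetic_study_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- spec$seed
  study_uid <- make_uid(s, 1)
  npx <- spec$pixel_dims^2
  files <- character(0)
  meta <- list()
  for (se in seq_len(spec$n_series)) {
    series_uid <- make_uid(s, 2, se)
    for (ins in seq_len(spec$instances_per_series)) {
      sop_uid <- make_uid(s, 3, se, ins)
      attrs <- list(
        SpecificCharacterSet = "ISO_IR 100",
        SOPClassUID = SOP_SECONDARY_CAPTURE,
        SOPInstanceUID = sop_uid,
        StudyDate = gsub("-", "", spec$study_date),
        AccessionNumber = spec$accession_number,
        Modality = spec$modality,
        InstitutionName = spec$institution,
        StudyDescription = spec$study_description,
        PatientName = spec$patient_name,
        PatientID = spec$canonical_mrn,
        PatientBirthDate = gsub("-", "", spec$birth_date),
        StudyInstanceUID = study_uid,
        SeriesInstanceUID = series_uid,
        SeriesNumber = as.character(se),
        InstanceNumber = as.character(ins),
        SamplesPerPixel = 1L,
        PhotometricInterpretation = "MONOCHROME2",
        Rows = spec$pixel_dims, Columns = spec$pixel_dims,
        BitsAllocated = 8L, BitsStored = 8L, HighBit = 7L,
        PixelRepresentation = 0L,
        PixelData = det_bytes(npx, "px", s, se, ins))
      path <- file.path(dir, sprintf("%s.dcm", sop_uid))
      dcm_write(path, attrs)
      if (!is.null(spec$target_bytes)) {
        pad <- spec$target_bytes - file.size(path) - 12L
        if (pad > 0) {
          attrs$DataSetTrailingPadding <- raw(pad)
          dcm_write(path, attrs)
        }
      }
      files <- c(files, path)
      meta[[length(meta) + 1L]] <- list(
        sop_uid = sop_uid, series_uid = series_uid,
        series_number = se, instance_number = ins, file = path)
    }
  }
  structure(list(spec = spec, study_uid = study_uid,
                 files = files, meta = meta),
            class = "synthetic_study")
}

#' Configure mock archive behavior
#'
#' @param association_latency seconds of (virtual) delay per association
#' @param move_failure_probability chance in `[0,1]` that a study move
#'   fails with a refused status
#' @param offline_fraction fraction of studies treated as residing in
#'   off-line (tape) storage, responding only after `offline_delay` seconds
#' @param offline_delay virtual seconds an off-line study takes
#' @param refuse_associations when `TRUE` the archive rejects every
#'   association (endpoint-down failure mode)
#' @param seed seed for the behavior's private deterministic random source
#' @export
mock_behavior <- function(association_latency = 0,
                          move_failure_probability = 0,
                          offline_fraction = 0,
                          offline_delay = 3600,
                          refuse_associations = FALSE,
                          seed = 1L) {
  stopifnot(move_failure_probability >= 0, move_failure_probability <= 1,
            offline_fraction >= 0, offline_fraction <= 1)
  structure(list(association_latency = association_latency,
                 move_failure_probability = move_failure_probability,
                 offline_fraction = offline_fraction,
                 offline_delay = offline_delay,
                 refuse_associations = refuse_associations,
                 seed = as.integer(seed)),
            class = "mock_behavior")
}

#' Start an in-process mock archive
#'
#' Serves patient- and study-level queries and study moves over the
#' package's in-process DICOM message layer. Every query received is
#' recorded in `$queries_seen` for test assertions.
#'
#' @param studies list of `synthetic_study` objects (the archive content)
#' @param behavior a [mock_behavior()]
#' @param ae_registry environment mapping destination AE titles to receiver
#'   functions (the broker and any forwarding targets register here)
#' @return a `mock_pacs` handle
#' @export
serve_mock_pacs <- function(studies, behavior = mock_behavior(),
                            ae_registry = new.env(parent = emptyenv())) {
  stopifnot(length(studies) > 0)
  mp <- new.env(parent = emptyenv())
  mp$studies <- studies
  mp$behavior <- behavior
  mp$registry <- ae_registry
  mp$queries_seen <- list()
  mp$counter <- 0L
  # deterministic offline assignment
  mp$offline <- vapply(seq_along(studies), function(i)
    hash_unif(behavior$seed, paste0("off", i)) < behavior$offline_fraction,
    logical(1))
  class(mp) <- "mock_pacs"
  mp
}

mp_rand <- function(mp) {
  mp$counter <- mp$counter + 1L
  hash_unif(mp$behavior$seed, mp$counter)
}

mp_check_assoc <- function(mp) {
  if (mp$behavior$refuse_associations)
    pb_unreachable_error("association rejected by archive")
}

record_query <- function(mp, level, key_type, keys) {
  mp$queries_seen[[length(mp$queries_seen) + 1L]] <-
    list(level = level, key_type = key_type, keys = keys)
}

#' Query the mock archive (C-FIND semantics)
#'
#' @param mp a `mock_pacs`
#' @param level `"PATIENT"` or `"STUDY"`
#' @param key_type `"mrn"` or `"accession"`
#' @param keys identifier values (exact match, one query per identifier is
#'   the broker's contract; the mock accepts a vector)
#' @return for PATIENT level, rows of (mrn, patient_name, birth_date); for
#'   STUDY level, one row per matching study with its identifying
#'   attributes
#' @export
pacs_find <- function(mp, level, key_type, keys) {
  mp_check_assoc(mp)
  record_query(mp, level, key_type, keys)
  hit <- Filter(function(st) {
    if (key_type == "mrn") st$spec$canonical_mrn %in% keys
    else st$spec$accession_number %in% keys
  }, mp$studies)
  if (level == "PATIENT") {
    if (length(hit) == 0) return(data.frame(mrn = character(0),
                                            patient_name = character(0),
                                            birth_date = character(0),
                                            stringsAsFactors = FALSE))
    df <- unique(data.frame(
      mrn = vapply(hit, function(s) s$spec$canonical_mrn, ""),
      patient_name = vapply(hit, function(s) s$spec$patient_name, ""),
      birth_date = vapply(hit, function(s) s$spec$birth_date, ""),
      stringsAsFactors = FALSE))
    rownames(df) <- NULL
    return(df)
  }
  if (length(hit) == 0)
    return(data.frame(mrn = character(0), accession_number = character(0),
                      study_instance_uid = character(0), study_date = character(0),
                      modalities = character(0), study_description = character(0),
                      institution = character(0), n_instances = integer(0),
                      stringsAsFactors = FALSE))
  df <- data.frame(
    mrn = vapply(hit, function(s) s$spec$canonical_mrn, ""),
    accession_number = vapply(hit, function(s) s$spec$accession_number, ""),
    study_instance_uid = vapply(hit, function(s) s$study_uid, ""),
    study_date = vapply(hit, function(s) s$spec$study_date, ""),
    modalities = vapply(hit, function(s) s$spec$modality, ""),
    study_description = vapply(hit, function(s) s$spec$study_description, ""),
    institution = vapply(hit, function(s) s$spec$institution, ""),
    n_instances = vapply(hit, function(s) length(s$files), 0L),
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' Move a study to a destination AE (C-MOVE semantics)
#'
#' Resolves the destination AE title in the archive's registry and streams
#' each instance file to it, honoring the configured failure probability
#' and off-line delays. Returns final sub-operation counts like a real
#' move response.
#'
#' @param mp a `mock_pacs`
#' @param study_instance_uid study to move
#' @param dest_aet destination application-entity title
#' @param context opaque list passed through to the receiver (the broker
#'   uses it to attribute instances to requests)
#' @return list with `status` ("COMPLETED" or "FAILED"), `completed` and
#'   `failed` sub-operation counts, `reason`, and `delay_seconds`
#' @export
pacs_move <- function(mp, study_instance_uid, dest_aet, context = list()) {
  mp_check_assoc(mp)
  record_query(mp, "MOVE", "study_uid", study_instance_uid)
  idx <- which(vapply(mp$studies, function(s) s$study_uid, "") ==
                 study_instance_uid)
  if (length(idx) == 0)
    return(list(status = "FAILED", completed = 0L, failed = 0L,
                reason = "no such study", delay_seconds = 0))
  if (!exists(dest_aet, envir = mp$registry, inherits = FALSE))
    return(list(status = "FAILED", completed = 0L, failed = 0L,
                reason = sprintf("move destination '%s' unknown", dest_aet),
                delay_seconds = 0))
  if (mp_rand(mp) < mp$behavior$move_failure_probability)
    return(list(status = "FAILED", completed = 0L, failed = 0L,
                reason = "move rejected", delay_seconds = 0))
  st <- mp$studies[[idx]]
  delay <- mp$behavior$association_latency +
    if (mp$offline[idx]) mp$behavior$offline_delay else 0
  if (length(st$files) == 0)
    return(list(status = "FAILED", completed = 0L, failed = 0L,
                reason = "empty study", delay_seconds = delay))
  receiver <- get(dest_aet, envir = mp$registry)
  completed <- 0L; failed <- 0L
  for (m in st$meta) {
    ok <- tryCatch({
      receiver(readBin(m$file, "raw", n = file.size(m$file)),
               c(context, list(study_uid = st$study_uid, sop_uid = m$sop_uid)))
      TRUE
    }, error = function(e) FALSE)
    if (ok) completed <- completed + 1L else failed <- failed + 1L
  }
  list(status = if (failed == 0L && completed > 0L) "COMPLETED" else "FAILED",
       completed = completed, failed = failed,
       reason = if (failed > 0L) "storage sub-operation(s) failed" else NULL,
       delay_seconds = delay)
}

#' All MRNs the archive has ever been asked about
#'
#' Support for leak auditing in tests: the union of MRN keys across every
#' recorded patient/study query.
#' @param mp a `mock_pacs`
#' @export
pacs_observed_mrns <- function(mp) {
  unique(unlist(lapply(mp$queries_seen, function(q)
    if (q$key_type == "mrn") q$keys else character(0))))
}

#' Generate a reproducible multi-project workload scenario
#'
#' Builds `n_projects` projects, each with its own allowlisted patients
#' and `n_requests_per_project` single-study retrieval requests, plus the
#' synthetic studies backing them. The same `(n_projects,
#' n_requests_per_project, seed)` always yields the identical scenario.
#'
#' @param n_projects,n_requests_per_project scenario size (both >= 1)
#' @param seed integer seed
#' @param users_per_project members per project
#' @return list with `projects` (config-shaped lists), `studies`
#'   (synthetic_study objects) and `submissions` (one row per request:
#'   project_id, user, study_uid, mrn, accession)
#' @export
generate_workload <- function(n_projects, n_requests_per_project, seed,
                              users_per_project = 1L) {
  stopifnot(n_projects >= 1, n_requests_per_project >= 1)
  projects <- list(); studies <- list(); rows <- list()
  seed <- as.numeric(seed)
  k <- 0L
  for (p in seq_len(n_projects)) {
    pid <- sprintf("P%02d", p)
    users <- sprintf("user%02d_%d", p, seq_len(users_per_project))
    mrns <- sprintf("%08d", (seed %% 97) * 1e5 + p * 1000 +
                      seq_len(n_requests_per_project))
    for (q in seq_len(n_requests_per_project)) {
      k <- k + 1L
      spec <- synthetic_study_spec(
        seed = (seed * 7919 + k) %% 2147483647,
        canonical_mrn = mrns[q],
        accession_number = sprintf("AN%07d", (seed %% 999) * 1000 + k),
        study_date = format(as.Date("2012-01-01") +
                              (seed + k) %% 730, "%Y-%m-%d"),
        n_series = 1L, instances_per_series = 1L,
        modality = c("MR", "CT", "US", "CR")[1L + (k %% 4L)],
        pixel_dims = 8L)
      st <- generate_study(spec)
      studies[[k]] <- st
      rows[[k]] <- data.frame(project_id = pid, user = users[1],
                              study_uid = st$study_uid, mrn = mrns[q],
                              accession = spec$accession_number,
                              stringsAsFactors = FALSE)
    }
    projects[[p]] <- list(id = pid, irb_id = sprintf("IRB-%04d", p),
                          members = users, allowlist = mrns,
                          cache_quota_bytes = 1e9)
  }
  list(projects = projects, studies = studies,
       submissions = do.call(rbind, rows))
}
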