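# Shared fixture builders. Everything is generated in code at test time;
# no binary fixtures are stored.

ALL_DAYS <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")

# Monday 02:00 UTC — deep inside an always-open window, outside none
T0 <- as.POSIXct("2013-06-03 02:00:00", tz = "UTC")

open_window <- function(rate_count = 1000L, rate_period = "minute",
                        days = ALL_DAYS, start = 0L, end = 1440L) {
  list(days = days, start = start, end = end,
       rate_count = rate_count, rate_period = rate_period)
}

# Build a loadable config doc and run it through load_config(), so every
# test configuration passes the same validation as a user's.
test_config <- function(root = tempfile("pbtest"),
                        projects = list(list(id = "P1", members = "alice",
                                             allowlist = "12345678")),
                        windows = list(open_window()),
                        max_concurrent = 5L,
                        max_studies_per_patient = NULL,
                        endpoints = NULL,
                        timezone = "UTC") {
  if (is.null(endpoints))
    endpoints <- list(list(id = "HOSP", institution = "Mock General",
                           aet = "PACS1", host = "inproc", port = 104L))
  policy <- list(max_concurrent = max_concurrent, windows = windows)
  if (!is.null(max_studies_per_patient))
    policy$max_studies_per_patient <- max_studies_per_patient
  doc <- list(
    cache_root = root,
    audit_store = file.path(root, "audit.tsv"),
    timezone = timezone,
    endpoints = endpoints,
    policies = stats::setNames(rep(list(policy), length(endpoints)),
                               vapply(endpoints, `[[`, "", "id")),
    projects = lapply(projects, function(p) {
      p$irb_id <- p$irb_id %||% paste0("IRB-", p$id)
      p$cache_quota_bytes <- p$cache_quota_bytes %||% 1e8
      p
    }))
  load_config(yaml::as.yaml(doc))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Broker over a virtual clock with a mock archive serving `studies`.
test_broker <- function(cfg, studies, behavior = mock_behavior(),
                        start = T0, endpoint_id = "HOSP") {
  b <- broker_new(cfg, new_clock(start))
  broker_attach_pacs(b, endpoint_id,
                     serve_mock_pacs(studies, behavior, b$registry))
  b
}

# A second storage endpoint that keeps everything it receives, for
# forwarding round-trip checks.
register_store_ae <- function(b, aet = "STORE2") {
  got <- new.env(parent = emptyenv())
  got$instances <- list()
  assign(aet, function(bytes, context) {
    got$instances[[context$sop_uid]] <- bytes
  }, envir = b$registry)
  got
}

simple_study <- function(seed, mrn = "12345678", an = sprintf("AN%04d", seed),
                         date = "2012-03-04", n_series = 1L, per_series = 2L,
                         modality = "MR", ...) {
  generate_study(synthetic_study_spec(
    seed, mrn, an, date, n_series = n_series,
    instances_per_series = per_series, modality = modality,
    pixel_dims = 8L, ...))
}

# Fully wired single-project broker with three studies for one patient
default_rig <- function(...) {
  cfg <- test_config(...)
  studies <- list(
    simple_study(11, date = "2011-02-02", modality = "MR",
                 n_series = 2L, per_series = 3L),
    simple_study(12, date = "2009-05-01", modality = "CT"),
    simple_study(13, mrn = "87654321", an = "AN9999", date = "2013-01-01",
                 modality = "US"))
  b <- test_broker(cfg, studies)
  list(cfg = cfg, b = b, studies = studies)
}

expect_audit_count <- function(b, action, n) {
  expect_equal(nrow(audit_query(b$audit, action = action)), n)
}
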