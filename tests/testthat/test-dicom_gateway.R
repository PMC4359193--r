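# Gateway behavior against the mock archive; faceting against a
# brute-force oracle.

test_that("patient search returns exactly the queried patients that exist", {
  rig <- default_rig(projects = list(list(
    id = "P1", members = "alice",
    allowlist = c("12345678", "87654321", "55555555"))))
  r <- broker_find_patients(rig$b, "P1", "alice", "HOSP",
                            c("12345678", "55555555"))
  expect_equal(r$patients$canonical_mrn, "12345678")  # 55555555 has no studies
  expect_equal(r$patients$source_endpoint_id, "HOSP")
  r2 <- broker_find_patients(rig$b, "P1", "alice", "HOSP", "55555555")
  expect_equal(nrow(r2$patients), 0)
})

test_that("a refusing archive surfaces as endpoint-unreachable", {
  cfg <- test_config()
  b <- test_broker(cfg, list(simple_study(1)),
                   behavior = mock_behavior(refuse_associations = TRUE))
  expect_error(broker_find_patients(b, "P1", "alice", "HOSP", "12345678"),
               class = "pb_endpoint_unreachable")
})

test_that("per-patient study limit keeps the newest, flags truncation", {
  cfg <- test_config(max_studies_per_patient = 3L)
  dates <- c("2009-01-01", "2010-06-15", "2011-02-02", "2012-12-31", "2013-05-05")
  studies <- lapply(seq_along(dates), function(i)
    simple_study(100 + i, an = sprintf("AN%02d", i), date = dates[i]))
  b <- test_broker(cfg, studies)
  r <- broker_find_studies(b, "P1", "alice", "HOSP", mrns = "12345678")
  expect_equal(nrow(r$studies), 3)
  expect_equal(r$studies$study_date, c("2013-05-05", "2012-12-31", "2011-02-02"))
  expect_true(all(r$studies$truncated_flag))
  # below the limit nothing is flagged
  cfg2 <- test_config(max_studies_per_patient = 10L)
  b2 <- test_broker(cfg2, studies)
  r2 <- broker_find_studies(b2, "P1", "alice", "HOSP", mrns = "12345678")
  expect_equal(nrow(r2$studies), 5)
  expect_false(any(r2$studies$truncated_flag))
})

test_that("accession search works on-list and is denied off-list", {
  rig <- default_rig()
  r <- broker_find_studies(rig$b, "P1", "alice", "HOSP", accessions = "AN0011")
  expect_equal(nrow(r$studies), 1)
  expect_equal(r$studies$canonical_mrn, "12345678")
  # AN9999 belongs to 87654321, not on P1's allowlist
  expect_error(
    broker_find_studies(rig$b, "P1", "alice", "HOSP", accessions = "AN9999"),
    class = "pb_authorization_error")
  denied <- audit_query(rig$b$audit, action = "ACCESS_DENIED")
  expect_equal(nrow(denied), 1)
  expect_match(denied$detail, "87654321")
})

test_that("off-list MRNs never reach the archive", {
  rig <- default_rig()
  broker_find_patients(rig$b, "P1", "alice", "HOSP",
                       c("12345678", "99999999", "00000001"))
  seen <- pacs_observed_mrns(rig$b$pacs$HOSP)
  expect_equal(seen, "12345678")
})

test_that("study attributes round-trip the generator's values", {
  spec <- synthetic_study_spec(77, "12345678", "AN0077", "2012-07-08",
                               n_series = 2L, instances_per_series = 2L,
                               modality = "CT", pixel_dims = 8L,
                               study_description = "CHEST CT",
                               institution = "Mock General Hospital")
  cfg <- test_config()
  b <- test_broker(cfg, list(generate_study(spec)))
  st <- broker_find_studies(b, "P1", "alice", "HOSP", mrns = "12345678")$studies
  expect_equal(st$accession_number, "AN0077")
  expect_equal(st$study_date, "2012-07-08")
  expect_equal(st$modalities, "CT")
  expect_equal(st$study_description, "CHEST CT")
  expect_equal(st$institution, "Mock General Hospital")
  expect_equal(st$n_instances, 4L)
})

# --- faceted filtering ---------------------------------------------------

toy_studies <- data.frame(
  study_date = c("2009-05-01", "2011-02-02", "2013-01-01"),
  modalities = c("MR", "CT", "US\\MR"),
  institution = c("Hospital X", "Hospital Y", "Hospital X"),
  n_instances = c(4L, 10L, 2L),
  stringsAsFactors = FALSE)

# independent oracle: literal row-by-row predicate evaluation
brute_filter <- function(df, ranges = list(), sets = list()) {
  keep <- vapply(seq_len(nrow(df)), function(i) {
    for (col in names(ranges)) {
      v <- df[[col]][i]; r <- ranges[[col]]
      num <- suppressWarnings(!is.na(as.numeric(v)))
      if (num) { if (as.numeric(v) < as.numeric(r[1]) ||
                     as.numeric(v) > as.numeric(r[2])) return(FALSE) }
      else if (v < r[1] || v > r[2]) return(FALSE)
    }
    for (col in names(sets)) {
      vals <- strsplit(df[[col]][i], "\\", fixed = TRUE)[[1]]
      if (!any(vals %in% sets[[col]])) return(FALSE)
    }
    TRUE
  }, logical(1))
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

test_that("date-range AND modality-set facets match hand evaluation", {
  f <- facet_filter(facet_range("study_date", "2009-01-01", "2012-01-01"),
                    facet_set("modalities", c("MR", "US")))
  got <- apply_facets(toy_studies, f)
  expect_equal(got, brute_filter(toy_studies,
                                 ranges = list(study_date = c("2009-01-01", "2012-01-01")),
                                 sets = list(modalities = c("MR", "US"))))
  expect_equal(got$study_date, "2009-05-01")  # 2011 study is CT, 2013 out of range
})

test_that("an empty filter is the identity; multi-valued cells use any-member semantics", {
  expect_identical(apply_facets(toy_studies, NULL), toy_studies)
  expect_identical(apply_facets(toy_studies, facet_filter()), toy_studies)
  got <- apply_facets(toy_studies, facet_filter(facet_set("modalities", "MR")))
  expect_equal(got$modalities, c("MR", "US\\MR"))  # US\MR passes via MR
})

test_that("apply_facets equals the brute-force oracle on random tables", {
  set.seed(99)
  mods <- c("MR", "CT", "US", "CR", "XA")
  insts <- c("Hospital X", "Hospital Y", "Clinic Z")
  for (i in 1:40) {
    n <- sample(1:12, 1)
    df <- data.frame(
      study_date = format(as.Date("2009-01-01") + sample(0:1800, n, TRUE)),
      modalities = vapply(seq_len(n), function(j)
        paste(sample(mods, sample(1:3, 1)), collapse = "\\"), ""),
      institution = sample(insts, n, TRUE),
      n_instances = sample(1:50, n, TRUE),
      stringsAsFactors = FALSE)
    lo <- format(as.Date("2009-01-01") + sample(0:900, 1))
    hi <- format(as.Date(lo) + sample(30:900, 1))
    pick_mods <- sample(mods, sample(1:3, 1))
    rng <- sort(sample(1:50, 2))
    f <- facet_filter(facet_range("study_date", lo, hi),
                      facet_set("modalities", pick_mods),
                      facet_range("n_instances", rng[1], rng[2]))
    expect_equal(apply_facets(df, f),
                 brute_filter(df,
                              ranges = list(study_date = c(lo, hi),
                                            n_instances = rng),
                              sets = list(modalities = pick_mods)))
  }
})

# --- instance reception and forwarding ----------------------------------

test_that("retrieval stages exactly the generator's instances, idempotently", {
  rig <- default_rig()
  st <- broker_find_studies(rig$b, "P1", "alice", "HOSP",
                            mrns = "12345678")$studies
  six <- st[st$accession_number == "AN0011", ]
  broker_request(rig$b, "P1", "alice", "HOSP", six)
  broker_pump(rig$b)
  entry <- list_entries(rig$b$cache, rig$cfg$projects$P1)
  expect_equal(entry$instance_count, 6L)  # 2 series x 3 instances
  expect_equal(entry$study_instance_uid, six$study_instance_uid)
})

test_that("unsolicited instances are rejected and audited", {
  rig <- default_rig()
  stray <- rig$studies[[3]]
  bytes <- readBin(stray$files[1], "raw", file.size(stray$files[1]))
  expect_error(
    receive_instance(rig$b$staging, rig$b$sched, rig$b$audit, bytes,
                     list(user = "alice", project_id = "P1")),
    class = "pb_unsolicited_instance")
  expect_audit_count(rig$b, "ACCESS_DENIED", 1)
})

test_that("forwarding delivers byte-identical instances to a second endpoint", {
  rig <- default_rig()
  st <- broker_find_studies(rig$b, "P1", "alice", "HOSP",
                            mrns = "12345678")$studies[1, ]
  broker_request(rig$b, "P1", "alice", "HOSP", st)
  broker_pump(rig$b)
  store <- register_store_ae(rig$b, "STORE2")
  res <- broker_forward(rig$b, "P1", "alice", st$study_instance_uid, "STORE2")
  expect_equal(nrow(res), 6)
  expect_true(all(res$stored))
  src <- rig$studies[[1]]
  for (m in src$meta)
    expect_identical(store$instances[[m$sop_uid]],
                     readBin(m$file, "raw", file.size(m$file)))
  expect_error(
    broker_forward(rig$b, "P1", "alice", st$study_instance_uid, "NOWHERE"),
    class = "pb_endpoint_unreachable")
  expect_error(
    broker_forward(rig$b, "P1", "mallory", st$study_instance_uid, "STORE2"),
    class = "pb_authorization_error")
})
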