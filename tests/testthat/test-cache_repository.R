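stage_study <- function(st, dir = tempfile("stage")) {
  dir.create(dir, recursive = TRUE)
  file.copy(st$files, file.path(dir, basename(st$files)))
  dir
}

fresh_repo <- function() new_cache_repo(tempfile("repo"),
                                        new_audit_log(tempfile(fileext = ".tsv")))

P1 <- structure(list(id = "P1", irb_id = "IRB-1", members = c("alice", "bob"),
                     allowlist = "12345678", expiration = NULL,
                     cache_quota_bytes = 1e8), class = "project")

test_that("admission accounts instances and bytes exactly", {
  cr <- fresh_repo()
  st <- simple_study(21, n_series = 2L, per_series = 3L)
  e <- admit_study(cr, P1, stage_study(st))
  expect_equal(e$instance_count, 6L)
  expect_equal(e$total_bytes, sum(file.size(vapply(e$file_layout, `[[`, "", "file"))))
  u <- cache_usage(cr, P1)
  expect_equal(u$used_bytes, e$total_bytes)
  expect_equal(u$entries, 1L)
  # layout ordered by (series, instance)
  expect_equal(vapply(e$file_layout, `[[`, 0L, "series_number"),
               c(1L, 1L, 1L, 2L, 2L, 2L))
  expect_equal(vapply(e$file_layout, `[[`, 0L, "instance_number"),
               rep(1:3, 2))
})

test_that("corrupt or empty staging is refused", {
  cr <- fresh_repo()
  mixed <- stage_study(simple_study(22))
  file.copy(simple_study(23, an = "ANX")$files, mixed)
  expect_error(admit_study(cr, P1, mixed), class = "pb_staging_corruption")
  empty <- tempfile(); dir.create(empty)
  expect_error(admit_study(cr, P1, empty), class = "pb_empty_study")
})

test_that("usage equals on-disk truth after arbitrary interleavings", {
  cr <- fresh_repo()
  set.seed(5)
  live <- character(0)
  for (i in 1:25) {
    if (length(live) == 0 || runif(1) < 0.6) {
      st <- simple_study(200 + i, an = sprintf("AN2%02d", i))
      e <- admit_study(cr, P1, stage_study(st))
      live <- c(live, e$study_instance_uid)
    } else {
      victim <- sample(live, 1)
      delete_study(cr, P1, victim, "alice")
      live <- setdiff(live, victim)
    }
    walked <- sum(file.size(list.files(file.path(cr$root, "cache", "P1"),
                                       recursive = TRUE, full.names = TRUE)))
    if (length(list.files(file.path(cr$root, "cache", "P1"))) == 0) walked <- 0
    expect_equal(cache_usage(cr, P1)$used_bytes, walked)
  }
})

test_that("deletion frees space and checks membership; unknown entries error", {
  cr <- fresh_repo()
  e <- admit_study(cr, P1, stage_study(simple_study(24)))
  expect_error(delete_study(cr, P1, e$study_instance_uid, "mallory"),
               class = "pb_authorization_error")
  u <- delete_study(cr, P1, e$study_instance_uid, "bob")
  expect_equal(u$used_bytes, 0)
  expect_error(delete_study(cr, P1, "1.2.3.4", "alice"),
               class = "pb_notfound_error")
})

test_that("entry listing is newest-first and facet-filterable", {
  cr <- fresh_repo()
  t0 <- as.POSIXct("2013-06-03 02:00:00", tz = "UTC")
  admit_study(cr, P1, stage_study(simple_study(25, modality = "MR")), now = t0)
  admit_study(cr, P1, stage_study(simple_study(26, an = "AN26", modality = "CT")),
              now = t0 + 60)
  admit_study(cr, P1, stage_study(simple_study(27, an = "AN27", modality = "US")),
              now = t0 + 120)
  all3 <- list_entries(cr, P1)
  expect_equal(nrow(all3), 3)
  expect_equal(all3$modalities, c("US", "CT", "MR"))  # newest first
  one <- list_entries(cr, P1, facet_filter(facet_set("modalities", "CT")))
  expect_equal(one$accession_number, "AN26")
  expect_equal(nrow(list_entries(fresh_repo(), P1)), 0)
})

test_that("plaintext export copies byte-identical files in the documented layout", {
  cr <- fresh_repo()
  st <- simple_study(28, n_series = 2L, per_series = 3L)
  e <- admit_study(cr, P1, stage_study(st))
  dest <- tempfile("exp")
  man <- export_study(cr, P1, e$study_instance_uid, "alice", dest)
  expect_equal(nrow(man), 6)
  for (i in seq_len(nrow(man))) {
    expect_match(man$destination[i],
                 file.path("12345678", e$study_instance_uid, "[12]"))
    expect_identical(readBin(man$destination[i], "raw", file.size(man$destination[i])),
                     readBin(man$source[i], "raw", file.size(man$source[i])))
  }
  expect_error(export_study(cr, P1, e$study_instance_uid, "mallory", dest),
               class = "pb_authorization_error")
  expect_error(export_study(cr, P1, e$study_instance_uid, "alice", dest,
                            encrypt = TRUE),
               class = "pb_usage_error")
})

test_that("encrypted export leaves nothing parseable as DICOM at the destination", {
  cr <- fresh_repo()
  e <- admit_study(cr, P1, stage_study(simple_study(29, n_series = 2L,
                                                    per_series = 3L)))
  dest <- tempfile("encexp")
  man <- export_study(cr, P1, e$study_instance_uid, "alice", dest,
                      encrypt = TRUE, passphrase = "s3cret")
  files <- list.files(dest, full.names = TRUE)
  expect_setequal(basename(files), c("000000.bin", sprintf("%06d.bin", 1:6)))
  for (f in files) {
    expect_error(dcm_read(f), class = "pb_dicom_error")  # parse-attempt oracle
    r <- readBin(f, "raw", n = 200)
    expect_false(length(r) >= 132 && rawToChar(r[129:132]) == "DICM")
  }
  # round trip through the manifest
  for (i in seq_along(man$names)) {
    pt <- decrypt_to_memory(file.path(dest, man$names[i]), "s3cret")
    orig <- e$file_layout[[i]]$file
    expect_identical(pt, readBin(orig, "raw", file.size(orig)))
  }
})

test_that("quota gates dispatch, admission overflow is truthful, deletion resumes", {
  # studies padded to ~30 KB each against a 50 KB quota
  cfg <- test_config(projects = list(list(id = "P1", members = "alice",
                                          allowlist = c("12345678"),
                                          cache_quota_bytes = 50000)))
  studies <- lapply(1:3, function(i)
    simple_study(400 + i, an = sprintf("AN4%02d", i), per_series = 1L,
                 target_bytes = 30000))
  b <- test_broker(cfg, studies)
  st <- broker_find_studies(b, "P1", "alice", "HOSP", mrns = "12345678")$studies
  for (i in 1:3) broker_request(b, "P1", "alice", "HOSP", st[i, ])
  broker_pump(b)
  # first two fit/overflow (30k, then 60k > 50k quota); third is gated
  u <- cache_usage(b$cache, cfg$projects$P1)
  expect_gte(u$used_bytes, u$quota_bytes)      # truthful overflow accounting
  expect_equal(u$entries, 2L)
  lg <- request_log(b$sched)
  expect_equal(sort(lg$state), c("COMPLETED", "COMPLETED", "SCHEDULED"))
  expect_null(next_dispatch(b$sched))          # blocked at/over quota
  # deleting brings usage under quota and dispatch resumes
  victim <- list_entries(b$cache, cfg$projects$P1)$study_instance_uid[1]
  broker_delete(b, "P1", "alice", victim)
  broker_pump(b)
  expect_equal(sum(request_log(b$sched)$state == "COMPLETED"), 3)
})
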