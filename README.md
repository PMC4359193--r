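# pacsbroker

Governed research access to clinical imaging archives.

Retrospective imaging research needs studies that live in clinical PACS
(Picture Archiving and Communication System) archives, but those archives
serve patient care first: research access must not degrade clinical
throughput, must be confined to IRB-approved patients, and must be fully
auditable. `pacsbroker` is a headless broker that sits between research
projects and one or more archives:

* **Query** — researcher MRN/accession lists become DICOM patient- and
  study-level C-FIND queries, with faceted (conjunction-of-disjunctions)
  filtering of results.
* **Govern** — study retrievals (C-MOVE, one study per request) are queued
  per project and dispatched round-robin, under per-endpoint time-of-day
  access windows with studies-per-minute/hour rates and concurrency caps,
  so every project is served fairly and no archive is flooded.
* **Restrict** — every operation is gated by a project's MRN allowlist,
  membership, and expiration date; off-list identifiers never reach an
  archive and every denial is recorded.
* **Cache** — retrieved studies land in per-project, quota-limited caches;
  usage accounting is truthful and deletion is user-controlled.
* **Audit** — an append-only, write-ahead, fail-closed audit trail records
  every query, retrieval, download, delete, forward and denial.
* **Export** — downloads can be AES-128 encrypted as a stream (passphrase
  key derivation, authenticated format, order-preserving obfuscated
  filenames) so no plaintext ever exists on the destination disk.

Everything is testable without clinical data: the package includes a
deterministic synthetic DICOM study generator and a configurable
in-process mock archive (failure injection, off-line-archive delays,
association refusal), plus an injectable clock so all governance behavior
runs on virtual time in tests.

For whom: imaging informatics groups prototyping research access
workflows, and methodologists who need a faithful, fully observable model
of governed PACS retrieval to test policies against.

## The governance model in brief

Per archive endpoint, a policy defines access windows
`(days, [start, end), rate_count / {minute|hour})` and `max_concurrent`.
Dispatch of the next queued request is permitted at time *t* iff

* *t* lies in some window `w` with `rate_count(w) > 0`,
* fewer than `rate_count(w)` dispatches occurred in the trailing rate
  period (a sliding-window rate bound, reset at window boundaries),
* fewer than `max_concurrent` moves are in flight at that endpoint, and
* the project's cache usage is under its quota.

Eligible projects are served round-robin from a persistent cursor: with
equal queues and no limits, per-project dispatch counts never differ by
more than 1 at any prefix. Request lifecycle is
`SCHEDULED → PROCESSING → {COMPLETED | FAILED}`.

## Worked example

```r
library(pacsbroker)

cfg <- load_config("
cache_root: /tmp/demo-broker
audit_store: /tmp/demo-broker/audit.tsv
timezone: UTC
endpoints:
  - id: HOSP
    institution: General Hospital
    department: Radiology
    aet: PACS1
    host: inproc
    port: 11112
    mrn_rule: {strip_chars: '-', pad_width: 8}
policies:
  HOSP:
    max_concurrent: 2
    max_studies_per_patient: 3
    windows:
      - {days: [Mon,Tue,Wed,Thu,Fri], start: 0, end: 420, rate_count: 2, rate_period: minute}
      - {days: [Sat,Sun], start: 0, end: 1440, rate_count: 60, rate_period: hour}
projects:
  - id: NEURO01
    irb_id: IRB-2013-0042
    members: [alice, bob]
    allowlist: ['123-45-67', '555-00-11']
    expiration: 2014-06-30
    cache_quota_bytes: 104857600
")

# a broker on virtual time (Monday 02:00, inside the weekday night window),
# talking to a mock archive holding two synthetic studies of one patient
b <- broker_new(cfg, new_clock("2013-06-03 02:00:00"))
studies <- list(
  generate_study(synthetic_study_spec(101, "01234567", "AN2011-441", "2011-02-02",
                 n_series = 2, instances_per_series = 3, modality = "MR",
                 study_description = "BRAIN MRI W/O CONTRAST",
                 institution = "General Hospital")),
  generate_study(synthetic_study_spec(102, "01234567", "AN2009-105", "2009-05-01",
                 modality = "CT", study_description = "HEAD CT",
                 institution = "General Hospital")))
broker_attach_pacs(b, "HOSP", serve_mock_pacs(studies, mock_behavior(), b$registry))

r <- broker_find_patients(b, "NEURO01", "alice", "HOSP", c("123-45-67", "999-99-99"))
r$decision$denied_mrns   # the off-list MRN is denied (and audited), never queried
#> [1] "09999999"
r$patients
#>   canonical_mrn   patient_name birth_date source_endpoint_id
#> 1      01234567 SYNTH^01234567   19700101               HOSP

s <- broker_find_studies(b, "NEURO01", "alice", "HOSP", mrns = "123-45-67",
       filter = facet_filter(facet_range("study_date", "2010-01-01", "2013-12-31")))
s$studies[, c("canonical_mrn","accession_number","study_date","modalities","n_instances")]
#>   canonical_mrn accession_number study_date modalities n_instances
#> 1      01234567       AN2011-441 2011-02-02         MR           6

req <- broker_request(b, "NEURO01", "alice", "HOSP", s$studies[1, ])  # ticket T000001, SCHEDULED
broker_pump(b)   # dispatch under governance, move into cache, record outcome
request_log(b$sched)[, c("id","state","accession_number")]
#>        id     state accession_number
#> 1 T000001 COMPLETED       AN2011-441

list_entries(b$cache, cfg$projects$NEURO01)[, c("accession_number","modalities","instance_count","total_bytes")]
#>   accession_number modalities instance_count total_bytes
#> 1       AN2011-441         MR              6       10656

man <- broker_download(b, "NEURO01", "alice", s$studies$study_instance_uid[1],
                       "/tmp/demo-export", encrypt = TRUE,
                       passphrase = "orchid-vermilion-42")
man$names   # obfuscated, order-preserving; 000000.bin is the encrypted manifest
#> [1] "000001.bin" "000002.bin" "000003.bin" "000004.bin" "000005.bin" "000006.bin"

audit_query(b$audit)[, c("seq","user","action")]
#>   seq  user            action
#> 1   1 alice     ACCESS_DENIED
#> 2   2 alice     PATIENT_QUERY
#> 3   3 alice       STUDY_QUERY
#> 4   4 alice  RETRIEVE_REQUEST
#> 5   5 alice RETRIEVE_COMPLETE
#> 6   6 alice    CACHE_DOWNLOAD
```

The filtered study search returned only the 2011 MR study (the 2009 CT
falls outside the date facet); the one denial, both searches, the
retrieval and the download each left exactly one audit record. The
encrypted export can be recovered anywhere with
`decrypt_to_memory("/tmp/demo-export/000001.bin", "orchid-vermilion-42")`
— a wrong passphrase or a tampered byte raises an authentication error.

A shell entry point wrapping the same functions is installed at
`inst/cli/pacsbroker` (`find-patients`, `find-studies`, `request`, `log`,
`repo list|delete|download|forward`, `audit`, `serve`, `mock-pacs`).

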