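---
title: "Governed research access to clinical imaging archives: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Governed research access to clinical imaging archives: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pacsbroker)
```

## The problem

Clinical PACS archives hold the imaging studies that retrospective research
needs, but they are production clinical systems: research access must not
degrade clinical service, must be confined to IRB-approved patients, and
must leave an audit trail sufficient for HIPAA-style ex post review.
`pacsbroker` implements the intermediary that reconciles those demands: a
headless broker that translates researcher queries into DICOM
patient/study C-FIND requests, queues study retrievals (C-MOVE) per
project, dispatches them under negotiated governance limits into a
central per-project cache, and releases data to users only through
audited, optionally encrypted export.

This vignette records the models the package implements, the parameters
that matter, and the design decisions taken where the problem statement
was genuinely open.

## Access-control model

A *project* is an IRB-scoped tenant: a set of members, a predefined
allowlist of medical record numbers (MRNs), an optional expiration date,
and a cache quota. Three rules are enforced before any archive traffic is
generated, and re-checked when queued work is dispatched:

* **Allowlist** — the MRNs in any outbound query are a subset of the
  project's allowlist. A mixed query proceeds for the on-list subset and
  the off-list subset is denied *as a value* (never an error), so every
  refusal can be audited. All-or-nothing refusal was the alternative; we
  chose partial filtering because it preserves utility while keeping the
  trail complete.
* **Membership** — only project members may act for a project.
* **Expiration** — a project is active through the whole of its stated
  expiration date (inclusive-end, matching how approval periods are
  written), in the configured service time zone; from the first instant
  of the next day every path is closed, including requests already
  queued. Dispatch-time re-authorization fails those tickets without
  contacting the archive.

MRN formats differ across institutions (dashes, zero-padding, letter
prefixes). Each endpoint carries a normalization rule (strip characters,
case-fold, left zero-pad, literal prefix); allowlists are normalized once
at configuration load with a fixed endpoint-independent default rule
(strip `-` and spaces, upper-case), and user input is normalized at query
time with the endpoint's rule. When an endpoint's rule maps into a
different canonical space (e.g. zero-padding), the allowlist is viewed
through that endpoint's rule for the comparison — normalization is
idempotent, so this is a no-op when the spaces coincide. All comparisons and all audit records use
canonical form only, so records join across formats. Normalization is
idempotent: a value already carrying the configured prefix is treated as
canonical and not re-padded.

## Scheduling and governance model

Each project has a FIFO queue; one retrieval request corresponds to one
radiological study. Dispatch walks the project ring round-robin from a
persistent cursor (projects ordered lexicographically by id; the cursor
advances past the project just served, and skips projects whose queue
head is blocked rather than stalling the rotation). With equal queues and
no limits this yields per-project dispatch counts that never differ by
more than one at any prefix — the fairness property the test suite checks
exhaustively for small rings and on randomized workloads.

Archive endpoints carry a governance policy:

* **Access windows** — an ordered list of `(days, start, end)` intervals
  in minutes of the service-local day, each with a `rate_count` per
  `minute` or `hour`. Windows are half-open `[start, end)` and
  start-inclusive, which makes boundary instants unambiguous; overlapping
  windows are a load-time error rather than being precedence-resolved.
  Outside every window, and inside a window with `rate_count = 0`, no
  dispatch happens — this is how "no access during peak clinical
  activity, highest access on nights and weekends" is expressed.
* **Rate limit** — we use the sliding-window form of a token bucket: a
  dispatch is permitted only when fewer than `rate_count` dispatches
  occurred in the trailing rate period, and crossing into a different
  window clears the history. The aligned-bucket alternative (refill to
  capacity each period) admits up to twice the nominal rate across a
  period boundary; the sliding form keeps the bound in *every* window of
  one period length, which is the guarantee a radiology department
  actually negotiates for.
* **Concurrency cap** — at most `max_concurrent` moves in flight per
  endpoint; `0` disables retrieval entirely. The cap is per endpoint
  (per policy), the natural binding since it protects each archive
  individually.

Failed retrievals are surfaced in the request log with their reason and
are not retried automatically; users resubmit. Request lifecycle is
strictly `SCHEDULED → PROCESSING → {COMPLETED | FAILED}` with monotone
timestamps; any other transition is an error.

All time-dependent behavior reads an injectable clock, so every window,
rate and expiry scenario in the test suite runs on virtual time,
instantly and deterministically. This changes no behavior in production,
where the clock is the system clock.

## Cache and quota model

Retrieved instances land in a staging area keyed by project and study,
then are admitted atomically into the project cache
(`<cache_root>/cache/<project>/<study_uid>/`), ordered by (SeriesNumber,
InstanceNumber, SOPInstanceUID). A study's size is unknown before it is
transferred — DICOM offers no reliable pre-move size — so quota is
enforced as a *dispatch gate* with truthful overflow accounting: an
admission may push usage over quota, the reported usage says so, and the
project simply cannot dispatch again until a user deletes entries. There
is no automatic eviction; deletion is always user-initiated, which
matches the intended workflow where researchers triage their cache.
Caches are strictly per project: the same study cached by two projects is
stored twice, because per-IRB isolation outweighs deduplication.

## Audit model

Every access-relevant action — patient query, study query, retrieval
request/completion/failure, download, delete, forward, and every denial —
is one immutable record with a strictly increasing, gap-free sequence
number in a tab-separated append-only store. The contract is
*write-ahead, fail-closed*: the event is durably appended before the
action touches an archive or returns a result, and if the store cannot be
written the action itself fails. A compliance log that actions can escape
is not a compliance log. Denials are audited although only queries
strictly require recording — a conservative superset that makes refusals
reviewable too.

## Encrypted export

Downloads may be encrypted so that no plaintext ever exists on the
destination disk. The scheme is AES-128 (the key size fixed by the
system's security design) in an authenticated streaming construction:

* PBKDF2-HMAC-SHA256 stretches the user passphrase with a fresh 16-byte
  salt per export (default 1000 iterations, roughly 100 ms — configurable);
  48 derived bytes split into a 16-byte AES key and a 32-byte MAC key.
* Each file is written as a fixed header (magic, version, salt,
  iteration count, per-file nonce) followed by length-prefixed
  AES-128-CBC chunks whose IVs derive from the nonce and chunk counter,
  and an HMAC-SHA256 tag over everything (encrypt-then-MAC). The format
  is documented byte-exactly in the `crypto_store` source so third
  parties can decrypt.
* Decryption authenticates first and returns bytes to memory only: a
  tampered file or wrong passphrase raises an authentication failure,
  never garbage, and no file is created.

Authentication is not part of bare AES-128; we added it because silently
corrupted medical images are worse than refused ones. Exported filenames
are obfuscated to zero-padded sequence numbers (`000001.bin` …) assigned
in instance order, so a plain lexicographic sort of names reproduces the
original image order; the reconstruction manifest (original identifiers
and ordering) is itself encrypted under the same key as index
`000000.bin`, so filenames leak nothing.

## The synthetic archive

The package ships a generator of standards-valid secondary-capture DICOM
studies and an in-process mock archive, so the entire stack is testable
with no clinical data. Generated instances carry the full identifying
attribute set (patient, study, series, instance, modality, institution)
with all UIDs deterministic functions of a seed — identical specs are
byte-identical — and small deterministic pixel data (default 32×32,
8-bit; 8×8 in most tests). Realistic study sizes for quota scenarios are
simulated with a trailing padding element rather than realistic pixel
volumes, so ~100 MB-scale accounting is exercised with kilobyte files.
The mock archive answers patient/study queries and study moves over the
package's in-process DICOM message layer, applies configurable behavior
(association refusal, per-move failure probability, off-line-archive
delays) from its own seeded random source, and records every query it
receives — that record is how the no-leak tests *observe* that off-list
MRNs never reach the wire.

What the mock does not emulate: the DICOM upper-layer network protocol
itself (TCP associations, PDU encoding), modality-specific IODs,
compressed transfer syntaxes, and HL7-driven content churn. Passing tests
therefore demonstrate the broker's governance, accounting and
cryptographic properties, and file-level interoperability (every
generated file parses with an independent DICOM reader); they do not
demonstrate wire-level interoperability with a vendor PACS.

## Numerical and procedural choices

* Per-patient study limits return the most recent studies first
  (StudyDate descending, ties broken by StudyInstanceUID ascending) and
  set a truncation flag — the ordering had to be fixed somewhere to be
  deterministic.
* Faceted filters are a conjunction across columns; a value-set facet
  passes a multi-valued cell (e.g. modalities `CT\MR`) when any member
  matches; range facets compare numerically when the column parses as
  numbers and lexicographically otherwise (ISO dates order correctly as
  text).
* Duplicate live requests for the same (project, study) are refused with
  the existing ticket named; resubmission after failure is allowed.
* Problem sizes in the shipped test and acceptance runs: fairness over
  rings of 2–5 projects (exhaustive) plus 100 randomized workloads;
  governance traces of a few simulated hours; a 500-request stochastic
  end-to-end run at 3 % injected move failure; 50-stream crypto
  round-trips up to ~120 KB. These sizes make the suites deterministic
  and fast while still exercising every boundary; they are scale models
  of deployment traffic, not reproductions of it.

## Known limitations

* Authentication of users is out of scope; the service trusts the
  username the CLI layer supplies, as authorization is project-scoped.
* The wire protocol is modeled in-process (see above); integrating a
  real DICOM network stack would replace the transport behind the
  gateway surface without changing any governance logic.
* No automatic retry, no priority classes, no preemption, no
  cross-endpoint rate pooling, no de-identification — the broker moves
  identified data under IRB constraints; protecting it after export is
  the user's responsibility, which is exactly what the encrypted export
  supports.
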