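Package: pacsbroker
Title: Governed Research Access Broker for Clinical Imaging Archives
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A headless broker that lets credentialed research projects find
    and retrieve radiology studies from clinical PACS archives under
    institutional governance. Provides DICOM patient/study query and
    study retrieval against one or more archive endpoints, IRB-scoped
    medical-record-number allowlists with project expiration, fair
    round-robin scheduling with time-of-day rate windows and concurrency
    caps, per-project quota-limited image caches, an append-only audit
    trail, and AES-128 authenticated encrypted export with
    order-preserving filename obfuscation. Ships a deterministic
    synthetic DICOM study generator and a configurable mock archive so
    the whole stack is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    yaml,
    jsonlite,
    openssl,
    digest
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
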