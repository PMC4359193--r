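# Encrypted export: AES-128 under a passphrase-derived key, streamed so no
# plaintext ever touches the destination disk, with order-preserving
# obfuscated filenames and an encrypted reconstruction manifest.
#
# On-disk container format (version 1), byte-exact so third parties can
# decrypt:
#   offset 0   magic   4 bytes  "PBE1"
#   offset 4   version 1 byte   0x01
#   offset 5   salt    16 bytes (PBKDF2 salt, random per export)
#   offset 21  iters   4 bytes  big-endian PBKDF2 iteration count
#   offset 25  nonce   16 bytes (random per file)
#   then ciphertext chunks, each: 4-byte big-endian length, then that many
#     bytes of AES-128-CBC ciphertext (PKCS#7, chunk i's IV is the first
#     16 bytes of HMAC-SHA256(mac_key, nonce || uint32_be(i)))
#   then a 4-byte zero sentinel
#   then 32 bytes HMAC-SHA256(mac_key, all preceding bytes)  (encrypt-then-MAC)
# Key schedule: PBKDF2-HMAC-SHA256(passphrase, salt, iters, 48 bytes);
# bytes 1-16 are the AES-128 key, bytes 17-48 the MAC key.

CRYPTO_MAGIC <- charToRaw("PBE1")
CRYPTO_VERSION <- as.raw(1L)
DEFAULT_KDF_ITERS <- 1000L  # ~100 ms of stretching on commodity hardware
CRYPTO_CHUNK <- 65536L

# PBKDF2-HMAC-SHA256 (RFC 2898); verified against hashlib.pbkdf2_hmac in
# the test suite.
pbkdf2_sha256 <- function(passphrase, salt, iterations, dklen = 32L) {
  prf <- function(msg) as.raw(openssl::sha256(msg, key = charToRaw(passphrase)))
  nblocks <- ceiling(dklen / 32L)
  out <- raw(0)
  for (i in seq_len(nblocks)) {
    u <- prf(c(salt, uint32_be(i)))
    t <- u
    if (iterations > 1) for (j in 2:iterations) {
      u <- prf(u)
      t <- as.raw(bitwXor(as.integer(t), as.integer(u)))
    }
    out <- c(out, t)
  }
  out[seq_len(dklen)]
}

#' Derive export key material from a passphrase
#'
#' Deterministic for a fixed (passphrase, salt, iterations) triple. The
#' encryption key is 128 bits; a separate MAC key is derived from the same
#' passphrase stretch.
#'
#' @param passphrase user-defined secret (non-empty)
#' @param salt 16 random bytes; freshly drawn when omitted (one salt per
#'   export)
#' @param iterations PBKDF2 iteration count
#' @return a `key_material` list: `key` (16 bytes), `mac_key` (32 bytes),
#'   `salt`, `kdf_params`
#' @export
derive_key <- function(passphrase, salt = openssl::rand_bytes(16),
                       iterations = DEFAULT_KDF_ITERS) {
  if (!is.character(passphrase) || length(passphrase) != 1 || !nzchar(passphrase))
    pb_usage_error("passphrase must be a non-empty string")
  salt <- as.raw(salt)
  stopifnot(length(salt) == 16)
  dk <- pbkdf2_sha256(passphrase, salt, iterations, 48L)
  structure(list(key = dk[1:16], mac_key = dk[17:48], salt = salt,
                 kdf_params = list(iterations = as.integer(iterations))),
            class = "key_material")
}

chunk_iv <- function(mac_key, nonce, i) {
  as.raw(openssl::sha256(c(nonce, uint32_be(i)), key = mac_key))[1:16]
}

#' Encrypt a byte stream to an export file
#'
#' Ciphertext is written incrementally: at no point during or after the
#' operation does any byte of plaintext reach the destination. On a
#' mid-stream write failure the partial file is removed.
#'
#' @param src a raw vector, or a path to a file read in chunks
#' @param key a `key_material` from [derive_key()]
#' @param dest destination file path
#' @param sink optional function(raw) replacing the file writer — used by
#'   tests to intercept every write; when supplied nothing touches disk
#' @return `dest` (or, with a `sink`, the total byte count), invisibly
#' @export
encrypt_stream <- function(src, key, dest, sink = NULL) {
  stopifnot(inherits(key, "key_material"))
  hmac_buf <- raw(0)
  if (is.null(sink)) {
    dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
    con <- file(dest, open = "wb")
    writer <- function(r) writeBin(r, con)
  } else {
    con <- NULL
    writer <- sink
  }
  cleanup_needed <- TRUE
  on.exit({
    if (!is.null(con)) close(con)
    if (cleanup_needed && is.null(sink) && file.exists(dest)) unlink(dest)
  })
  emit <- function(r) {
    hmac_buf <<- c(hmac_buf, r)
    writer(r)
  }
  nonce <- openssl::rand_bytes(16)
  emit(c(CRYPTO_MAGIC, CRYPTO_VERSION, key$salt,
         uint32_be(key$kdf_params$iterations), nonce))
  read_next <- if (is.raw(src)) {
    pos <- 0L
    function() {
      if (pos >= length(src)) return(NULL)
      take <- min(CRYPTO_CHUNK, length(src) - pos)
      out <- src[(pos + 1L):(pos + take)]
      pos <<- pos + take
      out
    }
  } else {
    fcon <- file(src, open = "rb")
    on.exit(close(fcon), add = TRUE)
    function() {
      r <- readBin(fcon, "raw", n = CRYPTO_CHUNK)
      if (length(r) == 0) NULL else r
    }
  }
  i <- 0L
  repeat {
    pt <- read_next()
    if (is.null(pt) && i > 0L) break
    i <- i + 1L
    ct <- openssl::aes_cbc_encrypt(pt %||% raw(0), key = key$key,
                                   iv = chunk_iv(key$mac_key, nonce, i))
    emit(c(uint32_be(length(ct)), as.raw(ct)))
    if (is.null(pt)) break
  }
  emit(uint32_be(0L))
  tag <- as.raw(openssl::sha256(hmac_buf, key = key$mac_key))
  writer(tag)
  cleanup_needed <- FALSE
  invisible(if (is.null(sink)) dest else length(hmac_buf) + 32L)
}

#' Decrypt an export file entirely to memory
#'
#' Authenticates before decrypting: a tampered file or a wrong passphrase
#' raises an authentication error rather than yielding garbage. No file is
#' ever created.
#'
#' @param path encrypted file produced by [encrypt_stream()]
#' @param key_or_passphrase a `key_material`, or the passphrase (the salt
#'   and iteration count are read from the file header)
#' @return the plaintext as a raw vector
#' @export
decrypt_to_memory <- function(path, key_or_passphrase) {
  r <- readBin(path, "raw", n = file.size(path))
  if (length(r) < 57 || !identical(r[1:4], CRYPTO_MAGIC))
    pb_crypto_error("not an encrypted export file")
  if (r[5] != CRYPTO_VERSION) pb_crypto_error("unsupported format version")
  salt <- r[6:21]
  iters <- read_uint32_be(r[22:25])
  nonce <- r[26:41]
  key <- if (inherits(key_or_passphrase, "key_material")) key_or_passphrase
         else derive_key(key_or_passphrase, salt = salt, iterations = iters)
  if (!identical(key$salt, salt))
    key <- derive_key_from_material_mismatch(key, salt, iters, key_or_passphrase)
  body <- r[1:(length(r) - 32L)]
  tag <- r[(length(r) - 31L):length(r)]
  want <- as.raw(openssl::sha256(body, key = key$mac_key))
  if (!identical(as.raw(tag), want))
    pb_crypto_error("authentication failure: wrong key or corrupted file")
  pos <- 42L
  out <- list(); i <- 0L
  repeat {
    len <- read_uint32_be(r[pos:(pos + 3L)])
    pos <- pos + 4L
    if (len == 0L) break
    i <- i + 1L
    ct <- r[pos:(pos + len - 1L)]
    pos <- pos + len
    out[[i]] <- as.raw(openssl::aes_cbc_decrypt(
      ct, key = key$key, iv = chunk_iv(key$mac_key, nonce, i)))
  }
  if (length(out) == 0) raw(0) else do.call(c, out)
}

# A key_material derived for a different salt cannot authenticate this
# file; surface that as an authentication failure, not a silent mismatch.
derive_key_from_material_mismatch <- function(key, salt, iters, orig) {
  pb_crypto_error("authentication failure: key material does not match file salt")
}

#' Build the order-preserving obfuscation manifest for a cache entry
#'
#' Instance files are renamed to zero-padded sequence numbers with a
#' non-semantic extension (`000001.bin`, `000002.bin`, ...) assigned in the
#' entry's (SeriesNumber, InstanceNumber, SOPInstanceUID) order, so a plain
#' lexicographic sort of the exported names reproduces the original image
#' order. Index `000000.bin` is reserved for the encrypted manifest itself.
#'
#' @param entry a `cache_entry`
#' @return an `obfuscation_manifest`: `names` (obfuscated, in order),
#'   `map` (one row per instance: obfuscated_name, sop_uid, series_number,
#'   instance_number, original_file) and study metadata needed to
#'   reconstruct the export
#' @export
build_obfuscation_manifest <- function(entry) {
  stopifnot(length(entry$file_layout) >= 1)
  n <- length(entry$file_layout)
  obf <- sprintf("%06d.bin", seq_len(n))
  map <- data.frame(
    obfuscated_name = obf,
    sop_uid = vapply(entry$file_layout, `[[`, "", "sop_uid"),
    series_number = vapply(entry$file_layout, `[[`, 0L, "series_number"),
    instance_number = vapply(entry$file_layout, `[[`, 0L, "instance_number"),
    original_file = vapply(entry$file_layout, `[[`, "", "file"),
    stringsAsFactors = FALSE)
  structure(list(names = obf, map = map,
                 study_instance_uid = entry$study_instance_uid,
                 accession_number = entry$accession_number,
                 canonical_mrn = entry$canonical_mrn,
                 manifest_name = "000000.bin"),
            class = "obfuscation_manifest")
}

#' Encrypted export of a cache entry
#'
#' Writes one `.bin` container per instance plus the encrypted manifest
#' (`000000.bin`) into `dest_dir`. All files share one export salt; no
#' plaintext file is ever created at the destination.
#'
#' @param entry a `cache_entry`
#' @param dest_dir destination directory
#' @param passphrase user-defined export secret
#' @param iterations PBKDF2 iteration count
#' @return the `obfuscation_manifest`, invisibly
#' @export
export_encrypted <- function(entry, dest_dir, passphrase,
                             iterations = DEFAULT_KDF_ITERS) {
  man <- build_obfuscation_manifest(entry)
  key <- derive_key(passphrase, iterations = iterations)
  dir.create(dest_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(entry$file_layout))
    encrypt_stream(entry$file_layout[[i]]$file, key,
                   file.path(dest_dir, man$names[i]))
  man_json <- charToRaw(jsonlite::toJSON(list(
    study_instance_uid = man$study_instance_uid,
    accession_number = man$accession_number,
    canonical_mrn = man$canonical_mrn,
    map = man$map[, c("obfuscated_name", "sop_uid", "series_number",
                      "instance_number")]), auto_unbox = TRUE))
  encrypt_stream(man_json, key, file.path(dest_dir, man$manifest_name))
  invisible(man)
}
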