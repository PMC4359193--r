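# Minimal DICOM Part-10 file I/O: explicit VR little endian only.
#
# Scope is deliberately narrow — the broker needs to write standards-valid
# secondary-capture instances (synthetic fixtures, staging, cache, export)
# and to read back the identifying attributes it wrote. Sequences,
# compressed transfer syntaxes and implicit VR are out of scope; files are
# validated against an independent third-party parser in the test suite.

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
SOP_SECONDARY_CAPTURE <- "1.2.840.10008.5.1.4.1.1.7"
IMPLEMENTATION_UID <- "1.2.826.0.1.3680043.9.7484.1"

# tag -> c(VR); keyword table for the attributes this package handles
DCM_DICT <- list(
  "00080005" = c("CS", "SpecificCharacterSet"),
  "00080016" = c("UI", "SOPClassUID"),
  "00080018" = c("UI", "SOPInstanceUID"),
  "00080020" = c("DA", "StudyDate"),
  "00080050" = c("SH", "AccessionNumber"),
  "00080060" = c("CS", "Modality"),
  "00080061" = c("CS", "ModalitiesInStudy"),
  "00080080" = c("LO", "InstitutionName"),
  "00081030" = c("LO", "StudyDescription"),
  "00100010" = c("PN", "PatientName"),
  "00100020" = c("LO", "PatientID"),
  "00100030" = c("DA", "PatientBirthDate"),
  "0020000d" = c("UI", "StudyInstanceUID"),
  "0020000e" = c("UI", "SeriesInstanceUID"),
  "00200011" = c("IS", "SeriesNumber"),
  "00200013" = c("IS", "InstanceNumber"),
  "00280002" = c("US", "SamplesPerPixel"),
  "00280004" = c("CS", "PhotometricInterpretation"),
  "00280010" = c("US", "Rows"),
  "00280011" = c("US", "Columns"),
  "00280100" = c("US", "BitsAllocated"),
  "00280101" = c("US", "BitsStored"),
  "00280102" = c("US", "HighBit"),
  "00280103" = c("US", "PixelRepresentation"),
  "7fe00010" = c("OB", "PixelData"),
  "fffcfffc" = c("OB", "DataSetTrailingPadding")
)
DCM_KEYWORDS <- stats::setNames(names(DCM_DICT),
                                vapply(DCM_DICT, `[`, "", 2))

uint16_le <- function(n) as.raw(c(bitwAnd(n, 255L), bitwAnd(bitwShiftR(n, 8), 255L)))
uint32_le <- function(n) {
  as.raw(c(n %% 256, (n %/% 256) %% 256, (n %/% 65536) %% 256, (n %/% 16777216) %% 256))
}

dcm_encode_element <- function(tag, vr, value) {
  grp <- strtoi(substr(tag, 1, 4), 16L)
  ele <- strtoi(substr(tag, 5, 8), 16L)
  body <- switch(vr,
    US = do.call(c, lapply(as.integer(value), uint16_le)),
    UL = do.call(c, lapply(as.integer(value), uint32_le)),
    OB = as.raw(value),
    {
      s <- paste(as.character(value), collapse = "\\")
      r <- charToRaw(s)
      if (length(r) %% 2 == 1)
        r <- c(r, if (vr == "UI") as.raw(0L) else charToRaw(" "))
      r
    })
  if (length(body) %% 2 == 1) body <- c(body, as.raw(0L))
  if (vr %in% c("OB", "OW", "UN", "UT", "SQ")) {
    c(uint16_le(grp), uint16_le(ele), charToRaw(vr), as.raw(c(0L, 0L)),
      uint32_le(length(body)), body)
  } else {
    c(uint16_le(grp), uint16_le(ele), charToRaw(vr), uint16_le(length(body)), body)
  }
}

#' Write a DICOM Part-10 file
#'
#' Encodes the given attributes as explicit VR little endian with a
#' standard 128-byte preamble, 'DICM' magic and file meta group. Element
#' values are named by DICOM keyword (e.g. `PatientID`, `StudyInstanceUID`,
#' `PixelData`); `PixelData` is a raw vector.
#'
#' @param path output file
#' @param attrs named list of attribute values keyed by DICOM keyword
#' @return `path`, invisibly
#' @export
dcm_write <- function(path, attrs) {
  stopifnot(!is.null(attrs$SOPInstanceUID), !is.null(attrs$SOPClassUID))
  tags <- DCM_KEYWORDS[names(attrs)]
  if (anyNA(tags))
    pb_stop("pb_dicom_error",
            sprintf("unknown DICOM keyword(s): %s",
                    paste(names(attrs)[is.na(tags)], collapse = ", ")))
  o <- order(tags)
  dataset <- do.call(c, lapply(o, function(i) {
    tag <- tags[[i]]
    dcm_encode_element(tag, DCM_DICT[[tag]][1], attrs[[i]])
  }))
  meta_elems <- c(
    dcm_encode_element("00020001", "OB", as.raw(c(0L, 1L))),
    dcm_encode_element("00020002", "UI", attrs$SOPClassUID),
    dcm_encode_element("00020003", "UI", attrs$SOPInstanceUID),
    dcm_encode_element("00020010", "UI", TS_EXPLICIT_LE),
    dcm_encode_element("00020012", "UI", IMPLEMENTATION_UID)
  )
  meta <- c(dcm_encode_element("00020000", "UL", length(meta_elems)), meta_elems)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, dataset), con)
  invisible(path)
}

#' Read a DICOM Part-10 file written in explicit VR little endian
#'
#' Returns attribute values keyed by DICOM keyword. String values are
#' trimmed of padding; multi-valued strings keep their `\` separators;
#' `US`/`UL` are integers; `PixelData` and other binary elements are raw.
#'
#' @param path file to read
#' @param keywords optional subset of keywords to return
#' @return named list of attribute values
#' @export
dcm_read <- function(path, keywords = NULL) {
  r <- readBin(path, "raw", n = file.size(path))
  if (length(r) < 140 || rawToChar(r[129:132]) != "DICM")
    pb_stop("pb_dicom_error", sprintf("'%s' is not a DICOM Part-10 file", path))
  pos <- 133L
  out <- list()
  u16 <- function(i) as.integer(r[i]) + 256L * as.integer(r[i + 1L])
  u32 <- function(i) as.integer(r[i]) + 256 * as.integer(r[i + 1L]) +
    65536 * as.integer(r[i + 2L]) + 16777216 * as.integer(r[i + 3L])
  while (pos + 7L <= length(r) + 1L && pos < length(r)) {
    grp <- u16(pos); ele <- u16(pos + 2L)
    vr <- rawToChar(r[(pos + 4L):(pos + 5L)])
    if (vr %in% c("OB", "OW", "UN", "UT", "SQ")) {
      len <- u32(pos + 8L); body_at <- pos + 12L
    } else {
      len <- u16(pos + 6L); body_at <- pos + 8L
    }
    body <- if (len > 0) r[body_at:(body_at + len - 1L)] else raw(0)
    tag <- sprintf("%04x%04x", grp, ele)
    kw <- if (!is.null(DCM_DICT[[tag]])) DCM_DICT[[tag]][2] else tag
    val <- switch(vr,
      US = vapply(seq_len(len %/% 2L), function(k) u16(body_at + 2L * (k - 1L)), 0L),
      UL = vapply(seq_len(len %/% 4L), function(k) u32(body_at + 4L * (k - 1L)), 0),
      OB = , OW = , UN = body,
      sub(" +$", "", rawToChar(body[body != as.raw(0L)])))
    if (grp != 2L) out[[kw]] <- val
    pos <- body_at + len
  }
  if (!is.null(keywords)) out <- out[intersect(names(out), keywords)]
  out
}

# Deterministic UID arithmetic: all synthetic UIDs live under one org root
# and are pure functions of (seed, indices), so identical generator specs
# yield identical identifiers.
uid_root <- function() "1.2.826.0.1.3680043.9.7484"
make_uid <- function(...) {
  uid <- paste(c(uid_root(), ...), collapse = ".")
  stopifnot(nchar(uid) <= 64)
  uid
}
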