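# Minimal DICOM Part-10 reader/writer, explicit VR little endian only.
#
# No DICOM library is available in the deployment environment, so the small
# subset of the standard this package needs -- file meta header, explicit VR
# LE datasets, nested sequences with defined or undefined lengths -- is
# implemented here. It is NOT a general DICOM implementation: other transfer
# syntaxes are rejected with a parse error, and only the VRs used by CT /
# RT Plan / RT Structure Set geometry are decoded.
#
# A dataset is represented as a named list keyed by "GGGGEEEE" (upper-case
# hex tag); each entry is list(vr = <2-char VR>, value = <decoded value>).
# SQ values are lists of item datasets.

TRANSFER_SYNTAX_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

SOP_CLASS <- c(
  ct       = "1.2.840.10008.5.1.4.1.1.2",
  rtstruct = "1.2.840.10008.5.1.4.1.1.481.3",
  rtplan   = "1.2.840.10008.5.1.4.1.1.481.5"
)

# VRs encoded with a 2-byte reserved field and 4-byte length
.LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")
.STRING_VRS <- c("AE", "AS", "CS", "DA", "DS", "DT", "IS", "LO", "LT",
                 "PN", "SH", "ST", "TM", "UI")

tagkey <- function(group, element) sprintf("%04X%04X", group, element)

dcm_el <- function(vr, value) list(vr = vr, value = value)

u16le <- function(x) {
  x <- as.integer(x)
  as.raw(c(x %% 256L, (x %/% 256L) %% 256L))
}

u32le <- function(x) {
  x <- as.numeric(x) # lengths can exceed .Machine$integer.max / 2 in theory
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
}

rd_u16 <- function(bytes, pos) as.integer(bytes[pos]) + 256L * as.integer(bytes[pos + 1L])
rd_u32 <- function(bytes, pos) {
  as.numeric(bytes[pos]) + 256 * as.numeric(bytes[pos + 1L]) +
    65536 * as.numeric(bytes[pos + 2L]) + 16777216 * as.numeric(bytes[pos + 3L])
}

# ---- encoding -------------------------------------------------------------

fmt_ds <- function(x) {
  # DS values are limited to 16 bytes; %.6f keeps every coordinate this
  # package handles (|mm| well under 1e8) exact to 5e-7 mm
  s <- sprintf("%.6f", x)
  if (any(nchar(s) > 16)) abort_value("DS value does not fit in 16 characters")
  s
}

encode_value <- function(vr, value) {
  if (vr == "SQ") {
    items <- lapply(value, function(item) {
      body <- encode_dataset(item)
      c(u16le(0xFFFE), u16le(0xE000), u32le(length(body)), body)
    })
    return(do.call(c, c(items, list(raw(0)))))
  }
  if (vr %in% c("OB", "OW")) {
    v <- as.raw(value)
    if (length(v) %% 2L == 1L) v <- c(v, as.raw(0))
    return(v)
  }
  if (vr == "US") return(do.call(c, lapply(as.integer(value), u16le)))
  if (vr == "UL") return(do.call(c, lapply(value, u32le)))
  if (vr %in% .STRING_VRS) {
    s <- if (vr == "DS") fmt_ds(value) else if (vr == "IS") sprintf("%d", as.integer(value)) else as.character(value)
    b <- charToRaw(paste(s, collapse = "\\"))
    if (length(b) %% 2L == 1L) b <- c(b, if (vr == "UI") as.raw(0) else charToRaw(" "))
    return(b)
  }
  abort_value(sprintf("unsupported VR for encoding: %s", vr))
}

encode_element <- function(key, el) {
  group <- strtoi(substr(key, 1, 4), 16L)
  element <- strtoi(substr(key, 5, 8), 16L)
  body <- encode_value(el$vr, el$value)
  hdr <- c(u16le(group), u16le(element), charToRaw(el$vr))
  if (el$vr %in% .LONG_VRS) {
    c(hdr, raw(2), u32le(length(body)), body)
  } else {
    if (length(body) > 65534) abort_value("value too long for short-form VR")
    c(hdr, u16le(length(body)), body)
  }
}

encode_dataset <- function(ds) {
  keys <- sort(names(ds))
  do.call(c, c(lapply(keys, function(k) encode_element(k, ds[[k]])), list(raw(0))))
}

#' Write a DICOM file (explicit VR little endian)
#'
#' Serializes a dataset (as produced by the fixture generator or read back by
#' [dcm_read()]) to a DICOM Part-10 file: 128-byte preamble, "DICM" marker,
#' file meta group, then the dataset.
#'
#' @param ds dataset: named list keyed by `"GGGGEEEE"` hex tags, entries
#'   `list(vr=, value=)`. Must contain SOPClassUID (0008,0016) and
#'   SOPInstanceUID (0008,0018).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
dcm_write <- function(ds, file) {
  sop_class <- ds[[tagkey(0x0008, 0x0016)]]
  sop_inst <- ds[[tagkey(0x0008, 0x0018)]]
  if (is.null(sop_class) || is.null(sop_inst)) {
    abort_value("dataset must carry SOPClassUID (0008,0016) and SOPInstanceUID (0008,0018)")
  }
  meta <- list()
  meta[[tagkey(0x0002, 0x0001)]] <- dcm_el("OB", as.raw(c(0, 1)))
  meta[[tagkey(0x0002, 0x0002)]] <- dcm_el("UI", sop_class$value)
  meta[[tagkey(0x0002, 0x0003)]] <- dcm_el("UI", sop_inst$value)
  meta[[tagkey(0x0002, 0x0010)]] <- dcm_el("UI", TRANSFER_SYNTAX_EXPLICIT_LE)
  meta[[tagkey(0x0002, 0x0012)]] <- dcm_el("UI", "1.2.826.0.1.3680043.9.7584.1")
  meta_body <- encode_dataset(meta)
  group_len <- encode_element(tagkey(0x0002, 0x0000), dcm_el("UL", length(meta_body)))
  bytes <- c(raw(128), charToRaw("DICM"), group_len, meta_body, encode_dataset(ds))
  writeBin(bytes, file)
  invisible(file)
}

# ---- decoding -------------------------------------------------------------

decode_value <- function(vr, body) {
  if (vr %in% c("OB", "OW", "UN", "OF")) return(body)
  if (vr == "US") {
    n <- length(body) %/% 2L
    return(vapply(seq_len(n), function(i) rd_u16(body, 2L * i - 1L), integer(1)))
  }
  if (vr == "UL") {
    n <- length(body) %/% 4L
    return(vapply(seq_len(n), function(i) rd_u32(body, 4L * i - 3L), numeric(1)))
  }
  s <- rawToChar(body[body != as.raw(0)])
  parts <- if (nzchar(s)) strsplit(s, "\\", fixed = TRUE)[[1]] else character(0)
  parts <- trimws(parts)
  if (vr == "DS") {
    v <- suppressWarnings(as.numeric(parts))
    if (anyNA(v)) abort_parse(sprintf("malformed DS value: %s", s))
    return(v)
  }
  if (vr == "IS") {
    v <- suppressWarnings(as.integer(parts))
    if (anyNA(v)) abort_parse(sprintf("malformed IS value: %s", s))
    return(v)
  }
  parts
}

# parse elements from `pos` up to `end` (exclusive, 1-based bytes index);
# stops early at an item-delimitation tag when `in_item` is TRUE
parse_elements <- function(bytes, pos, end, in_item = FALSE) {
  ds <- list()
  while (pos < end) {
    if (end - pos + 1L < 8L) abort_parse("truncated DICOM element header")
    group <- rd_u16(bytes, pos); element <- rd_u16(bytes, pos + 2L)
    if (group == 0xFFFE && element == 0xE00D) { # item delimiter
      if (!in_item) abort_parse("unexpected item delimitation tag")
      return(list(ds = ds, pos = pos + 8L, delimited = TRUE))
    }
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr)) {
      abort_parse(sprintf("tag (%04X,%04X): not explicit VR little endian", group, element))
    }
    if (vr %in% .LONG_VRS) {
      len <- rd_u32(bytes, pos + 8L)
      pos <- pos + 12L
    } else {
      len <- rd_u16(bytes, pos + 6L)
      pos <- pos + 8L
    }
    key <- tagkey(group, element)
    if (vr == "SQ") {
      sq <- parse_sequence(bytes, pos, len)
      ds[[key]] <- dcm_el("SQ", sq$items)
      pos <- sq$pos
    } else {
      if (len == 0xFFFFFFFF) abort_parse(sprintf("undefined length on non-SQ tag %s", key))
      if (pos + len - 1L > length(bytes)) abort_parse(sprintf("tag %s value overruns file", key))
      body <- if (len > 0) bytes[pos:(pos + len - 1L)] else raw(0)
      ds[[key]] <- dcm_el(vr, decode_value(vr, body))
      pos <- pos + as.integer(len)
    }
  }
  list(ds = ds, pos = pos, delimited = FALSE)
}

parse_sequence <- function(bytes, pos, len) {
  undefined <- len == 0xFFFFFFFF
  end <- if (undefined) length(bytes) + 1L else pos + as.integer(len)
  items <- list()
  while (pos < end) {
    group <- rd_u16(bytes, pos); element <- rd_u16(bytes, pos + 2L)
    ilen <- rd_u32(bytes, pos + 4L)
    pos <- pos + 8L
    if (group == 0xFFFE && element == 0xE0DD) { # sequence delimiter
      if (!undefined) abort_parse("sequence delimiter inside defined-length sequence")
      return(list(items = items, pos = pos))
    }
    if (!(group == 0xFFFE && element == 0xE000)) {
      abort_parse(sprintf("expected sequence item, found (%04X,%04X)", group, element))
    }
    if (ilen == 0xFFFFFFFF) {
      parsed <- parse_elements(bytes, pos, length(bytes) + 1L, in_item = TRUE)
      if (!parsed$delimited) abort_parse("unterminated undefined-length item")
    } else {
      parsed <- parse_elements(bytes, pos, pos + as.integer(ilen), in_item = FALSE)
    }
    items[[length(items) + 1L]] <- parsed$ds
    pos <- parsed$pos
  }
  if (undefined) abort_parse("unterminated undefined-length sequence")
  list(items = items, pos = pos)
}

#' Read a DICOM file (explicit VR little endian)
#'
#' @param file path to a DICOM Part-10 file.
#' @return a list with `meta` (file meta group) and `data` (the dataset),
#'   each a named list keyed by `"GGGGEEEE"` hex tags.
#' @export
dcm_read <- function(file) {
  if (!file.exists(file)) abort_parse(sprintf("no such file: %s", file))
  bytes <- readBin(file, "raw", n = file.size(file))
  if (length(bytes) < 140 || rawToChar(bytes[129:132]) != "DICM") {
    abort_parse(sprintf("%s: not a DICOM Part-10 file (missing DICM marker)", file))
  }
  pos <- 133L
  # file meta group (0002,xxxx) is always explicit VR LE; scan until the
  # group changes
  meta <- list()
  while (pos < length(bytes) && rd_u16(bytes, pos) == 0x0002) {
    one <- parse_one_meta(bytes, pos)
    meta[[one$key]] <- one$el
    pos <- one$pos
  }
  ts <- meta[[tagkey(0x0002, 0x0010)]]
  if (is.null(ts) || !identical(ts$value, TRANSFER_SYNTAX_EXPLICIT_LE)) {
    abort_parse(sprintf(
      "unsupported transfer syntax %s (only explicit VR little endian is supported)",
      if (is.null(ts)) "<missing>" else ts$value
    ))
  }
  parsed <- parse_elements(bytes, pos, length(bytes) + 1L)
  list(meta = meta, data = parsed$ds)
}

parse_one_meta <- function(bytes, pos) {
  group <- rd_u16(bytes, pos); element <- rd_u16(bytes, pos + 2L)
  vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
  if (vr %in% .LONG_VRS) {
    len <- rd_u32(bytes, pos + 8L); pos <- pos + 12L
  } else {
    len <- rd_u16(bytes, pos + 6L); pos <- pos + 8L
  }
  body <- if (len > 0) bytes[pos:(pos + len - 1L)] else raw(0)
  list(key = tagkey(group, element), el = dcm_el(vr, decode_value(vr, body)),
       pos = pos + as.integer(len))
}

# convenience accessor: value of a tag or NULL
dcm_get <- function(ds, group, element) {
  el <- ds[[tagkey(group, element)]]
  if (is.null(el)) NULL else el$value
}
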