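# Minimal multi-frame DICOM I/O: explicit VR little endian, MONOCHROME2,
# 16-bit grayscale, the handful of tags the pipeline needs. This is not a
# general DICOM toolkit: unsupported transfer syntaxes and missing
# spacing/timing attributes raise rather than silently default.

UID_EXPLICIT_VR_LE <- "1.2.840.10008.1.2.1"
UID_US_MULTIFRAME <- "1.2.840.10008.5.1.4.1.1.3.1"

# --- low-level byte helpers -------------------------------------------------

u16le <- function(x) as.raw(c(x %% 256L, x %/% 256L))

u32le <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

readU16 <- function(r, off) as.integer(r[off]) + 256L * as.integer(r[off + 1L])

readU32 <- function(r, off) {
  as.numeric(r[off]) + 256 * as.numeric(r[off + 1L]) +
    65536 * as.numeric(r[off + 2L]) + 16777216 * as.numeric(r[off + 3L])
}

# Encode one data element, explicit VR little endian.
dcmElement <- function(group, element, vr, value) {
  payload <- if (vr %in% c("UI", "CS", "DS", "IS", "LO", "SH")) {
    v <- charToRaw(paste(value, collapse = "\\"))
    if (length(v) %% 2L == 1L)
      v <- c(v, if (vr == "UI") as.raw(0L) else charToRaw(" "))
    v
  } else if (vr == "US") {
    do.call(c, lapply(as.integer(value), u16le))
  } else if (vr == "UL") {
    u32le(value)
  } else if (vr %in% c("OB", "OW")) {
    as.raw(value)
  } else stop("unsupported VR: ", vr)
  head <- c(u16le(group), u16le(element), charToRaw(vr))
  if (vr %in% c("OB", "OW", "UT", "UN", "SQ")) {
    c(head, as.raw(c(0L, 0L)), u32le(length(payload)), payload)
  } else {
    if (length(payload) > 65535L) stop("element too long for short VR")
    c(head, u16le(length(payload)), payload)
  }
}

dcmNumber <- function(x) sprintf("%.12g", x)

# --- writer -----------------------------------------------------------------

#' @keywords internal
writeDicomCine <- function(cine, path) {
  fr <- cine@frames
  if (any(fr < 0 | fr > 65535) || any(fr != round(fr)))
    stop("DICOM writer requires integer grey levels in [0, 65535]")
  d <- dim(fr)
  rows <- d[1]; cols <- d[2]; nf <- d[3]
  # pixel data: frames in order, row-major within each frame, uint16 LE
  vals <- integer(rows * cols * nf)
  k <- rows * cols
  for (f in seq_len(nf))
    vals[((f - 1) * k + 1):(f * k)] <- as.integer(t(fr[, , f]))
  pix <- as.raw(rbind(vals %% 256L, vals %/% 256L))

  # deterministic content-derived instance UID (keeps writing a pure function)
  chk <- sum(as.numeric(fr[seq(1, length(fr), by = 97)])) %% 1e9
  instanceUid <- sprintf("2.25.%d.%d.%d.%.0f", rows, cols, nf, chk)
  meta <- c(
    dcmElement(0x0002, 0x0001, "OB", c(0L, 1L)),
    dcmElement(0x0002, 0x0002, "UI", UID_US_MULTIFRAME),
    dcmElement(0x0002, 0x0003, "UI", instanceUid),
    dcmElement(0x0002, 0x0010, "UI", UID_EXPLICIT_VR_LE))
  body <- c(
    dcmElement(0x0008, 0x0016, "UI", UID_US_MULTIFRAME),
    dcmElement(0x0008, 0x0018, "UI", instanceUid),
    dcmElement(0x0008, 0x0060, "CS", "US"),
    dcmElement(0x0008, 0x103E, "LO", cine@sourceId),
    dcmElement(0x0018, 0x1063, "DS", dcmNumber(cine@frameInterval * 1000)),
    dcmElement(0x0028, 0x0002, "US", 1L),
    dcmElement(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcmElement(0x0028, 0x0008, "IS", as.character(nf)),
    dcmElement(0x0028, 0x0010, "US", rows),
    dcmElement(0x0028, 0x0011, "US", cols),
    dcmElement(0x0028, 0x0030, "DS",
               c(dcmNumber(cine@pixelSpacing[1]),
                 dcmNumber(cine@pixelSpacing[2]))),
    dcmElement(0x0028, 0x0100, "US", 16L),
    dcmElement(0x0028, 0x0101, "US", 16L),
    dcmElement(0x0028, 0x0102, "US", 15L),
    dcmElement(0x0028, 0x0103, "US", 0L),
    dcmElement(0x7FE0, 0x0010, "OW", pix))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(dcmElement(0x0002, 0x0000, "UL", length(meta)), con)
  writeBin(meta, con)
  writeBin(body, con)
  invisible(path)
}

# --- reader -----------------------------------------------------------------

#' @keywords internal
readDicomCine <- function(path) {
  r <- readBin(path, "raw", n = file.size(path))
  if (length(r) < 200 || rawToChar(r[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM marker): ", path)
  longVRs <- c("OB", "OW", "OF", "UT", "UN", "SQ")
  tags <- list()
  off <- 133L
  n <- length(r)
  while (off + 7L <= n) {
    group <- readU16(r, off); element <- readU16(r, off + 2L)
    vr <- rawToChar(r[(off + 4L):(off + 5L)])
    if (vr %in% longVRs) {
      len <- readU32(r, off + 8L)
      valOff <- off + 12L
    } else {
      len <- readU16(r, off + 6L)
      valOff <- off + 8L
    }
    if (len == 4294967295) {
      if (vr == "SQ") stop("undefined-length sequences are not supported")
      stop("undefined-length element: unsupported DICOM dialect")
    }
    key <- sprintf("%04x,%04x", group, element)
    if (vr == "SQ") {
      # structural skip: sequence contents are not interpreted
    } else if (key %in% c("0002,0010", "0008,103e", "0018,1063", "0018,1065",
                          "0028,0004", "0028,0008", "0028,0010", "0028,0011",
                          "0028,0030", "0028,0100", "0028,0103")) {
      val <- r[valOff:(valOff + len - 1L)]
      tags[[key]] <- if (vr %in% c("US", "UL")) {
        if (vr == "US") readU16(val, 1L) else readU32(val, 1L)
      } else trimws(rawToChar(val))
    } else if (key == "7fe0,0010") {
      tags[["pixeldata"]] <- r[valOff:(valOff + len - 1L)]
    }
    off <- valOff + len
  }
  ts <- tags[["0002,0010"]]
  if (!is.null(ts) && gsub("\\x00", "", ts, fixed = FALSE) != UID_EXPLICIT_VR_LE)
    stop("unsupported transfer syntax: ", ts)
  need <- function(key, what) {
    if (is.null(tags[[key]]))
      stop("DICOM file lacks required attribute ", what, " (", key, ")")
    tags[[key]]
  }
  rows <- need("0028,0010", "Rows")
  cols <- need("0028,0011", "Columns")
  nf <- as.integer(need("0028,0008", "NumberOfFrames"))
  if (nf < 2)
    stop("single-frame input: a cine loop needs at least 2 frames")
  sp <- as.numeric(strsplit(need("0028,0030", "PixelSpacing"), "\\\\")[[1]])
  if (length(sp) != 2 || anyNA(sp))
    stop("DICOM attribute PixelSpacing (0028,0030) is malformed")
  ftMs <- if (!is.null(tags[["0018,1063"]])) {
    as.numeric(tags[["0018,1063"]])
  } else if (!is.null(tags[["0018,1065"]])) {
    v <- as.numeric(strsplit(tags[["0018,1065"]], "\\\\")[[1]])
    median(v[v > 0])
  } else {
    stop("DICOM file lacks frame timing: need FrameTime (0018,1063) ",
         "or FrameTimeVector (0018,1065)")
  }
  if (is.na(ftMs) || ftMs <= 0)
    stop("DICOM frame timing attribute is non-positive or malformed")
  bits <- need("0028,0100", "BitsAllocated")
  if (!bits %in% c(8L, 16L)) stop("unsupported BitsAllocated: ", bits)
  pix <- tags[["pixeldata"]]
  if (is.null(pix)) stop("DICOM file lacks PixelData (7FE0,0010)")
  vals <- if (bits == 16L) {
    idx <- seq(1L, length(pix), by = 2L)
    as.integer(pix[idx]) + 256L * as.integer(pix[idx + 1L])
  } else as.integer(pix)
  if (length(vals) < rows * cols * nf)
    stop("PixelData shorter than Rows x Columns x NumberOfFrames")
  arr <- array(0, c(rows, cols, nf))
  k <- rows * cols
  for (f in seq_len(nf))
    arr[, , f] <- matrix(vals[((f - 1) * k + 1):(f * k)], rows, cols,
                         byrow = TRUE)
  srcId <- tags[["0008,103e"]]
  CineLoop(arr, sp, ftMs / 1000,
           sourceId = if (is.null(srcId)) basename(path) else srcId)
}
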