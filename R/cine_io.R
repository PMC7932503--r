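# Reading and writing cine loops, wall-trace / diameter tables, and
# cohort spreadsheets. All downstream modules consume only the in-memory
# types constructed here.

#' Read a cine loop
#'
#' Reads a multi-frame grayscale recording into a [CineLoop-class]. Two
#' on-disk forms are supported: multi-frame DICOM (explicit VR little
#' endian) and a multi-page TIFF stack accompanied by a JSON sidecar
#' (`<stem>.json`) holding `pixel_spacing_mm` (axial, lateral) and
#' `frame_interval_s`. Missing spacing or timing metadata raises an error
#' naming the missing attribute — it is never silently defaulted.
#'
#' @param path file path.
#' @param formatHint `"dicom"`, `"tiff"`, or `NULL` to infer from the
#'   file extension / magic bytes.
#' @return A [CineLoop-class].
#' @seealso [writeCine()], [simulateCine()]
#' @export
readCine <- function(path, formatHint = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- formatHint
  if (is.null(fmt)) {
    ext <- tolower(tools::file_ext(path))
    fmt <- if (ext %in% c("dcm", "dicom")) "dicom"
           else if (ext %in% c("tif", "tiff")) "tiff"
           else {
      magic <- readBin(path, "raw", n = 132)
      if (length(magic) == 132 && rawToChar(magic[129:132]) == "DICM")
        "dicom" else "tiff"
    }
  }
  switch(fmt,
    dicom = readDicomCine(path),
    tiff = readTiffCine(path),
    stop("unknown format hint: ", fmt))
}

#' Write a cine loop
#'
#' Writes a [CineLoop-class] as multi-frame DICOM or as a 16-bit
#' multi-page TIFF plus JSON metadata sidecar. Both forms round-trip
#' through [readCine()] losslessly (frames bit-exactly, metadata to
#' floating-point precision) provided the frames hold integer grey levels
#' in `[0, 65535]`, as [simulateCine()] emits.
#'
#' @param cine a [CineLoop-class].
#' @param path output path.
#' @param format `"dicom"` or `"tiff"`.
#' @return the path, invisibly.
#' @export
writeCine <- function(cine, path, format = c("dicom", "tiff")) {
  stopifnot(is(cine, "CineLoop"))
  format <- match.arg(format)
  if (format == "dicom") writeDicomCine(cine, path)
  else writeTiffCine(cine, path)
  invisible(path)
}

tiffSidecar <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

writeTiffCine <- function(cine, path) {
  fr <- cine@frames
  if (any(fr < 0 | fr > 65535 | fr != round(fr)))
    stop("TIFF writer requires integer grey levels in [0, 65535]")
  pages <- lapply(seq_len(dim(fr)[3]), function(f) fr[, , f] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(pixel_spacing_mm = cine@pixelSpacing,
         frame_interval_s = cine@frameInterval,
         source_id = cine@sourceId),
    tiffSidecar(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

readTiffCine <- function(path) {
  side <- tiffSidecar(path)
  if (!file.exists(side))
    stop("TIFF stack lacks metadata sidecar ", side,
         " (needs pixel_spacing_mm and frame_interval_s)")
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  for (field in c("pixel_spacing_mm", "frame_interval_s"))
    if (is.null(meta[[field]]))
      stop("metadata sidecar lacks required field ", field)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2) stop("single-frame input: a cine loop needs >= 2 frames")
  arr <- array(0, c(dim(pages[[1]]), length(pages)))
  for (f in seq_along(pages)) arr[, , f] <- round(pages[[f]] * 65535)
  CineLoop(arr, as.numeric(meta$pixel_spacing_mm),
           as.numeric(meta$frame_interval_s),
           sourceId = if (is.null(meta$source_id)) basename(path)
                      else meta$source_id)
}

# --- wall traces / diameter maps as delimited text --------------------------

#' Write wall traces or a diameter map as delimited text
#'
#' One row per lateral position, one column per frame, preceded by `#`
#' header lines recording the object type, units, pixel spacing and frame
#' interval (from which the time vector is reconstructed). QC-masked cells
#' are written as `NA` and survive a round trip. [readTraces()] restores
#' the object to within 1e-9.
#'
#' @param x a [WallTraces-class] or [DiameterMap-class].
#' @param path output path (CSV).
#' @return the path, invisibly.
#' @export
writeTraces <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeBlock <- function(name, m) {
    cat(sprintf("# block: %s\n", name), file = con)
    write.table(m, con, sep = ",", row.names = FALSE, col.names = FALSE,
                na = "NA")
  }
  if (is(x, "WallTraces")) {
    cat("# bariTrack: WallTraces\n", file = con)
    cat(sprintf("# pixel_spacing_mm: %.12g,%.12g\n",
                x@pixelSpacing[1], x@pixelSpacing[2]), file = con)
    cat(sprintf("# frame_interval_s: %.12g\n", x@frameInterval), file = con)
    cat("# units: rows in px; columns are frames\n", file = con)
    cat(sprintf("# x: %s\n", paste(x@x, collapse = ",")), file = con)
    writeBlock("yTop", x@yTop)
    writeBlock("yBottom", x@yBottom)
    writeBlock("qcMask", x@qcMask * 1L)
  } else if (is(x, "DiameterMap")) {
    cat("# bariTrack: DiameterMap\n", file = con)
    dt <- if (length(x@time) > 1) x@time[2] - x@time[1] else 0
    cat(sprintf("# frame_interval_s: %.12g\n", dt), file = con)
    cat("# units: D in mm; columns are frames\n", file = con)
    cat(sprintf("# x: %s\n", paste(x@x, collapse = ",")), file = con)
    writeBlock("D", x@D)
  } else stop("writeTraces handles WallTraces or DiameterMap")
  invisible(path)
}

#' Read back wall traces or a diameter map written by [writeTraces()]
#'
#' @param path file written by [writeTraces()].
#' @return A [WallTraces-class] or [DiameterMap-class], per the header.
#' @export
readTraces <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  typ <- sub("^# bariTrack: ", "", hdr[1])
  getField <- function(name) {
    ln <- grep(paste0("^# ", name, ":"), hdr, value = TRUE)
    if (!length(ln)) stop("header lacks field ", name)
    as.numeric(strsplit(sub(paste0("^# ", name, ": "), "", ln[1]), ",")[[1]])
  }
  blockStarts <- grep("^# block: ", lines)
  blockNames <- sub("^# block: ", "", lines[blockStarts])
  blockEnds <- c(blockStarts[-1] - 1L, length(lines))
  readBlock <- function(i) {
    rows <- lines[(blockStarts[i] + 1L):blockEnds[i]]
    rows <- rows[!grepl("^#", rows) & nzchar(rows)]
    do.call(rbind, lapply(strsplit(rows, ","), function(v) {
      v[v == "NA" | v == "NaN"] <- NA_character_
      as.numeric(v)
    }))
  }
  blocks <- setNames(lapply(seq_along(blockStarts), readBlock), blockNames)
  xgrid <- as.integer(getField("x"))
  if (typ == "WallTraces") {
    new("WallTraces", x = xgrid, yTop = blocks$yTop,
        yBottom = blocks$yBottom, qcMask = blocks$qcMask == 1,
        pixelSpacing = getField("pixel_spacing_mm"),
        frameInterval = getField("frame_interval_s"))
  } else if (typ == "DiameterMap") {
    dt <- getField("frame_interval_s")
    new("DiameterMap", D = blocks$D, x = xgrid,
        time = (seq_len(ncol(blocks$D)) - 1) * dt)
  } else stop("unrecognized traces file: ", path)
}

# --- cohort tables ----------------------------------------------------------

#' Classify aneurysm size from the anteroposterior diameter
#'
#' Surveillance size bands: `"small"` for APD of 30-39 mm, `"moderate"`
#' for 40-55 mm (both ends included), `"large"` above 55 mm. Diameters
#' below the 30 mm aneurysm definition are labelled `"HV"` (no aneurysm).
#' Values between the printed band edges (e.g. 39.5 mm) fall to the lower
#' band, so the labelling is total on (0, Inf).
#'
#' @param apd anteroposterior diameter(s), mm.
#' @return character vector of labels.
#' @export
apdGroup <- function(apd) {
  stopifnot(is.numeric(apd), all(apd > 0 | is.na(apd)))
  ifelse(is.na(apd), NA_character_,
    ifelse(apd < 30, "HV",
      ifelse(apd < 40, "small",
        ifelse(apd <= 55, "moderate", "large"))))
}

#' Read a cohort table
#'
#' Reads a per-participant spreadsheet (CSV, TSV or XLSX) into a
#' data.frame of participant records. Recognized columns (case- and
#' punctuation-insensitive): `id` (mandatory), `apd_baseline` (or `apd`),
#' `apd_followup`, `days_elapsed`, `bari`, `group`, `gender`
#' (1 = Male, 0 = Female), `bmi`, `map`, `htn`. Unknown columns are
#' preserved as pass-through demographics. A missing `group` is derived
#' from the baseline APD via [apdGroup()]; rows without follow-up keep
#' baseline-only status (`NA` follow-up fields).
#'
#' @param path CSV/TSV/XLSX file.
#' @return data.frame, one row per participant, with a `group` column.
#' @export
readCohortTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "xlsx") {
    as.data.frame(readxl::read_excel(path))
  } else {
    read.csv(path, sep = if (ext == "tsv") "\t" else ",",
             stringsAsFactors = FALSE)
  }
  canon <- function(x) gsub("[^a-z0-9]", "", tolower(x))
  names(df) <- ifelse(canon(names(df)) == "apd", "apd_baseline", names(df))
  key <- canon(names(df))
  alias <- c(id = "id", apdbaseline = "apd_baseline",
             apdfollowup = "apd_followup", dayselapsed = "days_elapsed",
             bari = "bari", group = "group", gender = "gender",
             bmi = "bmi", map = "map", htn = "htn")
  hit <- match(key, names(alias))
  names(df)[!is.na(hit)] <- alias[hit[!is.na(hit)]]
  if (nrow(df) == 0) {
    if (!"group" %in% names(df)) df$group <- character(0)
    return(df)
  }
  if (!"id" %in% names(df)) stop("cohort table lacks a mandatory id column")
  for (col in c("apd_baseline", "apd_followup", "days_elapsed", "bari")) {
    if (col %in% names(df)) {
      v <- suppressWarnings(as.numeric(df[[col]]))
      if (any(is.na(v) & !is.na(df[[col]]) & nzchar(trimws(df[[col]]))))
        stop("non-numeric values in column ", col)
      df[[col]] <- v
    }
  }
  if ("apd_baseline" %in% names(df) && any(df$apd_baseline <= 0, na.rm = TRUE))
    stop("apd_baseline must be > 0 where present")
  if ("days_elapsed" %in% names(df) && any(df$days_elapsed <= 0, na.rm = TRUE))
    stop("days_elapsed must be > 0 where present")
  if (!"group" %in% names(df)) {
    if (!"apd_baseline" %in% names(df))
      stop("cohort table needs either a group or an APD column")
    df$group <- apdGroup(df$apd_baseline)
  } else {
    miss <- is.na(df$group) | !nzchar(trimws(df$group))
    if (any(miss) && "apd_baseline" %in% names(df))
      df$group[miss] <- apdGroup(df$apd_baseline[miss])
  }
  df
}
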