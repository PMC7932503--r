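test_that("DICOM round trip is lossless for phantom loops", {
  spec <- quickSpec(frameRate = 50, duration = 0.4, baselineDiameter = 1.0,
                    peaks = 0.2)
  cine <- simulateCine(spec, seed = 3)$cine
  path <- tempfile(fileext = ".dcm")
  writeCine(cine, path, format = "dicom")
  back <- readCine(path)
  expect_identical(frames(back), frames(cine))
  expect_equal(pixelSpacing(back), pixelSpacing(cine), tolerance = 1e-9)
  expect_equal(frameInterval(back), frameInterval(cine), tolerance = 1e-9)
  # 50 frames/s encode as a 0.02 s frame interval
  expect_equal(frameInterval(back), 0.02, tolerance = 1e-9)
})

test_that("DICOM written here is readable by an independent parser", {
  spec <- quickSpec(baselineDiameter = 1.0, frameRate = 25)
  cine <- simulateCine(spec, seed = 9)$cine
  path <- tempfile(fileext = ".dcm")
  writeCine(cine, path, format = "dicom")
  script <- paste(
    "import pydicom, sys",
    "d = pydicom.dcmread(sys.argv[1])",
    "px = d.pixel_array",
    "print(d.Rows, d.Columns, d.NumberOfFrames, float(d.FrameTime),",
    "      float(d.PixelSpacing[0]), float(d.PixelSpacing[1]),",
    "      int(px.sum()))",
    sep = "\n")
  out <- suppressWarnings(
    system2("python", c("-c", shQuote(script), shQuote(path)),
            stdout = TRUE, stderr = FALSE))
  vals <- as.numeric(strsplit(trimws(out[length(out)]), "\\s+")[[1]])
  d <- dim(frames(cine))
  expect_equal(vals[1:3], d)
  expect_equal(vals[4] / 1000, frameInterval(cine), tolerance = 1e-9)
  expect_equal(vals[5:6], pixelSpacing(cine), tolerance = 1e-9)
  expect_equal(vals[7], sum(frames(cine)))
})

test_that("DICOM without frame timing raises an error naming the attribute", {
  spec <- quickSpec(baselineDiameter = 1.0)
  cine <- simulateCine(spec, seed = 1)$cine
  path <- tempfile(fileext = ".dcm")
  writeCine(cine, path, format = "dicom")
  # excise the FrameTime element by retagging it as a private element
  raw <- readBin(path, "raw", n = file.size(path))
  tag <- as.raw(c(0x18, 0x00, 0x63, 0x10))  # (0018,1063) little endian
  hit <- which(raw == tag[1])
  hit <- hit[raw[hit + 1] == tag[2] & raw[hit + 2] == tag[3] &
             raw[hit + 3] == tag[4]]
  expect_length(hit, 1)
  raw[hit] <- as.raw(0x09)  # now (0009,1063): private, ignored
  writeBin(raw, path)
  expect_error(readCine(path), "FrameTime")
})

test_that("single-frame and unreadable inputs are rejected", {
  bad <- tempfile(fileext = ".dcm")
  writeBin(as.raw(rep(0, 64)), bad)
  expect_error(readCine(bad), "DICM|DICOM")
  expect_error(readCine(tempfile(fileext = ".dcm")), "not found")
})

test_that("TIFF stack + sidecar round trip preserves frames and metadata", {
  spec <- quickSpec(baselineDiameter = 1.0)
  cine <- simulateCine(spec, seed = 4)$cine
  path <- tempfile(fileext = ".tif")
  writeCine(cine, path, format = "tiff")
  back <- readCine(path)
  expect_equal(frames(back), frames(cine), tolerance = 1e-9)
  expect_equal(frameInterval(back), frameInterval(cine), tolerance = 1e-9)
  file.remove(sub("\\.tif$", ".json", path))
  expect_error(readCine(path), "sidecar")
})

test_that("trace and diameter tables round trip through text, NA included", {
  mask <- matrix(TRUE, 4, 5); mask[2, 3] <- FALSE
  tr <- makeTraces(nx = 4, nf = 5, mask = mask)
  tr@yTop[1, 1] <- 101.25  # fractional, exercises precision
  p1 <- tempfile(fileext = ".csv")
  writeTraces(tr, p1)
  back <- readTraces(p1)
  expect_equal(back@yTop, tr@yTop, tolerance = 1e-9)
  expect_equal(back@yBottom, tr@yBottom, tolerance = 1e-9)
  expect_identical(back@qcMask, tr@qcMask)
  expect_equal(back@frameInterval, tr@frameInterval, tolerance = 1e-9)
  expect_true(is.na(back@yTop[2, 3]))

  dm <- computeDiameter(tr)
  p2 <- tempfile(fileext = ".csv")
  writeTraces(dm, p2)
  dback <- readTraces(p2)
  expect_equal(diameters(dback), diameters(dm), tolerance = 1e-9)
  # time vector is reconstructed from the frame interval in the header
  expect_equal(timeVector(dback), (0:4) * 0.02, tolerance = 1e-9)
  expect_true(is.na(diameters(dback)[2, 3]))
})

test_that("APD size banding matches the surveillance definitions", {
  expect_identical(apdGroup(35), "small")
  expect_identical(apdGroup(55), "moderate")  # 55 is inside 40-55
  expect_identical(apdGroup(55.5), "large")
  expect_identical(apdGroup(29.5), "HV")
  # total on a fine sweep across the bands
  sweep <- seq(29.5, 56.5, by = 0.5)
  labs <- apdGroup(sweep)
  expect_false(anyNA(labs))
  expect_identical(labs[sweep < 30], rep("HV", sum(sweep < 30)))
  expect_identical(labs[sweep >= 30 & sweep < 40],
                   rep("small", sum(sweep >= 30 & sweep < 40)))
  expect_identical(labs[sweep >= 40 & sweep <= 55],
                   rep("moderate", sum(sweep >= 40 & sweep <= 55)))
  expect_identical(labs[sweep > 55], rep("large", sum(sweep > 55)))
})

test_that("cohort tables parse, derive groups, and validate", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("id,APD,apd_followup,days_elapsed,bari,gender,extra",
               "p1,35,37,365,0.9,1,a",
               "p2,55,NA,NA,1.2,0,b",
               "p3,60,61,180,0.7,1,c",
               "p4,25,NA,NA,0.95,0,d"), path)
  df <- readCohortTable(path)
  expect_identical(df$group, c("small", "moderate", "large", "HV"))
  expect_true(is.na(df$apd_followup[2]))   # baseline-only row retained
  expect_identical(df$extra, c("a", "b", "c", "d"))  # pass-through

  empty <- tempfile(fileext = ".csv")
  writeLines("id,APD,bari", empty)
  expect_identical(nrow(readCohortTable(empty)), 0L)

  noid <- tempfile(fileext = ".csv")
  writeLines(c("APD,bari", "35,0.9"), noid)
  expect_error(readCohortTable(noid), "id column")

  badapd <- tempfile(fileext = ".csv")
  writeLines(c("id,APD,bari", "p1,thirty,0.9"), badapd)
  expect_error(readCohortTable(badapd), "non-numeric")
})
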