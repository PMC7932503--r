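test_that("noiseless waveform equals the closed-form model computed independently", {
  spec <- phantomSpec()
  tr <- simulateDiameterTrace(spec)
  pars <- tr$truth$params
  # independent evaluation from the per-cycle truth table
  expected <- rep(spec@baselineDiameter, length(tr$time))
  for (k in seq_len(nrow(pars))) {
    p <- pars[k, ]
    i <- tr$time >= p$tTrough & tr$time < p$tPeak
    expected[i] <- p$Ad - p$Bd * exp(-(tr$time[i] - p$Cd) / p$Td)
    j <- tr$time >= p$tPeak & tr$time <= p$tEnd
    expected[j] <- p$Ar + p$B1 * exp(-(tr$time[j] - p$Cr) / p$T1) +
      p$B2 * exp(-(tr$time[j] - p$Cr) / p$T2)
  }
  expect_equal(tr$waveform, expected, tolerance = 1e-12)
  # default spec programs the four systolic peaks of the study recording
  expect_equal(tr$truth$cycleBoundaries$peaks, c(0.5, 1.5, 3.0, 4.0))
})

test_that("waveform is continuous at every dilatation/relaxation junction", {
  spec <- phantomSpec()
  pars <- bariTrack:::phantomCycleParams(spec)
  eps <- 1e-9
  for (k in seq_len(nrow(pars))) {
    tj <- pars$tPeak[k]
    left <- bariTrack:::phantomDiameterAt(spec, tj - eps)
    right <- bariTrack:::phantomDiameterAt(spec, tj + eps)
    expect_lt(abs(left - right), 1e-6)
    # trough continuity into the next cycle
    if (k < nrow(pars)) {
      te <- pars$tEnd[k]
      expect_lt(abs(bariTrack:::phantomDiameterAt(spec, te - eps) -
                    bariTrack:::phantomDiameterAt(spec, te + eps)), 1e-6)
    }
  }
})

test_that("generators are pure functions of (spec, seed)", {
  spec <- quickSpec(traceNoiseSd = 0.01)
  a <- simulateDiameterTrace(spec, seed = 7)
  b <- simulateDiameterTrace(spec, seed = 7)
  expect_identical(a$waveform, b$waveform)
  s1 <- simulateCine(quickSpec(baselineDiameter = 1.0), seed = 11)
  s2 <- simulateCine(quickSpec(baselineDiameter = 1.0), seed = 11)
  expect_identical(frames(s1$cine), frames(s2$cine))
  s3 <- simulateCine(quickSpec(baselineDiameter = 1.0), seed = 12)
  expect_false(identical(frames(s1$cine), frames(s3$cine)))
})

test_that("static noise-free vessel renders identical frames", {
  spec <- quickSpec(baselineDiameter = 1.0, pulseAmplitude = 1e-12,
                    speckleContrast = 0, additiveNoiseSd = 0)
  sim <- simulateCine(spec, seed = 1)
  fr <- frames(sim$cine)
  for (f in 2:dim(fr)[3]) expect_identical(fr[, , f], fr[, , 1])
})

test_that("rasterized wall edges agree with analytic truth within half a pixel", {
  spec <- quickSpec(baselineDiameter = 1.0, speckleContrast = 0,
                    additiveNoiseSd = 0)
  sim <- simulateCine(spec, seed = 1)
  fr <- frames(sim$cine)
  half <- (spec@lumenIntensity + spec@wallIntensity) / 2
  # sub-pixel mid-intensity crossing by linear interpolation between rows
  crossing <- function(prof, from, step) {
    r <- from
    while (prof[r + step] < half) r <- r + step
    r1 <- r + step
    r + step * (half - prof[r]) / (prof[r1] - prof[r])
  }
  ctr <- round(sim$truth$centreRow)
  for (f in c(1, dim(fr)[3])) {
    prof <- fr[, 10, f]
    expect_lt(abs(crossing(prof, ctr, -1L) - sim$truth$yTopPx[10, f]), 0.5)
    expect_lt(abs(crossing(prof, ctr, +1L) - sim$truth$yBottomPx[10, f]), 0.5)
  }
})

test_that("speckle envelope follows the Rayleigh law", {
  set.seed(123)
  x <- bariTrack:::rayleighEnvelope(1e5)
  expect_equal(mean(x), 1, tolerance = 0.01)
  sigma <- sqrt(2 / pi)
  ks <- suppressWarnings(   # fp duplicates at n = 1e5 trip the tie check
    ks.test(x, function(q) 1 - exp(-q^2 / (2 * sigma^2))))
  expect_gt(ks$p.value, 0.01)
})

test_that("recovery experiment: exact at zero noise, degrades with noise", {
  rec <- recoveryExperiment(nReplicates = 12, noiseLadder = c(0, 0.5, 2.0),
                            seed = 21)
  expect_equal(nrow(rec), 3)
  expect_lt(rec$medAbsRelErrT2[1], 0.01)    # noiseless self-consistency
  expect_equal(rec$acceptedFrac[1], 1)
  # one-sided trend across the ladder, with sampling allowance
  expect_gt(rec$medAbsRelErrT2[3], rec$medAbsRelErrT2[1])
  expect_gt(rec$medAbsRelErrT2[2] + 0.05, rec$medAbsRelErrT2[1])
})
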