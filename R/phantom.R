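# Synthetic vessel phantom: analytic diameter traces from the
# dilatation/relaxation forward model, and full speckle cine loops of a
# pulsating two-wall vessel, both with exact ground truth.

#' Construct a phantom specification
#'
#' Defaults emulate the study conditions of a brachial-artery cine
#' recording: four cardiac cycles with systolic peaks at 0.5, 1.5, 3.0 and
#' 4.0 s, 50 frames/s, 21 um isotropic pixels, baseline diameter 3.5 mm
#' with a 0.15 mm pulse, systolic rise time constant 0.10 s and diastolic
#' fast/slow relaxation constants 0.10 s / 1.0 s, imaged as a dark lumen
#' between two bright wall bands in fully developed Rayleigh speckle.
#'
#' @param troughs,peaks cycle trough/peak times, s. One trough per peak;
#'   each cycle's relaxation runs to the next trough (or `duration`).
#' @param duration recording length, s.
#' @param frameRate frames per second.
#' @param pixelSpacing `(axial, lateral)` mm/px.
#' @param baselineDiameter,pulseAmplitude trough diameter and systolic
#'   excursion, mm.
#' @param dilTimeConstant systolic rise time constant T_d, s.
#' @param relaxFast,relaxSlow diastolic time constants T_R1 < T_R2, s.
#' @param relaxSplit fraction of relaxation amplitude on the fast mode.
#' @param wallThicknessPx,lateralCols,marginRows image geometry, px.
#' @param lumenIntensity,wallIntensity,tissueIntensity mean grey levels.
#' @param speckleContrast multiplicative Rayleigh speckle contrast (0-1).
#' @param additiveNoiseSd additive Gaussian noise, grey levels.
#' @param traceNoiseSd Gaussian noise on analytic diameter traces, mm.
#' @return A [PhantomSpec-class].
#' @examples
#' spec <- phantomSpec(troughs = 0, peaks = 0.4, duration = 1, frameRate = 25)
#' tr <- simulateDiameterTrace(spec, seed = 1)
#' range(tr$waveform)
#' @export
phantomSpec <- function(troughs = c(0, 1.1, 2.5, 3.6),
                        peaks = c(0.5, 1.5, 3.0, 4.0),
                        duration = 5, frameRate = 50,
                        pixelSpacing = c(0.021, 0.021),
                        baselineDiameter = 3.5, pulseAmplitude = 0.15,
                        dilTimeConstant = 0.10,
                        relaxFast = 0.10, relaxSlow = 1.0,
                        relaxSplit = 0.5,
                        wallThicknessPx = 8, lateralCols = 64,
                        marginRows = 16,
                        lumenIntensity = 8, wallIntensity = 180,
                        tissueIntensity = 60,
                        speckleContrast = 1.0, additiveNoiseSd = 2,
                        traceNoiseSd = 0) {
  new("PhantomSpec", troughs = troughs, peaks = peaks, duration = duration,
      frameRate = frameRate, pixelSpacing = pixelSpacing,
      baselineDiameter = baselineDiameter, pulseAmplitude = pulseAmplitude,
      dilTimeConstant = dilTimeConstant, relaxFast = relaxFast,
      relaxSlow = relaxSlow, relaxSplit = relaxSplit,
      wallThicknessPx = wallThicknessPx, lateralCols = lateralCols,
      marginRows = marginRows, lumenIntensity = lumenIntensity,
      wallIntensity = wallIntensity, tissueIntensity = tissueIntensity,
      speckleContrast = speckleContrast, additiveNoiseSd = additiveNoiseSd,
      traceNoiseSd = traceNoiseSd)
}

# Run expr with a locally seeded RNG, restoring the caller's stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Rayleigh envelope samples with unit mean: sigma * sqrt(-2 log U),
# sigma = sqrt(2/pi). First-order model of fully developed B-mode speckle.
rayleighEnvelope <- function(n) {
  sqrt(2 / pi) * sqrt(-2 * log(runif(n)))
}

# Per-cycle forward-model coefficients, with amplitudes re-solved so the
# trace is continuous at every trough->peak->trough junction.
phantomCycleParams <- function(spec) {
  np <- length(spec@peaks)
  ends <- c(spec@troughs[-1][seq_len(max(0, np - 1))], spec@duration)
  if (length(spec@troughs) > np) ends[np] <- spec@troughs[np + 1]
  peakVal <- spec@baselineDiameter + spec@pulseAmplitude
  b1 <- spec@relaxSplit * spec@pulseAmplitude
  b2 <- (1 - spec@relaxSplit) * spec@pulseAmplitude
  startVal <- spec@baselineDiameter
  out <- vector("list", np)
  for (k in seq_len(np)) {
    tk <- spec@troughs[k]; pk <- spec@peaks[k]; ek <- ends[k]
    w <- pk - tk
    Bd <- (peakVal - startVal) / (1 - exp(-w / spec@dilTimeConstant))
    Ad <- startVal + Bd
    out[[k]] <- data.frame(
      cycle = k, tTrough = tk, tPeak = pk, tEnd = ek,
      Ad = Ad, Bd = Bd, Cd = tk, Td = spec@dilTimeConstant,
      Ar = spec@baselineDiameter, B1 = b1, B2 = b2, Cr = pk,
      T1 = spec@relaxFast, T2 = spec@relaxSlow)
    wr <- ek - pk
    startVal <- spec@baselineDiameter +
      b1 * exp(-wr / spec@relaxFast) + b2 * exp(-wr / spec@relaxSlow)
  }
  do.call(rbind, out)
}

# Evaluate the noiseless phantom diameter at arbitrary times (mm).
phantomDiameterAt <- function(spec, t) {
  pars <- phantomCycleParams(spec)
  d <- rep(spec@baselineDiameter, length(t))
  for (k in seq_len(nrow(pars))) {
    p <- pars[k, ]
    dil <- t >= p$tTrough & t < p$tPeak
    d[dil] <- p$Ad - p$Bd * exp(-(t[dil] - p$Cd) / p$Td)
    rel <- t >= p$tPeak & t <= p$tEnd
    d[rel] <- p$Ar + p$B1 * exp(-(t[rel] - p$Cr) / p$T1) +
      p$B2 * exp(-(t[rel] - p$Cr) / p$T2)
  }
  d
}

#' Simulate an analytic diameter waveform with ground truth
#'
#' Generates the diameter-versus-time waveform of the forward model: per
#' cardiac cycle a mono-exponential systolic rise
#' `D_d(t) = A_d - B_d exp(-(t - C_d)/T_d)` over the trough-to-peak window
#' and a bi-exponential diastolic decay
#' `D_r(t) = A_r + B_R1 exp(-(t - C_r)/T_R1) + B_R2 exp(-(t - C_r)/T_R2)`
#' over the peak-to-trough window, with amplitudes re-solved so the trace
#' is continuous at every junction. Optional Gaussian noise
#' (`spec@traceNoiseSd`, mm) is added reproducibly under `seed`.
#'
#' @param spec a [PhantomSpec-class].
#' @param seed integer seed for the noise (ignored when noise sd is 0).
#' @return list with `time` (s), `waveform` (mm, noisy when requested) and
#'   `truth`: `clean` waveform, per-cycle parameter table `params`
#'   (post-continuity values actually generating the data), and
#'   `cycleBoundaries` (`troughs`, `peaks`, `ends` in s).
#' @export
simulateDiameterTrace <- function(spec, seed = NULL) {
  n <- round(spec@duration * spec@frameRate)
  t <- (seq_len(n) - 1) / spec@frameRate
  clean <- phantomDiameterAt(spec, t)
  wav <- clean
  if (spec@traceNoiseSd > 0)
    wav <- withSeed(seed, clean + rnorm(n, sd = spec@traceNoiseSd))
  pars <- phantomCycleParams(spec)
  list(time = t, waveform = wav,
       truth = list(clean = clean, params = pars,
                    cycleBoundaries = list(troughs = pars$tTrough,
                                           peaks = pars$tPeak,
                                           ends = pars$tEnd)))
}

# Anti-aliased axial intensity profile: mean grey level of each pixel row
# given continuous wall-interface positions (rows yt < yb bound the lumen,
# bright bands of thickness w sit outside them).
axialProfile <- function(nRows, yt, yb, w, lumen, wall, tissue) {
  r <- seq_len(nRows)
  cov <- function(lo, hi) pmax(0, pmin(r + 0.5, hi) - pmax(r - 0.5, lo))
  lumen * cov(yt, yb) +
    wall * (cov(yt - w, yt) + cov(yb, yb + w)) +
    tissue * (cov(-Inf, yt - w) + cov(yb + w, Inf))
}

#' Simulate a speckle cine loop of a pulsating vessel
#'
#' Renders a two-wall vessel: a dark lumen band between two bright wall
#' bands whose sub-pixel interface positions follow the forward-model
#' diameter trace, centred axially in the frame and uniform along the
#' lateral direction. Wall edges are anti-aliased (area-weighted pixel
#' coverage); texture is multiplicative Rayleigh speckle (unit-mean
#' envelope, scaled by `speckleContrast`) plus additive Gaussian noise.
#' Frames are quantized to integer grey levels in `[0, 65535]` so that a
#' DICOM round trip is bit-exact.
#'
#' @param spec a [PhantomSpec-class].
#' @param seed integer seed; the generator is a pure function of
#'   `(spec, seed, artefact)`.
#' @param artefact inject a bright horizontal band in the lumen centre (a
#'   slice-thickness artefact proxy) for QC testing.
#' @return list with `cine` (a [CineLoop-class]) and `truth`: matrices
#'   `yTopPx`, `yBottomPx` (`lateralCols x nFrames`, continuous row
#'   coordinates of the lumen-wall interfaces), `diameterMm`, `time`,
#'   per-cycle `params` and `cycleBoundaries` as in
#'   [simulateDiameterTrace()].
#' @export
simulateCine <- function(spec, seed = NULL, artefact = FALSE) {
  tr <- simulateDiameterTrace(spec)   # noiseless geometry
  dPx <- tr$truth$clean / spec@pixelSpacing[1]
  maxD <- (spec@baselineDiameter + spec@pulseAmplitude) / spec@pixelSpacing[1]
  nRows <- ceiling(maxD) + 2 * spec@wallThicknessPx + 2 * spec@marginRows
  nCols <- spec@lateralCols
  nF <- length(tr$time)
  centre <- (nRows + 1) / 2
  yt <- centre - dPx / 2
  yb <- centre + dPx / 2
  framesArr <- withSeed(seed, {
    a <- array(0, c(nRows, nCols, nF))
    for (f in seq_len(nF)) {
      prof <- axialProfile(nRows, yt[f], yb[f], spec@wallThicknessPx,
                           spec@lumenIntensity, spec@wallIntensity,
                           spec@tissueIntensity)
      if (artefact) {
        band <- abs(seq_len(nRows) - centre) <= 3
        prof[band] <- 0.8 * spec@wallIntensity
      }
      m <- matrix(prof, nRows, nCols)
      env <- matrix(rayleighEnvelope(nRows * nCols), nRows, nCols)
      m <- m * (1 + spec@speckleContrast * (env - 1))
      if (spec@additiveNoiseSd > 0)
        m <- m + matrix(rnorm(nRows * nCols, sd = spec@additiveNoiseSd),
                        nRows, nCols)
      a[, , f] <- pmin(65535, pmax(0, round(m)))
    }
    a
  })
  cine <- CineLoop(framesArr, spec@pixelSpacing, 1 / spec@frameRate,
                   sourceId = sprintf("phantom-seed%s",
                                      if (is.null(seed)) "NA" else seed))
  truth <- list(
    yTopPx = matrix(yt, nCols, nF, byrow = TRUE),
    yBottomPx = matrix(yb, nCols, nF, byrow = TRUE),
    diameterMm = tr$truth$clean, time = tr$time,
    params = tr$truth$params,
    cycleBoundaries = tr$truth$cycleBoundaries,
    centreRow = centre)
  list(cine = cine, truth = truth)
}

#' Seed rectangle inside the phantom lumen
#'
#' Builds a [RoiRect-class] wholly inside the lumen of a simulated loop,
#' with stated margins from the walls (at their closest approach over the
#' whole loop) and from the lateral image borders.
#'
#' @param truth the `truth` element returned by [simulateCine()].
#' @param rowMargin axial margin from the closest wall position, px.
#' @param colMargin lateral margin from the image borders, px.
#' @return A [RoiRect-class].
#' @export
phantomRoi <- function(truth, rowMargin = 12, colMargin = 6) {
  RoiRect(rowMin = ceiling(max(truth$yTopPx)) + rowMargin,
          rowMax = floor(min(truth$yBottomPx)) - rowMargin,
          colMin = 1 + colMargin,
          colMax = nrow(truth$yTopPx) - colMargin)
}

#' Parameter-recovery experiment for the relaxation fitter
#'
#' Simulates relaxation windows with parameters drawn from stated ranges,
#' adds Gaussian noise at each level of a noise ladder, fits the
#' bi-exponential model from the standard initialization, and tabulates
#' recovery of the slow time constant: bias, median absolute relative
#' error, and the fraction of accepted fits, per noise level.
#'
#' @param nReplicates windows per noise level.
#' @param ranges list of `c(lo, hi)` ranges for `T1`, `T2`, `amp`
#'   (total relaxation amplitude, mm), `A` (asymptote, mm) and `dur`
#'   (window duration, s — a diastolic interval). Defaults mirror the
#'   phantom's study conditions. Note that with a free asymptote the slow
#'   constant is only weakly identified from windows shorter than a few
#'   multiples of `T2`; see the methods vignette for the information
#'   analysis.
#' @param noiseLadder numeric vector of noise standard deviations in
#'   pixels (converted to mm with `pixelSize`).
#' @param seed integer seed.
#' @param frameRate sampling rate of the windows, Hz.
#' @param pixelSize mm per pixel (for noise scaling and initialization).
#' @param settings a [fitSettings()] list.
#' @return data.frame with one row per noise level: `noiseSdPx`,
#'   `biasT2`, `medAbsRelErrT2`, `medAbsRelErrT1`, `acceptedFrac`, `n`.
#' @export
recoveryExperiment <- function(nReplicates = 100,
                               ranges = list(T1 = c(0.05, 0.2),
                                             T2 = c(0.5, 1.5),
                                             amp = c(0.1, 0.3),
                                             A = c(3.0, 4.0),
                                             dur = c(0.6, 1.0)),
                               noiseLadder = c(0, 0.5, 1.0),
                               seed = 1, frameRate = 50,
                               pixelSize = 0.021,
                               settings = fitSettings(pixelSize = pixelSize)) {
  withSeed(seed, {
    rows <- lapply(noiseLadder, function(sdPx) {
      relT1 <- relT2 <- acc <- numeric(nReplicates)
      for (i in seq_len(nReplicates)) {
        T1 <- runif(1, ranges$T1[1], ranges$T1[2])
        T2 <- runif(1, ranges$T2[1], ranges$T2[2])
        amp <- runif(1, ranges$amp[1], ranges$amp[2])
        A <- runif(1, ranges$A[1], ranges$A[2])
        dur <- runif(1, ranges$dur[1], ranges$dur[2])
        t <- seq(0, dur, by = 1 / frameRate)
        y <- A + 0.5 * amp * exp(-t / T1) + 0.5 * amp * exp(-t / T2)
        if (sdPx > 0) y <- y + rnorm(length(y), sd = sdPx * pixelSize)
        fit <- fitRelaxation(y, t, settings = settings)
        fit <- acceptFit(fit, settings)
        relT1[i] <- (fit@T1 - T1) / T1
        relT2[i] <- (fit@T2 - T2) / T2
        acc[i] <- fit@accepted
      }
      data.frame(noiseSdPx = sdPx,
                 biasT2 = mean(relT2),
                 medAbsRelErrT2 = median(abs(relT2)),
                 medAbsRelErrT1 = median(abs(relT1)),
                 acceptedFrac = mean(acc),
                 n = nReplicates)
    })
    do.call(rbind, rows)
  })
}
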