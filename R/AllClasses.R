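#' @import methods
#' @importFrom stats median quantile sd approx lm coef cor.test t.test
#'   wilcox.test kruskal.test pairwise.wilcox.test optim rnorm runif
#'   complete.cases setNames
#' @importFrom utils read.csv write.csv head tail
#' @useDynLib bariTrack, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' CineLoop: a multi-frame grayscale ultrasound recording
#'
#' Container for a B-mode cine loop: a stack of grayscale frames together
#' with the physical pixel spacing and the time between frames. All
#' downstream stages (segmentation, diameter extraction, fitting) consume
#' this type only, so a loop read from DICOM, from a TIFF stack, or
#' synthesized by [simulateCine()] is interchangeable.
#'
#' Frames are stored as a numeric array with dimensions
#' `(rows, columns, frames)`: the row index is axial depth y (increasing
#' downward, as displayed on the scanner), the column index is lateral
#' position x.
#'
#' @slot frames numeric array `(rows, columns, frames)` of finite
#'   grayscale intensities.
#' @slot pixelSpacing numeric(2): `(axial, lateral)` spacing in mm/pixel.
#' @slot frameInterval numeric(1): seconds between consecutive frames.
#' @slot sourceId character(1): opaque identifier of the recording.
#'
#' @seealso [readCine()], [writeCine()], [simulateCine()]
#' @export
setClass("CineLoop",
  representation(
    frames        = "array",
    pixelSpacing  = "numeric",
    frameInterval = "numeric",
    sourceId      = "character"
  )
)

setValidity("CineLoop", function(object) {
  msg <- character()
  d <- dim(object@frames)
  if (length(d) != 3L)
    msg <- c(msg, "frames must be a 3-D array (rows, columns, frames)")
  else if (d[3] < 2L)
    msg <- c(msg, "a cine loop needs at least 2 frames")
  if (!all(is.finite(object@frames)))
    msg <- c(msg, "frame intensities must be finite")
  if (length(object@pixelSpacing) != 2L || any(object@pixelSpacing <= 0))
    msg <- c(msg, "pixelSpacing must be two positive values (axial, lateral) in mm/px")
  if (length(object@frameInterval) != 1L || object@frameInterval <= 0)
    msg <- c(msg, "frameInterval must be a single positive number of seconds")
  if (length(msg)) msg else TRUE
})

#' Construct a CineLoop
#'
#' @param frames numeric array `(rows, columns, frames)`.
#' @param pixelSpacing numeric(2), `(axial, lateral)` mm per pixel.
#' @param frameInterval seconds between frames.
#' @param sourceId identifier string.
#' @return A [CineLoop-class] object.
#' @examples
#' cl <- CineLoop(array(0, c(8, 8, 3)), c(0.021, 0.021), 0.02)
#' nFrames(cl)
#' @export
CineLoop <- function(frames, pixelSpacing, frameInterval, sourceId = "cine") {
  new("CineLoop", frames = frames, pixelSpacing = as.numeric(pixelSpacing),
      frameInterval = as.numeric(frameInterval), sourceId = sourceId)
}

#' RoiRect: user-defined seed rectangle inside the lumen
#'
#' Pixel-index rectangle placed wholly inside the vessel lumen in the first
#' frame, used to initialize the level-set evolution. It must be strictly
#' inside the frame and should keep a margin from both walls so that the
#' wall never crosses it during the cardiac cycle.
#'
#' @slot rowMin,rowMax,colMin,colMax integer pixel indices (inclusive).
#' @export
setClass("RoiRect",
  representation(rowMin = "integer", rowMax = "integer",
                 colMin = "integer", colMax = "integer")
)

setValidity("RoiRect", function(object) {
  msg <- character()
  if (object@rowMin < 1L || object@colMin < 1L)
    msg <- c(msg, "indices must be >= 1")
  if (object@rowMax <= object@rowMin || object@colMax <= object@colMin)
    msg <- c(msg, "rectangle must be nonempty (max > min)")
  if (length(msg)) msg else TRUE
})

#' Construct a RoiRect
#' @param rowMin,rowMax,colMin,colMax inclusive pixel indices.
#' @return A [RoiRect-class] object.
#' @export
RoiRect <- function(rowMin, rowMax, colMin, colMax) {
  new("RoiRect", rowMin = as.integer(rowMin), rowMax = as.integer(rowMax),
      colMin = as.integer(colMin), colMax = as.integer(colMax))
}

#' ContourSet: converged zero-level contours per frame
#'
#' Output of [segmentLumen()]: for each frame, the points of the converged
#' zero level set (fractional pixel coordinates), plus per-frame
#' convergence diagnostics. Frames where the evolution did not converge or
#' where no wall contour was found outside the seed rectangle are flagged
#' failed rather than silently returned.
#'
#' @slot contours list of data.frames with columns `col`, `row`
#'   (fractional pixel coordinates of contour points), one per frame.
#' @slot diagnostics data.frame with columns `frame`, `iterations`,
#'   `residual`, `failed`.
#' @slot roi the seed [RoiRect-class] used.
#' @export
setClass("ContourSet",
  representation(contours = "list", diagnostics = "data.frame",
                 roi = "RoiRect")
)

#' WallTraces: single-valued top/bottom wall positions on a lateral grid
#'
#' Per-column, per-frame axial positions (sub-pixel rows) of the anterior
#' (top, `yTop`) and posterior (bottom, `yBottom`) lumen-wall interfaces,
#' with a QC mask. Wherever the mask is TRUE, `yTop < yBottom` holds.
#'
#' @slot x integer columns of the common lateral grid.
#' @slot yTop,yBottom numeric matrices `(length(x), nFrames)`, rows in px.
#' @slot qcMask logical matrix, TRUE where the cell is valid.
#' @slot pixelSpacing numeric(2) `(axial, lateral)` mm/px, carried from the loop.
#' @slot frameInterval seconds between frames.
#' @export
setClass("WallTraces",
  representation(x = "integer", yTop = "matrix", yBottom = "matrix",
                 qcMask = "matrix", pixelSpacing = "numeric",
                 frameInterval = "numeric")
)

setValidity("WallTraces", function(object) {
  msg <- character()
  dm <- dim(object@yTop)
  if (!identical(dm, dim(object@yBottom)) || !identical(dm, dim(object@qcMask)))
    msg <- c(msg, "yTop, yBottom and qcMask must share dimensions")
  if (dm[1] != length(object@x))
    msg <- c(msg, "first dimension must match the lateral grid x")
  ok <- object@qcMask
  if (any(ok) && any(object@yTop[ok] >= object@yBottom[ok]))
    msg <- c(msg, "yTop must be < yBottom wherever the QC mask is valid")
  if (length(msg)) msg else TRUE
})

#' DiameterMap: the diameter surface D(x,t)
#'
#' Lumen diameter `D(x,t) = |y_b - y_t|` in mm on the lateral grid of the
#' wall traces, with the time vector of the recording. QC-masked cells of
#' the traces propagate as `NA`.
#'
#' @slot D numeric matrix `(length(x), length(time))`, mm; `NA` where masked.
#' @slot x integer lateral grid (columns).
#' @slot time numeric vector, seconds from the first frame.
#' @export
setClass("DiameterMap",
  representation(D = "matrix", x = "integer", time = "numeric")
)

setValidity("DiameterMap", function(object) {
  msg <- character()
  if (nrow(object@D) != length(object@x))
    msg <- c(msg, "nrow(D) must equal length(x)")
  if (ncol(object@D) != length(object@time))
    msg <- c(msg, "ncol(D) must equal length(time)")
  v <- object@D[!is.na(object@D)]
  if (length(v) && any(v < 0))
    msg <- c(msg, "diameters must be >= 0 where valid")
  if (length(msg)) msg else TRUE
})

#' DilatationFit: mono-exponential fit of systolic dilatation
#'
#' Parameters of `D_d(t) = A_d - B_d * exp(-(t - C_d)/T_d)` fitted by
#' Nelder-Mead least squares over one dilatation window.
#'
#' @slot A asymptote, mm. @slot B amplitude, mm. @slot C time shift, s.
#' @slot T rise time constant, s.
#' @slot rmse root-mean-square residual, mm.
#' @slot converged logical. @slot degenerate logical (amplitude below
#'   identifiability floor, time constant meaningless).
#' @slot init numeric, the initial parameter vector used (provenance).
#' @export
setClass("DilatationFit",
  representation(A = "numeric", B = "numeric", C = "numeric", T = "numeric",
                 rmse = "numeric", converged = "logical",
                 degenerate = "logical", init = "numeric")
)

#' RelaxationFit: bi-exponential fit of diastolic relaxation
#'
#' Parameters of
#' `D_r(t) = A_r + B_R1 * exp(-(t - C_r)/T_R1) + B_R2 * exp(-(t - C_r)/T_R2)`
#' fitted over one relaxation window. After fitting, time constants are
#' relabeled so that `T_R1 < T_R2` (fast vs slow).
#'
#' @slot A asymptote, mm. @slot B1,B2 amplitudes of the fast/slow modes, mm.
#' @slot C time shift, s. @slot T1 fast time constant, s. @slot T2 slow
#'   time constant, s.
#' @slot rmse root-mean-square residual, mm.
#' @slot converged,degenerate,accepted logicals.
#' @slot reasons character, rejection reasons from [acceptFit()].
#' @slot init numeric, the initial parameter vector used (provenance).
#' @export
setClass("RelaxationFit",
  representation(A = "numeric", B1 = "numeric", B2 = "numeric",
                 C = "numeric", T1 = "numeric", T2 = "numeric",
                 rmse = "numeric", converged = "logical",
                 degenerate = "logical", accepted = "logical",
                 reasons = "character", init = "numeric")
)

setValidity("RelaxationFit", function(object) {
  msg <- character()
  if (object@rmse < 0) msg <- c(msg, "rmse must be >= 0")
  if (is.finite(object@T1) && is.finite(object@T2) && object@T1 > object@T2)
    msg <- c(msg, "time constants must satisfy T1 <= T2 (fast < slow)")
  if (length(msg)) msg else TRUE
})

#' BariResult: aggregated brachial artery relaxation index
#'
#' BARI is the arithmetic mean of the slow relaxation time constant T_R2
#' over all accepted relaxation fits (all cycles, all cross-sections) of a
#' recording, in seconds. When no fit is accepted the index is undefined
#' (`NA`) and the reason is recorded.
#'
#' @slot bari seconds; `NA` when not derivable.
#' @slot nAcceptedFits integer count.
#' @slot fits data.frame of per-fit provenance: `x`, `cycle`, `tR1`, `tR2`,
#'   `rmse`.
#' @slot classification "fast", "slow" or "none" (see [classifyGrowth()]).
#' @slot reason character, why the index is missing (empty when defined).
#' @export
setClass("BariResult",
  representation(bari = "numeric", nAcceptedFits = "integer",
                 fits = "data.frame", classification = "character",
                 reason = "character")
)

setValidity("BariResult", function(object) {
  msg <- character()
  if (!is.na(object@bari)) {
    if (object@nAcceptedFits < 1L)
      msg <- c(msg, "a defined bari requires >= 1 accepted fit")
    m <- mean(object@fits$tR2)
    if (abs(object@bari - m) > 1e-9 * max(1, abs(m)))
      msg <- c(msg, "bari must equal the mean of the per-fit tR2 values")
  }
  if (length(msg)) msg else TRUE
})

#' PhantomSpec: parameters of the synthetic vessel phantom
#'
#' Everything the generators need to produce a pulsating two-wall vessel:
#' cardiac-cycle timing (trough and peak times), the forward-model
#' parameters of the dilatation and relaxation exponentials, vessel
#' geometry, frame metadata, and the noise model. Defaults emulate a
#' brachial-artery recording: baseline diameter 3.5 mm, pulse amplitude
#' 0.15 mm, four cycles with systolic peaks at 0.5, 1.5, 3.0 and 4.0 s,
#' 50 frames/s, 21 um isotropic pixels, fully developed Rayleigh speckle.
#'
#' @slot troughs,peaks numeric, cycle trough and peak times in s
#'   (one more trough than peaks is allowed to close the last cycle; else
#'   the loop duration closes it).
#' @slot duration recording length, s.
#' @slot frameRate frames per second.
#' @slot pixelSpacing numeric(2) `(axial, lateral)` mm/px.
#' @slot baselineDiameter diastolic (trough) diameter, mm.
#' @slot pulseAmplitude systolic diameter excursion, mm.
#' @slot dilTimeConstant T_d of the systolic rise, s.
#' @slot relaxFast,relaxSlow T_R1 and T_R2 of the diastolic decay, s.
#' @slot relaxSplit fraction of the relaxation amplitude carried by the
#'   fast mode (B_R1 / (B_R1 + B_R2)).
#' @slot wallThicknessPx bright wall band thickness, px.
#' @slot lateralCols number of image columns.
#' @slot marginRows extra rows above/below the outer wall edges.
#' @slot lumenIntensity,wallIntensity,tissueIntensity mean grey levels.
#' @slot speckleContrast multiplicative Rayleigh speckle contrast in
#'   `[0, 1]`; 1 is fully developed speckle.
#' @slot additiveNoiseSd additive Gaussian noise, grey levels.
#' @slot traceNoiseSd Gaussian noise added to analytic diameter traces, mm.
#' @export
setClass("PhantomSpec",
  representation(
    troughs = "numeric", peaks = "numeric", duration = "numeric",
    frameRate = "numeric", pixelSpacing = "numeric",
    baselineDiameter = "numeric", pulseAmplitude = "numeric",
    dilTimeConstant = "numeric", relaxFast = "numeric", relaxSlow = "numeric",
    relaxSplit = "numeric", wallThicknessPx = "numeric",
    lateralCols = "numeric", marginRows = "numeric",
    lumenIntensity = "numeric", wallIntensity = "numeric",
    tissueIntensity = "numeric", speckleContrast = "numeric",
    additiveNoiseSd = "numeric", traceNoiseSd = "numeric"
  )
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  np <- length(object@peaks)
  if (length(object@troughs) < np)
    msg <- c(msg, "need at least one trough per peak")
  if (np >= 1 && any(object@peaks <= object@troughs[seq_len(np)]))
    msg <- c(msg, "each peak must follow its trough")
  if (any(c(object@dilTimeConstant, object@relaxFast, object@relaxSlow) <= 0))
    msg <- c(msg, "all time constants must be > 0")
  if (object@relaxFast >= object@relaxSlow)
    msg <- c(msg, "relaxFast must be < relaxSlow")
  if (object@frameRate * min(object@dilTimeConstant, object@relaxFast) < 2)
    msg <- c(msg, "frame rate too low: need >= 2 samples per fastest timescale")
  if (object@duration <= max(object@peaks))
    msg <- c(msg, "duration must extend past the last peak")
  if (object@relaxSplit <= 0 || object@relaxSplit >= 1)
    msg <- c(msg, "relaxSplit must be in (0, 1)")
  if (object@speckleContrast < 0 || object@speckleContrast > 1)
    msg <- c(msg, "speckleContrast must be in [0, 1]")
  if (length(msg)) msg else TRUE
})
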