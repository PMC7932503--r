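#' Accessors for cine loops and derived surfaces
#'
#' @param object a [CineLoop-class], [WallTraces-class] or
#'   [DiameterMap-class].
#' @return `frames()` the raw frame array; `pixelSpacing()` numeric(2)
#'   `(axial, lateral)` mm/px; `frameInterval()` seconds between frames;
#'   `nFrames()` integer; `timeVector()` the acquisition times in seconds;
#'   `diameters()` the D(x,t) matrix in mm.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("pixelSpacing", function(object) standardGeneric("pixelSpacing"))
#' @rdname accessors
#' @export
setGeneric("frameInterval", function(object) standardGeneric("frameInterval"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("timeVector", function(object) standardGeneric("timeVector"))
#' @rdname accessors
#' @export
setGeneric("diameters", function(object) standardGeneric("diameters"))
#' @rdname accessors
#' @export
setGeneric("qcMask", function(object) standardGeneric("qcMask"))
#' @rdname accessors
#' @export
setGeneric("lateralGrid", function(object) standardGeneric("lateralGrid"))

#' @rdname accessors
#' @export
setMethod("frames", "CineLoop", function(object) object@frames)
#' @rdname accessors
#' @export
setMethod("pixelSpacing", "CineLoop", function(object) object@pixelSpacing)
#' @rdname accessors
#' @export
setMethod("pixelSpacing", "WallTraces", function(object) object@pixelSpacing)
#' @rdname accessors
#' @export
setMethod("frameInterval", "CineLoop", function(object) object@frameInterval)
#' @rdname accessors
#' @export
setMethod("frameInterval", "WallTraces", function(object) object@frameInterval)
#' @rdname accessors
#' @export
setMethod("nFrames", "CineLoop", function(object) dim(object@frames)[3])
#' @rdname accessors
#' @export
setMethod("nFrames", "WallTraces", function(object) ncol(object@yTop))
#' @rdname accessors
#' @export
setMethod("timeVector", "CineLoop", function(object)
  (seq_len(nFrames(object)) - 1) * object@frameInterval)
#' @rdname accessors
#' @export
setMethod("timeVector", "WallTraces", function(object)
  (seq_len(ncol(object@yTop)) - 1) * object@frameInterval)
#' @rdname accessors
#' @export
setMethod("timeVector", "DiameterMap", function(object) object@time)
#' @rdname accessors
#' @export
setMethod("diameters", "DiameterMap", function(object) object@D)
#' @rdname accessors
#' @export
setMethod("qcMask", "WallTraces", function(object) object@qcMask)
#' @rdname accessors
#' @export
setMethod("lateralGrid", "WallTraces", function(object) object@x)
#' @rdname accessors
#' @export
setMethod("lateralGrid", "DiameterMap", function(object) object@x)

#' Wall trace matrices
#'
#' @param object a [WallTraces-class].
#' @param units "px" (sub-pixel rows) or "mm" (rows times axial spacing).
#' @return numeric matrix `(length(x), nFrames)`.
#' @export
setGeneric("wallTop", function(object, units = c("px", "mm"))
  standardGeneric("wallTop"))
#' @rdname wallTop
#' @export
setGeneric("wallBottom", function(object, units = c("px", "mm"))
  standardGeneric("wallBottom"))
#' @rdname wallTop
#' @export
setMethod("wallTop", "WallTraces", function(object, units = c("px", "mm")) {
  units <- match.arg(units)
  if (units == "px") object@yTop else object@yTop * object@pixelSpacing[1]
})
#' @rdname wallTop
#' @export
setMethod("wallBottom", "WallTraces", function(object, units = c("px", "mm")) {
  units <- match.arg(units)
  if (units == "px") object@yBottom else object@yBottom * object@pixelSpacing[1]
})

#' BARI accessors
#' @param object a [BariResult-class].
#' @return `bari()` the index in seconds (`NA` when not derivable);
#'   `acceptedFits()` the per-fit provenance data.frame.
#' @export
setGeneric("bari", function(object) standardGeneric("bari"))
#' @rdname bari
#' @export
setGeneric("acceptedFits", function(object) standardGeneric("acceptedFits"))
#' @rdname bari
#' @export
setMethod("bari", "BariResult", function(object) object@bari)
#' @rdname bari
#' @export
setMethod("acceptedFits", "BariResult", function(object) object@fits)

setMethod("show", "CineLoop", function(object) {
  d <- dim(object@frames)
  cat(sprintf("CineLoop '%s': %d frames of %d x %d px\n",
              object@sourceId, d[3], d[1], d[2]))
  cat(sprintf("  pixel spacing %.4g x %.4g mm, frame interval %.4g s (%.3g fps)\n",
              object@pixelSpacing[1], object@pixelSpacing[2],
              object@frameInterval, 1 / object@frameInterval))
})

setMethod("show", "RoiRect", function(object) {
  cat(sprintf("RoiRect rows [%d, %d], cols [%d, %d]\n",
              object@rowMin, object@rowMax, object@colMin, object@colMax))
})

setMethod("show", "ContourSet", function(object) {
  nf <- length(object@contours)
  cat(sprintf("ContourSet: %d frames, %d failed\n",
              nf, sum(object@diagnostics$failed)))
})

setMethod("show", "WallTraces", function(object) {
  cat(sprintf("WallTraces: %d lateral positions x %d frames (%.1f%% cells valid)\n",
              length(object@x), ncol(object@yTop),
              100 * mean(object@qcMask)))
})

setMethod("show", "DiameterMap", function(object) {
  v <- object@D[!is.na(object@D)]
  cat(sprintf("DiameterMap: %d x %d cells, D in [%.3g, %.3g] mm, %.1f%% valid\n",
              nrow(object@D), ncol(object@D),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA,
              100 * mean(!is.na(object@D))))
})

setMethod("show", "DilatationFit", function(object) {
  cat(sprintf("DilatationFit: A=%.4g B=%.4g C=%.4g T=%.4g s, rmse=%.3g mm%s%s\n",
              object@A, object@B, object@C, object@T, object@rmse,
              if (object@converged) "" else " [not converged]",
              if (object@degenerate) " [degenerate]" else ""))
})

setMethod("show", "RelaxationFit", function(object) {
  cat(sprintf(
    "RelaxationFit: A=%.4g B1=%.4g B2=%.4g C=%.4g T1=%.4g T2=%.4g s, rmse=%.3g mm\n",
    object@A, object@B1, object@B2, object@C, object@T1, object@T2, object@rmse))
  cat(sprintf("  converged=%s accepted=%s%s\n", object@converged, object@accepted,
              if (length(object@reasons))
                paste0(" (", paste(object@reasons, collapse = ", "), ")") else ""))
})

setMethod("show", "BariResult", function(object) {
  if (is.na(object@bari)) {
    cat(sprintf("BariResult: not derivable (%s)\n", object@reason))
  } else {
    cat(sprintf("BariResult: BARI = %.4g s from %d accepted fits (%s)\n",
                object@bari, object@nAcceptedFits, object@classification))
  }
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %d cycles over %.3g s at %g fps, D0=%.3g mm, pulse=%.3g mm\n",
              length(object@peaks), object@duration, object@frameRate,
              object@baselineDiameter, object@pulseAmplitude))
  cat(sprintf("  T_d=%.3g s, T_R1=%.3g s, T_R2=%.3g s; voxel %.3g mm; speckle contrast %.2g\n",
              object@dilTimeConstant, object@relaxFast, object@relaxSlow,
              object@pixelSpacing[1], object@speckleContrast))
})
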