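# Diameter surface D(x,t) and partition of each cross-section's waveform
# into systolic dilatation and diastolic relaxation windows.

#' Compute the diameter surface D(x,t)
#'
#' `D(x,t) = |y_b(x,t) - y_t(x,t)|`, converted from pixels to mm with the
#' axial pixel spacing. QC-masked cells of the traces propagate as `NA`.
#'
#' @param traces a [WallTraces-class].
#' @return A [DiameterMap-class] in mm.
#' @examples
#' ## 100 px separation at 21 um/px is 2.1 mm
#' abs(250 - 150) * 0.021
#' @export
computeDiameter <- function(traces) {
  stopifnot(is(traces, "WallTraces"))
  D <- abs(traces@yBottom - traces@yTop) * traces@pixelSpacing[1]
  D[!traces@qcMask] <- NA_real_
  new("DiameterMap", D = D, x = traces@x,
      time = (seq_len(ncol(D)) - 1) * traces@frameInterval)
}

#' Cycle-detection settings
#'
#' @param smoothSeconds width of the moving-average smoother applied to a
#'   copy of the waveform before extremum detection (the windows returned
#'   always index the raw samples), s.
#' @param prominenceFrac minimum peak/trough prominence as a fraction of
#'   the waveform range.
#' @param minSamples minimum samples per window.
#' @return named list of settings.
#' @export
cycleSettings <- function(smoothSeconds = 0.12, prominenceFrac = 0.25,
                          minSamples = 4L) {
  stopifnot(smoothSeconds >= 0, prominenceFrac > 0, minSamples >= 2)
  list(smoothSeconds = smoothSeconds, prominenceFrac = prominenceFrac,
       minSamples = as.integer(minSamples))
}

# Moving-average smoother with replicated ends (length preserved).
movingAverage <- function(y, w) {
  if (w <= 1L) return(y)
  half <- (w - 1L) %/% 2L
  yp <- c(rep(y[1], half), y, rep(y[length(y)], w - 1L - half))
  as.numeric(stats::filter(yp, rep(1 / w, w), sides = 1))[(w - 1L + 1):(w - 1L + length(y))]
}

# Local maxima with topographic prominence. Returns indices of maxima
# whose prominence is >= minProm. Plateaus count once (first index).
peaksWithProminence <- function(y, minProm) {
  n <- length(y)
  if (n < 3) return(integer())
  cand <- which(diff(sign(diff(y))) < 0) + 1L
  if (!length(cand)) return(integer())
  prom <- vapply(cand, function(i) {
    # key saddle on each side: minimum between the peak and the nearest
    # strictly higher point (or the end of the record if none)
    left <- if (i > 1) {
      j <- which(y[seq_len(i - 1)] > y[i])
      if (length(j)) min(y[(max(j) + 1):i]) else min(y[seq_len(i)])
    } else y[i]
    right <- if (i < n) {
      j <- which(y[(i + 1):n] > y[i])
      if (length(j)) min(y[i:(i + min(j))]) else min(y[i:n])
    } else y[i]
    y[i] - max(left, right)
  }, numeric(1))
  cand[prom >= minProm]
}

#' Detect cardiac cycles in a diameter waveform
#'
#' Locates systolic peaks and diastolic troughs by prominence-based
#' extremum detection on a lightly smoothed copy of the waveform, and
#' assembles trough-to-peak (dilatation) and peak-to-trough (relaxation)
#' windows. Leading/trailing partial cycles are dropped. Smoothing is used
#' for detection only: the returned indices address the raw samples, and
#' fits always run on raw data. A manual annotation table overrides
#' detection entirely.
#'
#' @param d diameter waveform at one cross-section, mm (`NA` gaps are
#'   linearly interpolated for detection when they span < 20% of samples).
#' @param t time vector, s (constant sampling interval).
#' @param settings a [cycleSettings()] list.
#' @param annotations optional data.frame with columns `troughIdx`,
#'   `peakIdx`, `endIdx` (1-based sample indices) that bypasses detection.
#' @return data.frame with columns `troughIdx`, `peakIdx`, `endIdx`; zero
#'   rows when no complete cycle is detectable. The dilatation window of a
#'   cycle is `[troughIdx, peakIdx]`, the relaxation window
#'   `[peakIdx, endIdx]`: exhaustive and non-overlapping within the cycle.
#' @export
detectCycles <- function(d, t, settings = cycleSettings(),
                         annotations = NULL) {
  empty <- data.frame(troughIdx = integer(), peakIdx = integer(),
                      endIdx = integer())
  if (!is.null(annotations)) {
    stopifnot(all(c("troughIdx", "peakIdx", "endIdx") %in% names(annotations)))
    ann <- annotations[, c("troughIdx", "peakIdx", "endIdx")]
    ok <- ann$troughIdx < ann$peakIdx & ann$peakIdx < ann$endIdx
    return(ann[ok, , drop = FALSE])
  }
  if (anyNA(d)) {
    if (mean(is.na(d)) >= 0.2 || is.na(d[1]) || is.na(d[length(d)]))
      return(empty)
    d <- approx(t[!is.na(d)], d[!is.na(d)], xout = t)$y
  }
  rng <- diff(range(d))
  if (rng == 0) return(empty)
  dt <- t[2] - t[1]
  w <- max(1L, round(settings$smoothSeconds / dt))
  if (w %% 2L == 0L) w <- w + 1L
  ds <- movingAverage(d, w)
  minProm <- settings$prominenceFrac * diff(range(ds))
  pk <- peaksWithProminence(ds, minProm)
  tr <- peaksWithProminence(-ds, minProm)
  if (!length(pk)) return(empty)
  # refine each extremum on the raw samples within the smoothing window
  refine <- function(i, fun) {
    lo <- max(1L, i - w); hi <- min(length(d), i + w)
    as.integer(lo + fun(d[lo:hi]) - 1L)
  }
  pk <- sort(unique(vapply(pk, refine, integer(1), fun = which.max)))
  tr <- sort(unique(vapply(tr, refine, integer(1), fun = which.min)))
  # the pre-systolic baseline may not be a prominent minimum at the
  # recording edges; accept the global minimum before the first peak /
  # after the last peak as boundary troughs
  if (!any(tr < pk[1]) && pk[1] > settings$minSamples)
    tr <- sort(c(which.min(d[seq_len(pk[1] - 1)]), tr))
  last <- pk[length(pk)]
  if (!any(tr > last) && length(d) - last >= settings$minSamples)
    tr <- sort(c(tr, last + which.min(d[(last + 1):length(d)])))
  out <- lapply(pk, function(p) {
    before <- tr[tr < p]; after <- tr[tr > p]
    if (!length(before) || !length(after)) return(NULL)
    data.frame(troughIdx = max(before), peakIdx = p, endIdx = min(after))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) return(empty)
  ok <- (out$peakIdx - out$troughIdx + 1L) >= settings$minSamples &
    (out$endIdx - out$peakIdx + 1L) >= settings$minSamples
  out <- out[ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}
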