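# End-to-end convenience: cine loop -> contours -> traces -> D(x,t) ->
# windows -> fits -> BARI.

#' Analyze one recording end to end
#'
#' Runs the full pipeline on a cine loop: level-set segmentation from the
#' seed rectangle, wall-trace extraction, recording QC, the diameter
#' surface, per-cross-section cycle detection, dilatation and relaxation
#' fits on the raw window samples, fit acceptance, and BARI aggregation.
#'
#' @param cine a [CineLoop-class].
#' @param roi a [RoiRect-class] inside the lumen.
#' @param lse a [lseSettings()] list.
#' @param fit a [fitSettings()] list; its `pixelSize` defaults to the
#'   loop's axial spacing when left at the factory default.
#' @param cycles a [cycleSettings()] list.
#' @param qc a [qcThresholds()] list.
#' @param xStride process every `xStride`-th cross-section (1 = all).
#' @param enforceQc when TRUE (default), an excluded recording returns an
#'   undefined BARI carrying the QC reasons instead of fitted values.
#' @return list with `bari` (a [BariResult-class]), `qc`, `traces`,
#'   `diameterMap`, `windows` (per-x data.frames), `relaxationFits` and
#'   `dilatationFits`.
#' @export
analyzeRecording <- function(cine, roi, lse = lseSettings(),
                             fit = fitSettings(pixelSize = pixelSpacing(cine)[1]),
                             cycles = cycleSettings(),
                             qc = qcThresholds(), xStride = 1L,
                             enforceQc = TRUE) {
  cs <- segmentLumen(cine, roi, lse)
  traces <- extractWallTraces(cs, roi, cine)
  verdict <- qcRecording(traces, cine, qc)
  dmap <- computeDiameter(traces)
  if (enforceQc && !verdict$usable) {
    empty <- new("BariResult", bari = NA_real_, nAcceptedFits = 0L,
                 fits = data.frame(x = integer(), cycle = integer(),
                                   tR1 = numeric(), tR2 = numeric(),
                                   rmse = numeric()),
                 classification = "none",
                 reason = paste("recording excluded:",
                                paste(verdict$reasons, collapse = "; ")))
    return(list(bari = empty, qc = verdict, traces = traces,
                diameterMap = dmap, windows = list(),
                relaxationFits = list(), dilatationFits = list()))
  }
  t <- timeVector(dmap)
  xs <- dmap@x[seq(1, length(dmap@x), by = xStride)]
  relFits <- list(); dilFits <- list(); prov <- list(); windows <- list()
  for (x in xs) {
    d <- dmap@D[match(x, dmap@x), ]
    win <- detectCycles(d, t, cycles)
    windows[[as.character(x)]] <- win
    for (k in seq_len(nrow(win))) {
      di <- win$troughIdx[k]:win$peakIdx[k]
      ri <- win$peakIdx[k]:win$endIdx[k]
      if (!anyNA(d[di]))
        dilFits[[length(dilFits) + 1L]] <- fitDilatation(d[di], t[di],
                                                         settings = fit)
      if (anyNA(d[ri])) next
      rf <- acceptFit(fitRelaxation(d[ri], t[ri], settings = fit), fit)
      relFits[[length(relFits) + 1L]] <- rf
      prov[[length(prov) + 1L]] <- data.frame(x = x, cycle = k)
    }
  }
  provDf <- if (length(prov)) do.call(rbind, prov) else NULL
  res <- computeBari(relFits, provenance = provDf)
  list(bari = res, qc = verdict, traces = traces, diameterMap = dmap,
       windows = windows, relaxationFits = relFits,
       dilatationFits = dilFits)
}

#' Wall-localization error of the pipeline on a simulated loop
#'
#' Convenience benchmark used by the validation suite: simulates a phantom
#' loop, segments it with default settings, and returns the mean absolute
#' difference between detected and true wall positions over all valid
#' (x, t) cells and both walls, in micrometres.
#'
#' @param spec a [PhantomSpec-class].
#' @param seed integer seed for the phantom.
#' @param lse a [lseSettings()] list.
#' @param roi optional [RoiRect-class]; defaults to [phantomRoi()].
#' @return list with `meanAbsErrorUm`, `nCells`, `traces`, `truth`.
#' @export
wallErrorBenchmark <- function(spec, seed, lse = lseSettings(), roi = NULL) {
  sim <- simulateCine(spec, seed = seed)
  if (is.null(roi)) roi <- phantomRoi(sim$truth)
  cs <- segmentLumen(sim$cine, roi, lse)
  traces <- extractWallTraces(cs, roi, sim$cine)
  idx <- match(traces@x, seq_len(nrow(sim$truth$yTopPx)))
  ok <- traces@qcMask
  errTop <- abs(traces@yTop - sim$truth$yTopPx[idx, ])[ok]
  errBot <- abs(traces@yBottom - sim$truth$yBottomPx[idx, ])[ok]
  umPerPx <- 1000 * pixelSpacing(sim$cine)[1]
  list(meanAbsErrorUm = mean(c(errTop, errBot)) * umPerPx,
       nCells = 2 * sum(ok), traces = traces, truth = sim$truth)
}
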