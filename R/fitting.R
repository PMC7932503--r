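# Mono-/bi-exponential fitting of the diameter waveform windows by
# Nelder-Mead least squares, with the standard initialization and
# post-fit acceptance rules.

#' Fitting settings
#'
#' All tunables of the curve-fitting stage in one place. Time constants
#' and amplitudes are optimized in log-space to enforce positivity
#' (Nelder-Mead is unconstrained); the tolerances below act on the
#' least-squares cost and the parameter simplex.
#'
#' @param pixelSize mm per (axial) pixel; sets the one-pixel amplitude
#'   initialization and the rmse acceptance scale.
#' @param relTol relative convergence tolerance of the optimizer.
#' @param maxIter maximum Nelder-Mead iterations.
#' @param restarts number of starts; the first uses the supplied (or
#'   standard) initialization, the second rescales its amplitudes to the
#'   data range, the next up to three come from a variable-projection
#'   screen of the time-constant grid, and any further ones jitter in log
#'   space. The best-cost fit wins. The default five starts are all
#'   deterministic; with `restarts = 1` only the prescribed
#'   initialization is used.
#' @param jitterSd standard deviation of the log-space jitter.
#' @param rmseFactor accept a relaxation fit only when
#'   `rmse <= rmseFactor * pixelSize`.
#' @param t2Bounds plausibility interval for the slow time constant, s.
#' @param ratioMin minimum `T2/T1` ratio for a genuine two-timescale fit.
#' @param ampFloorFrac amplitudes below `ampFloorFrac * pixelSize` mark a
#'   degenerate (collapsed) mode.
#' @return named list of settings.
#' @export
fitSettings <- function(pixelSize = 0.021, relTol = 1e-8, maxIter = 2000,
                        restarts = 5, jitterSd = 0.2, rmseFactor = 2,
                        t2Bounds = c(0.05, 10), ratioMin = 2,
                        ampFloorFrac = 0.05) {
  stopifnot(pixelSize > 0, relTol > 0, maxIter > 0, restarts >= 1,
            jitterSd >= 0, rmseFactor > 0, all(t2Bounds > 0),
            ratioMin >= 1, ampFloorFrac > 0)
  list(pixelSize = pixelSize, relTol = relTol, maxIter = maxIter,
       restarts = restarts, jitterSd = jitterSd, rmseFactor = rmseFactor,
       t2Bounds = t2Bounds, ratioMin = ratioMin,
       ampFloorFrac = ampFloorFrac)
}

#' Standard initialization of the exponential fits
#'
#' The initialization rule: asymptote `A` and time shift `C` start at the
#' mean of the diameter range and of the time range within the window;
#' every exponential amplitude starts at the size of one pixel; the slow
#' time constant `T2` starts at the duration of the window and the fast
#' one at `T1 = T2 / 10`. For the mono-exponential dilatation model the
#' single time constant starts at the window duration.
#'
#' @param samples diameter samples in the window, mm.
#' @param t sample times, s.
#' @param settings a [fitSettings()] list (supplies the pixel size).
#' @param model `"relaxation"` (6 parameters) or `"dilatation"` (4).
#' @return named numeric vector: `A, B1, B2, C, T1, T2` for relaxation,
#'   `A, B, C, T` for dilatation.
#' @export
defaultInit <- function(samples, t, settings = fitSettings(),
                        model = c("relaxation", "dilatation")) {
  model <- match.arg(model)
  if (length(samples) < 4L || length(t) != length(samples))
    stop("window too short: need >= 4 samples with matching times")
  A0 <- mean(range(samples))
  C0 <- mean(range(t))
  B0 <- settings$pixelSize
  T2 <- diff(range(t))
  if (model == "relaxation")
    c(A = A0, B1 = B0, B2 = B0, C = C0, T1 = T2 / 10, T2 = T2)
  else
    c(A = A0, B = B0, C = C0, T = T2)
}

# model evaluators -----------------------------------------------------------

dilatationModel <- function(p, t)
  p[["A"]] - p[["B"]] * exp(-(t - p[["C"]]) / p[["T"]])

relaxationModel <- function(p, t)
  p[["A"]] + p[["B1"]] * exp(-(t - p[["C"]]) / p[["T1"]]) +
    p[["B2"]] * exp(-(t - p[["C"]]) / p[["T2"]])

# log-space transforms: positivity of amplitudes and time constants
toLogPar <- function(p, logIdx) { q <- p; q[logIdx] <- log(p[logIdx]); q }
fromLogPar <- function(q, logIdx) { p <- q; p[logIdx] <- exp(q[logIdx]); p }

# Coarse variable-projection screen: on a small log-grid of time
# constants the model is linear in the amplitudes (and asymptote), so
# each grid point is solved by least squares; the best point seeds one
# Nelder-Mead start. Standard hybrid initialization for sums of
# exponentials, whose cost surface traps a single simplex run.
varproSolve <- function(samples, t, Ts, signs) {
  X <- cbind(1, t(signs * t(exp(-outer(t - t[1], Ts, `/`)))))
  co <- qr.coef(qr(X), samples)
  if (anyNA(co)) return(NULL)
  list(cost = sum((samples - X %*% co)^2), co = co)
}

# Coarse variable-projection screen: on a log-grid of time constants the
# model is linear in the amplitudes (and asymptote), so every grid point
# is solved exactly by least squares. The k best well-separated grid
# points (competing basins often differ by well under 1% in cost) are
# returned as deterministic Nelder-Mead starts. Standard hybrid
# initialization for sums of exponentials, whose cost surface traps a
# single simplex run.
varproStarts <- function(samples, t, init, nT = 12, k = 3) {
  dur <- diff(range(t))
  biexp <- length(init) == 6L
  tg <- exp(seq(log(max(dur / 50, 1e-3)), log(10 * dur), length.out = nT))
  cand <- list()
  if (biexp) {
    for (i in seq_len(nT)) for (j in seq_len(nT)) {
      if (tg[i] >= tg[j]) next
      s <- varproSolve(samples, t, c(tg[i], tg[j]), c(1, 1))
      if (is.null(s)) next
      cand[[length(cand) + 1L]] <- list(
        cost = s$cost,
        par = c(A = unname(s$co[1]), B1 = max(unname(s$co[2]), 1e-6),
                B2 = max(unname(s$co[3]), 1e-6), C = t[1],
                T1 = tg[i], T2 = tg[j]))
    }
  } else {
    for (i in seq_len(nT)) {
      s <- varproSolve(samples, t, tg[i], -1)
      if (is.null(s)) next
      cand[[length(cand) + 1L]] <- list(
        cost = s$cost,
        par = c(A = unname(s$co[1]), B = max(unname(s$co[2]), 1e-6),
                C = t[1], T = tg[i]))
    }
  }
  if (!length(cand)) return(list())
  cand <- cand[order(vapply(cand, `[[`, numeric(1), "cost"))]
  tNames <- if (biexp) c("T1", "T2") else "T"
  picked <- list()
  for (ci in cand) {
    if (length(picked) >= k) break
    sep <- all(vapply(picked, function(p)
      any(abs(log(ci$par[tNames]) - log(p[tNames])) > log(2)), logical(1)))
    if (!length(picked) || sep)
      picked[[length(picked) + 1L]] <- ci$par
  }
  picked
}

# Shared Nelder-Mead driver over a model function. Each start is run to
# convergence and then re-run from its own solution until the cost stops
# improving (the classic simplex-restart guard against premature
# collapse). Start 1 is the supplied initialization; start 2 rescales the
# amplitudes to the data range (the one-pixel init can be orders of
# magnitude off scale); starts 3+ come from the variable-projection
# screen's best distinct basins; any remaining restarts jitter in log
# space. Best cost wins. Starts 1 through 2 + k are deterministic, so the
# default fit is reproducible; with restarts = 1 only the prescribed
# initialization is used.
nmFit <- function(samples, t, init, logIdx, ampNames, modelFun, settings) {
  cost <- function(q) {
    p <- fromLogPar(q, logIdx)
    r <- samples - modelFun(p, t)
    sum(r * r)
  }
  runPolished <- function(q) {
    o <- optim(q, cost, method = "Nelder-Mead",
               control = list(reltol = settings$relTol,
                              maxit = settings$maxIter))
    for (i in 1:5) {
      o2 <- optim(o$par, cost, method = "Nelder-Mead",
                  control = list(reltol = settings$relTol,
                                 maxit = settings$maxIter))
      if (o2$value >= o$value * (1 - 10 * settings$relTol)) {
        if (o2$value < o$value) o <- o2
        break
      }
      o <- o2
    }
    o
  }
  q0 <- toLogPar(init, logIdx)
  qScaled <- q0
  rng <- diff(range(samples))
  if (rng > 0)
    qScaled[ampNames] <- log(rng / length(ampNames))
  screen <- if (settings$restarts >= 3)
    varproStarts(samples, t, init) else list()
  best <- NULL
  for (k in seq_len(settings$restarts)) {
    qk <- if (k == 1) q0
          else if (k == 2) qScaled
          else if (k - 2 <= length(screen))
            toLogPar(screen[[k - 2]], logIdx)
          else qScaled + rnorm(length(q0), sd = settings$jitterSd)
    o <- runPolished(qk)
    if (is.null(best) || o$value < best$value) best <- o
  }
  p <- fromLogPar(best$par, logIdx)
  list(par = p, rmse = sqrt(best$value / length(samples)),
       converged = best$convergence == 0L)
}

#' Fit the systolic dilatation mono-exponential
#'
#' Fits `D_d(t) = A_d - B_d exp(-(t - C_d)/T_d)` to one dilatation window
#' by Nelder-Mead minimization of the sum of squared residuals, starting
#' from the standard initialization (or a supplied one). Amplitude and
#' time constant are optimized in log space. A fit whose amplitude falls
#' below the identifiability floor (essentially constant data) is flagged
#' degenerate: its time constant is meaningless.
#'
#' @param samples diameter samples, mm.
#' @param t sample times, s.
#' @param init optional named initial vector `(A, B, C, T)`.
#' @param settings a [fitSettings()] list.
#' @return A [DilatationFit-class].
#' @export
fitDilatation <- function(samples, t, init = NULL,
                          settings = fitSettings()) {
  if (is.null(init))
    init <- defaultInit(samples, t, settings, model = "dilatation")
  f <- nmFit(samples, t, init, logIdx = c("B", "T"), ampNames = "B",
             modelFun = dilatationModel, settings = settings)
  floorAmp <- settings$ampFloorFrac * settings$pixelSize
  # a window flatter than the identifiability floor has no rise to fit
  degen <- f$par[["B"]] < floorAmp || diff(range(samples)) < floorAmp
  new(Class = "DilatationFit", A = f$par[["A"]], B = f$par[["B"]],
      C = f$par[["C"]], T = f$par[["T"]], rmse = f$rmse,
      converged = f$converged, degenerate = degen, init = init)
}

#' Fit the diastolic relaxation bi-exponential
#'
#' Fits
#' `D_r(t) = A_r + B_R1 exp(-(t - C_r)/T_R1) + B_R2 exp(-(t - C_r)/T_R2)`
#' to one relaxation window by Nelder-Mead least squares from the standard
#' initialization (amplitudes and time constants in log space). After
#' convergence the two modes are relabeled so `T1 < T2` (fast before
#' slow), whatever their order in the initial vector. The fit is flagged
#' degenerate when the two time constants collapse onto each other or one
#' amplitude drops below the identifiability floor — a single-exponential
#' decay in disguise.
#'
#' @param samples diameter samples, mm.
#' @param t sample times, s.
#' @param init optional named initial vector `(A, B1, B2, C, T1, T2)`.
#' @param settings a [fitSettings()] list.
#' @return A [RelaxationFit-class] (acceptance flag unset; see
#'   [acceptFit()]).
#' @export
fitRelaxation <- function(samples, t, init = NULL,
                          settings = fitSettings()) {
  if (is.null(init))
    init <- defaultInit(samples, t, settings, model = "relaxation")
  f <- nmFit(samples, t, init, logIdx = c("B1", "B2", "T1", "T2"),
             ampNames = c("B1", "B2"), modelFun = relaxationModel,
             settings = settings)
  p <- f$par
  if (p[["T1"]] > p[["T2"]]) {   # relabel: fast mode first
    p[c("B1", "T1", "B2", "T2")] <- p[c("B2", "T2", "B1", "T1")]
  }
  floorAmp <- settings$ampFloorFrac * settings$pixelSize
  collapse <- p[["T2"]] / p[["T1"]] < 1.05
  degen <- collapse || p[["B1"]] < floorAmp || p[["B2"]] < floorAmp ||
    diff(range(samples)) < floorAmp
  new(Class = "RelaxationFit", A = p[["A"]], B1 = p[["B1"]], B2 = p[["B2"]],
      C = p[["C"]], T1 = p[["T1"]], T2 = p[["T2"]], rmse = f$rmse,
      converged = f$converged, degenerate = degen,
      accepted = NA, reasons = character(), init = init)
}

#' Accept or reject a relaxation fit
#'
#' A fit enters the relaxation index only when it is a credible
#' two-timescale decay. Rejection reasons (all that apply are returned):
#' `"not converged"`; `"rmse"` when the residual exceeds
#' `rmseFactor * pixelSize`; `"t2 bounds"` when the slow constant falls
#' outside the plausibility interval; `"timescale collapse"` when
#' `T2/T1 < ratioMin`; `"degenerate"` when the fitter flagged an
#' unidentifiable mode.
#'
#' @param fit a [RelaxationFit-class].
#' @param settings a [fitSettings()] list (thresholds).
#' @return the fit with `accepted` and `reasons` slots filled in.
#' @export
acceptFit <- function(fit, settings = fitSettings()) {
  reasons <- character()
  if (!fit@converged) reasons <- c(reasons, "not converged")
  if (fit@rmse > settings$rmseFactor * settings$pixelSize)
    reasons <- c(reasons, "rmse")
  if (fit@T2 < settings$t2Bounds[1] || fit@T2 > settings$t2Bounds[2])
    reasons <- c(reasons, "t2 bounds")
  if (fit@T2 / fit@T1 < settings$ratioMin)
    reasons <- c(reasons, "timescale collapse")
  if (fit@degenerate) reasons <- c(reasons, "degenerate")
  fit@accepted <- length(reasons) == 0L
  fit@reasons <- reasons
  fit
}

#' Grid-search reference fit of the bi-exponential (slow, exact)
#'
#' Independent reference for the Nelder-Mead fitter: on a dense
#' `(T1, T2)` log grid the model is linear in `(A, b1, b2)` (the time
#' shift folds into the amplitudes), so each grid point is solved exactly
#' by least squares and the best grid point bounds the achievable cost.
#' The amplitudes are constrained nonnegative — the model class being
#' fitted decays from above — by exact active-set enumeration (both
#' amplitudes free, either one zeroed, or both). Used for validation; far
#' too slow for production fitting.
#'
#' @param samples,t window samples (mm) and times (s).
#' @param nGrid grid points per axis.
#' @param tRange range of time constants covered, s.
#' @return list with `cost` (residual sum of squares at the best grid
#'   point), `T1`, `T2`.
#' @export
gridReferenceFit <- function(samples, t, nGrid = 60,
                             tRange = c(0.01, 10)) {
  tg <- exp(seq(log(tRange[1]), log(tRange[2]), length.out = nGrid))
  n <- length(samples)
  costA <- sum((samples - mean(samples))^2)   # both amplitudes zero
  nnCost <- function(e1, e2) {
    best <- costA
    for (cols in list(cbind(1, e1, e2), cbind(1, e1), cbind(1, e2))) {
      co <- tryCatch(qr.coef(qr(cols), samples), error = function(e) NULL)
      if (is.null(co) || anyNA(co)) next
      if (any(co[-1] < 0)) next                 # infeasible support
      cost <- sum((samples - cols %*% co)^2)
      if (cost < best) best <- cost
    }
    best
  }
  best <- list(cost = Inf, T1 = NA_real_, T2 = NA_real_)
  for (i in seq_len(nGrid)) for (j in seq_len(nGrid)) {
    if (tg[i] >= tg[j]) next
    cost <- nnCost(exp(-t / tg[i]), exp(-t / tg[j]))
    if (cost < best$cost) best <- list(cost = cost, T1 = tg[i], T2 = tg[j])
  }
  best
}
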