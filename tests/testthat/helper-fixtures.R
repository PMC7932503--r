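# Shared fixtures: small phantoms and hand-built objects used across the
# module tests. Everything is generated in code; no binary fixtures.

# short single-cycle phantom loop (small and fast to segment);
# any phantomSpec argument can be overridden
quickSpec <- function(...) {
  args <- list(troughs = 0, peaks = 0.3, duration = 0.6, frameRate = 25)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(phantomSpec, args)
}

# hand-built wall traces: straight walls at given rows, optionally masked
makeTraces <- function(nx = 5, nf = 4, top = 100, bottom = 250,
                       spacing = c(0.021, 0.021), dt = 0.02,
                       mask = NULL) {
  yT <- matrix(top, nx, nf)
  yB <- matrix(bottom, nx, nf)
  if (is.null(mask)) mask <- matrix(TRUE, nx, nf)
  yT[!mask] <- NA_real_
  yB[!mask] <- NA_real_
  new("WallTraces", x = seq_len(nx), yTop = yT, yBottom = yB,
      qcMask = mask, pixelSpacing = spacing, frameInterval = dt)
}

# a RelaxationFit with given values (bypasses fitting)
makeRelFit <- function(t1 = 0.1, t2 = 1.2, rmse = 0.001, converged = TRUE,
                       degenerate = FALSE, accepted = NA) {
  new(Class = "RelaxationFit", A = 3, B1 = 0.1, B2 = 0.1, C = 0,
      T1 = t1, T2 = t2, rmse = rmse, converged = converged,
      degenerate = degenerate, accepted = accepted,
      reasons = character(), init = numeric())
}

# exhaustive two-sided Mann-Whitney permutation p-value (independent of
# wilcox.test): enumerates all group assignments of the pooled sample
exactMannWhitneyP <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  r <- rank(pooled)
  uObs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(length(pooled), n)
  u <- apply(combs, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  pl <- mean(u <= uObs)
  pg <- mean(u >= uObs)
  min(1, 2 * min(pl, pg))
}
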