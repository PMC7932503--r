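---
title: "Measuring arterial wall relaxation from B-mode cine ultrasound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring arterial wall relaxation from B-mode cine ultrasound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bariTrack)
```

## The measurement model

A short segment of the brachial artery is imaged in B-mode over a few
cardiac cycles. In each frame the lumen appears as a dark band between
two bright wall echoes. At every lateral position $x$ the anterior and
posterior lumen-wall interfaces $y_t(x,t)$ and $y_b(x,t)$ are tracked,
and the diameter surface is

$$D(x,t) = |y_b(x,t) - y_t(x,t)|,$$

converted to millimetres with the axial pixel spacing. Within a cardiac
cycle the waveform at one cross-section has three regimes: a steep
systolic rise (driven by the pressure pulse), a steep fall, and a slow
fall toward the diastolic baseline. Treating the wall as a spring-dashpot
(Zener) solid motivates exponential responses: the dilatation is fitted
by a mono-exponential rise

$$D_d(t) = A_d - B_d\, e^{-(t - C_d)/T_d},$$

and the whole diastolic relaxation — steep and slow fall together — by a
bi-exponential decay

$$D_r(t) = A_r + B_{R1}\, e^{-(t - C_r)/T_{R1}}
               + B_{R2}\, e^{-(t - C_r)/T_{R2}},
  \qquad T_{R1} < T_{R2}.$$

Systole convolves the driving pressure with the wall response, so wall
properties are read from diastole; the slow constant $T_{R2}$, acting
when arterial pressure is lowest, is the most wall-sensitive quantity.
The *brachial artery relaxation index* (BARI) of a recording is the
arithmetic mean of $T_{R2}$ over all accepted fits — every cycle at every
cross-section contributes one value. A pilot threshold of 1.5 s separates
growth types; because the threshold's orientation is a study-level
choice, `classifyGrowth()` requires the caller to state which side means
"fast" and assigns values exactly on the threshold to the $\geq$ side.

## Segmentation

Wall positions come from a distance-regularized level-set evolution
(double-well potential, so no reinitialization is needed). The level-set
function starts as a binary step on a user rectangle placed wholly inside
the lumen and evolves by

$$\partial_t \phi = \mu\, \mathrm{distReg}(\phi)
  + \lambda\, \delta_\epsilon(\phi)\, \mathrm{div}\!\left(g \frac{\nabla\phi}{|\nabla\phi|}\right)
  + \alpha\, g\, \delta_\epsilon(\phi),$$

with edge indicator $g = 1/(1 + |\nabla (G_\sigma * I)|^2)$ on the
0–255-normalized frame and an outward balloon force ($\alpha < 0$). The
contour therefore grows from the rectangle until the wall echoes stop it;
the zero level set is extracted with sub-pixel interpolation. Frames
after the first warm-start from the previous frame's converged level set
(wall motion between frames is well under the Dirac band width at
clinical frame rates); `reinitEachFrame = TRUE` forces independent
evolution for ablation. All constants live in `lseSettings()`:

| parameter | default | meaning |
|---|---|---|
| `sigma` | 2 px | Gaussian smoothing before the gradient |
| `mu`, `timestep` | 0.2, 1 | distance regularization (stability: $\mu\,\Delta t < 0.25$) |
| `lambda` | 5 | edge/curvature attraction |
| `alpha` | −3 | outward balloon force |
| `epsilon` | 1.5 px | Dirac band width |
| `maxIter`, `warmIter` | 1000, 250 | iteration budgets (first / warm-started frames) |
| `convTol` | 0 | converged when no pixel changes sign between checks |

Defaults were fixed once on the phantom benchmark (below): across 20
seeded loops at 21 µm pixels and fully developed speckle the mean
absolute wall-localization error is ≈ 18–19 µm, i.e. below one voxel.

Contours are reduced to single-valued traces by splitting at the
rectangle's vertical midline and averaging multiple contour points that
fall on the same image column (S- or Z-shaped stretches). A recording is
excluded by `qcRecording()` when more than 50 % of cells are masked, when
traces jump more than 5 px between frames on more than 10 % of columns,
or when the 99th-percentile intensity inside the detected lumen exceeds
0.35 of the frame's 99th percentile — a proxy for slice-thickness
artefacts, the dominant failure mode on clinical loops. The thresholds
are explicit configuration: exclusion on real data was a judgment call,
and these defaults reproduce it mechanically on the phantom.

## Cycle windows

Peaks and troughs are found on a lightly smoothed copy of the waveform
(moving average over 0.12 s) by topographic prominence (≥ 25 % of the
waveform range), then refined to the raw-sample extremum; fits always run
on raw samples so smoothing cannot bias time constants. Windows are
trough → peak (dilatation) and peak → next trough (relaxation), dropping
partial leading/trailing cycles; the partition is exhaustive and
non-overlapping within each cycle. A manual annotation table (per-x
trough/peak/trough indices) overrides detection entirely, reproducing a
manual-marking workflow. Cycle irregularity is not itself a QC criterion.

## Fitting

The fits minimize the residual sum of squares with Nelder-Mead. The
initialization follows a fixed rule: $A$ and $C$ start at the means of
the diameter and time ranges of the window, every exponential amplitude
starts at the size of one pixel, $T_{R2}$ at the window duration, and
$T_{R1} = T_{R2}/10$ (both bi-exponential amplitudes get the one-pixel
start; the dilatation time constant starts at the window duration).
Because Nelder-Mead is unconstrained, amplitudes and time constants are
optimized in log space, which enforces positivity. Three safeguards make
the simplex reliable on exponential sums, whose cost surfaces trap single
runs:

* each start is re-run from its own solution until the cost stops
  improving (simplex-restart guard);
* start 2 rescales the one-pixel amplitudes to the data range;
* starts 3–5 come from a coarse variable-projection screen — on a small
  log-grid of time constants the model is linear in the amplitudes, so
  each grid point is solved exactly and the best well-separated basins
  seed the simplex. The five default starts are deterministic;
  `restarts = 1` keeps only the prescribed initialization.

After convergence the modes are relabeled so $T_{R1} < T_{R2}$, whatever
the initial ordering. Note that $C$ is not separately identifiable — it
trades exactly against the amplitudes via $B\,e^{C/T}$ — so only the time
constants and effective amplitudes are meaningful outputs.

`acceptFit()` admits a fit to the index only when it converged, its rmse
is at most twice the pixel size, $T_{R2}$ lies in a plausibility interval
(0.05–10 s), the timescales have not collapsed ($T_{R2}/T_{R1} \geq 2$),
and no amplitude fell below the identifiability floor. Degenerate cases
(flat windows, single-exponential decays) are flagged rather than
silently reported.

### Identifiability of the slow constant

With a free asymptote and both modes free, the information a single
window carries about $T_{R2}$ is limited. The Cramér-Rao bound at
0.5 px (10.5 µm) Gaussian noise and 50 Hz sampling gives a relative
standard deviation for $T_{R2}$ of roughly 0.25–0.7 for every
physiologically plausible combination of diastolic window (≤ 1.2 s),
relaxation amplitude (≤ 0.6 mm) and $T_{R2}$ (0.25–1.5 s); windows
shorter than a few multiples of $T_{R2}$ barely pin the asymptote at all.
Monte-Carlo recovery with an exact grid reference matches the bound. Two
consequences are designed into the package: BARI averages over all
accepted (x, cycle) fits rather than trusting any single window, and the
validation suite checks the *optimizer* (noiseless recovery to well under
1 %, cost never worse than the constrained dense-grid reference) and
reports the noisy-recovery error honestly via `recoveryExperiment()`
(bias and median absolute relative error per noise level) instead of
asserting precision the data cannot support.

## The synthetic phantom

`phantomSpec()` fixes the study conditions once: four cardiac cycles with
systolic peaks at 0.5, 1.5, 3.0 and 4.0 s (deliberately irregular), 50
frames/s, 21 µm isotropic pixels, baseline diameter 3.5 mm, pulse
amplitude 0.15 mm (≈ 4 % distension), $T_d = T_{R1} = 0.1$ s,
$T_{R2} = 1.0$ s, and a relaxation amplitude split evenly between the
modes. `simulateDiameterTrace()` evaluates the forward model with
amplitudes re-solved at every junction so the waveform is continuous at
peaks and troughs — window-by-window fitting does not need continuity,
but unambiguous ground truth does. `simulateCine()` renders the vessel as
a dark lumen between two bright wall bands with anti-aliased
(area-weighted) sub-pixel edges, multiplies fully developed Rayleigh
speckle (unit-mean envelope; `speckleContrast` scales it), adds Gaussian
readout noise (sd 2 grey levels), and quantizes to integer grey levels so
a DICOM round trip is bit-exact. Both generators are pure functions of
(spec, seed).

What the phantom does *not* emulate: a point-spread function (speckle is
per-pixel, not convolved scatterers), attenuation/TGC, out-of-plane
motion, wall-thickness texture, or curved/tapering vessels. Passing the
phantom benchmark therefore shows that the algorithm chain is correct and
voxel-accurate under the stated image model; it does not certify
performance on clinical recordings, where slice artefacts — handled only
by the QC exclusion rules — and probe motion dominate.

## Numerical and design choices

* **Units.** Traces are stored in sub-pixel rows with the pixel spacing
  carried alongside; diameters are in mm, times in seconds. DICOM frame
  time is read in ms and converted once.
* **Missing metadata raise.** A cine file without pixel spacing or frame
  timing is an error naming the missing attribute, never a default.
* **Size bands.** APD < 30 mm is labelled `HV`, 30–39 `small`, 40–55
  `moderate` (both ends closed), > 55 `large`; fractional diameters
  between printed band edges (e.g. 39.5 mm) fall to the lower band so the
  labelling is total.
* **Group comparisons.** The healthy-vs-patient comparison reports both
  an unpaired t-test and a Mann-Whitney test, clearly labeled, because
  median/IQR summaries and a t-test sit uneasily together; readers can
  use either. Kruskal-Wallis follow-ups use rank-based pairwise tests
  with Bonferroni adjustment.
* **Problem sizes in the validation suite.** Segmentation properties use
  single-cycle loops at 25 fps (the localization error is a per-cell
  statistic, independent of loop length); fitting properties use 100
  simulated windows per noise level; the seeded benchmark uses 20
  replicates.
* **Known limitations.** Per-window $T_{R2}$ at clinical noise is a
  low-information estimate (see above); the level-set edge-stopping
  position carries a small contrast-dependent bias (fractions of a pixel
  at default contrast, larger when speckle is switched off entirely,
  since a clean steep edge freezes the front earlier); BARI values from
  different acquisition settings should not be pooled without checking
  window lengths, which bound the estimable $T_{R2}$.
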