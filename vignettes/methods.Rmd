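---
title: "Methods: models, calibration and design choices in spheroidGNP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, calibration and design choices in spheroidGNP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheroidGNP)
```

## The scientific problem

In 3D cultures of cancer cells grown on an extracellular-matrix (ECM) bed,
ultrasmall gold nanoparticles (GNPs) added to the medium first lodge in the
matrix and only gradually redistribute into the multicellular nodules.
Because GNP radiosensitization acts over micrometre ranges, the *location*
of the particles on the day of irradiation — matrix versus nodule — governs
the damage enhancement. The package quantifies this redistribution from
time-lapse darkfield (morphology) and fluorescence (labelled GNP) imaging,
and links it to clonogenic outcomes through the sensitivity enhancement
ratio (SER).

## Growth model

Nodule size follows the Gompertz law
$$N(t) = N_0\, e^{A(1-e^{-\alpha t})/\alpha},$$
with growth rate $A$ (day$^{-1}$) decaying at rate $\alpha$ (day$^{-1}$);
the small-time expansion $N/N_0 \approx e^{At} = 2^{t/\tau}$ defines the
exponential-phase doubling time $\tau = \ln 2 / A$, reported in hours
($24\ln 2/A$). `fit_gompertz()` works on the log scale by default
(multiplicative residuals), because sizes span orders of magnitude over a
culture's life; parameters are log-transformed inside the optimiser so
positivity is structural, and Levenberg–Marquardt iterations make the fit
deterministic for fixed inputs and starting values. A linear-residual loss
is available (`loss = "linear"`). Non-convergence is returned as a flagged
result with the optimiser message, never silently.

The growth stage of the pipeline fits the per-day mean volume of the
*large* (second-peak) population, identified by the mixture model below,
because that is the aggressively growing population whose kinetics are of
interest; days on which the mixture cannot separate two components
contribute the mean over all objects.

## Size distributions

Projection areas are treated as lognormal, so Gaussian mixtures are fitted
in log-area space — a single description that is simultaneously "Gaussian
in the histogram of log areas" and "lognormal in linear areas". The
1-component fit is the closed-form Gaussian MLE; the 2-component fit uses
expectation–maximisation (unequal variances, deterministic model-based
initialisation via *mclust*, with an equal-variance fallback for
near-degenerate draws). Both BIC scores (conventional sign: lower is
better) are always reported so callers select the supported component
count; components are ordered by ascending mean, and zero-variance input
is rejected as degenerate rather than fitted.

## Segmentation and morphometry

The study-level processing chain is standardised as: min–max
normalisation, global Otsu threshold (hence invariance to positive
intensity rescaling), morphological opening (disc radius 2 px by default),
hole filling, 8-connected component labelling, and removal of objects
below a minimum area expressed in µm² (default 100 µm² — below a single
~19.3 µm cell's ~293 µm² projection, above shot-noise specks) so that
results are resolution independent. The background (ECM) mask is the exact
logical negation of the foreground; the partition is asserted on every
call. Segmentation runs on the darkfield channel by default
(morphology-driven), with a config switch for fluorescence.

Per-object semi-axes come from the second central moments of the pixel
region, scaled so a solid disc of radius $r$ returns $a=b=r$; volumes use
the prolate-ellipsoid estimate $V = \tfrac43\pi a b^2$. Touching or merged
clusters are measured as single nodules — aggregation is part of the
growth story in this culture system, and no watershed splitting or
cross-day tracking is attempted.

## Transfer model and intensity kinetics

GNP redistribution is modelled by the minimal single-rate two-compartment
exchange
$$\mathrm{ecm}(t) = E_\mathrm{floor} + E_0 e^{-k\Delta},\qquad
  \mathrm{nodule}(t) = b + \eta E_0 (1 - e^{-k\Delta}),\qquad
  \Delta = t - t_\mathrm{delivery},$$
which conserves signal exactly when $\eta = 1$. The defaults encode the
study conditions: delivery on day 7 and $k = \ln(20)/6 \approx
0.499$ day$^{-1}$, placing 95% transfer six days post-delivery, i.e. the
intensity plateau on day 13. $E_\mathrm{floor} = 20$ (of $E_0 = 100$)
represents irreversibly matrix-bound residue — modelled as GNP-derived,
so no-treatment control wells carry only camera offset and cellular
autofluorescence, matching how the control-based background is used. The
nodule baseline $b = 5$ a.u. is calibrated so the nodule-intensity
trajectory changes by less than 2%/day from the 95%-transfer day onward
(the plateau contract); with baseline $b$ the day-13→14 relative change is
$1.97/(95+b)$, so $b \ge 3.5$ is required and 5 matches the camera-offset
scale. A plateau contract on the nodule/ECM *ratio* is not attainable
under this model: $\mathrm{d}\ln(\mathrm{ratio})/\mathrm{d}t = kE_0
e^{-k\Delta}(1/\mathrm{fg} + 1/\mathrm{bg}) > 2\%/\mathrm{day}$ at
$\Delta = 6$–7 for any floor small enough to allow the nodule signal to
cross the ECM signal, so the plateau is defined on the nodule intensity —
which is also what the underlying plateau observation describes.

Analysis mirrors the experimental procedure: the scalar background (mean
of matched no-treatment frames, nearest day with a warning if the exact
day is missing) is subtracted first with flooring at zero, compartment
means are taken under the darkfield-derived masks, and per-day statistics
average across wells (the ratio uses per-day mean foreground over per-day
mean background, not the mean of per-well ratios — across-well means of
per-well compartment means, since pooled-pixel weighting is not
identifiable from summary imaging). `--no-bg-subtract`-style behaviour is
available via `kinetics$bg_subtract = FALSE`.

The two-phase uptake fit treats each time window as roughly linear: for
every candidate break day (any observed day with at least three points on
each side; the break day belongs to both windows) two independent OLS
lines are fitted and the break minimising the total RSS is returned — the
implementation *is* the exhaustive search. Slopes are in ratio units per
day (the natural reading of an uptake-ratio trend). A
continuity-constrained variant is available by flag; a fixed break (e.g.
day 11, the by-inspection choice) can be forced through
`candidate_breaks`. The plateau tolerance for `detect_peak_day()` is 5%
relative (none is prescribed by the source observations); a series still
rising at its last day is returned censored. The crossover day is linearly
interpolated between the bracketing observations.

## Clonogenic analysis

Per-replicate survival factors $(\mathrm{colonies}/\mathrm{plated})/
\mathrm{PE}$ are averaged with their standard error;
$\mathrm{SER} = \mathrm{SF}_{RT}/\mathrm{SF}_{RT+GNP}$ with first-order
(delta-method) error propagation. Plating efficiency defaults to 1 —
survival factors taken at face value — but is an explicit argument, and
per-time-point normalisation to unirradiated controls is assumed (the
alternative is expressible by passing a different PE per arm). With a
single 2 Gy dose no linear-quadratic fitting is attempted.

## What the generator emulates — and what it does not

Per well and day the generator draws a nodule population, paints a
darkfield and a fluorescence frame, and records truth. Key choices:

* **Population trajectory.** Day 0 is all single cells with lognormal
  areas around the 19.3 µm cell diameter. Later days mix a persistent
  small population with an aggregation-driven large population; each
  component's geometric-mean area follows a Gompertz-shaped profile in
  $\alpha = 0.35$ day$^{-1}$ (plateau near day 9), with amplitude
  *calibrated* so the day-7 modes hit the configured targets (defaults
  1,300 and 19,300 µm²). The calibration is deliberate: with
  $\alpha = 0.35$, proliferation at $A = 0.8$ day$^{-1}$ alone caps growth
  at $e^{A/\alpha} \approx 9.8\times$ in volume, far short of the observed
  day-7 large mode — comigration and aggregation dominate, so the
  image-derived growth coefficient reported by the pipeline is an
  *effective* rate conflating both processes, and the $A = 0.8$,
  $\alpha = 0.35$ pair is exercised directly through the closed-form
  growth API. Setting `growth$A = 0` freezes sizes;
  `aggregation$enabled = FALSE` freezes composition.
* **Scene layout.** Ellipses (aspect ratio 1–1.6, uniform orientation) are
  placed uniformly at random with centre separations exceeding the sum of
  semi-major axes plus 3 px, so rendered objects never touch and truth
  masks map one-to-one onto segmented components; objects that cannot be
  placed in 300 attempts are dropped. Pixel size defaults to
  1.29 µm/px on 1024×1024 frames (a cell spans ~15 px) — chosen for
  segmentability, and scaled down in tests.
* **Noise.** Signal-dependent Gaussian noise (variance = gain × signal,
  the Poisson-like camera term, gain 0.5), additive read noise (sd 2),
  constant offset (5) — a standard fluorescence-camera model. Per-well
  session jitter is 1% (lognormal) per compartment: frame means pool
  $\sim 10^4$–$10^6$ pixels, so replicate scatter is acquisition-, not
  pixel-, limited, and a day-resolved plateau (adjacent days differing by
  ~2%) is only detectable at all if replicate CV is of that order.
* **Monolayer contrast.** Cellular signal $E_0(1-e^{-kt})$ with
  $k = \ln 50$ day$^{-1}$: 98% of the asymptote within the first day, so
  the day-1 level is at least 95% of the asymptote *and* days 1–8 agree
  within 5% — both flat-uptake properties hold simultaneously (at
  $k = \ln 20$ the day-5/day-1 ratio would be $1/0.95 = 1.053$,
  violating the second).
* **Assays.** Lysate absorbance is proportional to the per-well nodule
  GNP content with 15% multiplicative CV (monotonicity is assessed over
  the transfer window, delivery day through the 95% day: past the
  plateau, adjacent true values differ by <1.3% and their ranks shuffle
  under any realistic assay noise). Colony counts are
  Binomial(n plated, SF × PE) draws at the four arm survival levels
  (0.680/0.246 four-day, 0.423/0.309 one-day).

Not emulated: confocal z-stacks or any 3D rendering, physical
diffusion-versus-sedimentation transport, intranodular radial GNP
gradients (nodules are painted uniformly; the periphery-first ingress seen
in confocal imaging is a known simplification), photobleaching (constant
acquisition settings are assumed and none is injected), sub-day kinetics
(the 45 min exposure window is metadata only), and culture-age-dependent
radioresistance beyond the per-schedule RT-only baselines. Passing tests
therefore demonstrate correctness of the measurement chain under this
generative model, not robustness to imaging artefacts absent from it
(debris, illumination gradients, focus drift).

The two-phase appearance of the ratio curve is *emergent* from the
exponential transfer plus noise; the early/late slope values are analysis
outputs, never generator inputs — the only place printed slopes enter is a
noiseless piecewise-linear fixture used to verify that the fitting
machinery recovers known lines exactly.

## Determinism and numerical conventions

One master seed drives the whole study; fixed loop order makes reruns
bit-identical, and sub-seeds used by the acceptance script are small
multiples of the driver seed (kept within 32-bit range). Coordinates are
0-based, row-major, origin top-left; config and outputs use physical units
(µm, µm², µm³, days, hours) with pixels confined to segmentation
internals. Images are rendered un-quantised and rounded to 16-bit counts
at write time, so integer-valued frames round-trip losslessly through
TIFF. Mixture ties are broken by ascending component mean; break-day ties
by the earliest candidate; survival factors above 1 are clamped with a
warning; blank frames segment to an empty foreground with a warning
rather than an error.

## Problem sizes used in the shipped checks

The test-suite and acceptance studies run at reduced scale — 160–256 px
frames with 6–10 seeded cells for rendered-pipeline checks (the default
1024 px geometry is exercised by the population-level statistics, which
do not require rendering), 20 seeds for image-level Monte-Carlo checks and
50 for table-level ones. These sizes were chosen so each check exercises
the full chain at well-conditioned object counts; all distributional
parameters, rates and noise levels are the package defaults throughout.

## Known limitations

* The effective growth coefficient from image morphometry conflates
  proliferation with aggregation; the package reports it without
  attempting the (non-identifiable) decomposition.
* Whether area histograms of real data count merged aggregates as single
  objects is analyst-dependent; this pipeline does, consistently.
* The transfer model is phenomenological: one rate constant, uniform
  nodule painting, no efflux. It reproduces declining-ECM/rising-nodule
  curves and a plateau, not mechanistic transport.
* SER standard errors assume independent replicate dishes; plate- or
  batch-level correlation would require a hierarchical extension.
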