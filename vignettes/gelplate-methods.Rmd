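---
title: "Modelling thin hydrogel films in multiwell plates: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling thin hydrogel films in multiwell plates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gelplate)
```

# The problem

Casting a hydrogel precursor solution into a multiwell plate normally ends
with a meniscus: the liquid wets the sidewalls and the air-liquid interface
curves strongly, which ruins focal planarity for microscopy on the gel
surface. Dispensing a small volume at the well centre and immediately
re-aspirating most of it exploits contact-angle hysteresis: the receding
contact line stays pinned, leaving a thin, nearly flat boundary-layer film
that crosslinks into a gel a few tens of micrometres thick. `gelplate`
models this process quasi-statically and provides the image-analysis
pipelines used to quality-control and characterize the resulting plates.

# The quasi-static interface model

## Governing equation

The air-liquid interface in a cylindrical well is axisymmetric. At
equilibrium its shape obeys the Young-Laplace balance

$$\sigma \, \kappa(z) = \Delta p_0 - \rho g z,$$

where $\kappa$ is twice the mean curvature, $\sigma$ the surface tension,
$\rho$ the density and $\Delta p_0$ the pressure jump at the reference
height. We integrate the arc-length form

$$\frac{d\varphi}{ds} = \kappa_0 + \frac{\rho g}{\sigma} z - \frac{\sin\varphi}{r},
\qquad \frac{dr}{ds} = \cos\varphi, \qquad \frac{dz}{ds} = \sin\varphi,$$

which avoids the $dz/dr$ singularity at steep interface angles. Two
families are solved by shooting (see `solve_cap_profile()` and
`solve_wall_meniscus()`):

* **Pinned sessile cap** — integration starts at the drop apex and stops at
  the prescribed contact radius (or contact angle); the apex curvature is
  found by bisection on the enclosed-volume residual (relative tolerance
  $10^{-4}$, tighter than the 0.1% volume contract). Both the
  sub-hemispherical and the bulged ($\theta > 90^\circ$) branches are
  handled.
* **Wall-wetted meniscus** — integration runs from the axis (zero slope) to
  the wall, shooting on the centre curvature until the interface meets the
  sidewall at the wall contact angle. Because a vertical shift of the shape
  plus a matching shift of $\Delta p_0$ leaves the equation invariant, the
  shape is independent of volume and the vertical offset is fixed
  analytically by the volume; a configuration whose centre would fall below
  the well bottom is reported as infeasible.

At zero gravity the cap family reduces to spherical caps; the closed-form
cap relations (`spherical_cap_oracle()`) serve as an independent reference
and the solver matches them to better than 0.5% over $5^\circ$–$90^\circ$.

## Hysteresis state machine

`simulate_protocol()` steps the volume quasi-statically (default step: 1%
of the largest protocol step; halving the step moves the final flatness by
well under 0.5 percentage points):

* **Dispensing.** While the apparent contact angle is below the advancing
  angle $\theta_a$ the contact line is pinned and the angle grows; at
  $\theta_a$ the line advances at constant angle. If the footprint reaches
  the well radius, the state switches to the wall-wetted regime.
* **Aspirating.** While the apparent angle exceeds the receding angle
  $\theta_r$ the line is pinned and the angle falls; at $\theta_r$ the line
  recedes at constant angle. Aspiration stops at the residual volume.
* **Wall regime.** Dispensing in the wall regime just raises the level.
  When aspiration shrinks the volume below the smallest feasible
  wall-wetted configuration, the state switches to a cap pinned at the well
  radius and the cap rules resume. This is a simplification of the gradual
  de-pinning of the wall contact line; the metrics reported here depend on
  whether wall contact ever happened, not on the fine structure of that
  transition.

## Metrics

* `flatness_metric()` — percentage of the well radius over which the
  interface inclination stays within $3^\circ$ of horizontal (the
  $90^\circ \pm 3^\circ$ rule relative to the vertical dispensing axis).
  The planar length is measured as a radial projection; for near-flat
  regions the difference from arc length is below $\tan^2 3^\circ \approx
  0.3\%$.
* `coverage_metric()` — footprint radius as a percentage of the well
  radius.

## Default parameters and their provenance

| parameter | default | rationale |
|---|---|---|
| well radius $R_w$ | 3.2 mm | conventional 96-well geometry |
| well height | 11 mm | conventional 96-well geometry |
| density $\rho$ | 1000 kg m$^{-3}$ | water-like precursor |
| surface tension $\sigma$ | 0.05 N m$^{-1}$ | gelatin solutions depress water's 0.072 |
| viscosity | 0.05 Pa s | metadata only; a quasi-static model has no flow |
| advancing angle $\theta_a$ | 50$^\circ$ | calibrated, see below |
| receding angle $\theta_r$ | 2$^\circ$ | near-zero, see below |
| wall angle $\theta_w$ | 60$^\circ$ | moderately wetting polystyrene |
| residual film | 30 µm mean over footprint | matches the hydrated gel thickness ceiling; gels crosslink in place at high humidity, so the film thickness carries over |

Two wetting parameters deserve explanation, since contact angles of
protein-rich solutions on plastic are poorly tabulated:

* $\theta_a = 50^\circ$ was fixed by requiring the simulated dispensing
  regime to reproduce the reported volume thresholds in a 96-well plate:
  12 µL must stay clear of the walls even under a +20% volume and
  $-200$ µm radius perturbation, 18 µL must reach the wall only under such
  perturbations, and 24 µL must wet the wall outright. This regime pins
  $\theta_a$ to within a few degrees (45$^\circ$ floods the well at 21.6 µL
  nominal; 55$^\circ$ keeps 24 µL off the wall), and 50$^\circ$ sits in the
  range observed for gelatin solutions on polystyrene.
* $\theta_r = 2^\circ$ encodes the strong pinning that makes the method
  work: adsorbed gelatin nearly eliminates contact-line recession. A simple
  geometric argument fixes the scale: for the line to stay pinned at a
  $\approx 2.5$ mm footprint down to a 30 µm mean film, the receding angle
  must be below $4V/(\pi r_c^3) \approx 2.8^\circ$. Larger values (e.g.
  20$^\circ$) would retract the film to under half the well radius,
  contradicting the observed ~20% coverage reduction.

## What the model does and does not capture

With these defaults the wall-wetting (conventional casting) configuration
covers the well fully with ~13% flatness, and the 12 µL dispense/
re-aspirate protocol ends pinned at ~80% coverage. Both match the reported
behaviour of the fabrication method.

The equilibrium model relaxes every transient feature of the real flow:
pipette-driven dimples, rim curvature left by the moving contact line and
flow-rate effects are all absent. One visible consequence: the residual
30 µm film's edge angle ($\approx 2.8^\circ$) falls just inside the
$3^\circ$ planarity tolerance, so the equilibrium film is planar over
essentially its entire footprint and the predicted flatness improvement
over the meniscus (~6x) is an upper bound; dynamic simulations that retain
rim curvature yield smaller improvements (~4.5x). The robustness-sweep
conclusions (which volumes risk wall wetting) are insensitive to this,
because they depend on the advancing phase only.

# Synthetic data: what the generators emulate

All generators are seeded and bit-reproducible; every pipeline in the
package can therefore be tested against exact ground truth without any
external data.

* `generate_well_phantom()` renders a two-channel QC z-stack: a thick
  bright wall ring (plate walls span many pixels at 4x-style
  magnification) and a gel volume speckled with beads placed by a Poisson
  point process, blurred with a per-slice Gaussian PSF ($\sigma = 1.2$ px)
  and degraded with Poisson-then-Gaussian noise. Shape classes: planar
  slab, concave slab (central sag), wall-touching meniscus, empty. The
  default bead density ($1.2\times 10^{-4}$ µm$^{-3}$) makes planar
  projections near-saturated — the regime the "mean gray $\geq 250$"
  shape rule presupposes — while a concave well's thin centre shows bead
  gaps. No 3D PSF is modelled: QC works on maximum-intensity projections,
  so axial blur fidelity is not needed.
* `generate_confluency_movie()` renders logistic growth,
  $C_{t+1} = C_t + r\,C_t(1-C_t)$ with
  $r(d) = r_0 / (1 + (d/\mathrm{IC}_{50})^{h})$, as textured disks placed
  cumulatively until the rendered covered fraction matches the true one
  within one area-percent. Defaults ($C_0 = 0.03$, $r_0 = 0.04$ per hourly
  frame, 49 frames) emulate a sparsely seeded 48 h drug-response run whose
  vehicle endpoint (~25%) stays inside the regime where threshold-based
  segmentation is reliable (see below).
* `generate_fucci_timelapse()` runs each nucleus through the cycle state
  machine EG1 → G1 → S/G2 → T → M → division, with cyan high in G1,
  magenta high in S/G2/M, both high in T, both low in EG1, and nuclear
  tubulin elevated 1.6x over the cytoplasm in M. Optional features:
  M-arrested cells (drug-like), fragmented nuclei (area < 0.5x the mean)
  and linear cyan-to-green bleed-through. Note that EG1 nuclei are dark in
  both reporter channels by construction, so they are invisible to any
  segmenter working on those channels — classification accuracy is
  assessed on ground-truth labels, and the default segmenter is expected
  to miss EG1 cells.
* `generate_dry_height_map()` revolves a radial gel profile and adds a
  quadratic instrument background plus noise, emulating dry-state
  profilometry with spherical aberration and substrate curvature.

None of the generators attempt training-grade realism (no holographic
speckle, no optical-path modelling); they are designed so that the
*decision rules* of each pipeline face exactly the contrasts they key on.

# Image-analysis pipelines

## Plate QC

`classify_well()` reproduces a plate-QC macro chain: per-channel maximum
projections, recentring on the wall-ring centroid, gamma 0.5, triangle
threshold (wall) / isodata threshold (gel), opening and closing with a
2 px disk, hole filling, bright-outlier removal (radius 10 px; a pixel
deviating above its local median is replaced by it, which strips specks
without eroding the ring), then a logical AND of gel and wall masks for
wall contact and a secondary gamma-2 analysis for the planar/concave call.
Design readings worth noting:

* "mean gray value $\geq 250$" is interpreted on the binarized (0/255)
  gamma-2 projection within the gel footprint, i.e. a fill fraction of
  $\geq 98\%$ — the only reading under which 250 is attainable.
* Wall contact requires an overlap above 5 px by default so a single noise
  pixel cannot flag a well; the bare AND rule is `min_overlap = 0`.
* Both threshold algorithms are implemented from their definitions
  (triangle: maximal distance from the peak-to-tail chord; isodata:
  intermeans fixed point) and are verified against brute-force searches in
  the tests.

On noise-free phantoms classification is exact; on a 100-well plate at
default noise (91/6/3 planar/bad/concave) accuracy exceeds 95%.

## Gel profiles

`extract_height_map()` thresholds the whole z-stack with Otsu's method
(global histogram, avoiding slice-wise threshold drift; a per-slice mode
exists), closes each slice with a 2 px disk and takes per-column heights as
(last $-$ first detected slice) x z-step. A column with signal in one
slice reports zero by this convention; `inclusive = TRUE` adds one step.
Because bead extent underestimates the true gel boundary by roughly the
mean gap to the first/last bead, recovered medians sit within one z-step
below the nominal height, which is the stated accuracy of the method.
`detrend_dry_map()` removes a least-squares quadratic surface fitted to
bare-substrate pixels and is idempotent to $10^{-9}$.

## Confluency and dose response

`segment_cells_phase()` chains non-local-means denoising (noise SD
auto-estimated by the Immerkaer pseudo-residual; patch 7 px, search 21 px;
implemented with per-offset integral images and symmetric offset pairing),
triangle threshold, opening/closing and hole filling. Above ~30%
confluency the background becomes enclosed and hole filling over-reports
coverage; such frames are flagged `review` rather than corrected, matching
the manual-adjustment caveat of the original workflow.

For dose-response experiments the package deliberately fits growth *rates*
rather than endpoint ratios. The endpoint ratio of a rate-suppressed
logistic is not log-logistic in dose: in the exponential regime the
apparent IC$_{50}$ of an endpoint fit is biased low by ~30%, and the bias
only cancels under saturation levels where thresholding is unreliable. For
logistic growth, however, $\mathrm{logit}(C_T) - \mathrm{logit}(C_0) = rT$
exactly, so `logistic_rate()` recovers $r$ from the two endpoint
measurements and the Hill suppression of $r$ is exactly a four-parameter
log-logistic in dose. `run_ic50_experiment()` uses this readout; across
seeded experiments (6 doses, 12 replicates) the median IC$_{50}$ error is
a few percent. `fit_dose_response()` itself is readout-agnostic
(Levenberg-Marquardt 4PL with a seeded residual bootstrap for the CI; dose
zero is mapped half a decade below the lowest nonzero dose).

## Cell-cycle scoring and tracking

`classify_nuclei()` subtracts the image background (median outside all
nuclei) from per-nucleus mean cyan/magenta and applies the four-way rule;
default thresholds are 6x the MAD of the background pixels, so
classification is invariant to adding a constant to all channels.
`detect_mitotic()` corrects tubulin for cyan bleed-through (linear
coefficient, matching the generator's model), estimates the background
from a 5 px cytoplasmic annulus and calls mitosis when the *relative*
excess reaches 0.2 (plastic) or 0.4 (hydrogel — doubled for gel
autofluorescence); an absolute-excess mode is available.
`fragmentation_filter()` applies the literal area rule (strictly below the
control mean, fraction configurable) — note that applied to an untreated
population the literal rule would discard roughly half the cells, so it is
meant for treated conditions. `link_tracks()` is a deterministic greedy
nearest-neighbour linker (50 µm max distance, 3-frame gap closing, ties
broken by label id); it deliberately does not implement intensity
penalties or division linking — tracks terminate at division.

# Numerical choices and problem sizes

* Volume-residual bisections: relative tolerance $10^{-3}$ along protocol
  trajectories, $10^{-4}$ for final profiles; radial grids have > 400
  points.
* Adaptive arc-length steps bound the inclination change per RK4 step to
  0.004 rad.
* Test and demonstration workloads use 96-128 px frames, 100-well plates,
  and 12-replicate dose series — sizes chosen so the full suite exercises
  every pipeline end to end in a few minutes on one core while keeping
  every statistical margin (classification accuracy, IC$_{50}$ recovery)
  comfortably away from its threshold.
* TIFF round trips store 32-bit float pages normalized to [0, 1] with the
  intensity scale and axis metadata in a JSON sidecar; reconstruction is
  exact to float precision ($<10^{-6}$ relative).

# Known limitations

* The solver is quasi-static: flow-rate effects, pipette-interior wetting
  and transient interface shapes are out of scope, and the predicted
  flatness of the residual film is an upper bound (see above).
* Wall de-pinning during aspiration is simplified to a regime switch at
  the infeasibility boundary of the wall-wetted configuration.
* The default nucleus segmenter cannot see EG1 nuclei (dark in both FUCCI
  channels) and splits touching nuclei only via a distance-map watershed;
  the segmentation interface is pluggable for anything stronger.
* Confluency measurements above ~30% are flagged, not fixed; quantitative
  use of flagged frames is the caller's responsibility.
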