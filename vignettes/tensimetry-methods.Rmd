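---
title: "Quantifying nuclear membrane tension proxies from confocal stacks"
author: "tensimetry authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nuclear membrane tension proxies from confocal stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tensimetry)
```

## The measurement problem

Inner nuclear membrane (INM) tension cannot be measured directly in live
cells. What can be measured is the adsorption of amphipathic
lipid-packing-sensor proteins — cytosolic phospholipase A2 (cPLA2) and
ALPS-motif biosensors targeted to the nucleus (ALPIN) — to the nuclear rim:
when the INM is stretched, lipid-packing defects open and these sensors
enrich at the rim relative to the nucleoplasm. `tensimetry` implements the
image-analysis pipeline around this proxy: 3D nuclear segmentation and
tracking, the ratiometric rim-adsorption signal S, nuclear-envelope fold
counting, ER vesiculation morphometrics, equilibrium GUV binding isotherms,
FLIP connectivity traces, and the statistical battery that compares
conditions. A synthetic-microscopy generator with exact ground truth backs
every stage, because the original raw data (tens of terabytes of
proprietary-format stacks) are not publicly deposited.

Nothing in the package claims to output tension itself; S is a proxy, and
all downstream statements are about S.

## The ratiometric signal S

For each tracked nucleus, the z plane with the largest segmented area is
the representative mid-section. Two 3-pixel-wide contours are placed on it:
a *membrane contour* centred on the segmentation boundary (one pixel
inside, the boundary, one pixel outside) and a *background contour*, a ring
around the 2-D centroid at 20% of the equivalent radius — comfortably
inside the nucleoplasm for any convex nucleus (the background contour is
conventionally placed at the nuclear centre without a stated geometry; the
ring radius is exposed as `centre_ring_fraction`). Then

$$S = \frac{\mathrm{median}\,I_{\mathrm{sensor}}(\text{membrane contour})}
           {\mathrm{median}\,I_{\mathrm{sensor}}(\text{background contour})}.$$

Medians make S robust to shot noise and stray bright pixels, and the ratio
makes it invariant under global intensity scaling (laser power, detector
gain). A caveat inherited from the assay: S can rise because the
nucleoplasmic signal falls rather than because rim binding rises. The
alternative ratio `S_alt` divides the same rim median by the NE-marker
(lamin B1) median over the whole mid-section, which is constant over the
experiment, and is reported alongside S.

## Segmentation, tracking and QC

Nuclei are segmented by masked-object thresholding: a global Otsu threshold
yields coarse foreground components; within each component a second,
stricter Otsu split re-segments the bright object — the NE shell when a
lamin marker is used, the nucleoplasmic body when the sensor itself is the
only marker — holes are closed slice-wise, and the local objects seed a
3-D marker-controlled watershed (priority flooding over the smoothed
intensity, 26-connected, constrained to the refined mask). Marker fragments
whose centroids fall within 10 px are merged first, so a shell whose top
and bottom caps exceed the local threshold separately still yields one
nucleus, while two touching nuclei with distinct bright cores still split.

Preprocessing follows the published recipe: percentile-clipped (0.5/99.5)
min–max normalization (intensity normalization is otherwise underspecified;
clipping keeps hot pixels from compressing the usable range), a 3-D Gaussian blur of 1-px radius, and per-slice
rolling-ball background subtraction. The rolling-ball background is a
grayscale opening with a flat 2r+1 square structuring element (default
r = 50 px, unstated in the original and therefore configurable): on a
monotone background gradient the opening reproduces the gradient exactly
while plateaus narrower than the window are excluded, which is the
behaviour the correction needs.

Tracking is greedy mutual-nearest-neighbour linking of 3-D centroids with a
maximum link distance (130 px default). No gap closing is attempted,
because the published QC discards broken tracks anyway. QC raises flags for
mid-slice area below 8,000 px², lateral border contact, frame-to-frame
displacement above 130 px, broken tracks, and degenerate background
contours (nucleoplasmic marker leakage); a track is retained only if no
flag is ever raised, and every exclusion is reported with its reasons. The
size test uses mid-slice area: the published threshold is quoted in px²
with a ~140 µm² equivalent, which matches a single-plane area at the
instrument's pixel sizes, and the mid-slice is the plane all other 2-D
measurements use.

## Fold counting

Nuclear-envelope shrivelling is scored on the NE mid-slice as the number of
condensed skeleton branch points. The outline mask comes from a
single-scale Hessian ridge filter at scale 1.6 (≈3–4 px membranes): the
response is the magnitude of the negative leading eigenvalue, thresholded
automatically. We use an Otsu cut plus hysteresis (response above 40% of
the cut is kept when connected to a super-threshold ridge), then a 3×3
closing. The hysteresis matters: where a fold meets the envelope the
intensity forms a plate rather than a ridge, the ridge response dips, and a
single global cut disconnects exactly the junctions being counted. On
ring-plus-spur phantoms a plain global cut loses ~8% of junctions; with
hysteresis the condensed count equals the rendered spur count for k = 0…8
across all tested seeds, and the result is insensitive to the low fraction
over 0.3–0.5.

The mask is thinned (Zhang–Suen) and then minimized by sequential
simple-point removal, which deletes the staircase corner pixels thinning
leaves behind without changing topology. On the minimal skeleton, curve
pixels have exactly two 8-neighbours, so branch points — pixels with at
least `branch_neighbour_threshold` skeleton neighbours — mark genuine
junctions. Branch points are sometimes defined as pixels with more than
three neighbours, but a clean Y junction pixel has exactly three; the
default is therefore ≥ 3, with the stricter ≥ 4 selectable in the
configuration. Raw branch
points are condensed by single-linkage clustering at 4 px (about the filter
thickness; unstated in the original) and the cluster count is the fold
metric. Condensation merges the short chains of adjacent junction pixels
that noise produces, and the count is non-increasing in the condensation
radius by construction.

## ER morphology

The ER is segmented from the luminal channel (KDEL) by coarse Otsu
threshold plus marker-controlled watershed — markers are local maxima of a
further-smoothed channel (σ = 2), merged by single-linkage at 5 px so a
tube's ridge of plateau maxima seeds one basin while well-separated
vesicles seed their own — or from the membrane channel (SEC61B) by the same
ridge filter used for the lamina at thickness 1.6 followed by
connected-component labelling. All components are 26-connected in 3-D.

Metrics are 2-D, on the z slice with the largest total segmented area: area
as pixel count, perimeter with the Crofton 4-direction estimator, and
$\mathrm{Cir} = 4\pi A / P^2$. Crofton is used instead of chain-length
perimeters because pixel-counting biases Cir above 1 for small disks; with
Crofton a rasterized r = 50 px circle measures within [0.95, 1.05], and
values are clipped at 1.05. Objects below 40 px² are dropped (the
documented cutoff range is 30–50 px²; 40 is the midpoint and
configurable). Per FOV and
frame, the summary is the largest object area and the unweighted mean
circularity — deliberately FOV-level, since neighbouring cells' ER cannot
be separated without a plasma-membrane label. The "largest area" is the
2-D mid-section area rather than a 3-D voxel area: full 3-D ER metrics are
explicitly treated as unreliable at confocal anisotropy, which is why the
mid-section workaround exists.

Normalization `to_t0` divides each frame by its FOV's frame-0 value, so
baseline is exactly 1 and vesiculation shows as circularity rising toward
2; `to_control` divides by the mean of an isosmotic (or Ca²⁺-free,
osmotically balanced) control. The two schemes produce incomparable ranges
and are recorded in the output metadata.

## GUV equilibrium binding

A GUV is cropped by a user line from its centre to its edge; the crop is a
square of side 2.4× the line length (the factor is a package choice — it
guarantees margin around the rim for any orientation). After normalization
and a 3-px 3-D blur of the membrane-dye channel, each slice is segmented by
a marker-controlled watershed whose seeds are the crop centre (the line
origin is the GUV centre by construction of the assay) and the crop border;
flooding the intensity landscape places the region boundary on the rim
crest, so the 3-px boundary-centred contour straddles the rim. The rim
binding is the median protein intensity along that contour on the
largest-area slice, normalized by the fluorescence of a 1 µM protein
solution.

Titration series are fitted with the Hill-expanded Langmuir isotherm

$$B_{\mathrm{bound}}(c) = B_{\max}\frac{c^{H}}{c^{H} + K_d'^{\,H}}$$

by bounded nonlinear least squares on the per-GUV measurements
(unweighted; the source fits pooled per-GUV values without stating
weights). Initialization uses the maximum per-concentration mean for
\(B_{\max}\), the interpolated half-maximum concentration for \(K_d'\) and
H = 1; H is bounded to [0.5, 4] to keep the fit identifiable on
eight-point titrations. 95% CIs come from the parameter covariance. The
packaged presets `alps-hypotonic` (\(K_d' = 150\) nM) and `c2-ca20`
(\(K_d' = 20\) nM at 20 µM Ca²⁺) carry the eight published concentrations
(0–500 nM) and the published per-concentration replicate counts, and are
the generating truths for all recovery tests.

## FLIP connectivity

Fluorescence loss in photobleaching scores diffusional continuity between
the ER and the nuclear envelope: a 2.5-µm-radius spot is bleached
repeatedly and fixed 5-µm ROIs are read out — ROI 1 at the bleach site,
ROI 2 on the median axis (implemented as the midpoint between bleach
centre and nucleus centroid; the published wording is ambiguous and the
offset is configurable), ROI 3 diametrically opposite across the nucleus
centroid, plus a non-bleached neighbouring cell as control and a nuclear
trace from an Otsu mask. Traces are ROI means (the published statistic is
unstated; median is available), normalized to frame 0. The synthetic
two-pool model bleaches one pool and exchanges a fraction r per cycle, so
under continuous bleaching the measured pool decays as \((1-r)^k\) when
connected and stays at baseline when not; a threshold of 0.5 on the final
opposite-site value separates the classes with no errors in the packaged
tests.

## Gated statistics

Two groups: Shapiro–Wilk on both (α = 0.05, configurable — the source
states α only for significance, not for gating); if both pass, Levene
(median-centred) routes to Student's or Welch's t test, otherwise
Mann–Whitney U; all two-tailed, and the gate trace is returned so the
choice is reproducible. Three or more groups: Welch's ANOVA with
Games–Howell post hoc under normality, else Kruskal–Wallis with Dunn's
test (unadjusted by default, matching the source's silence on correction;
Bonferroni/Holm selectable). Games–Howell and Dunn are implemented from
their closed forms and verified against an independent reference
implementation in the tests. Adsorption rates are OLS slopes of S versus
time on the linear window t = 4–5 min, pooled across cells (the published
fits are on the pooled linear portion; per-cell series can be passed
individually), with Breusch–Pagan, residual Shapiro–Wilk and Durbin–Watson
diagnostics and HC3 robust standard errors whenever either of the first
two is significant at 0.05. With exactly two time points the
linearity/multicollinearity checks are skipped as inapplicable.

## The synthetic generator, and what it does not emulate

The generator renders ellipsoidal nuclei with bright NE shells (default
rim width 3 px, matching the ~3–4 px apparent membrane thickness at the
instruments' pixel sizes), sensor channels whose rim:nucleoplasm ratio is
the ground-truth ρ, inward capsule-shaped fold spurs of 6–15 px that
produce exactly one junction each, frame-to-frame drift and volume
schedules, lysis events (nuclear lysis-dye influx, cytoplasmic sensor
decay), ER as random-walk tube networks that convert into disjoint
spheres as the vesiculation fraction φ rises — nested across φ so the
ground-truth largest area is non-increasing and mean circularity
non-decreasing by construction — spherical GUV shells whose rim intensity
follows the isotherm, and two-pool FLIP dynamics. Noise is Poisson shot
noise on the scaled signal, additive Gaussian read noise and a planar
background gradient (parameters are package choices; the source reports
none), which exercises exactly the robustness mechanisms in the pipeline:
rolling-ball correction, percentile clipping and median contours.

Passing recovery tests on these scenes shows the *computational* pipeline
is correct and calibrated; it does not show robustness to everything real
data contain — out-of-focus haze, anisotropic PSFs beyond Gaussian blur,
chromatic offsets, photobleaching outside FLIP, or segmentation-adjacent
biology such as apoptotic blebbing. Those limitations are inherited from
any synthetic benchmark and are the reason the QC report exists.

## Numerical choices and problem sizes

Degenerate inputs are defined rather than left to chance: blank frames
segment to zero labels; an all-zero channel is a validation error; a zero
background-contour median flags the frame and leaves S undefined; an
all-zero titration returns a non-converged fit rather than crashing; ties
in mid-slice selection go to the lower index. Thresholds are computed on
256-bin histograms. The test-suite and acceptance scenes use fields of view
of 80–360 px laterally and 9–16 planes, 20-seed replication for stochastic
recoveries, 2,000 simulations for the type-I calibration of the gate, and
the full published replicate counts (n = 14–89 per concentration) for the
isotherm recoveries; these sizes were chosen so that every documented
tolerance is met with margin while the whole suite runs in minutes on one
CPU.
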