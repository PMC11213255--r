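---
title: "Measuring leaf hyponasty kinetics from side-view time-lapse imagery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring leaf hyponasty kinetics from side-view time-lapse imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leaflapse)
```

## The measurement problem

Rosette plants such as Arabidopsis respond to vegetation shade cues — a low
red : far-red photon ratio perceived by phytochrome B — with the shade
avoidance syndrome: petiole elongation and hyponasty, the upward movement of
leaves. These movements unfold over hours, are superimposed on an endogenous
diurnal rhythm, and involve the petiole and the lamina (leaf blade) as
partially independent organs hinged at the petiole–lamina junction.
Quantifying them requires imaging one leaf from the side for one or more
photoperiods, day and night, at a cadence of about a frame per minute, and
reducing each frame to a handful of angles and lengths.

`leaflapse` implements the full analysis chain for such experiments:

1. **frame I/O** — ordering frames by filename timestamp, cropping,
   day/night classification;
2. **landmark tracking** — following the petiole–lamina junction and the
   leaf tip from a single first-frame annotation, with the rosette center
   interpolated between its first- and last-frame annotations;
3. **geometry** — converting pixel trajectories to petiole, lamina, leaf
   and junction angles (degrees above horizontal) and lengths (mm), via a
   scale segment of known physical length;
4. **kinetics** — baseline-relative series, day/night time synchronization
   across plants, windowed angular speed, 2-h binning;
5. **statistics** — per-bin ANOVA, Tukey pairwise tests and compact letter
   displays;
6. **a synthetic leaf-movie generator** that renders a moving, elongating
   leaf with exact ground truth, so every stage above is testable without
   any real imagery.

## The synthetic generator and what it emulates

No public image sequences accompany this class of experiment, so the
package ships its own generator ([sim_scenario()], [render_sequence()]). It
emulates the imaging regime the pipeline targets: short days (9 h light,
15 h dark), one frame per minute for 24 h, treatment onset at Zeitgeber
time (ZT) 2, a focal leaf whose petiole starts near 5 mm (the 4.5–5.5 mm
selection window typical for such experiments), plants photographed in RGB
against a uniform blue background by day and with near-infrared
illumination at night — rendered here as an exactly achromatic
bright-on-dark frame, since an IR camera yields one intensity signal
replicated over R, G and B.

The motion model is deliberately minimal — a kinematic stand-in with the
qualitative shape of the real responses, not a biophysical model:

$$\theta_p(t) = \theta_0 + A_d \sin\!\big(2\pi\,zt/24\big)
  + d\,H\,\sigma(t) + d\,A_{osc}\sin\!\big(2\pi (t-t_{off})/T_{osc}\big)\,g(t)$$

with $\sigma(t) = 1/(1+e^{-k(t-t_{on})})$ a logistic ramp for the
far-red-induced rise (dose $d \in [0,1]$, amplitude $H$, default 15° for
the petiole and 9° for the lamina), $A_d$ a shared diurnal amplitude
(default 5°), and a night-gated oscillation ($g(t)$ switches on at the
first lights-off $t_{off}$) standing in for the rapid angular adjustments
far-red-treated plants show at night. The oscillation's phase is anchored
at lights-off so the term turns on continuously at a zero crossing; an
un-anchored phase would inject a discontinuous jump of several pixels in a
single frame, which no real leaf produces and which would break the
generator's own smoothness guarantee (landmark displacement stays below
3 px/frame for all default scenarios — the regime the tracker is designed
for). The oscillation period and amplitude (90 min, 3°) are placeholders:
the real phenomenon has not been characterized numerically, and nothing
downstream depends on their values.

Petiole length grows linearly at `elong_rate_mm_per_h` scaled by
`1 + dose * (elong_fr_multiplier - 1)`; lamina length always grows at the
white-light rate, reflecting the observation that far-red promotes petiole
but not lamina elongation. Ground truth is kept at full floating-point
precision and rounded only at rasterization, so tests can separate tracker
error from quantization.

What the generator does *not* emulate — and therefore what passing tests do
not certify about real data: petiole/lamina curvature (both are rendered
straight: a line segment and an ellipse), occlusion by neighbouring
leaves, specular highlights, camera shake, defocus, and any appearance
change other than growth, rotation and the day/night switch. Real
deployments should expect somewhat worse tracking accuracy than the
synthetic benchmarks and should watch the per-frame confidence values.

## Tracking: an adaptive-template correlation localizer

The reference workflow for this kind of experiment uses an off-the-shelf
discriminative correlation filter tracker (CSRT) on a 40 × 60 px bounding
box around each user-annotated point. `leaflapse` keeps the behavioral
contract — appearance-based localization within a bounded search window,
adaptive appearance model, per-frame confidence — but implements it as an
adaptive-template normalized cross-correlation (NCC) localizer, which is
self-contained, deterministic, and checkable against an exhaustive-search
oracle:

* **Matching.** The stored template slides over a ±20 px search window
  (motion in the targeted regime is under 3 px/frame); the match is the
  peak of |NCC|, refined to sub-pixel precision by a 1-D quadratic fit in
  each axis. Using the absolute correlation makes the localizer immune to
  the global contrast inversion at the day→night switch (dark leaf on
  bright blue channel → bright leaf on dark IR frame).
* **Rotation handling.** A petiole or lamina rotates as the leaf moves.
  Matching a purely translated template against a rotated shape biases the
  estimate tangentially — on the synthetic benchmark this bias alone
  reaches ~2 px at the leaf tip. The tracker therefore keeps its template
  in a canonical orientation (padded so rotated crops stay inside) and each
  step also evaluates the template rotated one step (default 1°) either
  way, accumulating an orientation estimate. A small hysteresis margin
  (`rot_margin`, default 0.002 correlation units) is required before the
  orientation moves, because near-rotation-symmetric patches would
  otherwise random-walk their orientation.
* **Adaptation.** After a confident match the canonical template is
  blended with the newly matched patch (learning rate 0.05), resampled
  bilinearly at the refined sub-pixel position and derotated — so the
  template stays registered to the reference point and does not drift.
  A second small blend (`anchor_rate`, 0.03) pulls the template toward the
  appearance captured at the annotation, bounding long-run drift without
  blocking adaptation to growth or the illumination switch.
* **Failure handling.** Matches below `min_confidence` (0.2) or jumps
  beyond `max_jump_px` (15) flag the frame; the estimate and template
  freeze and tracking continues. More than `max_lost_fraction` (10%)
  flagged frames aborts the run with advice to re-annotate. Flagged frames
  propagate as missing values through the geometry layer and are never
  interpolated there.

The rosette center is not tracked: it is interpolated linearly in frame
index between its first- and last-frame annotations. This is the simplest
defensible model for a slowly drifting rosette and it is worth knowing
that it is an interpolation, not a measurement.

On day frames tracking runs on the single RGB channel with the highest
contrast inside the initial box (chosen once at initialization); night
frames are achromatic, so the choice is immaterial there.

## Geometry and conventions

Image coordinates are 0-based, origin top-left, y down — the convention of
every raster format. All angles are converted to the y-up botanical
convention in one place ([segment_angle()]): positive angles point upward,
matching the presentation of hyponasty as an angle increase. Angles are
signed and unclamped; published panels that clamp at zero may differ for
leaves that dip below horizontal.

Per frame: petiole angle/length from (center, junction), lamina from
(junction, tip), whole leaf from (center, tip). Derived quantities: the
junction angle is the signed difference lamina − petiole (negative for a
downward-kinked lamina); leaf-tip elevation is the vertical tip position
above the rosette center; projected lamina length is the absolute
horizontal junction→tip extent (absolute, so it stays a length for leaves
pointing either way). Calibration divides a known physical length by the
pixel length of an annotated scale segment; the simulator renders its own
scale bar and recovers its `mm_per_px` to machine precision.

## Kinetics

Relative series subtract, per metric and plant, the mean of the first five
*valid* frames — skipping flagged frames rather than failing, with the
count configurable. Plants are time-synchronized on their first
day→night transition (assigned ZT = 9 by default): treatments start in the
light phase, so that transition is the nearest anchor shared by all
plants, and the shift is a pure translation (no resampling). The synced ZT
axis is continuous (not wrapped at 24 h). Angular speed over a window
(default 60 min) is a backward difference, not a regression slope — the
simplest reading of "speed over 60-min periods"; it is identical on
absolute and relative series since baselines cancel in differences.
Binning uses left-closed 2-h bins anchored at ZT 0, so bin boundaries are
reproducible regardless of treatment start; bins with fewer than 10 valid
frames per plant are marked unreliable.

## Statistics

The sampling unit is the per-plant bin mean. Per metric and bin:
one-way ANOVA on the grouping factor (`stats::aov`), or a two-way model
with interaction tested by Type II sums of squares (`car::Anova`) when a
second factor (e.g. genotype) is present — Type II being the conventional
default for the unbalanced group sizes these experiments produce. Pairwise
comparisons use Tukey's studentized-range adjustment; at k = 2 the Tukey
p-value collapses to the pooled t-test (verified numerically in the test
suite). Letters come from an insert-and-absorb compact letter display:
groups ordered by descending mean (so "a" labels the highest group),
columns split on each significant pair and absorbed when contained in
another. The construction guarantees that two groups share a letter
exactly when their adjusted p ≥ α; the test suite checks this against a
brute-force clique oracle over random significance structures. Each bin is
tested independently with no multiplicity correction across bins — this
mirrors how such kinetics panels are conventionally annotated, and it is a
known caveat: isolated significant bins should be read with care.

## Numerical and design choices

* Tracker sub-pixel refinement clamps the parabola offset to ±0.5 px and
  falls back to the integer peak when the quadratic is degenerate.
* NCC returns 0 (not NaN) for zero-variance patches; placements that
  would leave the image are excluded from the search.
* The day/night classifier thresholds the mean per-pixel channel spread at
  `gray_tol` = 8 gray levels; at the default noise levels (σ ≤ 5) the two
  classes are separated by two orders of magnitude, and the classifier
  agrees with ground truth on 100% of benchmark frames.
* Ties in the letter ordering are broken by input order; ties in the
  correlation argmax by the first (row-major) position.
* Problem sizes: the tracking benchmark uses 720-min scenarios sampled
  every 3 min — 240 frames that span the lights-off transition at ZT 9.
  At a 1-min cadence starting at ZT 2 a 240-frame sequence would end at
  ZT 6 and never see the night, so the benchmark widens the frame interval
  rather than shortening the photoperiod. Landmark motion stays well
  within the tracker's design envelope at either cadence.
* Determinism: all simulator randomness flows from `rng_seed`; identical
  scenarios produce byte-identical frames, ground truth, and downstream
  CSVs. Tracking and statistics contain no randomness.

## A worked example

```{r example, eval = FALSE}
library(leaflapse)

# render two treatment groups of synthetic plants, three replicates each
runs <- list()
for (tre in c("WL", "FRw")) {
  for (i in 1:3) {
    sc <- benchmark_scenario(tre, rng_seed = 100 + i)
    dir <- file.path(tempdir(), sprintf("%s_%d", tre, i))
    render_sequence(sc, dir)
    seqs <- load_sequence(dir)
    ann <- read_annotation(file.path(dir, "annotation.yaml"))
    track <- track_sequence(seqs, ann)
    cal <- calibrate(ann$scale_p1, ann$scale_p2, ann$scale_len_mm)
    m <- compute_metrics(track, cal, start_zt_h = sc$start_zt_h)
    rel <- relative_series(m)
    rel$plant_id <- sprintf("%s_%d", tre, i)
    rel$treatment <- tre
    rel$illumination <- m$illumination
    runs[[length(runs) + 1]] <- rel
  }
}
series <- dplyr::bind_rows(runs) |> sync_by_transition()

plot_kinetics(series, "petiole_angle_deg")
bs <- binned_stats(bin_series(series))
tidy(bs)
autoplot(bs, metric = "petiole_angle_deg")
```

## Known limitations

Straight-segment geometry (no curvature; adding intermediate spine points
would be the natural extension); one leaf per image; translation+rotation
appearance model (no scale search — growth is handled by template
adaptation); linear center interpolation; no re-detection after long
occlusions; per-bin statistics without cross-bin multiplicity control; and
the synthetic benchmark's idealizations listed above.
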