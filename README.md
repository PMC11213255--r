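# leaflapse

Leaf hyponasty kinematics from side-view time-lapse imagery.

Rosette plants answer vegetation-shade cues (a low red : far-red ratio) with
the shade avoidance syndrome: petioles elongate and leaves move upward
(hyponasty), with the petiole and the lamina acting as partly independent
organs hinged at the petiole–lamina junction. `leaflapse` is for plant
biologists who film one leaf from the side — about a frame per minute,
through day and night — and need those films reduced to quantitative,
statistically annotated kinetics.

From a directory of frames and a single annotation (rosette center in the
first and last frame, junction and tip in the first frame, plus a scale
segment of known length), the package:

* orders and crops frames, and classifies each as day or night from its
  RGB channel spread (night IR frames are achromatic);
* tracks the junction and tip through all frames with an adaptive-template
  normalized cross-correlation localizer (40 × 60 px appearance box,
  ±20 px search window, |NCC| matching so the day→night contrast inversion
  is harmless, in-plane rotation search, sub-pixel quadratic refinement,
  per-frame confidence); the rosette center is interpolated between its
  two annotations;
* converts pixel trajectories to the metric set
  $\theta_{petiole}, \theta_{lamina}, \theta_{leaf}$ (degrees above
  horizontal), the junction angle
  $\theta_{junction} = \theta_{lamina} - \theta_{petiole}$, lengths
  $L_{petiole}, L_{lamina}, L_{leaf}$ (mm), leaf-tip elevation and
  projected lamina length;
* derives kinetics: per-plant baselines (mean of the first 5 frames
  subtracted), day–night time synchronization across plants, angular
  speed over 60-min windows, 2-h binning;
* computes per-bin statistics: one-/two-way ANOVA, Tukey post-hoc tests,
  and compact-letter displays (groups share a letter iff not significantly
  different at α = 0.05).

A built-in synthetic movie generator (`sim_scenario()`,
`render_sequence()`) renders a moving, elongating leaf over a 9 h light /
15 h dark photoperiod with exact ground truth, so the whole pipeline is
testable end to end without real imagery.

## Worked example

Two synthetic treatment groups — white-light control (WL) and whole-plant
supplemental far-red (FRw) — three replicate plants each, tracked,
quantified and tested per 2-h bin:

```r
library(leaflapse)
library(dplyr)

runs <- list()
for (tre in c("WL", "FRw")) {
  for (i in 1:3) {
    sc <- benchmark_scenario(tre, rng_seed = 100 + i)   # 240 frames, day+night
    dir <- file.path(tempdir(), sprintf("%s_%d", tre, i))
    render_sequence(sc, dir)
    seqs  <- load_sequence(dir)
    ann   <- read_annotation(file.path(dir, "annotation.yaml"))
    track <- track_sequence(seqs, ann)
    cal   <- calibrate(ann$scale_p1, ann$scale_p2, ann$scale_len_mm)
    m     <- compute_metrics(track, cal, start_zt_h = sc$start_zt_h)
    rel   <- relative_series(m)
    rel$plant_id  <- sprintf("%s_%d", tre, i)
    rel$treatment <- tre
    rel$illumination <- m$illumination
    runs[[length(runs) + 1]] <- rel
  }
}
series <- bind_rows(runs) |> sync_by_transition()

bs <- binned_stats(bin_series(series))
tidy(bs) |> filter(metric == "petiole_angle_deg")
```

```
              metric bin_start_zt_h group   mean      sem n letter
1  petiole_angle_deg              2   FRw  1.008 0.002930 3      a
2  petiole_angle_deg              2    WL  0.840 0.000392 3      b
3  petiole_angle_deg              4   FRw  3.462 0.001439 3      a
4  petiole_angle_deg              4    WL  2.213 0.002847 3      b
5  petiole_angle_deg              6   FRw  9.178 0.001514 3      a
6  petiole_angle_deg              6    WL  2.163 0.002136 3      b
7  petiole_angle_deg              8   FRw 14.296 0.001091 3      a
8  petiole_angle_deg              8    WL  0.914 0.001176 3      b
...
```

Reading the output: `mean` is the group mean of per-plant bin means of the
baseline-relative petiole angle (degrees; ~0 in the first bin by
construction), `sem` its standard error over plants, and the letters mark
Tukey-separated groups within each bin — here the far-red-driven rise
separates FRw from WL in every bin, approaching the simulated 15°
hyponastic amplitude by ZT 8 while the control follows only its diurnal
rhythm. `plot_kinetics(series, "petiole_angle_deg")` draws the mean ± SEM
ribbons with night shading, and `autoplot(bs, ...)` the per-bin letters.

The same chain is scriptable from a shell via the bundled CLI
(`exec/leaflapse`): `simulate`, `track`, `quantify`, `stats`, or `all` —
each writes its outputs plus a resolved-config YAML for provenance.

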