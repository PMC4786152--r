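# cohortviz

Animated, specification-driven visualization of HIV cohort data stored as
HICDEP-style flat tables.

Multi-site HIV cohorts exchange data as a small set of relational CSV tables
— a patient register (`basic`), longitudinal labs (`lab_cd4`), treatment
starts (`art`), follow-up (`follow`) — keyed by a subject identifier.
cohortviz reads and validates such tables, derives per-subject timelines and
aggregates, and renders three classes of animated graphics as PNG frame
sequences plus a self-contained HTML scrubber viewer:

1. **Longitudinal / event panel** — a scatter of a longitudinal measure
   (e.g. CD4 count) against days since therapy start, with per-group LOESS
   curves, marginal density curves, and a linked Kaplan–Meier pane showing
   cumulative probability of death, stratified by a classifier such as
   clinical AIDS status. One frame per day (configurable step).
2. **Bubble panels** — per enrollment period, one bubble per group at
   (x = proportion with indicator 2, y = proportion with indicator 1), area
   ∝ number enrolled; with either marginal 2×2 mosaic panels or a
   darkening multi-period trail per group.
3. **Choropleth maps** — per year, a world-context map and a cropped region
   map shading each country by a proportion, binned into width-10 percent
   intervals on a sequential red ramp.

Every plot is configured by a plain CSV spec file (`name,specification`
rows). Subsets and indicators are written in a safe expression
mini-language (`cd4_base < 200`, `aids_y in (0,1) and not missing(aids_y)`)
that is parsed and interpreted — configuration text is never executed as
code.

At the core sit the standard estimators of the field: the Kaplan–Meier
product-limit estimator S(t) = ∏_{t_i ≤ t} (1 − d_i/n_i) with cumulative
event probability 1 − S(t); locally weighted polynomial regression with
tricube weights over `ceiling(span·n)` nearest neighbors (span 0.75,
degree 1 by default), fit once over the whole span and revealed frame by
frame; Gaussian kernel densities with Silverman bandwidth; and 2×2
indicator tables per (group, period) with minimum-count suppression.

Because real cohort data of this kind is not redistributable, the package
includes a deterministic synthetic-cohort generator
(`simulate_cohort()`) with known ground truth (group-wise exponential
mortality, square-root-scale CD4 recovery, a per-year drift in the
probability of presenting with CD4 < 200), and ships a small pre-generated
fixture under `inst/extdata/democohort/` together with demo spec files and
synthetic country boundaries.

## Worked example

```r
library(cohortviz)

data_dir <- system.file("extdata", "democohort", package = "cohortviz")
specs    <- system.file("extdata", "demospecs",  package = "cohortviz")

res <- run_panel1(data_dir, file.path(specs, "panel1_specs.csv"),
                  out_dir = "output", frame_step = 10)
```

which prints:

```
panel1: 75 frames (days 0..730, step 10)
subjects plotted: 150
observations: 1110; death markers: 36
warnings during load: 0
viewer: output/panel1_viewer.html
```

75 frames cover days 0–730 in 10-day steps (closing on the completed
figure); all 150 fixture subjects pass the spec's filters; 1,110 CD4
observations are in play and 36 deaths have a CD4 value recent enough
(within the 360-day attribution window) to receive an X marker. Open
`output/panel1_viewer.html` in a browser to scrub or play the animation;
frames live in `output/scroll_images/panel_0001.png` … and can be encoded
to video with any external tool.

The bubble and map classes run the same way:

```r
run_bubbles(data_dir, file.path(specs, "panel2_specs.csv"), "output_bb")
run_maps(data_dir, file.path(specs, "map1_specs.csv"),
         system.file("extdata", "synthetic_boundaries.geojson", package = "cohortviz"),
         "output_mp")
```

A thin CLI wrapper with the same four verbs (`panel1`, `bubbles`, `maps`,
`simulate`) is installed at `inst/cli/cohortviz`.

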