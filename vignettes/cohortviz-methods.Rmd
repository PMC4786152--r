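---
title: "Methods behind cohortviz: statistics, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind cohortviz}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortviz)
```

cohortviz turns flat-file HIV cohort data laid out in the HICDEP style
(patient register, longitudinal labs, treatment starts, follow-up) into three
classes of animated graphics: a longitudinal scatter with group-level smooth
curves, marginal densities and a linked cumulative-mortality pane; per-period
bubble plots of paired indicator proportions; and temporal choropleth maps of
country-level proportions. Everything is driven by plain CSV specification
files, so an analyst changes a plot by editing text, not code. This vignette
records the statistical methods, the conventions the package commits to, and
the reasoning behind the choices that were genuinely open.

## Data model and ingestion

A cohort is a directory of CSV tables sharing a subject identifier column.
`load_cohort()` parses declared date columns under a strict ISO-8601 rule:
`YYYY-MM-DD` parses, empty cells and the literal `NA` are missing, and
anything else — including superficially plausible forms like `15/03/2011` —
is a validation *error*, not a guess. Cohort exchange files pass through many
national conventions; silently coercing an ambiguous date is exactly the kind
of bug a validation layer exists to catch. Subjects appearing in a
longitudinal or event table but not in the patient register are retained and
*warned* about rather than dropped: the row may be a register omission, and
dropping it silently would bias event counts. Unknown extra columns pass
through untouched so that specification expressions can reference them.

## The specification mini-language

Legacy spec files embedded fragments of R (`basic_cd4$cd4_v_cmp < 200`,
`aids_cl_y %in% c(0,1) &! is.na(aids_cl_y)`) that were executed verbatim.
Executing configuration text as code is both unsafe and unportable, so
cohortviz defines a closed expression language that covers every construct
such files actually use: column references (a `table$` prefix is accepted
and stripped), numeric/string/true-false literals, the six comparison
operators, `and`/`or`/`not`, membership `in (...)`, and `missing(col)`. The
R spellings `&`, `|`, `!`, `%in%`, `is.na` are token-level synonyms, so most
legacy expressions parse unchanged. Anything outside the grammar — function
calls, assignment — is a syntax error with a character position; nothing is
ever evaluated by the R interpreter.

Evaluation is three-valued: a comparison against a missing cell is missing,
`missing(col)` is always true/false, and `and`/`or` follow Kleene logic
(conveniently, base R's vectorized `&` and `|` implement this exactly).
Callers that subset treat a missing row verdict as "excluded", which makes
`x > 0 and not missing(x)` behave the way an epidemiologist expects.

Omitted spec names take documented defaults — follow-up horizon
`maxtime = 730` days, event-attribution window `long2eventwindow = 360`
days, bubble minimum count `minnum = 10`, `starttype = "first"`, period
`"year"`, identity transformation — and unknown names warn rather than fail
so forward-compatible spec files still run.

## Per-subject timelines

Day 0 is the selected start date (earliest or latest of the subject's start
records, per `starttype`); all day arithmetic is exact calendar-day
difference. Follow-up is truncated at `maxtime`: a subject whose end date
falls beyond the horizon is administratively censored *at* the horizon
rather than excluded, matching standard practice for a fixed-horizon
product-limit display (exclusion would bias the risk sets). An event beyond
the horizon is unobserved within it.

A death marker is placed at (death day, last observed value) only when the
last value is at most `long2eventwindow` days old at death, with an
*inclusive* boundary (a gap of exactly 360 days qualifies; the convention
had to be fixed one way and inclusive is the more permissive reading of
"within"). Deaths with no attributable value still enter the mortality pane
— they are real events — but receive no marker in the scatter.

Baseline measures (e.g. CD4 at enrollment) take the observation closest to
the anchor date within an asymmetric window, by default 180 days before to
30 days after. Pre-anchor values are biologically valid for much longer than
post-anchor ones, which are quickly contaminated by treatment response; on
an exact distance tie the earlier observation wins for the same reason. Both
windows are arguments.

## Statistical primitives

**Survival.** Group-wise mortality uses the Kaplan-Meier product-limit
estimator, S(t) = ∏_{t_i ≤ t} (1 − d_i/n_i), computed through
`survival::survfit` and displayed as cumulative event probability 1 − S(t).
Ties between events and censorings at the same day follow the universal
convention (events first in the risk-set accounting). The test suite checks
the estimator against an independently coded brute-force product-limit
oracle on a thousand randomized small instances, against 1 − ECDF in the
uncensored case, and against the exponential ground truth of the synthetic
cohort. No confidence bands are drawn; uncertainty display is deliberately
out of scope for these animations.

**Smoothing.** The longitudinal trend per group is locally weighted
polynomial regression: at each grid point, a weighted least-squares
polynomial over the `ceiling(span * n)` nearest x-neighbors with tricube
weights `(1 − (d/d_max)³)³`. Defaults are span 0.75 and degree 1; degree 1
is markedly more stable than 2 at the sparse right edge of follow-up, where
few subjects remain. The implementation is the package's own (the
neighborhood rule and arbitrary evaluation grids are pinned by contract and
verified to 1e-9 against a brute-force oracle; `stats::loess` uses a
different neighborhood size rule and an interpolated surface). The curve is
fit **once** over the whole time span and merely revealed frame by frame, so
the smooth never changes shape mid-animation.

**Densities.** The marginal density of the "current" value distribution uses
a Gaussian kernel with Silverman's rule-of-thumb bandwidth,
`0.9·min(sd, IQR/1.34)·n^(−1/5)`, evaluated directly on the fixed value
axis. The subject set at frame day *t* is: subjects still under follow-up at
*t*, each contributing their latest observation at or before *t* that is no
older than `long2eventwindow` days. The construction keeps the terminal
frame's density interpretable as the end-of-horizon value distribution of
survivors, while preventing long-dead measurements from haunting the margin.
A group whose current sample has fewer than two distinct values simply
skips its margin curve for that frame.

**Bubble statistics.** Each (group, period) cell carries the 2×2 joint
counts of the two indicators; marginal proportions refer to subjects with
*both* indicators observed (a missing indicator removes the row from that
cell's denominator, so a plotted proportion never mixes observed and
imputed information). Cells below `minnum` subjects are suppressed — a
proportion of 2/3 is noise, not signal — but their period still occupies an
animation frame so the time axis never silently skips a year.

## Rendering conventions

All statistical state — axis limits, tick positions, smooth curves, survival
curves, colors, labels — is computed once before the first frame; frames
differ only in what they reveal. Default axis rules: the value axis spans
the 0.5th to 99.5th percentile of the data (explicit limits override); the
event axis spans 0 to 1.4 times the highest final group rate, leaving
headroom so no curve touches the frame edge. Degenerate limits (a constant
value) widen by ±5% (±1 at zero). Tick labels always show the *original*
scale even when plotting on a square-root or log scale; explicit tick values
outside the limits are dropped. With a frame step above one day, an explicit
terminal frame at `maxtime` always closes the sequence, so the completed
figure is the last file and the animation holds on it.

Bubbles encode count as *area* (radius ∝ √n): perceived size tracks area,
and a radius encoding would wildly exaggerate large cells. Bubble axes are
fixed to [0, 1] in every frame — cross-frame comparability is the entire
point of the animation. Trail shades darken linearly in HSV value toward
35% as bubbles age, so luminance is strictly decreasing with age and the
current period is always the lightest, topmost bubble.

Maps draw longitude/latitude directly (plate carrée); for reading a
choropleth this is adequate and keeps the package free of projection
dependencies. Values are binned into width-10 percentage intervals covering
the observed range (half-open, last bin closed), colored by a single-hue
sequential red ramp, lightest bin first; inputs with maximum ≤ 1 are read
as proportions, and an explicit `varscale` field resolves the ambiguous
all-small-percentage case. The region view crops to the bounding box (plus
5% margin) of every country with data in *any* period, so the viewport
never jumps between frames. ISO-3 codes with no boundary polygon are listed
in the run report — no row is ever silently dropped.

All rendering is deterministic: identical inputs produce byte-identical PNG
frames, which the end-to-end tests verify by checksum.

## The synthetic cohort generator

Real multi-site HIV cohort data cannot be redistributed, so the package
ships a generator whose output has *known* ground truth. It emulates:
staggered enrollment over calendar years across sites in several countries;
clinical-AIDS status at therapy start (35% AIDS, 5% unknown-coded-9 by
default); lognormal baseline CD4 (median 90 cells/µL with AIDS, 250
without, sdlog 0.6); square-root-scale CD4 recovery of 1.3 √-units per 100
days with visit-level Gaussian noise at roughly quarterly visits; and
exponential mortality (6.8×10⁻⁴/day with AIDS ≈ 22% two-year mortality,
2×10⁻⁴/day without) with exponential dropout and administrative close-out.
The drawn baseline is recorded verbatim as the day-0 measurement — it *is*
the enrollment lab — so the generator's per-year drift in P(baseline CD4 <
200) is exactly recoverable from the tables it writes. All draws flow from
one seed; identical parameters give byte-identical CSV files.

What it does **not** emulate: informative censoring, site-level measurement
batch effects, guideline-driven treatment-threshold shifts, competing
risks, or any real cohort's joint distributions. Passing tests therefore
demonstrate that the pipeline computes its statistics correctly and
reproducibly on structurally realistic data — not that any epidemiological
finding generalizes.

## Problem sizes and numerical notes

The test suite exercises the estimators at n = 2,000 subjects (consistency
checks against exponential truth within 0.03), a thousand randomized
product-limit instances at n ≤ 12 with heavy ties (agreement with brute
force to 1e-12), and local regression at n = 200 against its oracle to
1e-9. End-to-end rendering demos use 120–150 subjects with a coarse frame
step (10–30 days); at the default one-day step the same code simply writes
731 frames. Degenerate inputs are handled explicitly rather than left to
numerics: duplicated x-neighborhoods in the smoother fall back to the local
mean, sub-two-point densities skip their margin, empty groups drop with a
warning, and an empty cohort after filtering is an error.

## Command-line use

`inst/cli/cohortviz` wraps the four entry points (`panel1`, `bubbles`,
`maps`, `simulate`) for shell use. Frame sequences land in
`output/scroll_images/`, ready for an external encoder, e.g.

```
ffmpeg -framerate 24 -i output/scroll_images/panel_%04d.png -pix_fmt yuv420p panel1.mp4
```

while `output/*_viewer.html` scrubs the frames in any browser with no
encoding step at all.
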