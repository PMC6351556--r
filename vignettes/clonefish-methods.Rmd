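---
title: "Methods: clonal-expansion and smFISH quantification in clonefish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonal-expansion and smFISH quantification in clonefish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonefish)
```

clonefish implements the image-derived statistics of a dual-reporter
(mT/mG) lineage-tracing analysis of tumour tissue: clonal-area
quantification, clone detection and size classes, growth-law fitting, and
per-cell smFISH dot counting. This vignette records the models, the
parameter choices, and the design decisions that were genuinely open.

## Clonal-area statistic

Both reporter channels are binarized — by a manual threshold or, by
default, an Otsu threshold computed from the image histogram, which
replaces per-section manual adjustment with a reproducible rule — and the
foreground pixels are summed: `A` over the Tomato channel (total tumour
area), `B` over the GFP channel (recombined area). The statistic is

$$\mathrm{GFP\%} = \frac{100\,B}{A - B}.$$

The subtraction in the denominator reflects the homozygous reporter: every
GFP+ cell is also Tomato+, so the unrecombined reference area is `A - B`.
Consequences worth noting:

* the statistic is strictly increasing in `B` at fixed `A`;
* it reaches 100% when `B = A/2` and exceeds 100% beyond that — it is a
  ratio to the unrecombined area, not a fraction of the total;
* `B = 0` is defined as 0% (the limit value), so unlabelled sections do
  not error;
* `A - B <= 0` with `B > 0` has no defined value and raises an error; the
  pipeline driver additionally logs a warning when `B` approaches `A`.

## Clone detection and size classes

Clone counting is traditionally done by eye; clonefish needs an algorithmic
definition. A cell is called GFP+ when more than 50% of its
membrane-adjacent pixels (its own pixels within `membrane_width` px of a
wall shared with another cell) fall in the GFP foreground — the same
majority convention the dot-assignment rule uses. A clone is a connected
component of GFP+ cells under territory contact (8-connectivity on the
label adjacency graph); contact is the weakest defensible adjacency
criterion, and the choice only matters for clones separated by a single
pixel. Size classes default to small (1–2 cells), intermediate (3–5) and
large (≥6). Stated class bounds of "three to five" and "more than six"
leave 6-cell clones unclassified; we assign 6 to *large* (the gap is closed
downwards) and expose both cut points as configuration.

## Growth law

The expansion of the labelled population is modelled as

$$y = a \ln(t + b),$$

with `y` the GFP% statistic and `t` the chase time in days (24 h maps to
1.0 and 36 h to 1.5, so hour- and day-denominated chase points share one
axis). The default, *constrained*, mode fixes `b = 1`, which makes the fit
a no-intercept linear regression on `ln(t + 1)` with the closed form
`a = Σ y·l / Σ l²`, `l = ln(t+1)`. A *free* mode fits both parameters by
Levenberg–Marquardt least squares (start `a = 1, b = 1`, `ftol = ptol =
1e-10`, 500 iterations). The constrained form is the default because the
one-coefficient law is the verifiable anchor; which second parameter a
"two-parameter" fit should free (the offset, or an intercept) is not
determinable, and neither model carries an intercept — a freshly labelled
population occupies no measurable area at `t = 0`.

The alternative model is the saturating exponential
`y = c(1 - e^{-t/\tau})`; "exponential decay" for a growing, saturating
quantity is read as decay of the growth *rate*. Models are ranked by R²
(`1 - SS_res/SS_tot`, `SS_tot` about the mean) with residual RMS as
tie-break; residual summaries replace visual inspection. Degenerate
inputs are refused: fewer than 2 (constrained) or 3 (free) distinct times,
and a constant series for the exponential fit, whose `tau` is then
unidentifiable. A constant zero series is legal and returns `a = 0` with
zero residuals. FACS- and surface-derived observations are pooled
unweighted into one fit.

## smFISH dot counting

The pipeline order is fixed: classify → erode → particle analysis →
cross-channel filter → per-cell assignment → ratio. Stages only set an
`eliminated_by` flag (`circularity_filter`, `overlap_filter`,
`assignment`); no record is deleted and no pixel set mutated, so the
output table is a full audit trail.

**Classification.** A deterministic intensity rule stands in for a trained
pixel classifier: threshold mode keeps pixels at or above a fixed
intensity (default 0.25 on the [0, 1] scale, about 28% of the rendered dot
amplitude); quantile mode keeps exactly the top `1 - q` fraction of
pixels, ties broken by intensity then raster order.

**Erosion.** Applied exactly once. A foreground pixel is eliminated when
at least one neighbour in its 3×3 window is background (out-of-raster
counts as background). The wording "surrounded by background pixels in a
3×3 matrix" also admits a weaker reading — eliminate only fully isolated
pixels — but that reading cannot separate touching dot aggregates, which
is the stated purpose of the step, so the any-neighbour rule (standard
morphological erosion) is the default and the isolated-only rule is
available as `rule = "isolated"`.

**Particle analysis.** 8-connected components, no size limit, enumerated
by their top-left-most pixel for determinism. Circularity is
`4πA/P²` clamped to ≤1, with single-pixel particles set to 1 by the usual
particle-analysis convention; bounds default to [0.4, 1.0]. The perimeter
`P` is the boundary-crack count (exposed pixel edges) scaled by π/4. The
raw crack count systematically overestimates the perimeter of smooth
shapes — a digital disc of radius r has crack length 8r, giving every
disc a circularity near π²/16 ≈ 0.62 — whereas the π/4-scaled estimator
is exact for discs (a filled disc of radius 10 px measures ≥ 0.9) while
still rejecting elongated debris (a 1×20 px line measures ≈ 0.23, below
the 0.4 bound). The raw estimator remains available via
`perimeter = "crack"`.

**Cross-channel filter.** Each surviving dot is challenged against the
surviving dots of the other channel and eliminated when the overlap
exceeds 20% *of its own area* for some partner. The denominator of "20%
of overlapping surface" is not self-evident (own area, smaller dot, or
union); per-dot own area was chosen because it is scale-free per dot and
symmetric in treatment, and the elimination is applied simultaneously in
both channels. Setting `overlap_frac = 0` eliminates any touching pair.

**Assignment.** A dot belongs to the unique cell containing strictly more
than 50% of its pixels; disjoint cells plus strict majority guarantee
uniqueness, and an exact 50/50 split stays unassigned. Cell ROIs come in
as a label map (synthetic truth or an external segmentation); manual ROI
drawing is inherently irreproducible and is not emulated.

**Ratio.** Mean surviving assigned dots per cell, over *all* cells of each
GFP population (zero-dot cells included), ratio GFP+/GFP−. A zero GFP−
mean leaves the ratio undefined and raises an error. The analysis operates
strictly on single 2D planes; selecting which Z-plane to quantify is the
caller's responsibility.

## The synthetic scene generator

The generator emulates one field of view of a tumour section: a Voronoi
tessellation of uniformly sampled seeds (convex, epithelial-like
territories with shared walls), a membrane band of `membrane_width_px`
(default 2 px) rendered along every wall on each cell's own pixels —
membrane fluorescence belongs to the cell that owns the pixel, and this
keeps the GFP paint of a cell off its neighbours' territory — with Tomato
on all cells and GFP on the recombined subset (nearest integer to
`recombined_fraction · n_cells`). FISH dots are per-cell Poisson counts
(green rate uniform; far-red rate 2 for GFP+ vs 4 for GFP− by default,
the mother-vs-progeny asymmetry), rendered as Gaussian spots of
`dot_sigma_px = 1.6` and amplitude 0.9; coincident speckles are rendered
at identical coordinates in both channels (Poisson, default 5 per image)
to emulate the non-specific background the cross-channel filter targets.
Additive Gaussian noise (default SD 0.02) is the only noise source — one
knob, sufficient to exercise thresholding.

Defaults were chosen once to represent a realistic high-magnification
acquisition: 600×600 px with 40 cells gives ~9000 px per cell, i.e. a
~95 px cell diameter, matching a ~10 µm epithelial cell at the ~0.1 µm/px
scale typical of RNAscope imaging, where dots (~5 px across) are small
relative to cells. `recombined_fraction` defaults to 0.5 — a field of
view centred on a traced clone — while tissue-wide induction experiments
use values near 0.01.

Two placement rules keep the ground truth well defined. Dot centres are
drawn uniformly over the cell's cytoplasmic interior — cell pixels clear
of the membrane band and of the image border (margin
`ceiling(2·dot_sigma) + 1` px) — emulating cytoplasmic mRNA localisation;
border-clipped spots would otherwise not be countable particles. And all
dots of one cell (both channels jointly) keep at least `dot_min_sep_px`
(default 6 px) between centres: two transcripts closer than the optical
resolution limit are not resolvable as distinct dots, so true counts are
defined over resolvable dots and positions follow a hard-core process at
roughly the diffraction limit. Tiny cells that cannot satisfy the
constraint fall back to unconstrained placement after 200 rejection
attempts. Boundary-straddling dots and unresolvable pairs are therefore
*not* exercised by scene-level recovery tests; the corresponding rules
(majority assignment, 50/50 ties, aggregate separation) are tested
directly on hand-built pixel sets instead — passing recovery tests show
the pipeline recovers counts under clean geometry, not that real tissue is
free of these effects.

Determinism: a configuration (including its seed) reproduces scenes
bit-identically; the FISH stage derives its stream from `seed + 1` so both
stages are reproducible independently, and the pipeline driver overrides
section seeds with its single top-level seed.

What the generator does not emulate: 3D stacks, realistic point-spread
functions, photobleaching, shot noise, tissue folds, stromal (reporter-
negative) cells, and spatial clustering of transcripts such as
transcription-site aggregates.

## Problem sizes in the test suite

Scene-level checks run on 40-cell 600×600 scenes (several seeds), ratio
recovery on 200-cell 1340×1340 scenes, and the estimator-consistency check
on 50/200/800-cell scenes whose area scales with the cell count. The
erosion rule is compared against a brute-force per-pixel scan on all
65,536 4×4 masks; the cross-channel and assignment rules against
set-arithmetic oracles on 1000 random small scenes; clone detection
against a flood-fill oracle on grid tessellations up to 4×4 cells. Growth
fitting is verified against its closed form, by Monte-Carlo recovery over
100 noisy series, and exactly on noise-free series sampled from the law at
the seven chase points (1, 1.5, 4, 10, 30, 60, 90 days). The growth
generator's default observation noise (SD 0.5 GFP%) was set so that
constrained fits on default series have goodness of fit in the region the
real pooled data showed (R² ≈ 0.95).

## Known limitations

* Otsu thresholding assumes a bimodal intensity histogram; sections with
  very sparse signal may need a manual threshold.
* The clone definition by territory contact cannot distinguish two
  abutting clones of independent origin; at low recombination fractions
  this is rare.
* Merged dots that survive the circularity filter are counted as one; the
  erosion step separates moderate aggregates but not near-coincident ones.
* The dot-count ratio is a ratio of population means within one scene;
  summarising across replicate scenes is left to the caller (compute one
  ratio per scene, then summarise).
* The -ddCt utility assumes equal amplification efficiency between target
  and housekeeping reactions.
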