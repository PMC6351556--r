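# clonefish

Quantification tools for clonal lineage tracing in dual-fluorescent-reporter
tumour tissue, and for single-molecule FISH (RNAscope) dot counting per
cell.

## The problem

In mT/mG lineage-tracing experiments every tumour cell expresses membrane
Tomato, and Cre-recombined cells (and their clonal progeny) additionally
express membrane GFP. Three quantities describe how the labelled population
behaves:

1. **Clonal area.** On a two-channel section, let `A` be the number of
   Tomato-foreground pixels (total tumour area) and `B` the number of
   GFP-foreground pixels (recombined area). Because the reporter is
   homozygous, GFP+ cells are also Tomato+, so the reference area is
   `A - B` and the clonal-area statistic is

   ```
   GFP% = 100 * B / (A - B)
   ```

2. **Clone sizes.** A clone is a maximal set of touching GFP+ cells;
   clones are classified as small (1–2 cells), intermediate (3–5) or large
   (6 or more).

3. **Expansion kinetics.** Pooled (chase time, GFP%) observations are
   fitted with the saturating logarithmic law `y = a * ln(t + b)`
   (constrained mode fixes `b = 1`, leaving the single coefficient `a`),
   and compared against an exponential-saturation alternative
   `y = c * (1 - exp(-t / tau))` by R² and residual summaries.

For smFISH sections, dots are counted per cell with a fully specified rule
set: intensity classification → one-pass 3×3 erosion → particle analysis
(8-connected components, circularity `4πA/P²` kept in [0.4, 1.0]) →
cross-channel elimination of dots overlapping a dot of the other channel by
more than 20% of their own surface (removing coincident background
speckles) → assignment of each dot to the cell containing a strict majority
(>50%) of its surface → mean dots per cell in the GFP+ and GFP−
populations and their ratio.

A ground-truthed synthetic scene generator (Voronoi epithelial sheet,
membrane-band reporters, per-cell Poisson dot counts with
population-specific rates, coincident speckles, Gaussian noise) makes every
stage testable without microscopy data.

## Worked example

```r
library(clonefish)

cfg    <- scene_config(seed = 7)          # 600x600 px, 40 cells, half GFP+
scene  <- simulate_tissue(cfg)
fish   <- simulate_fish_channels(cfg, scene$truth)
status <- ifelse(seq_len(cfg$n_cells) %in% scene$truth$gfp_cell_ids,
                 "gfp_pos", "gfp_neg")
cells  <- cell_rois(scene$truth$cell_label_map, status)

quantify_gfp_area(binarize_channel(scene$tomato, "auto"),
                  binarize_channel(scene$gfp, "auto"))
#> Area quantification: A (Tomato px) = 32506, B (GFP px) = 16821, GFP% = 107.2

fish_count(fish$green, fish$farred, cells)$ratios$farred
#> Dot ratio [farred]: mean GFP+ = 2.450 (n=20), mean GFP- = 3.650 (n=20), ratio = 0.671

fit_log_growth(simulate_growth_series(growth_config(seed = 7)))
#> Growth fit [log_constrained]: y = a * ln(t + 1)
#>   coefficients: a = 1.49282, b = 1
#>   R-squared = 0.9319 on 21 observations
```

Half the cells in this field are recombined, so the GFP membrane area is
about half the Tomato area and GFP% is near 100 (the statistic exceeds
100% once `B > A/2`). The far-red dot ratio of 0.67 reflects the
generator's default asymmetry (GFP+ cells carry a lower far-red rate, 2 vs
4, expected ratio 0.5 up to Poisson noise over 20 cells per group). The
growth fit recovers a coefficient near the generating value 1.4 from noisy
replicates at seven chase points.

A command-line driver over the same functions lives in
`inst/scripts/run-pipeline.R`:

```sh
Rscript inst/scripts/run-pipeline.R all --seed 1 --out out/
```

writes the scene TIFFs, ground-truth tables, `areas.csv`, `clones.csv`,
`fit.json`, `dots.csv`, `ratios.csv` and a run log.

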