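# fiberlayer

Layer-stratified quantification of labeled axonal fibers in fluorescence
micrographs of brain sections.

When axonal projections are traced anterogradely (or a neurotransmitter is
immunostained), the scientific question is often *which anatomical layer* the
labeled fibers terminate in — for example, whether serotonergic raphe
afferents to the olfactory bulb target the glomerular layer (GL), the
external plexiform layer (EPL), or the granule cell layer (GCL). fiberlayer
is an R package for that measurement: it turns a calibrated section image
plus an anatomical layer mask into per-layer signal densities with group
statistics, pixel-level and marker-level colocalization tests, and an
association analysis between injection-site composition and projection
composition. A synthetic-section simulator with exact ground truth makes the
entire pipeline testable end to end.

## The method

For each animal, ten 120 × 120 µm square samples are placed per layer —
approximately one per 36° sector around the layer centroid — using only the
anatomy mask, never the signal channel. Each sample is despeckled (3×3
median) and background-subtracted (rolling ball, radius 30 µm ≙ 210 px at
the 7 px/µm calibration). Signal is defined per animal as pixels strictly
above

&nbsp;&nbsp;&nbsp;&nbsp;threshold = µ + k·σ,&nbsp;&nbsp;k = 6,

with µ, σ the mean and (population) SD pooled over all of the animal's
samples. Signal density is

&nbsp;&nbsp;&nbsp;&nbsp;D = 100 · (detected px) / (total px analysed)&nbsp;&nbsp;[µm²/100 µm²],

compared across layers by one-way ANOVA (animal as unit) with Tukey HSD post
hoc tests.

Pixel-level colocalization of two channels uses the van Steensel
shift-correlation diagnostic: Pearson's r(dx) as one channel is displaced by
integer dx ∈ [−50, 50] px, computed over the overlap region; genuine
colocalization peaks at dx = 0. The null is the same statistic with one
channel rotated by 90°, and the per-sample peak r values are compared by a
paired t-test. Marker-level colocalization pairs point annotations
one-to-one by greatest proximity under a 12 µm cutoff.

The association stage correlates, across animals, the infection covariate
log₁₀((n_MRN + 1)/(n_DRN + 1)) with the projection covariate
log₁₀((D_GL + ε)/(D_GCL + ε)), ε = 10⁻⁴ µm²/100 µm², including the
RGB = (L, 0.8(1−L), 1−L) colour encoding of the clipped abundance ratio L.

Design rationale, parameter tables and generator details are in the methods
vignette (`vignettes/fiberlayer-methods.Rmd`).

## Worked example

A compact synthetic cohort (coarse 2 px/µm calibration so it runs in a
minute or two; the defaults reproduce the full 7 px/µm study conditions):

```r
library(fiberlayer)

cfg <- run_config(resolution = 2, n_animals = 3,
                  per_layer_density = c(GL = 0.05, EPL = 0.01, GCL = 0.01),
                  n_coloc_samples = 5, fiber_width_um = 2, seed = 7)
dir <- tempfile("cohort")
run_synthesize(cfg, dir)          # masks, channels, truth tables on disk

res <- run_density(cfg, dir)      # sample -> preprocess -> threshold -> density
print(res$comparison)
#> <layer_comparison> one-way ANOVA: F(2, 6) = 45.47, p = 0.000237
#> per-layer mean +/- SEM (um^2/100 um^2):
#>  layer n       mean         sem
#>    EPL 3 0.01035880 0.003007589
#>    GCL 3 0.01759259 0.001881455
#>     GL 3 0.04241898 0.002464082
#> Tukey HSD adjusted p-values:
#>  contrast        diff        p_adj
#>   GCL-EPL 0.007233796 0.1808781571
#>    GL-EPL 0.032060185 0.0002446534
#>    GL-GCL 0.024826389 0.0010023255

cl <- run_coloc(cfg, dir)         # shift curves vs rotated-90-degree null
print(cl$test)
#> <coloc_test> n = 5 samples; peak at -0.2 +/- 0.2 px
#> paired t vs rotated control: t = 10.48, p = 0.000468

as <- run_associate(cfg, dir)     # infection vs projection composition
print(as)
#> <composition_cor> r = 0.999, p = 1.37e-07, n = 7 animals (log_ratio form)
```

The generator was asked for a GL-dominant laminar profile
(0.05 vs 0.01/0.01 µm²/100 µm²), and the pipeline recovers it: GL mean
0.042 is well above EPL/GCL, the across-layer ANOVA is decisive, and the
GL–EPL and GL–GCL Tukey contrasts are significant while EPL–GCL is not. The
colocalization fixture shares 80% of its fibers between channels, so the
shift-correlation peak sits at ~0 px displacement and beats its rotated
control (p < 0.001). The simulated 7-animal cohort couples layer densities
to infected-cell composition, giving the strong positive correlation.

Every result type has `tidy()` / `glance()` methods returning tibbles, and
`autoplot()` / `plot_*()` displays (density-by-layer bars, shift-correlation
curves, association scatter with the abundance colour map). A thin
command-line wrapper over the same four stages ships at
`inst/scripts/fiberlayer.R`.

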