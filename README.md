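# bzdti

Quantifying microstructural remodeling of the myocardial infarct border zone
from co-registered late gadolinium enhancement (LGE) and diffusion tensor MRI
(DT-MRI).

## What it does, and for whom

After a myocardial infarction the ventricular wall splits into remote
myocardium, dense scar, and the border zone (BZ) between them — a mixture of
viable myocytes and replacement fibrosis that supports slow conduction and
reentrant arrhythmias. Builders of cardiac electromechanics models and
ex vivo imaging groups need voxel-wise maps of these regions and quantitative
measures of how remodeled each one is.

`bzdti` implements that analysis as a tested R pipeline:

1. **Tensor reconstruction** — per-voxel log-linear least squares on the
   Stejskal–Tanner model, ln(Sᵢ/S₀) = −b gᵢᵀ D gᵢ, from a DWI stack
   (one b = 0 plus 30 directions at b = 1000 s/mm² by default).
2. **Invariant maps** — ADC = tr(D)/3; FA = √(3/2)·‖D̃‖/‖D‖ with
   D̃ = D − (tr(D)/3)·I; tissue mode = 3√6·det(D̃/‖D̃‖). ADC rises with
   falling cellularity, FA falls with fibrosis, mode falls with fiber
   disarray.
3. **LGE segmentation** — per-heart signal-intensity thresholds (infarct above
   the halfway level between remote and infarct ROI means; BZ between that
   and two remote SDs above the remote mean), label down-sampling to the DTI
   grid (slice-direction block average + in-plane bicubic + majority vote),
   and morphological refinement (≤ 3-voxel infarct islands removed; BZ
   farther than 3 mm from infarct reverted to remote).
4. **Rigid registration** — apex alignment through-plane, then one global
   in-plane integer shift maximizing summed 2D cross-correlation of the
   binary myocardium masks.
5. **Spatial decorrelation** — per-region, per-axis autocorrelation lengths
   (1/e crossing) used as decimation strides, so the statistics run on
   approximately independent samples.
6. **Bootstrap statistics** — per-bin histogram 95% CIs, median CIs, a
   two-group median comparison, and a bootstrap analog to repeated-measures
   ANOVA (cell-median F with a region-effect-removed resampling null).

Because ex vivo data of this kind is rarely shareable, the package includes a
fully parameterized synthetic phantom (`phantom_spec()`, `simulate_heart()`):
an LV annulus with an infarct wedge and BZ shell, region-wise invariant and
signal-intensity distributions, imposed spatial correlation, Rician noise,
and a hidden rigid offset between the LGE and DWI frames — so the whole chain
is testable against known ground truth.

## Worked example

Simulate one infarcted heart on a 48 × 48 × 8 grid and push it through the
full pipeline:

```r
library(bzdti)

spec <- phantom_spec(grid_dims_dti = c(48, 48, 8),
                     lv_geometry = list(center_mm = NULL, inner_radius_mm = 9,
                                        outer_radius_mm = 17, slices = NULL),
                     seed = 7)
heart <- simulate_heart(spec)
res <- process_heart(heart, "example")

unlist(res$qc$shift)          # registration: recovered shift, in voxels
#> dx dy dz
#> -2  1 -1
```

The phantom's hidden LGE offset was (2, −1, 3) mm = (2, −1, 1) voxels; the
recovered shift is exactly its negation. The decorrelated per-region medians:

```r
aggregate(value ~ region + invariant, res$samples, function(v) signif(median(v), 3))
#>    region invariant    value
#> 1      bz       adc 0.000648
#> 2 infarct       adc 0.000761
#> 3  remote       adc 0.000580
#> 4      bz        fa 0.417000
#> 5 infarct        fa 0.338000
#> 6  remote        fa 0.451000
#> 7      bz      mode 0.625000
#> 8 infarct      mode 0.527000
#> 9  remote      mode 0.673000
```

ADC rises and FA falls from remote through BZ to infarct — the remodeling
signature the pipeline is built to detect. A bootstrapped median CI for one
cell (n is small on this desk-scale grid):

```r
v <- subset(res$samples, region == "infarct" & invariant == "adc")$value
ci <- bootstrap_median_ci(v, bootstrap_config(seed = 1))
#> infarct ADC median 0.761 [0.736, 0.807] x10-3 mm2/s (n = 75)
```

Multi-heart studies pool per-heart samples and add the repeated-measures
ANOVA and two-group tests:

```r
report <- run_pipeline(run_config(n_infarcted = 7, n_normal = 7, seed = 1))
report$median_table   # pooled medians with bootstrap CIs per region/invariant
report$anova$adc$p    # bootstrap repeated-measures ANOVA across regions
```

A thin command-line wrapper is installed at `inst/cli/bzdti.R`
(`Rscript bzdti.R simulate|run --out <dir> --seed N`).

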