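# geoparmap

Topological inference on sparse geospatial point data by statistical
parametric mapping. `geoparmap` turns irregular point observations —
each record a planar location plus one or more numeric or binary
variables — into regular-grid maps of *where* an association is
statistically significant, with family-wise error control over the
whole map.

**Who it is for.** Spatial epidemiologists and geostatisticians who
want regionally specific inference ("type 2 diabetes is associated
with household income *here*, controlling for age and sex") rather
than point prediction, on datasets too sparse and irregular for
per-areal-unit methods.

## Method

For observations $(x_i, y_i)$, $i = 1..N$:

1. **Kernel rasterization.** Each observation is distributed over the
   grid by an isotropic Gaussian kernel of 95% iso-density diameter
   $s$ (so $\sigma = (s/2)/\sqrt{2\ln 20}$), evaluated at cell centres
   times cell area, truncated at $4\sigma$. The resulting
   $N \times n_\text{cells}$ response matrix is the dependent variable.
2. **Mass-univariate GLM.** The same regression
   $y(j,k) = X\beta(j,k) + \varepsilon(j,k)$ is fitted by OLS at every
   cell; $X$ holds covariates, one-hot spatial-condition dummies
   and/or interaction products ($y_1 \cdot y_2$).
3. **Random-field-theory thresholding.** Contrast t maps are
   thresholded at the voxel-level FWE-corrected value solving
   $\sum_d R_d\,\rho_d(t) = \alpha$, with resel counts $R_d$ from the
   residual-field smoothness (FWHM of forward differences of
   unit-normalized residuals) and Euler-characteristic densities
   $\rho_d$ of a t field; the threshold is capped at the Bonferroni
   bound. Conjunctions are intersections of thresholded maps.

The package also contains the full synthetic validation suite the
method is tested with: Koch-snowflake region layouts, binary outcome
models with noise level γ and interaction strength c₃, ground-truth
target maps, segmentation scoring (Jaccard, Dice, MCC, symmetric
uncertainty, modified Hausdorff), and coverage-based smoothing-scale
selection. See the methods vignette
(`vignettes/geoparmap-methods.Rmd`) for the model and every design
choice.

## Worked example

Simulate a univariate snowflake model at noise γ = 0.1, analyse it
across the standard scale ladder, and score the recovery against the
generative truth:

```r
library(geoparmap)

obs <- sample_dataset("snowflake", n = 600, parameter = 0.1, seed = 42)
rec <- recover_variables(obs, grid_spec(120, 120), scales = seq(10, 60, 5))
rec$coverage
#>   10   15   20   25   30   35   40   45   50   55   60
#>    0  100  939 2208 2696 3074 3457 3983 4606 5224 5826
rec$selected_scale
#> [1] 60
round(rec$threshold, 3)
#> [1] 3.344

tgt <- target_map(layout_for_model("snowflake"), "Z", 0.1)
segmentation_scores(rec$variable_maps$Z, tgt, grid_spec(120, 120))
#>   jaccard  dice   mcc symmetric_uncertainty mhd_fraction
#> 1   0.741 0.851 0.795                 0.538      0.00428
```

The coverage score (cells significant for exactly one spatial
condition) grows with the smoothing diameter here, so the selection
rule picks s = 60; at that scale the one-tailed FWE threshold is
t ≈ 3.34, and the significant area for Z = 1 overlaps the snowflake
target with Dice 0.85 while its modified Hausdorff distance is under
half a percent of the grid diagonal.

Covariate-style analyses run through `run_pipeline()` /
`run_config()` (beta, t and significance rasters plus a summary CSV
per scale and contrast), or from a shell via the thin CLI:

```sh
Rscript inst/cli/geoparmap.R simulate --model bivariate_snowflake \
    --n 1600 --gamma 0.1 --seed 1 --out ds.csv
Rscript inst/cli/geoparmap.R run --input ds.csv --scales 20,40,60 \
    --design one_hot --out out/
```

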