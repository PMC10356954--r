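# marref — full-reference evaluation of CT metal artifact reduction

Metallic implants produce streaks and dark bands in CT images; vendor
metal-artifact-reduction (MAR) algorithms suppress them during
reconstruction, but the correction itself can distort pixel values close
to the metal. `marref` is for physicists and imaging researchers running
phantom studies who need to quantify *both* effects at once, against a
matched metal-free reference scan of the same object.

## The method

For each structure (bone, tissue) and zone (whole, and near/far split at
20 mm from the metal centroid) the pipeline:

1. **registers** the metal-free reference slice to the uncorrected
   metal-bearing slice (rigid: translation + rotation; masked MSE with
   multistart grid + Nelder–Mead, deterministic);
2. **segments** metal by thresholding (`HU > 2000`, label size filter
   `< 100 px`) and bone/tissue by a gradient-vector-flow active contour
   (edge map `f = |∇G_σ ∗ I|`; GVF field from
   `μ∇²u = |∇f|²(u − f_x)`; snake refinement; flood fill), fully
   automatically;
3. **models** each region's HU histogram as a Gaussian
   `A·exp(−(x−μ)²/2σ²)` and extracts the centroid `μ` and
   `FWHM = √(2 ln 2)·σ`;
4. **scores** the correction with four full-reference ratios

       FWHM_NM = FWHM(non-MAR)/FWHM(reference)   FWHM_M = FWHM(MAR)/FWHM(reference)
       CENT_NM = cent(non-MAR)/cent(reference)   CENT_M = cent(MAR)/cent(reference)

   plus the mask overlap ratio `100·|A∩B|/|A∪B|`. `FWHM_NM > FWHM_M`
   means artifacts were reduced; `FWHM_NM < FWHM_M` means the correction
   distorted the region.

Because no public scanner data exists for this kind of experiment, the
package includes a deterministic phantom simulator (`phantom_spec()`,
`simulate_triple()`) producing matched reference / non-MAR / MAR triples
with exact ground-truth masks — streaks with controllable amplitude and
radial decay, a dark band, a partially corrected MAR counterpart with an
optional near-metal distortion patch, and a sub-pixel misalignment of the
reference.

## Worked example

Simulate a triple whose near-zone tissue sd is inflated ×1.5 by streaks,
with half the streak residue surviving the emulated correction, then run
the full evaluation:

```r
library(marref)

sp <- phantom_position1(
  image_size = 160, spacing_mm = 1.0, seed = 5,
  artifact = list(n_streaks = 24, amplitude_hu = 1, decay_power = 1, dark_band_hu = 0),
  mar = list(residual_fraction = 0.5, distortion = list(radius_mm = 18, amplitude_hu = 0))
)
sp$artifact$amplitude_hu <- calibrate_streak_amplitude(sp, 1.5)

tr  <- simulate_triple(sp)
rep <- run_evaluation(tr$nonmar, tr$mar, tr$reference, config = list(min_label_px = 30))
rep
#> <mar_report>
#>   registration: theta -0.1840 deg, t (-0.395, 0.292) px
#> # A tibble: 6 × 9
#>   structure zone  fwhm_nm fwhm_m cent_nm cent_m overlap_ratio_pct  dice
#>   <chr>     <chr>   <dbl>  <dbl>   <dbl>  <dbl>             <dbl> <dbl>
#> 1 bone      whole    1.20   1.19    1.01   1.01              98.6 0.993
#> 2 bone      near     1.11   1.11    1.02   1.01              99.4 0.997
#> 3 bone      far      1.21   1.20    1.01   1.01              98.4 0.992
#> 4 tissue    whole    1.31   1.23    1.01   1.00              99.9 0.999
#> 5 tissue    near     2.10   1.54    1.01   1.01              99.9 0.999
#> 6 tissue    far      1.25   1.21    1.00   1.00              99.9 0.999
```

Reading the output: the recovered registration transform is close to the
simulated sub-pixel misalignment; evaluation and reference masks agree to
98–100% overlap; near-zone tissue shows the strongest artifact
(`FWHM_NM = 2.10`) and the correction narrows it back towards the
reference (`FWHM_M = 1.54`, still above 1 because half the residue was
left in) — classified `artifact_reduced` — while centroids stay within
~1–2% everywhere. `tidy(rep)` returns the metrics tibble, `glance(rep)` a
one-row summary, `autoplot(rep)` a ratio chart, and
`write_report(rep, "report.json")` / `write_report(rep, "report.csv", "csv")`
export it.

A thin CLI wraps the same functions:

```sh
inst/exec/marref simulate --seed 1 --out phantom_out/
inst/exec/marref evaluate --non-mar phantom_out/nonmar.nii --mar phantom_out/mar.nii \
  --reference phantom_out/reference.nii --min-label-px 30 --out report.json
```

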