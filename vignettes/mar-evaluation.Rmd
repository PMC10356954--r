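---
title: "Full-reference evaluation of CT metal artifact reduction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Full-reference evaluation of CT metal artifact reduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marref)
```

## The problem

Metallic implants corrupt CT images: photon starvation and beam hardening
along rays through the metal produce bright and dark streaks and dark
bands in the surrounding tissue. Vendor metal-artifact-reduction (MAR)
algorithms suppress these artifacts during reconstruction, but they are a
form of approximation and can themselves distort pixel values — most
visibly in the structures closest to the metal. A fair assessment of a MAR
method therefore needs to measure two things at once: how much artifact it
removes, and how much distortion it introduces.

`marref` implements a full-reference evaluation: alongside the
metal-bearing scan (reconstructed with and without MAR, from the same raw
data), a matched metal-free scan of the same object serves as the
reference. Because the reference comes from a separate scan, the object's
position differs by a small rigid displacement, which must be corrected
before any pixel-level comparison.

## The measurement model

For every anatomical region the pipeline summarises the Hounsfield-unit
(HU) histogram by a fitted Gaussian

$$f(x) = A \exp\!\left(-\frac{(x-\mu)^2}{2\sigma^2}\right),$$

whose mean $\mu$ (the *centroid*) is the region's average HU and whose
width, reported as the full width at half maximum
$\mathrm{FWHM} = \sqrt{2\ln 2}\,\sigma$, captures how widely the pixel
values spread. Artifacts widen the histogram; a successful correction
narrows it back towards the reference. The amplitude $A$ is left free
because region histograms are unnormalised counts; $\mu$ and $\sigma$ are
unaffected by that choice. (The FWHM definition above follows the
convention used for the published comparison values; the textbook form
$2\sqrt{2\ln 2}\,\sigma$ is available via `fwhm(..., "conventional")` and
— because every reported metric is a FWHM *ratio* — changes nothing
downstream. This invariance is tested.)

Four ratio metrics compare the uncorrected (non-MAR) and corrected (MAR)
images against the metal-free reference:

$$\mathrm{FWHM_{NM}} = \frac{\mathrm{FWHM}_{\text{non-MAR}}}{\mathrm{FWHM}_{\text{reference}}},\quad
  \mathrm{FWHM_{M}} = \frac{\mathrm{FWHM}_{\text{MAR}}}{\mathrm{FWHM}_{\text{reference}}},$$

and analogously $\mathrm{CENT_{NM}}, \mathrm{CENT_{M}}$ for the centroid.
The reading is:

* $\mathrm{FWHM_{NM}} > \mathrm{FWHM_{M}}$ — the correction narrowed the
  distribution towards the reference: artifacts were reduced;
* $\mathrm{FWHM_{NM}} < \mathrm{FWHM_{M}}$ — the corrected image is wider
  than the uncorrected one: the correction distorted the region.

`classify_mar_effect()` applies this comparison with a small tolerance
`epsilon` (default 0.02) because the ratios are noisy in small regions;
differences within `epsilon` are reported as `neutral`. The published
comparisons use strict inequalities; the tolerance is this package's
choice and is configurable.

Each structure (bone, tissue) is additionally split at 20 mm from the
metal centroid into a *near* and a *far* zone, because both artifact
severity and correction side effects are strongly distance-dependent.

## Pipeline stages and their numerics

### Rigid registration

The metal-free reference is the moving image and the uncorrected
metal-bearing slice the target; only translation and rotation are
estimated, since a rigid phantom on a fixed table can only have shifted or
tilted slightly between scans. The metric is mean squared HU difference
over pixels that (a) lie outside the metal mask dilated by 3 px — the
reference has no metal to match — and (b) map inside the moving image's
domain, so border fill never drives the cost. No similarity metric or
optimiser is prescribed by the measurement model itself; masked MSE with a
coarse multistart grid (±5 px, ±3° by default) followed by Nelder–Mead
refinement is the package's choice, chosen for determinism (no RNG
anywhere in the optimisation) and sub-pixel accuracy on same-modality
slices.

Two numerical details matter:

* both images are pre-smoothed with a Gaussian of 1.5 px inside the metric
  (only for the cost; the returned transform applies to the originals).
  Bilinear interpolation of sharp edges biases the MSE minimum by a few
  hundredths of a pixel/degree; smoothing suppresses that bias well below
  the 0.1 px / 0.05° accuracy the tests require;
* the identity transform is always a candidate and wins ties, so
  self-registration returns the exact identity and the identity-triple
  metric check below holds with no tolerance.

Resampling is bilinear about the geometric image centre, with out-of-domain
pixels set to −1000 HU (air); `resample_rigid()` and `register_rigid()`
share this convention, so transforms are interchangeable.

### Segmentation

Metal is segmented by thresholding (`HU > 2000`) followed by a connected
component size filter (`< 100 px` removed as noise) — metal is by far the
brightest structure and its expected cross-section is known.

Bone and tissue are delineated without human intervention by a gradient
vector flow (GVF) active contour. The edge map is
$f = |\nabla G_\sigma * I|$ (gradient-of-Gaussian magnitude, reflective
boundaries, $\sigma$ = 1 px by default), normalised to $[0,1]$ so the GVF
regularisation weight $\mu$ means the same thing on every image. The GVF
field $(u, v)$ solves

$$\mu \nabla^2 u = |\nabla f|^2 (u - f_x), \qquad
  \mu \nabla^2 v = |\nabla f|^2 (v - f_y),$$

iterated explicitly from the initialisation $(f_x, f_y)$ with a 5-point
Laplacian and zero-flux boundaries. The explicit scheme is monotone-stable
for $\Delta t \le 1/(4\mu + \max|\nabla f|^2)$; note the reaction term in
the bound — the diffusion-only bound $1/(4\mu)$ is not sufficient and
demonstrably diverges for small $\mu$ on normalised edge maps. `gvf()`
refuses a `dt` above the bound rather than diverging, and
`gvf_steady_state()` provides an exact sparse direct solve of the same
linear steady state for small grids; the test suite requires the two
routes to agree to $10^{-3}$ at residual $10^{-8}$.

The deformable contour is evolved semi-implicitly (tension $\alpha$,
rigidity $\beta$ handled through a cyclic pentadiagonal system; the GVF
force sampled bilinearly at the vertices, weight $\kappa$), with uniform
arc-length resampling each iteration. Defaults
($\alpha = 0.01, \beta = 0.02, \kappa = 4$) keep the internal forces weak
relative to the field: tension shrinks small circles inward at
equilibrium, and with these weights the residual bias is below a quarter
pixel on disk-like structures. Contour initialisation is deterministic:
bone contours start from connected components of `HU > 200` (components
that are mostly metal are skipped), the body outline from the largest
component above −200 HU. Each refined contour is rasterised and flood
filled from a validated interior seed; a fill that escapes to the image
border signals an unclosed boundary and is an error, never a silently
leaked mask. Tissue is the filled body minus bone and metal, so bone and
tissue are disjoint by construction.

In metal-bearing images the metal mask dilated by 2 px is excluded from
bone and tissue so blooming does not contaminate the histograms. The same
exclusion is applied to the registered reference masks: the published
per-region pixel counts for evaluation and reference differ by far less
than the metal area, which implies both masks excluded the metal region,
and only then do identical inputs yield exactly identical regions.

Segmentation runs on the MAR image by default (configurable); the masks
are reused verbatim on the non-MAR twin, which comes from the same scan
and therefore has identical geometry. The reference is segmented
independently after registration, and mask agreement is quantified by the
overlap ratio $100\,|A \cap B| / |A \cup B|$. The Dice coefficient
$2|A \cap B|/(|A|+|B|)$ is reported alongside because at least one
published overlap value is arithmetically consistent only with a
Dice-type ratio; the primary output follows the intersection-over-union
formula as defined.

### Distribution modelling

Histograms use 1 HU bins by default (configurable; fits are stable across
1–5 HU bins, which is tested). The Gaussian is fitted by least squares on
bin centres and counts, initialised from the sample moments
(Levenberg–Marquardt via `minpack.lm`). Regions with fewer than 5 occupied
bins or zero variance are refused as degenerate; if the optimiser fails,
the moment estimates are returned flagged as such (`method = "moments"`)
with a warning.

## The phantom simulator

No public scanner data accompanies this kind of experiment, so the package
ships a simulator that generates matched (reference, non-MAR, MAR) triples
with exact ground-truth masks. It emulates a lower-extremity phantom: a
soft-tissue ellipse (40 ± 15 HU) on air, circular bone inserts
(1000 ± 100 HU), and an 8 mm metal disk at 8000 HU — by default on the
clinical geometry of 512 px at 0.39 mm spacing. Two presets place the
metal in tissue near a partial bone cross-section (`phantom_position1()`)
and inside the bone (`phantom_position2()`).

Design choices, and what they do and do not emulate:

* **Artifacts are additive in image space**: streaks are
  $A\cos(n\theta + \varphi)\,(1 + r/r_{\text{metal}})^{-p}$ around the
  metal centre plus a uniform dark band within two metal radii. This gives
  a controllable, analysable ground truth whose near-zone severity and
  radial decay can be set exactly. It does *not* simulate sinogram-domain
  physics (polychromatic beam hardening, photon starvation) or
  reconstruction kernels, so passing tests demonstrate that the
  *measurement pipeline* behaves correctly, not that any particular
  scanner's artifact structure is reproduced.
* **The correction emulator** blends the streak residue
  (`mar = reference + residual_fraction * (nonmar - reference)`) and adds
  a seeded band-limited perturbation inside a configurable near-metal
  patch — the qualitative signature of restoration failing close to the
  metal.
* **Pixel noise is spatially correlated** (Gaussian correlation scale
  1 px, exactly unit pixel variance). Reconstructed CT noise is correlated
  by the kernel; white pixel noise would be an adversarial special case
  for any interpolation step — resampling would visibly narrow every
  histogram and inflate all FWHM ratios for a reason that has nothing to
  do with artifacts.
* **The reference is misaligned** by a sub-pixel rigid transform (0.15°,
  0.4/−0.3 px by default), emulating table/gantry motion between scans.
* **Determinism**: one integer seed makes the triple bit-reproducible;
  all seeded draws (noise, streak phase, distortion field) derive from it.

`calibrate_streak_amplitude()` computes, rather than tunes, the streak
amplitude that inflates the near-zone tissue sd by a requested factor: the
unit-amplitude streak field's RMS over near-zone tissue pixels and the
empirical near-zone sd of the seeded reference are both deterministic, so
the amplitude follows in closed form.

## Test and verification strategy

Every stage is tested against an independent oracle where one exists: the
GVF iteration against a sparse direct solve; registration against the
generating transform of a displaced slice; the Gaussian fit against the
generating distribution of seeded draws; flood fill against brute-force
point-in-polygon; the near/far split against exhaustive distance
computation; segmentation against the simulator's exact masks (Jaccard
≥ 0.98 on the noiseless phantom). Metric identities are exact: an
identical triple yields every ratio equal to 1 with no tolerance, because
registration returns the exact identity and both segmentations see
identical inputs.

End-to-end checks run the full pipeline on calibrated simulations: with
near-zone sd inflation ×1.5 and half the residue surviving correction, the
near-tissue metrics must order as
$\mathrm{FWHM_{NM}} > \mathrm{FWHM_{M}} > 1$; adding a strong near-metal
distortion patch must flip the near zone to correction-induced distortion
while the far zone stays artifact-reduced.

Tests and the acceptance script run the pipeline on reduced geometry —
160 px at 1.0 mm (evaluation scenarios) and 256 px at 0.6 mm (segmentation
fidelity), with `min_label_px` scaled to the smaller metal cross-section —
keeping the full suite around two minutes while preserving the mm geometry
of the default phantom. These sizes are the package's own choice of test
problem; the defaults remain the clinical 512 px / 0.39 mm.

## Known limitations

* The additive artifact model cannot reproduce scanner-specific streak
  textures, and reconstruction methods are represented only through noise
  presets, not kernel emulation.
* The measurement cannot distinguish a region corrected by MAR from a
  region distorted by MAR within the same histogram — the metrics detect
  the net widening/narrowing per zone. This is a limitation of the
  pixel-distribution approach itself.
* A full-reference design requires a metal-free scan of the same object,
  so the method applies to phantom studies, not clinical images.
* Only single 2D axial slices are evaluated; volumes are deliberately
  rejected by the readers.
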