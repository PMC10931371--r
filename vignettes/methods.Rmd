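---
title: "Quantifying polystyrene nanoparticle uptake: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying polystyrene nanoparticle uptake: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

psuptake implements two complementary quantification workflows for
polystyrene (PS) nanoparticle uptake by cultured cells, plus the synthetic
data needed to test them end to end.

## 1. The fluorescence workflow

Sub-resolution fluorescent beads (about 200 nm) cannot be counted
individually once they cluster, so uptake is measured semi-quantitatively as
the *area* of above-threshold bead fluorescence, normalized per cell:

$$ \frac{\text{size of image scan in px}}{255} \times \text{mean gray value of the binary bead mask} = \text{bead pixels} $$
$$ \frac{\text{bead pixels}}{\text{number of nuclei in the field}} = \text{bead pixels per cell} $$

For a binary 0/255 mask the first expression is exactly the foreground pixel
count; `count_bead_pixels()` implements the formula and the test suite checks
its exact equivalence to brute-force counting on random masks.

The chain per field of view (`quantify_fov()`):

1. **z-projection** (`z_project()`): maximum-intensity by default. Beads are
   sparse bright puncta, and the maximum preserves a punctum wherever it sits
   along z; a sum projection is available by flag.
2. **Nuclei segmentation** (`segment_nuclei()`): Gaussian blur with
   $\sigma = 3$ px, global threshold (Otsu by default; any manual 8-bit value
   can be supplied, matching the original manual workflow), hole filling,
   watershed splitting of touching nuclei on the distance transform, then a
   filter on physical area and circularity $4\pi A / P^2$. The minimum
   nucleus area is 20 µm² for THP-1 macrophages and 10 µm² for the A549 and
   CaCo-2 epithelial lines; the circularity range defaults to the full
   $[0, 1]$ (a configurable no-op kept for faithfulness). The watershed
   tolerance is 0.3: after a $\sigma = 3$ blur, the distance-map saddle
   between two 20%-overlapping nuclei is shallow (about half a pixel), and a
   larger tolerance merges them.
3. **Cell-area masking**: the actin channel is thresholded, closed and
   hole-filled (`segment_cell_area_actin()`). When the actin mask fails to
   cover the segmented nuclei, the brightfield image is used instead
   (`segment_cell_area_brightfield()`): percentile contrast stretch, Canny
   edge detection, maximum filter, binary closing and opening, hole filling,
   and removal of sub-nucleus regions. Two implementation details matter
   here. The Canny strong-edge threshold is taken from Otsu on the gradient
   magnitudes, because a fixed magnitude quantile breaks down when cells
   cover a small fraction of the frame. And the filled mask is finally
   eroded by the maximum-filter radius plus one pixel: the maximum filter
   grows every edge outward by its radius and the edge ridge itself is 1-2
   px wide, so without the erosion the mask is systematically dilated
   (planted-layout Jaccard saturates near 0.5 instead of 0.85).
4. **Bead masking** (`mask_beads()`): pixels at or above the bead threshold
   *and* inside the cell mask, so residual extracellular beads are excluded.
   The threshold comes from control fields never exposed to beads
   (`calibrate_bead_threshold()`: a high percentile, 99.95 by default, of
   within-cell control intensities, rounded up) and can be overridden
   manually, as in the original workflow.

Records carry both pixel counts and µm² areas so fields of different pixel
size remain comparable.

## 2. The statistics layer

`ttest_unpaired()` performs the two-sided unpaired t-test between
concentration groups. The variant is configurable: Welch by default (robust
to unequal variances), classical pooled optionally; both agree exactly for
balanced equal-variance groups. Identical constant groups are reported as
$t = 0$, $p = 1$ rather than an error. `fit_dose_response()` is ordinary
least squares of bead pixels per cell on exposure concentration with 95%
confidence intervals on $n - 2$ degrees of freedom and a mean-response
confidence band, exactly the `lm`-based analysis used in this field.
`summarize_uptake()` groups records by cell line, concentration and time,
reports group means, raw pairwise p-values (no multiple-testing correction
by default, with an optional Holm flag) flagged at $p \le 0.05$, and a
regression per cell line and time. Calibration is tested empirically: type-I
error of the t-test over 10,000 null simulations must lie in $[0.04, 0.06]$
and slope CI coverage over 500 simulated dose-response sets in
$[0.93, 0.97]$.

## 3. The Raman workflow

Label-free identification of intracellular PS uses hyperspectral image scans
(one spectrum per pixel, 600-3100 cm⁻¹ at 2 cm⁻¹ spacing by default) and a
linear mixing model: each pixel spectrum is a non-negative combination of a
few pure-component spectra (endmembers).

Preprocessing (`preprocess()`), per pixel and in order:

1. **Spike removal** (`despike()`). Cosmic-ray spikes are single-channel
   events. A channel is flagged when the modified z-scores (threshold 6) of
   the first differences into and out of it both exceed the threshold with
   opposite signs *and* the smaller of those two jumps dwarfs (5-fold) the
   slopes immediately outside. The second condition is essential: a sharp
   genuine band such as the PS ring-breathing mode at 1001 cm⁻¹ rises
   steeply enough that a plain z-score rule amputates it, whereas its flank
   differences are comparable to the neighboring ones. Flagged channels are
   replaced by the mean of unflagged channels within ±5 channels. The robust
   scale falls back to the mean absolute deviation when the median absolute
   deviation of the differences is zero (noiseless spectra).
2. **SNIP baseline** (`snip_baseline()`): iterative clipping
   $v_i \leftarrow \min(v_i, (v_{i-w} + v_{i+w})/2)$ with the window $w$
   increasing from 1 to 60 channels. Clipping is performed on the intensity
   scale. The log-log-square-root compression sometimes combined with SNIP
   was evaluated and rejected here: it makes the operator non-homogeneous
   (breaking the property that scaling a spectrum scales its baseline, on
   which mean normalization relies) and its concavity erodes curved
   baselines over many windows, misestimating a narrow peak on a linear ramp
   by ~18% where the intensity-scale clip is exact to better than 5%.
3. **Mean normalization** (`normalize_mean()`): division by the spectral
   mean, removing per-pixel intensity scale. Pixels whose baseline-corrected
   spectrum has non-positive mean cannot be normalized; they are flagged
   degenerate and excluded from unmixing.
4. **Silent-region cut** (`cut_silent_region()`): channels strictly inside
   (1800, 2700) cm⁻¹ are removed; a channel exactly at a bound is retained.
   Normalization precedes the cut, so the mean equals 1 on the full pre-cut
   axis (removing the near-zero silent channels afterwards raises the
   retained-axis mean; this is intentional and scale-free).

Unmixing:

* **N-FINDR** (`nfindr_extract()`): pixels are projected onto the first
  $k - 1$ principal components; the algorithm searches for the $k$ pixel
  spectra spanning the maximum-volume simplex, accepting single-vertex
  replacements only when the volume strictly increases, best of 5 seeded
  restarts by default. Because the determinant is linear in any one column,
  each vertex update evaluates all candidate pixels at once through the
  cofactor expansion, which also behaves correctly when the starting simplex
  is degenerate. Endmembers are actual pixel spectra (pure-pixel
  assumption); all z planes are pooled so one endmember set spans the stack.
* **NNLS abundances** (`nnls_abundances()`): per pixel,
  $\min_a \|Ea - s\|_2$ subject to $a \ge 0$, no sum-to-one constraint;
  per-pixel residual norms are kept for quality control.
* **Band images** (`band_intensity_image()`): the univariate quick look,
  mean intensity in a window (1000 cm⁻¹, width 25 cm⁻¹ by default, the PS
  aromatic ring breathing mode).
* **Identification** (`classify_endmembers()`): cosine similarity against
  the reference library; below 0.5 an endmember stays unassigned. Two
  endmembers may share a label (PS typically appears at two intensities).
  The number of endmembers $k$ is a configuration parameter rather than an
  interactive choice.

## 4. The synthetic-data generators

`make_raman_fixture()` emulates a cell scan: a water background, circular
lipid droplets and PS clusters (pure regions, guaranteeing the pure pixels
N-FINDR assumes), mixed through a reference band library. The library holds
the eight published PS bands (621, 1001, 1031, 1201, 1450, 1604, 2913,
3057 cm⁻¹), five lipid bands (1302, 1442, 1656, 2882, 2929 cm⁻¹) and the
single broad water band at 1644 cm⁻¹ (fwhm 200 cm⁻¹). Published band
*positions* are authoritative; relative intensities and widths are package
choices (PS 1001 set to 1.0, other PS bands 0.15-0.6 with fwhm 8-14 cm⁻¹,
pseudo-Voigt; lipid 1442/2882 at 0.8/1.0) that reproduce the qualitative
appearance of measured endmember spectra - tests depend only on positions.
Degradations: a random polynomial baseline (degree 3 by default, amplitude
half the signal peak), Poisson shot noise scaled so that the clean signal
peak has the target SNR (20 by default; defined against the clean peak so
the noise level does not depend on the baseline draw) plus Gaussian read
noise at 1% of peak, and single-channel positive spikes of at least 20 times
the local signal in a configurable fraction of pixels (0.5% default). The
default geometry is 50 × 50 pixels at 0.5 µm (a 25 µm × 25 µm scan) with
three z planes 1.5 µm apart.

`make_confocal_fixture()` renders 4-channel 8-bit z-stacks: elliptical DAPI
nuclei, actin rims, textured brightfield cell footprints with a dark rim
drawn at (and inside) the true cell boundary, and Gaussian bead puncta
($\sigma \approx 1$ px) planted inside cells, with total count Poisson in
(bead rate × concentration × number of cells). The bead rate per
concentration is a free parameter of the simulation, not an estimate of a
real uptake rate - no such calibration is published. Ground truth includes
nucleus labels, the projected pre-noise bead mask (at half amplitude) and
the raw pre-noise bead signal, so tests can score recall over true bead
cores and false positives over pixels that carry no bead signal at all
(each sub-resolution punctum has a faint halo between those levels that
belongs to neither class). The default field is 512 × 512 px at 0.684 µm/px
(≈350 µm field); tests use 256 × 256 or smaller frames with 4-8 cells,
which preserves all object scales in pixels.

`make_dose_response_set()` draws replicate bead-pixels-per-cell values from
a linear truth with Gaussian noise truncated at zero, at the three standard
exposure concentrations 7.81, 15.63 and 31.25 µg/cm².

Every generator requires an explicit seed and is bit-reproducible given one.

What the generators do *not* emulate: optical point-spread functions beyond
Gaussian puncta, photobleaching, instrument noise spectra, spatially
correlated autofluorescence, or cell-shape irregularity. Passing tests
therefore certify the algorithmic chain - segmentation logic, counting
rules, baseline and unmixing behavior - under controlled conditions, not
performance on real micrographs, whose thresholds the original workflow set
manually per image.

## 5. Validation experiments and problem sizes

The acceptance-style experiments in the test suite run at the following
scales, chosen as the package's standard desk-scale conditions:

* Pixel-counting exactness: 1,000 random binary masks.
* Nuclei recovery: 100 fixtures (50 THP-1, 50 A549 profile), 256 × 256 px,
  8 cells and 2 planted sub-threshold debris objects each; at least 98%
  exact-count recovery is required, which simultaneously certifies the size
  filter.
* Dose monotonicity: 30 fixtures per concentration level, strictly
  increasing mean uptake across 7.81 / 15.63 / 31.25 µg/cm².
* Unmixing recovery: 20 noiseless 20 × 20 cubes; endmember cosines ≥ 0.999
  and abundance errors ≤ 10⁻⁶ in at least 19.
* Band-position recovery (`band_recovery_experiment()`): one 50 × 50 cube
  with full degradations (SNR 20, degree-3 baseline, 0.5% spikes), full
  preprocessing, N-FINDR (k = 3, 5 restarts) and NNLS; endmembers are
  identified by correlating abundance maps with the planted layout. Sharp
  bands are read at their apex channel. The water band is located by the
  intensity centroid over 1500-1800 cm⁻¹: after 60 SNIP windows the 200
  cm⁻¹-wide hump is strongly attenuated and nearly flat-topped, so the
  argmax of a single noisy pixel spectrum wanders by ±20 cm⁻¹ while the
  centroid is stable to ~2 cm⁻¹. The lowest detected PS band (prominence
  ≥ 10%) sits within one channel of 621 cm⁻¹ in most runs; apex noise at
  SNR 20 occasionally shifts it one further channel.
* Statistics calibration: 10,000 null t-tests and 500 CI-coverage
  simulations.

## 6. Numerical choices and degenerate inputs

* Wavenumber grid: 600-3100 cm⁻¹ at 2 cm⁻¹. 1001 cm⁻¹ falls between
  channels; its apex reads as 1000 or 1002.
* "25 µm at 0.5 µm steps" is resolved as 50 pixels (area divided by step),
  not 51.
* All-zero spectra, flat cubes and empty masks raise typed conditions or
  return empty results rather than NaN.
* A field with zero detected nuclei yields an invalid record with a warning
  (the ratio is undefined), never a division by zero.
* Cube containers: long CSV (text, order-independent, exact to 10⁻⁹) and
  RDS (bit-exact); TIFF for image stacks and masks.
* The t-test refuses two constant groups with different means (no finite
  statistic exists); equal constants return $p = 1$.

## 7. Known limitations

The original study set fluorescence thresholds manually per image and chose
the endmember count interactively; neither the exact thresholds nor the raw
data are published, so reproduction of the study's absolute uptake
magnitudes is out of reach and not attempted - the package validates the
method's properties instead. Abundances are qualitative (no sum-to-one
constraint, no particle counts). Segmentation assumes roughly convex,
non-confluent cells; heavily confluent layers would need different cell-area
logic.
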