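# psuptake

Quantification of polystyrene (PS) nanoparticle uptake by cultured cells
from two complementary imaging modalities:

* **Confocal fluorescence**: fluorescent beads of ~200 nm are below the
  resolution limit and cluster inside cells, so uptake is measured as the
  *area* of above-threshold bead fluorescence per cell. From a multi-channel
  z-stack the package computes, per field of view,

  ```
  bead pixels      = (image size in px / 255) x mean gray value of the binary bead mask
  bead px per cell = bead pixels / number of nuclei in the field
  ```

  via maximum-intensity z-projection, DAPI nuclei segmentation (Gaussian
  blur sigma 3, threshold, watershed, area and circularity filters with
  cell-line profiles: 20 um^2 minimum for THP-1, 10 um^2 for A549/CaCo-2),
  cell-area masking from the actin channel (brightfield Canny/morphology
  fallback) and a bead threshold calibrated on unexposed control fields.
  Dose-response statistics (two-sided unpaired t-tests, linear regression
  with 95% confidence bands) complete the workflow.

* **Raman microspectroscopy (label-free)**: hyperspectral image scans are
  preprocessed per pixel - cosmic-spike removal, SNIP baseline correction,
  mean normalization, excision of the 1800-2700 cm^-1 silent region - and
  unmixed under the linear mixing model: N-FINDR extracts the k pixel
  spectra spanning the maximum-volume simplex (pure-pixel assumption), NNLS
  computes non-negative abundance maps, and endmembers are identified
  against a reference band library (PS: 621, 1001, 1031, 1201, 1450, 1604,
  2913, 3057 cm^-1; lipid: 1302, 1442, 1656, 2882, 2929 cm^-1; water: broad
  1644 cm^-1). Univariate band images (1000 cm^-1, width 25 cm^-1) provide
  the quick look.

Because raw micrographs and spectra for studies of this kind are rarely
deposited, the package ships first-class synthetic-data generators
(`make_confocal_fixture()`, `make_raman_fixture()`,
`make_dose_response_set()`) with complete ground truth, and every pipeline
stage is validated against planted truth.

It is aimed at microscopy and spectroscopy practitioners studying
nanoparticle or microplastic uptake who want a scripted, testable version of
what is usually an interactive Fiji + vendor-software workflow.

## Worked example

Simulate an exposed field of view and quantify it:

```r
library(psuptake)

fx <- make_confocal_fixture(width = 256, height = 256, n_cells = 8, nz = 3,
                            concentration = 31.25, cell_line = "THP-1",
                            seed = 42)
quantify_fov(fx$stack, segmentation_params(cell_line = "THP-1"),
             bead_threshold = 100, cell_line = "THP-1",
             concentration = 31.25, time_h = 24, replicate = 1)
#> # A tibble: 1 x 10
#>   bead_pixels n_nuclei bead_px_per_cell bead_area_um2 fov_area_um2 cell_line ...
#> 1         427        8             53.4          200.       30661. THP-1
```

All 8 planted nuclei are found; 427 bead pixels (200 um^2) give 53.4 bead
pixels per cell at 31.25 ug/cm^2. A dose-response across the three standard
concentrations:

```r
dose <- make_dose_response_set(truth_slope = 2, truth_intercept = 5,
                               noise_sd = 4, n_replicates = 6, seed = 42)
fit <- fit_dose_response(dose)
fit
#> <dose_fit> slope 1.781 [1.556, 2.007] bead px per cell per (ug/cm^2), R^2 = 0.946
tidy(fit)        # broom-style coefficients with CIs
autoplot(fit)    # points, fit line, 95% confidence band
```

The planted slope 2 lies inside the 95% CI [1.56, 2.01]. The full Raman
pipeline on a degraded synthetic scan (peak SNR 20, degree-3 baseline, 0.5%
cosmic spikes):

```r
ex <- band_recovery_experiment(seed = 42)
round(ex$positions, 1)
#>   ps_main_band ps_lowest_band     lipid_band     water_band
#>         1002.0          622.0         1654.0         1646.7
classify_endmembers(ex$endmembers)$labels
#> [1] "lipid"       "polystyrene" "water"
```

The recovered polystyrene endmember peaks at 1002 cm^-1 (ring breathing,
true position 1001 on a 2 cm^-1 grid) with its lowest band at 622 cm^-1
(ring deformation, 621); the lipid endmember at 1654 cm^-1 (C=C stretch,
1656) and the water endmember's broad hump at 1646.7 cm^-1 (H-O-H bend,
1644) - all within one to two channels of the reference positions.

A thin command-line wrapper (`inst/cli/psuptake.R`, subcommands
`synth-fluor`, `synth-raman`, `fluor-quantify`, `raman-unmix`, `report`)
exposes the same functions for shell pipelines.

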