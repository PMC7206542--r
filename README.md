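# saxsred

Data reduction for high-throughput solution X-ray scattering (SAXS/WAXS) on
pixel-array detectors, written for beamline-style pipelines: many samples,
automated buffer subtraction, and in-line size-exclusion chromatography
(SEC-SAXS).

The package covers:

- **Geometry**: pixel → (q, azimuth) mapping for normal-incidence detectors,
  q = (4π/λ) sin θ with 2θ = arctan(r/D), and sample-to-detector distance
  calibration against silver behenate powder rings.
- **Reduction**: azimuthal averaging by q-histogramming with Poisson error
  propagation, multi-detector merging scaled strictly by the solid-angle
  ratio (D/D_ref)², frame averaging with outlier exclusion, ASCII export and
  a bit-exact plain-text data bundle.
- **Buffer subtraction** anchored on the water scattering peak at
  q ≈ 2.0 Å⁻¹: the buffer is scaled by the sample/buffer peak-height ratio,
  which needs no knowledge of protein concentration. A small adjustment
  (< 0.5% in practice) absorbs the protein's minute positive contribution
  under the peak; over-subtraction and anomalous scales are flagged as
  delivery-error indicators. Iterative Guinier fitting (q·Rg ≤ 1.3) gives
  I(0) and Rg.
- **SEC-SAXS**: X-ray chromatograms over user q-ranges, 2D (q × time) maps,
  UV/X-ray split-flow offset alignment, and background removal in normal
  mode (averaged buffer frames) or SVD mode — decompose the non-sample
  frames, interpolate each significant component's time coefficients across
  the elution window, and subtract the reconstructed drifting background.
- **Synthetic data**: phenomenological water background, sphere and
  Guinier–Porod form factors, Poisson-rendered detector images, SEC runs
  with linear baseline drift, and an ideal-mixing flow-cell broadening
  model.
- **Operations calculators**: absorbed dose (static and flowing), PEEK
  tubing volume/transit, dual-channel measurement scheduling, sample-sheet
  validation, and liquid-front arrival detection.

## Worked example

```r
library(saxsred)

# 1. Reduce a (synthetic) WAXS image to I(q)
geom <- xs_geometry(distance = 300, beam_center = c(0, 0), pixel_size = 0.7,
                    shape = c(256, 256), energy = 13.5, label = "waxs")
img  <- render_detector_image(function(q) water_intensity(q, amplitude = 500),
                              geom, seed = 7)
prof <- azimuthal_average(img, n_bins = 690)
print(prof)
#> <xs_profile> 690 bins (1 empty), q in [0.003398, 4.685] 1/A
#>   I in [89.5, 604.5]  [waxs]

# 2. Buffer subtraction for a 5 mg/ml protein solution (phi = 0.365%)
q        <- seq(0.01, 2.5, length.out = 690)
buffer   <- water_profile(q)
solution <- solution_profile(buffer, function(qq) 0.02 * sphere_intensity(qq, 20),
                             concentration = 0.005, specific_volume = 0.73)
sub <- subtract_buffer(solution, buffer, auto_adjust = TRUE)
print(sub)
#> <xs_subtraction> base scale 0.99635, adjustment -0.0010% -> scale 0.99634
#>   flags: over_subtraction=FALSE large_adjustment=FALSE delivery_error_suspected=FALSE

# 3. Radius of gyration of the recovered protein signal (sphere R = 20 A)
print(guinier_fit(sub$profile))
#> Guinier fit: I(0) = 0.02006, Rg = 15.789 A (21 points, q in [0.01, 0.08228], max qRg = 1.30)

# 4. Instrument numbers at the typical operating point
dose_static(beam_conditions())         # 3.31 kGy for a 1 s static exposure
schedule_sim(90, 60, 360, 2)$makespan_h  # 9 h for a full 20-holder magazine
```

Reading the numbers: the rendered water image peaks at 2.0 Å⁻¹ after
azimuthal averaging; the solution's water peak sits 0.365% below the
buffer's because 5 mg/ml of protein at 0.73 ml/g displaces that volume
fraction of water — comfortably inside the 0.5% adjustment bound — and the
subtracted profile Guinier-fits to Rg ≈ 15.8 Å, close to the R√(3/5) =
15.5 Å of the generating 20 Å sphere.

A thin command-line front end over the same functions is installed at
`inst/cli/saxsred.R` (subcommands `dose`, `throughput`, `tubing`,
`validate-sheet`, `reduce`, `export`, `subtract`, `sec-process`,
`simulate-image`).

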