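---
title: "Methods: solution scattering reduction, buffer matching and SEC-SAXS background removal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: solution scattering reduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Scope

`saxsred` implements the data-reduction chain of a high-throughput
solution-scattering beamline: mapping pixel-array detector images to
reciprocal space, azimuthal averaging, distance calibration against powder
standards, merging of simultaneously exposed SAXS/WAXS detectors, buffer
subtraction anchored on the liquid-water scattering peak, and in-line
SEC-SAXS processing with either averaged-buffer-frame or SVD-based removal
of time-dependent background. It also ships the synthetic-data generators
the test suite runs on, and a set of instrument-performance calculators
(radiation dose, fluidics, dual-channel scheduling, sample-sheet
validation). Hardware control, absolute intensity calibration and
downstream structural analysis (P(r), envelope reconstruction) are out of
scope.

# Geometry and azimuthal averaging

Each pixel at radial distance $r$ from the beam center on a
normal-incidence detector scatters at $2\theta = \arctan(r/D)$, giving

$$q = \frac{4\pi}{\lambda}\sin\theta, \qquad \lambda = \frac{12.3984}{E\,[\mathrm{keV}]}\ \mathrm{\mathring{A}}.$$

Conventions that had to be fixed (they are not dictated by the physics):
pixel indices are 0-based `(row, column)` with rows increasing downward;
the azimuth is 0° along the +column axis, counter-clockwise positive, in
[-180°, 180°). Only normal-incidence detectors are modelled; a tilt flag is
rejected with an error rather than silently approximated.

Azimuthal averaging is histogramming on the q grid: each bin takes the
plain mean of its valid pixels' counts. No solid-angle or polarization
re-weighting is applied *within* a detector; the only geometric scaling is
the inter-detector factor $(D/D_\mathrm{ref})^2$ applied when merging,
which is exact for detectors built from identical modules. A possible
consequence is a small systematic curvature at the outer edge of a
short-distance detector (q above roughly 2.5 1/Å); none of the quantities
this package anchors on (water-peak height ratios, low-q profiles) are
sensitive to it.

Counting statistics: photon-counting detectors make raw counts Poisson, so
the per-pixel variance is taken as `max(counts, 1)` (the floor keeps empty
pixels from claiming zero uncertainty) and the bin variance is the summed
pixel variance over $n^2$. Bins with no pixels carry an explicit empty
flag, never a zero. The default grid is 690 linear bins over the detector's
q span — a bin count chosen to resolve the water peak and Guinier region
comfortably on the detector sizes used here; it is configurable everywhere.

Distance calibration locates the rings of a powder standard (silver
behenate, fundamental spacing 58.38 Å, harmonics d/n) in the 1-pixel-bin
radial profile, refines each ring position by quadratic interpolation
around the maximum, and least-squares fits $D$ so that predicted radii
$D\tan 2\theta_n$ match. Rings are searched within ±20% of the radius
predicted from the starting distance, and accepted only if the peak stands
more than 5 robust sigmas above the window median — a pure-noise image
therefore fails loudly instead of returning a number. The render-then-fit
round trip on noiseless rings recovers the distance to better than 0.1%.

# Buffer subtraction at the water peak

The broad liquid-water maximum near q = 2.0 1/Å is used as an internal
intensity reference: the buffer profile is scaled by the ratio of
sample-to-buffer water-peak heights before subtraction. The height
estimator smooths the curve with a 5-bin moving average and fits a
quadratic, linearly in intensity, to the top 20% of points inside the
window (default 1.8–2.2 1/Å; the exact production window is not published,
so it is configurable). Linearity in intensity matters: it makes the
sample/buffer ratio exact under common rescaling, and any baseline shared
by the two nearly identical curves cancels in the ratio, so no baseline is
subtracted under the peak.

Because the protein contributes a minute but strictly positive amount at
2 1/Å, exact peak matching slightly over-subtracts. The conventional remedy
is a small manual adjustment of the scaling factor, under 0.5% in practice;
the `large_adjustment` flag marks anything beyond that bound. The optional
automated mode searches, by bisection to 1e-5, the smallest-magnitude
adjustment that restores the positivity criterion — necessarily a downward
tweak of the scale, which is why the search runs over non-positive
adjustments.

Validation follows the "positive and smoothly varying" expectation:
`over_subtraction` is raised when more than 1% of bins inside the check
ranges fall below $-3\sigma$. The check ranges are the water-peak window
plus q < 0.3 1/Å rather than the full range, because detector seams and
merge edges can produce benign artifacts in between. A smoothness score
(mean |second difference| / sigma) is reported but not thresholded — no
quantitative criterion exists to calibrate one against. The
`delivery_error_suspected` flag fires on over-subtraction or on a base
scale deviating more than 2% from unity: a genuine dilute solution can only
move the scale by its excluded volume fraction (0.365% at 5 mg/ml and
0.73 ml/g), so a several-percent deviation indicates bubbles, insufficient
sample, or a mismatched buffer. Notably, a *purely proportional* deficit
(sample exactly 0.95 × buffer) cancels in the subtraction and can only be
caught by the scale rule; visible negativity requires a water-independent
additive component such as cell-window scattering, which is how the test
suite constructs the failure case.

The Guinier fit iterates the standard rule: fit $\ln I$ against $q^2$ over
the largest low-q range with $q R_g \le 1.3$, re-selecting until the range
is self-consistent. Non-positive low-q intensities or a non-negative slope
abort with an error rather than returning a fabricated radius.

# SEC-SAXS background removal

A SEC run is a matrix of frame profiles on a common q grid plus UV/RI
traces from the split flow. Chromatograms are per-frame means over
user-chosen q ranges; ranges with different q weighting discriminate
species by size. The UV-to-X-ray time offset caused by the unequal split
flows is recovered by maximizing the cross-correlation between the UV
trace (resampled to frame times) and the low-q X-ray chromatogram over
lags on the frame grid; both series are linearly detrended first so that a
drifting baseline cannot masquerade as correlation, and a peak correlation
below 0.5 yields a warning and a zero offset instead of a spurious lag.

Normal-mode background is the inverse-variance average of user-selected
buffer frames. SVD mode handles drifting backgrounds: the frame matrix
*excluding* the declared sample window is decomposed, the significant
components retained (auto rule: singular values at least 1% of the
largest, capped at 5 — "first few significant" made concrete and
configurable), and each component's time-coefficient series (singular
value times right singular vector) interpolated across the window. The
interpolation of scalar singular values alone cannot produce a
time-dependent background, so the coefficient-series reading is the one
implemented. Interpolation is a GCV cubic smoothing spline by default with
a linear fallback for short runs; both are exposed because the production
choice is unpublished, and for an exactly linear drift both reproduce a
noiseless rank-1 background to machine precision. The model provably never
uses window frames: perturbing them leaves the background bit-identical,
which the suite asserts. The regime validated by the generator is a drift
that is slow relative to the elution peak; strongly overlapping drift and
elution timescales are outside any claim made here.

# Synthetic data generators

The water background is phenomenological — a flat term plus a Gaussian peak
at $q_0 = 2.0$ 1/Å (width 0.3 1/Å, baseline 20% of the amplitude). It
reproduces the one property the pipeline relies on (a dominant, well-defined
peak whose height scales linearly with the water amount) and nothing else;
it is *not* a physical water structure factor, and passing tests say
nothing about absolute water scattering levels. Protein terms use the
analytic dilute-sphere form factor and a Guinier–Porod model. Detector
images are rendered by evaluating a 1D model at each pixel's q and
Poisson-sampling, deterministically for a fixed seed and without touching
the caller's RNG stream; an optional reference-distance argument adds the
$(D_\mathrm{ref}/D)^2$ solid-angle factor so multi-distance renders merge
consistently.

SEC runs are frames $b(t) I_w(q) + \sum_s c_s(t) P_s(q)$ with a linear
drift $b(t) = 1 + \alpha t$ (sign free; $\alpha = 0.001\,\mathrm{s^{-1}}$
over a 1200 s run takes the buffer level to 2.2× its start), Gaussian
elution peaks (exponentially modified tailing available but off by
default), Poisson noise at a counting scale of ~500 expected counts at the
water peak per 1 s frame — realistic shot noise for a pixel-array WAXS
detector — and a UV trace delayed by the split-flow offset (default 30 s).
Dilute solutions are built as $(1-\varphi)\,\mathrm{buffer} + P(q)$ with
$\varphi = c\,\bar v$; at the 5 mg/ml, 0.73 ml/g defaults
$\varphi = 0.365\%$, which is what keeps the required scale adjustment
under the 0.5% practice bound. The flow cell is modelled as an ideal
mixing volume: a rectangular injection plug (duration = load volume /
flow rate) convolved with the column's Gaussian kernel and an exponential
kernel of time constant cell volume / flow rate; the closed form for the
zero-cell-volume limit anchors the numerics.

What the generators do *not* emulate: inter-particle structure factors,
radiation-damage evolution, non-Poisson detector artifacts (module gaps,
flat-field error), realistic water S(q), or partially overlapping
drift/elution timescales. Green tests demonstrate internal consistency of
the algorithms under the stated noise model, not agreement with any real
beamline dataset.

# Instrument-performance models

The static dose is absorbed energy over illuminated mass:
$\Phi E_\gamma (1 - e^{-\mu_{en}\rho t})\,t_\mathrm{exp} / (\rho A t)$,
with water $\mu_{en}/\rho$ log-log interpolated from the NIST
(Hubbell–Seltzer) values at 10/15/20 keV. At the default conditions
(2.3e12 ph/s, 13.5 keV, 0.5 × 0.5 mm, 1.5 mm path, 1 s) this gives
3.31 kGy. The flowing dose spreads the same energy over the flowed plus
initially illuminated volume; this reading is attached to every result as
an explicit assumption string because the normalization is genuinely
ambiguous — plausible readings differ by ~50% — and the static number is
the quantitative anchor.

The dual-channel scheduler is a small event simulation: a sample's
load/measure/return block needs both the beam and a clean channel; washing
frees the channel afterwards. With two strictly alternating channels the
steady-state cycle is max(measure, wash) when wash ≤ measure (90 s at the
typical 90/60 s timings, 40% below the 150 s sequential cycle, 9.0 h for
360 samples) and (measure + wash)/2 when wash dominates, where the beam
idles — the simulation, not a formula, is authoritative. Holder-exchange
overhead is off by default and configurable.

Sample sheets are ingested from CSV (a holders table and an optional
holder-to-slot storage table) and validated for duplicate names, missing
buffers, sample/buffer channel mismatches, duplicate or out-of-range
positions and slot conflicts; the violation set is canonical (sorted) and
independent of row order. Sample arrival in the camera statistic is the
first run of at least 2 consecutive points above median + 6 MAD — the
sustain rule rejects single-frame glitches.

# Problem sizes and numerical choices

The test suite and acceptance checks run on deliberately modest problem
sizes chosen as the smallest that exercise each property cleanly: detector
renders of 48–256 px squared, 150–690 q bins, SEC runs of 120–601 frames
on 60–500 q bins, and 100-seed Monte-Carlo loops for distributional
checks. Weighted averages guard zero uncertainties by capping weights
(sigma floored at 1e-150) so that noiseless profiles combine exactly
instead of overflowing. Ties in the UV lag search resolve to the smallest
|lag|. The SEC generator's default q grid (500 bins over 0.005–2.5 1/Å)
is fine enough at low q for Guinier analysis of proteins up to roughly
Rg ≈ 45 Å at qRg ≤ 1.3.

# Known limitations

- No polarization, flat-field, parallax or in-detector solid-angle
  corrections; no absolute calibration to cm⁻¹.
- Only normal-incidence detector geometry.
- The bundle is a plain-text directory format, chosen for portability and
  inspectability; it stores full double precision and round-trips
  bit-exactly, but is not a standard binary container.
- The water model is phenomenological; quantities that depend on the true
  water structure factor (e.g. absolute scaling by water) are out of
  scope.
- Elution-peak deconvolution into species (evolving factor analysis and
  related methods) is deliberately not implemented.
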