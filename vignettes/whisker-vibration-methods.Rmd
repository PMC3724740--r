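---
title: "Models and methods behind whiskvib"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind whiskvib}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(whiskvib)
```

## The scientific problem

Pinniped whiskers (vibrissae) are hydrodynamic sensors. When a seal or sea
lion swims, water flowing past each whisker sheds alternating vortices that
drive the shaft into vibration — self-noise that competes with the
hydrodynamic signals the animal is trying to detect. Two structural traits
plausibly shape this self-noise: the surface profile of the shaft (smooth
in sea lions and walrus, undulated with repeating crests and troughs in
most true seals) and the flattened, elliptical cross-section that all
pinniped vibrissae share. Because the section is flattened, the whisker has
a thin edge and a broad face, and the angle of attack — which of the two
faces into the flow — changes the stream-wise diameter that sets the scale
of the wake.

`whiskvib` implements the full analysis chain of a flume study of this
system: cross-sectional morphometry of CT-scanned whisker shafts, spectral
analysis of laser-vibrometer recordings at three angles of attack (0°,
45°, 90°), an empirical vortex-shedding frequency model, and the
mixed-design group statistics. Because the original specimens are not
available, the package also generates all three kinds of input as
synthetic data with known ground truth, so every stage of the chain can be
validated end to end.

## Whisker phantoms

`whisker_spec()` describes a parametric whisker: an elliptical
cross-section swept along a shaft of length $L$, with

* an area taper $A(s) = A_0\,(1 - 0.2\,s/L)^{p}$ ($p = 2$ by default,
  giving a 36% base-to-tip reduction),
* eccentricity ramping linearly from base to tip (the section flattens
  toward the tip),
* for the undulated archetype, a sinusoidal modulation of the major
  semi-axis, $a(s) = a_0(s)\,(1 + \alpha \sin(2\pi s/\lambda))$, with the
  minor semi-axis set to $b(s) = A(s)/(\pi a(s))$ so the undulation leaves
  the area profile untouched — the defining geometric observation for
  undulated vibrissae is exactly this: caliper width oscillates while area
  stays on the taper curve,
* a principal-axis angle profile $\theta(s)$: 0 for the undulated
  archetype (flattening in-plane with the shaft's major curvature) and a
  15° offset for the smooth archetype (in sea lions the flattened profile
  is rotated off the curvature plane by roughly 10–20°).

The default taper is deliberately gentler than a real whisker's taper to a
point. Two considerations fix it: every section must stay at least a few
voxels thick at the 30 µm scan resolution (the generator rejects specs
that fall below 3 voxels), and the area signal must be locally flat
relative to the undulation so that the area-conservation property (area CV
under 1% across one wavelength) is a property of the geometry rather than
an artifact of window placement. Undulation wavelength and relative
amplitude are not reported numerically anywhere we could anchor them; the
defaults (λ = 3 mm, α = 0.2) were chosen once to visually match published
profile plots and are flagged as package choices, not measured values.

`generate_phantom()` voxelizes the spec at an isotropic voxel size
(default 30 µm, as in the study's micro-CT protocol) with the whisker
"lying flat on a slide": the slide plane contains the shaft axis and the
in-slice horizontal, and θ is measured from that horizontal. By default
the centerline is straightened along the slice axis so that every axial
slice is a true perpendicular cross-section and the analytic ground truth
is exact slice-for-slice; `bend = "slide"` instead bows the centerline at
the spec's curvature radius inside the slide plane, emulating raw
scanner-axis slices of a curved specimen. Whether the original analysis
sliced perpendicular to the local axis or along the scanner axis is not
stated; the perpendicular reading is the default because it makes ground
truth exact. The undulation must never swap the major and minor axes
(otherwise "max caliper" would jump between orthogonal directions), which
requires $(1-\alpha)^2 > b_0(s)/a_0(s)$ everywhere; specs violating this
are rejected, and the default undulated eccentricities (0.80 base, 0.95
tip) leave the default α = 0.2 valid.

## Morphometry

`profile_along_shaft()` re-implements the cross-sectional analysis
pipeline: each slice is thresholded (Otsu by default, fixed threshold as
an option — the original tooling's choice is unstated), reduced to its
largest connected component, hole-filled, and measured:

* **Caliper (Feret) widths** — extents of the convex hull of foreground
  pixel centers projected onto directions swept over [0°, 180°) in 0.5°
  steps, plus one pixel spacing for the pixel footprint (this makes a
  digitized disc of diameter $n$ pixels measure $n$ pixels, unbiased).
  The 0.5° step contributes an error of order $W\theta_{step}^2/2 \approx
  10^{-5} W$, far below voxel quantization for sections under a few
  hundred pixels across.
* **Theta** — the principal-axis angle from second central image moments,
  $\theta = \tfrac12\,\mathrm{atan2}(2\mu_{11},\, \mu_{20}-\mu_{02})$,
  mapped to (−90°, 90°]. When the moment anisotropy is below a relative
  tolerance the orientation is undefined (circular section) and θ is
  reported as 0 with a flag. Orientation accuracy is quantization-limited
  for small or near-circular sections — the validation suite uses
  sections at least ~18 pixels in semi-axis and axis ratios below 0.8,
  which is where whisker shafts live at 30 µm.
* **Eccentricity** — $e = \sqrt{1 - (\text{min}/\text{max})^2}$ from the
  caliper pair: 0 for a circle, approaching 1 for a flattened section.

Profiles run base to tip, with the base fixed as the largest-area end.
`detect_crests_troughs()` finds interleaved local extrema of the max
caliper series (prominence at least 5% of the series median by default),
and `area_consistency_stat()` quantifies the area-vs-caliper contrast at
those extrema after removing the taper with a local linear fit.

At 30 µm voxels the recovered calipers track the analytic ground truth to
about one voxel, and halving the voxel size roughly halves the worst-case
error; both behaviours are asserted in the test suite.

## Spectral analysis

Recordings are single-point velocity series sampled at 1200 Hz for 6 s.
`averaged_fft()` follows the minimal reading of the published processing —
"FFT averaging with a 240-point FFT, 5 Hz resolution": consecutive
non-overlapping 240-sample segments (the remainder discarded), a
single-sided amplitude spectrum per segment scaled so an on-bin sinusoid
of amplitude $A$ reads $A$ at its bin, amplitudes averaged across the 30
segments. The window is rectangular by default (no windowing is
mentioned); Hann is available as an option. Amplitudes, not powers, are
averaged because the published spectra are in velocity units.
`peak_pick()` takes the arg-max over bins, always excluding DC and
optionally excluding a band — 0–50 Hz rejects the sting-mount artifact,
whose band does not overlap the whisker tones. Ties break toward the lower
frequency. `segment_quality_filter()` drops segments whose RMS falls below
a fraction (default 0.25) of the median segment RMS, mirroring the
study's practice of averaging fewer spectra for recordings with dropout
stretches; the criterion they actually used is unstated, so the RMS rule
is this package's own.

The synthetic recording generator composes a deterministic tone (plus
optional harmonics), the sting artifact, and white Gaussian noise. The
sting artifact is a random-phase multisine on a 5 Hz grid with a Gaussian
spectral envelope (mode 15 Hz, width 5 Hz, hard-zeroed above 50 Hz),
scaled so its spectral peak is 0.005 m/s — the rig's reported
characteristics. Gridding the components onto the analysis bins means
every segment sees them on-bin, so the artifact's energy is exactly zero
above 50 Hz in the averaged spectrum; a continuous-spectrum artifact
would leak past the band edge through the rectangular segment window and
contaminate weak whisker tones, which is a property of the analysis
window, not of the rig being emulated.

## Shedding-frequency model

For a bluff cylinder of stream-wise diameter $d$ in flow $U$, the wake
sheds vortices at $f = \mathrm{St}(\mathrm{Re})\,U/d$ with
$\mathrm{Re} = Ud/\nu$. The Strouhal number follows the classical
empirical cylinder-wake fits: $\mathrm{St} = 0.212 - 4.5/\mathrm{Re}$ on
the laminar branch (Re 50–150) and $\mathrm{St} = 0.212 - 2.7/\mathrm{Re}$
on the turbulent branch (Re 300–2000). The transition range in between is
irregular in the source literature; the package blends the two branches
linearly across Re 150–300, keeping the map total and continuous (the fit
constants are arguments, so other calibrations can be substituted). The
defaults are $U = 0.5$ m/s (the flume speed) and $\nu = 10^{-6}$ m²/s
(fresh water near 20 °C; the flume temperature is unstated). Requests
outside Re 50–2000 raise an out-of-range error rather than extrapolate.

At 0° the thin edge faces the flow, so $d$ is the section's minimum
caliper; at 90° it is the maximum. Larger $d$ means higher Re and lower
$f$, which is the mechanism behind the study's headline ordering: peak
frequency is highest at 0° and falls as the whisker rotates to 90°. For
undulated whiskers the crest and trough nearest the reference section
bound $d$, so the prediction is an interval; its midpoint serves as the
single group-comparable number (how the original analysis combined the
two is unstated). The reference section defaults to half the total arc
length, with an area-weighted (volumetric) centroid as the alternative
reading of "measured at the centroid". The 45° orientation is never
predicted — the profile facing the flow is an angled plane there — and
the model predicts only frequency, not velocity.
`percent_difference()` compares measured against theoretical frequency as
$100\,|f_m - f_t|/f_m$ (the measured value is the denominator, so the
statistic is asymmetric by convention).

## Group statistics

The study design is mixed: species (sea lion, elephant seal, harbor seal)
varies between subjects, angle of attack within subjects. Subjects missing
any angle are removed wholesale (`enforce_complete_cases()`), reproducing
the published retained sample of 8/8/6 subjects. `mixed_anova()`
decomposes the total sum of squares into species (from subject means,
group-size weighted), subjects-within-species, angle, species × angle,
and the angle × subject residual; species is tested against
subjects-within-species, everything else against the residual — the
convention that reproduces the published (DFn, DFd) pairs (2, 38), (2,
19), (4, 38), (19, 38) for the 8/8/6 × 3 layout. No sphericity correction
is applied (none is reported). The implementation is validated against
`aov()` error-stratum fits on random unbalanced layouts, and its angle
test holds the nominal 5% type-I rate in a 2000-replicate null simulation.

`tukey_within_species()` compares the three angle pairs within each
species, using the pooled within-subject residual MS and its 38 degrees
of freedom in the studentized-range distribution with the species' own
subject count — the single-error-term reading consistent with the
published post-hoc tables. `length_regression()` is an ordinary
least-squares fit of a measurement on whisker length in cm.

## Synthetic study tables and the pipeline

`study_design()` carries the per-cell means and standard errors of the
published measurement tables (the package defaults), the subject counts,
and a reference count per species stating the $n$ at which each SE was
reported. The implied between-subject SD in a cell,
$\mathrm{SE}\sqrt{n_{\mathrm{ref}}}$, splits into a subject effect shared
across that subject's angles and an independent residual. Draws are
Gaussian and not truncated, so generated cell means converge exactly to
the design means as cohorts grow — this preserves, for instance, the
elephant-seal 90°/0° velocity mean ratio of 0.1745/0.0029 ≈ 60, the
"60 times" headline — at the cost that a velocity draw in a
low-mean/high-SD cell can occasionally be negative in the far tail.

`run_study()` ties everything together deterministically under one seed:
phantom per species → morphometry profile → shedding predictions at
0°/90°; design-driven per-subject tone frequencies and amplitudes →
synthetic recordings → segment filtering → averaged spectra → peak
extraction; then complete-case enforcement, group summaries with
theoretical frequencies and mean percent differences, ANOVAs, Tukey
tables, and length regressions, all written as CSV artifacts. Tone
frequencies snap to the 5 Hz bin grid by default, so spectral recovery is
exact rather than scalloped, and amplitudes are floored at 0.1 mm/s so
every recording carries a recoverable tone. With
`tone_source = "theory"` the tones are instead set to the shedding
predictions themselves, closing the loop: the pipeline's
measured-vs-theoretical percent difference then collapses to bin
quantization (≲1.5%), an end-to-end correctness oracle that real specimen
data cannot provide. A `mismatch_hz` knob injects a known discrepancy when
one is wanted.

## What the synthetic data do and do not establish

The generators emulate the study conditions — sampling rates, record
lengths, angles, cell means and SEs, sting characteristics, CT voxel
size — but they are idealizations: elliptical sections with a single
sinusoidal undulation, Gaussian noise, tones rather than broadband
vortex forcing, no fluid–structure interaction, no scanner greyscale
calibration. Passing tests therefore establish that the analysis chain is
correct (it recovers known ground truth and holds its nominal error
rates), not that the biological conclusions would replicate on new
specimens. Published group means, Tukey differences, regression
coefficients and percent differences depend on the original specimens and
are deliberately not reproduction targets; the direction-of-effect and
structural properties are.

## Problem sizes and numerical choices

Test phantoms are 6–12 mm long at 30 µm voxels (a few hundred slices);
pipeline phantoms default to 40 mm. The null-calibration simulations use
2000 replicates (acceptance) and 400–500 (unit). Caliper sweeps step 0.5°.
Moment-based orientation flags sections as circular below a relative
anisotropy of 10⁻³. Segment dropout threshold is 0.25 of the median RMS.
Sums-of-squares differences are clamped at zero to absorb floating-point
cancellation in degenerate (constant-cell) tables. All randomness flows
from explicit integer seeds; identical seeds give byte-identical pipeline
artifacts.
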