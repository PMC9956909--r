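---
title: "Quantifying mouse retinal structure and function: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mouse retinal structure and function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retscreen)
```

`retscreen` implements the quantitative core of a high-throughput mouse
vision screen built on two complementary instruments: optical coherence
tomography (OCT), which images the layered structure of the retina in
cross-section, and the full-field electroretinogram (ERG), which records
the retina's summed electrical response to calibrated light flashes. The
screen is two-staged: OCT is the primary examination of every eye, and ERG
follows only for eyes whose structural findings justify it. This vignette
explains the models and measurement rules the package implements, the
synthetic data that exercises them, and the design choices made where the
underlying procedures left details open.

## The ERG measurement model

A flash ERG epoch contains a baseline segment, the flash at time zero, a
fast negative deflection (the a-wave, photoreceptor-driven) and a slower
positive deflection (the b-wave, ON-bipolar-cell-driven). The package
follows the standard clinical measurement convention:

* the **baseline** is the mean of the 10 ms of signal immediately
  preceding the flash (10 samples at the 1024 samples/s instrument rate);
* the **a-wave amplitude** is measured from baseline down to the local
  minimum after the flash; the **b-wave amplitude** from that trough up to
  the subsequent local maximum;
* **implicit times** are the latencies of the two extrema from flash
  onset.

Raw sweeps are band-pass filtered between 1 and 300 Hz and the 20 repeats
of each flash strength averaged before measurement. The filter is realized
as a cascade of a 4th-order Butterworth high-pass (1 Hz) and low-pass
(300 Hz), each applied forward and backward (`signal::filtfilt`), so the
pass band is the stated one and the filter contributes no group delay —
implicit times must not be biased by the preprocessing. A single 4th-order
band-pass with a 1 Hz lower edge at a 1024 Hz sampling rate places poles
essentially on the unit circle and is numerically fragile in double
precision; the cascade is equivalent for this purpose and stable.

Three details are deliberate choices rather than given procedure, and are
configurable through `erg_config()`:

* **Search windows.** The a-trough is sought 3–50 ms post-flash and the
  b-peak from the a-trough to 150 ms. Windowing makes the "local minimum"
  rule well defined on noisy traces; the defaults bracket the normal mouse
  implicit-time range (a ≈ 13–18 ms, b ≈ 33–47 ms) with a wide margin.
* **Detection rule.** The noise level is estimated as the SD of the
  baseline window, and a wave counts as detected only when its excursion
  exceeds 3× that estimate. This reproduces the practice of omitting
  implicit times of responses near the noise floor: an undetected wave
  carries no implicit time. Note that the maximum of ~50 noise samples
  exceeds 3 baseline SDs more often than a single-sample 3-sigma rule
  would suggest, so occasional spurious "detections" of tiny amplitudes
  are expected on null signals; amplitudes remain at the noise floor.
* **b-wave fallback.** When no a-trough is detected (a pure positive
  response), the b-wave is measured from baseline instead and the result
  labelled `b_reference = "baseline"`. Exact ties between extremum
  candidates resolve to the earliest sample.

## The synthetic ERG generator

The generator exists so that every analysis stage can be tested against a
known ground truth. Component amplitudes follow the Naka–Rushton
(Hill) saturating intensity–response function standard in retinal
physiology,

$$A(I) = A_{max}\, I^h / (I^h + k^h),$$

with half-saturation luminance $k$ (default 0.05 cd·s/m²) and exponent
$h = 1$. The a-wave is a negative Gaussian transient (default trough at
15 ms, width 4 ms) and the b-wave a positive gamma-shaped transient
(default peak at 35 ms, Gaussian-equivalent width 12 ms), so the
trough-then-peak measurement rules apply literally. Noise is additive
i.i.d. Gaussian per sample (10 µV SD by default, matching a realistic
recording); 50 Hz mains interference can be switched on but is off by
default. Epochs carry 100 ms of pre-stimulus signal — so the 10 ms
baseline window always exists — and 300 ms post-stimulus; inter-stimulus
intervals are not modelled, as averaging treats sweeps as exchangeable.
The returned ground truth records the trough and peak of the *noise-free*
trace under the same windowed rules the analysis uses, so generator and
analysis agree exactly at zero noise; because the two components overlap
in time, the measured a-amplitude saturates slightly below $A_{max}$, and
the ground truth accounts for that.

Stimulus protocols mirror the screen's two conditions: a dark-adapted
series of 9 flash strengths log-spaced over 0.001–10 cd·s/m², and a
light-adapted series of 5 strengths over 1–100 cd·s/m² on a 30 cd/m²
rod-suppressing background, 20 sweeps per strength.

What the generator does *not* emulate: biophysical photoreceptor kinetics,
oscillatory potentials riding on the b-wave, electrode drift, or
non-stationary noise. A passing recovery test therefore demonstrates that
the measurement stage is unbiased and noise-robust under the stated model,
not that it handles every artifact of live recordings.

## OCT: boundaries, thickness maps, sectors

Four boundaries define the reported layers: the internal limiting membrane
(ILM), the lower edge of the outer plexiform layer (OPL), the external
limiting membrane (ELM) and Bruch's membrane (BM). Thicknesses are
**TRT** = BM−ILM (total retinal thickness), **IR** = ELM−ILM,
**OR** = BM−ELM and **ONL** = ELM−OPL; by construction TRT = IR + OR
exactly wherever all are defined. Depths are kept in pixels internally and
converted to µm only at reporting, which keeps the additivity identity
exact.

### Automatic segmentation

Vendor segmentation algorithms are closed; the package implements the
standard graph-based alternative: Gaussian pre-smoothing (σ = 2 px), a
vertical gradient image, and per-boundary minimum-cost paths across
A-scans found by dynamic programming with the axial step between
neighbouring A-scans limited to 2 px (the smoothness constraint). Sign
constraints encode the expected contrast: dark→bright for the ILM and
ELM, bright→dark for the OPL lower edge and BM. Boundaries are found in
the order ILM → BM → OPL → ELM, each search restricted by the previously
found boundaries, and a minute depth-proportional cost term breaks exact
ties (shallow-preferring for the ILM, deep-preferring for BM). The
ordering ILM ≤ OPL ≤ ELM ≤ BM is enforced on the result. A constant image
has no boundary and is rejected. This design assumes the ILM is the
strongest dark→bright transition of the image and BM the strongest
bright→dark one below it — true for the phantoms and typical B-scans, and
the interior searches are additionally protected by their bounds.

### Outlier correction and manual mode

The screen's second measurement mode emulates the manual clean-up of gross
auto-segmentation failures: per B-scan and boundary, points deviating from
a 31-A-scan running median by more than 5× the local median absolute
deviation are replaced by linear interpolation from their neighbours;
everything else is left untouched. Two numerical guards are the package's
own: the MAD is floored at 0.5 px so that clean integer-pixel boundaries
(whose local MAD is 0) are never "corrected", and a column at which the
boundary ordering is violated is treated as wholly outlying since the
violation cannot be attributed to one boundary. A B-scan row in which more
than half the points are outliers cannot be repaired from neighbours and
is flagged invalid rather than silently smoothed. The third mode adopts
operator-supplied boundaries verbatim after validating the ordering.

### Sector geometry

Thickness maps are summarized on a grid centered on the optic disc (OD):
four 90° quadrants (superior, inferior, nasal, temporal; dividers on the
diagonals) and two rings. The ring radii are not dictated by the
procedure being emulated; the defaults — OD exclusion 0.25 mm, inner ring
to 1.0 mm, outer ring to 1.5 mm — were chosen to match the 1 and 1.5 mm
eccentricities of the manual sampling scheme, and are configurable in
`sector_grid()`. Pixels inside the OD circle are excluded from every
summary. The quadrant value is reported as the unweighted mean of the
inner- and outer-ring means (not an area-weighted mean — the two rings
are quantified separately and then averaged). Nasal/temporal orientation
mirrors between eyes; the package's convention places the nasal retina on
the −x side of the en-face image for a right eye. An empty sector is
reported as missing, never as zero.

### The retinal phantom

Synthetic volumes render each A-scan as a piecewise-constant reflectance
profile with transitions exactly at integer-pixel ground-truth depths,
plus Gaussian noise (5 gray levels by default on the 0–255 scale),
quantized to 8-bit so that the TIFF round-trip is lossless. Default
geometry follows the screening protocol: 55 B-scans 120 µm apart. Layer
reflectances are chosen so the sign and ranking assumptions of the
segmenter hold (vitreous 13, inner retina 166, OPL 192, ONL 38, outer
retina 179, choroid 10). Presets: `wt` (230 µm total, the normal mouse
retina), `crx` (ONL collapsed to 0, outer segments missing, ~125 µm — an
extreme photoreceptor degeneration) and `xrcc5` (mild ONL-driven
thinning). Inside the OD circle the layered structure is replaced by a
uniform column and the ground truth flagged invalid, mirroring the
excluded OD. The phantom has no speckle, no optical distortion and no
vendor-specific artifacts; segmentation accuracy on it bounds algorithmic
error, not instrument error.

## Cohort statistics

Observations are eyes: both eyes of each animal enter the analyses
without averaging, as in the emulated screen. This ignores the
within-animal correlation of the two eyes (pseudo-replication); a
per-animal averaging switch (`average_eyes = TRUE`) is provided, and
mixed-effects modelling is deliberately out of scope.

* `welch_from_summary()` computes the unequal-variance t test directly
  from (mean, SD, n) triples — the closed-form layer used to verify
  published group differences when only summary statistics are printed.
* `two_way_anova()` fits `value ~ A * B` with Type II sums of squares,
  the standard choice for unbalanced factorials (the screen compares,
  e.g., 96 control eyes against 10 knockout eyes). The factors default to
  whatever pair the caller supplies: genotype × quadrant for thickness,
  group × luminance for ERG series, age × quadrant for aging.
* `posthoc()` provides Tukey (studentized-range) and Šídák
  ($p_{adj} = 1-(1-p)^m$) pairwise comparisons, either marginal or within
  each level of the second factor. Whether an ERG intensity series forms
  one family or one family per flash strength is not fixed by the
  emulated analysis; the `by` argument makes the family definition
  explicit, with per-level families as the intended use.
* `aging_ratio()` expresses group means as percent of a reference group,
  the quantity behind statements like "amplitudes fell below 30% of the
  10-week value at 100 weeks".

The cohort simulator draws per-eye values from each group's normal
(mean, SD), truncated at zero by rejection sampling because amplitudes and
thicknesses are non-negative; published summary tables are available as
presets (`xrcc5_summary()`, `aging_summary()`). Truncation shifts the
realized mean upward only when the mean is within ~2 SD of zero, which
none of the preset cells approach closely.

## The screening pipeline

`run_screen()` chains the stages under a single seed: per-eye phantom
volumes (control eyes drawn from the 244.9 ± 9.1 µm wild-type
normal-range distribution, mutants from their preset), automatic
segmentation with outlier correction, TRT sector summaries, and a
follow-up rule that flags an eye for ERG when its TRT z-score against the
control distribution exceeds 3 (the qualitative "findings justify it"
criterion made explicit and configurable). ERG is then simulated and
analyzed for flagged eyes only (or all eyes), a Welch test compares the
groups, and tidy CSVs plus a JSON manifest (configuration, seed,
versions) are written. Reruns with the same configuration and seed are
byte-identical, and no ERG output exists for an unflagged eye.

## Problem sizes and numerical notes

The test suite and the acceptance script run on reduced but
geometry-faithful problem sizes chosen by the package: phantoms of 15
B-scans × 48 A-scans at 2 µm axial pitch (the full 55-section geometry is
exercised in the I/O tests), 100 seeded replicates for the noisy ERG
recovery study, and 1000 null replicates for the ANOVA type-I calibration.
Floating-point identities (TRT = IR + OR, sector means versus a
brute-force pixel loop) are exact because both sides are computed from the
same integer pixel differences; tolerances elsewhere reflect sampling
noise, not implementation slack.

Known limitations: the segmenter's contrast-ranking assumptions can fail
on pathologies that inverted layer reflectance; the degenerate collapsed-
ONL phantom makes OPL and ELM coincide, where only the ground truth (not
the interior segmentation) is meaningful; the detection rule's
false-positive behaviour on null signals is inherent to extremum
statistics; and the permutation agreement of the Welch test is asymptotic,
checked at moderate n.
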