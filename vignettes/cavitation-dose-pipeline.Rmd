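---
title: "Scoring cavitation emissions and BBB opening: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring cavitation emissions and BBB opening: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cavidose)
```

`cavidose` implements the quantitative readouts of a microbubble-mediated
focused-ultrasound blood-brain barrier (BBB) opening experiment: spectral
scoring of passive cavitation detection (PCD) recordings, cavitation dose
with baseline normalization, hemisphere contrast-enhancement quantification,
damage-score aggregation, and the small-sample group statistics. This
vignette explains the models behind each step, the tunable parameters, and
the choices made where more than one reasonable definition exists.

## The acoustic model

A treatment is a train of `n_bursts = floor(total_duration * prf)` bursts,
burst k starting at `k / prf` seconds. The defaults of
`treatment_schedule()` encode a common small-animal protocol: 10 ms bursts
at 0.5 Hz pulse repetition frequency for 2 min (60 bursts), a 1.1 MHz
transducer fundamental, and a 25 MHz digitization rate. The sampling rate
is configurable; 25 MHz is chosen so that Nyquist (12.5 MHz) clears the
10 MHz broadband analysis ceiling with margin.

The synthetic emission model (`emission_model()`) is phenomenological, not
physical: no bubble-dynamics integration is performed. A burst is a sum of

- tones at band multipliers m in {0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4} times f0,
  with user-set zero-to-peak amplitudes (volts) — the narrowband signatures
  of stable cavitation;
- band-limited white noise of a set RMS, confined below the broadband
  ceiling by spectral masking — the signature of inertial cavitation;
- an always-on full-band electronic noise floor.

Per-burst variability multiplies the tone amplitudes and broadband RMS by a
shared lognormal factor `exp(N(0, sigma^2))`. The log-symmetric choice keeps
the geometric mean of per-burst band Vrms at the nominal amplitude over
sqrt(2), which makes injected amplitudes recoverable in expectation and the
round-trip tests interpretable. Phases are either zero (tones start
coherently; useful for exact expectations) or uniform per burst.

Every generator is seeded. Sub-seeds are derived from the master seed by a
fixed integer hash chain keyed by (arm, subject) and burst index, so
enlarging a study or regenerating a single burst never changes what any
other subject or burst receives.

## Spectral scoring

`amplitude_spectrum()` computes a rectangular-window DFT calibrated so that
an on-grid tone of amplitude A appears as a single bin of amplitude A;
frequency resolution is `1 / burst_duration` (100 Hz for a 10 ms burst).
The per-bin power is each bin's contribution to the mean square of the
signal, so total spectral power equals time-domain power exactly
(Parseval), which the tests verify to numerical precision.

Each narrowband is the 200 Hz window `center ± 100 Hz` (a multiplier times
f0). Two Vrms estimators are provided:

- `method = "peak"` (default): the peak single-sided spectral amplitude in
  the window, divided by sqrt(2). For a pure in-band tone this returns the
  tone's true RMS, A/sqrt(2) — the natural calibration.
- `method = "rms"`: the square root of total in-band power, i.e. the
  time-domain RMS of the band-filtered signal.

The two coincide for a single in-band tone and differ only when several
spectral components share a window. The peak-based form is the default
because it is the more literal reading of a "peak spectral amplitude"
measurement; the filtered-RMS form is kept behind the switch because the
distinction is empirically unresolvable from a pure-tone calibration. The
band filter is realized as a frequency-domain mask of whole bins (about
3 bins at 100 Hz resolution), with no zero padding: bit-reproducible and
free of filter-design ambiguity. The rectangular window is exact for
on-grid tones, which the synthesizer guarantees by construction; off-grid
tones in real data incur scalloping loss, a known limitation noted below.

The broadband residual zeroes all eight narrowbands and everything outside
`[broadband_floor, broadband_ceiling]` (defaults 0.1 and 10 MHz), then
returns the square root of the summed residual power. Total power rather
than a residual "peak" is used because a noise continuum has no meaningful
single peak; this is the one place the scoring deliberately departs from a
peak-based reading, and it is the decision that makes the broadband score
insensitive to narrowband amplitudes (verified to 1e-6 relative in the
tests). The floor excludes DC and low-frequency drift; all eight
narrowbands are excluded — subharmonic and ultraharmonics included —
because the named bands are scored separately and the residual is defined
as everything that remains.

## Dose and normalization

`accumulate_dose()` sums Vrms times burst duration over the treatment, per
band, in volt-seconds; accumulation is exactly additive over concatenated
record lists. `normalize_dose()` divides each band's treatment dose by the
matching dose of a baseline scan — the low-pressure, no-microbubble
recording generated with the identical schedule and processed identically.
The ratio convention (not dB, not subtraction) is the minimal reading of
"normalized to", and per-band ratios (rather than one global factor) let
hydrophone sensitivity cancel band by band; both choices are conventions,
not measurements, and are isolated in this one function. Denominators below
a numeric floor (default 1e-12 V s) raise an error naming the silent band
rather than returning infinities — a baseline needs a noise floor to have a
finite broadband dose, and `generate_baseline()` includes one by default.

`compare_emissions()` reports, for each requested band (default 2f, 3f, 4f
and broadband, the bands usually shown for such studies), group means with
SEM and the exact two-sided Mann-Whitney p on per-subject normalized doses.

## Enhancement quantification

BBB opening is quantified from a single post-contrast grayscale image as
the fold difference in mean intensity between the treated and contralateral
hemispheres; the contralateral side is the internal reference, so no
pre-contrast image enters the metric. Masks default to the left/right image
halves split at the midline column (row-major, origin top-left); explicit
masks override. Intensities are treated as linear and no bias-field
correction is applied.

The phantom generator places a contiguous region of interest covering a
fraction phi of the treated hemisphere at `background * e`; the noiseless
fold is analytically `1 + phi * (e - 1)`, which the package reproduces
exactly and which anchors the unbiasedness checks under noise (Gaussian,
clipped at zero — keep the noise SD well below the background so clipping
is negligible).

## Group statistics

`mann_whitney_exact()` counts pairwise wins (ties half) and, for pooled
sizes up to 14, enumerates all `choose(n_a + n_b, n_a)` assignments of the
observed pooled values — a conditional exact test that remains valid under
ties. The two-sided p is twice the smaller tail probability, capped at 1:
with complete separation at 4 vs 4 this gives 2/70 = 0.0286, the smallest
level that design can achieve, which is also why null studies at n = 4
reject at ~2.9% rather than the nominal 5% (the test is conservative at
unattainable levels). Larger samples use the tie-corrected normal
approximation with continuity correction, clearly labelled in the result.

`anova_dunnett()` computes the one-way pooled-variance F, then
Dunnett-adjusted two-sided p-values from the Monte-Carlo null of the
maximum absolute Dunnett t: each draw simulates group means from their null
normals and a pooled variance from its chi-squared distribution, preserving
the control-induced correlation. Monte-Carlo (default 1e5 draws, seeded)
was chosen over numerical multivariate-t integration because it is simple,
reproducible, and directly testable — at k = 2 it must and does converge to
the pooled two-sample t-test, and the suite cross-checks k = 3 against an
independent multivariate-t implementation. Zero residual variance (an
all-zero damage table, the common case at moderate pressure) reports p = 1
with a warning instead of erroring.

`aggregate_scores()` averages the ordinal 0-3 damage scores (0 none,
1 mild, 2 moderate, 3 severe; per-field scores for RBC extravasation and
vacuolation) up the image → section → subject hierarchy and reports group
mean ± SEM at the requested level. Which level is the right unit of
inference is genuinely design-dependent — scoring happens per 20x image
but group sizes are stated per animal — so all three levels are exposed and
none is silently preferred; the default in examples is image-level.

## What the generator does and does not emulate

The synthetic module reproduces the *structure* of the real data — burst
timing, narrowband/broadband spectral content, per-burst variability,
matched baselines, unilateral enhancement — with amplitudes that are free
parameters. It does not model bubble dynamics, pressure fields, skull
transmission, MR physics, or scanner noise statistics. Passing round-trip
and calibration tests therefore demonstrates that the *analysis* is
correct and well-calibrated, not that any particular biological effect size
is realistic; group-level conclusions on real data still depend on the
usual experimental controls.

Microbubble diameters are modeled as lognormal, moment-matched to the
stated mean 2.32 um and SD 1.41 um (sigma^2 = ln(1 + (sd/mean)^2),
mu = ln(mean) - sigma^2/2, giving sigma ≈ 0.561, mu ≈ 0.684). The family
choice is the package's: it is the standard model for microbubble size
distributions, has the right support, and its implied 90.2% of diameters
below 4.09 um independently matches the stated 90th-percentile
characterization to within rounding — three printed numbers, two fitted
parameters.

## Problem sizes in the test suite

Exactness properties (Parseval, linearity, band orthogonality, dose
additivity, the phantom law) hold at any scale and are tested on bursts of
a few thousand samples. Calibration against the full protocol (60 bursts of
10 ms at 25 MHz) is run once, in the tone-calibration test. Replicated
studies — the 1000-replicate null-calibration of the exact test — use a
scaled schedule (100 kHz fundamental, 2 MHz sampling, four 2 ms bursts,
0.9 MHz broadband ceiling) chosen because the quantity under test, the
achievable-level rejection rate 2/70, is invariant to the schedule scale;
the scaling keeps the replication count high where the statistics need it.
Monte-Carlo assertions use 3-4 standard-error tolerances throughout.

## Known limitations

- Off-grid tones (real transducers drift) incur rectangular-window
  scalloping; a flat-top window is a natural extension and the `"rms"`
  estimator is less sensitive to the effect.
- Burst detection refines boundaries to within about one sample on clean
  data but is a simple energy detector; heavily reverberant or low-SNR
  records should be segmented by schedule.
- The exact Mann-Whitney enumerates up to pooled n = 14 (3432
  assignments); beyond that the normal approximation is used and labelled.
- Waveform interchange is CSV (bit-exact round trip); image interchange is
  16-bit TIFF, which quantizes intensities to ~1.5e-5 of full scale.
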