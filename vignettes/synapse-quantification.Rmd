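---
title: "Quantifying synapse density, cortical morphometry and miniature PSCs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying synapse density, cortical morphometry and miniature PSCs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synaptiq)
```

## Scope and model

synaptiq quantifies three things from cortical tissue data:

1. **Structural synapse density.** A synapse is operationalised as a
   colocalized pair: a pre-synaptic punctum and a post-synaptic punctum
   whose 3D object centers lie within a fixed physical distance — 1 µm for
   human confocal/array-tomography material, 0.5 µm for mouse. Densities
   are reported per mm³ of analyzed neuropil.
2. **Field morphometry.** Cell counts per area, thresholded signal area of
   a marker, axonal fibers crossing a 100 µm measurement line, and the
   partition of a section into lesion, a 150 µm perilesion band, and the
   remainder.
3. **Miniature postsynaptic currents.** Template-matching detection of
   mEPSCs (inward at −70 mV) and mIPSCs (outward near 0 mV) in 5-minute
   20 kHz voltage-clamp recordings, summarised as frequency, amplitude and
   charge transfer, behind whole-cell QC gates (≤ 200 pA holding current,
   series resistance ≤ 30 MΩ and stable within 20%).

Because such tissue and recordings are not distributable, the package
ships seeded generators (`simulate_puncta_stack()`,
`simulate_section_series()`, `simulate_field()`, `simulate_mpsc_trace()`)
that emit data plus exact ground truth; every claim below is established
by parameter recovery against that truth in the test suite.

## Image model and segmentation

A punctum is modelled as an isotropic Gaussian object (sd = radius/2)
convolved analytically with a Gaussian PSF, so the rendered blob has
per-axis sd `sqrt((r/2)² + σ_psf²)`. Confocal stacks blur continuously
across z-planes (0.15 µm step); array-tomography series render each
punctum only on the 70 nm sections its physical z-extent intersects,
weighted by slab overlap — there is no optical cross-talk between
physical sections. Noise is Poisson shot noise on signal + background
followed by Gaussian read noise. The defaults (peak 150, background 20,
read noise 5, giving peak SNR ≈ 10) are stated assumptions: the noise
statistics of the original acquisitions are not published, and nothing
downstream depends on their exact values beyond an SNR ≳ 5.

Segmentation thresholds each section adaptively: foreground iff intensity
exceeds the local mean + `k` × local SD over a (2r+1)² window (Niblack
style; local mean/median + fixed offset are available alternatives).
Parameters are per channel and constant across sections. Defaults: window
radius 8 px, `k = 3`, minimum footprint 4 px. The window statistics come
from integral images with border-clamped windows, with a 1e-9 relative
tolerance on the comparison so that constant regions are never foreground
under floating-point jitter. `k = 3` keeps the per-pixel false-positive
rate near 0.1% under the combined shot + read noise; at `k = 1` roughly a
sixth of background pixels pass locally and noise clusters survive the
footprint filter, inflating object counts severalfold. A bright punctum
core sits far above the local statistic, so recovery is insensitive to
`k` between about 2 and 3.5.

Footprints are 8-connected in plane. Footprints on consecutive sections
sharing at least one pixel are merged transitively into 3D objects —
pixel overlap is the weakest linking assumption consistent with an object
being "present" on consecutive sections. Centroids are unweighted means
of member voxel centers (physical µm; voxel (i,j,k), 1-based, has center
((i−½)px, (j−½)px, (k−½)Δz)); volume is voxel count × pixel area ×
section spacing.

`persistence_filter()` then removes every object whose section span lacks
two consecutive indices. This is the false-positive control for
single-section artifacts; the generator's "flicker" objects (default 10%
of puncta density in section-series mode) exist to exercise exactly this
rule, and on noise-free ribbons the filtered output matches the
non-flicker truth one-to-one with centroid error below one voxel
diagonal.

## Pairing and densities

`pair_puncta()` matches pre against post objects greedily one-to-one:
candidate cross-channel pairs within the radius are sorted by ascending
distance (ties by pre id, then post id) and accepted iff neither partner
is used. One-to-one prevents a single post punctum from being counted
against several pre puncta; the permissive any-within-radius variant is
retained behind `mode = "any_within"` for sensitivity analysis. Distances
are always physical µm on the anisotropic grid, never voxel units.

Pairs are counted over a regular grid of 10 × 10 µm neuropil ROIs
(`make_neuropil_rois()`); an ROI overlapping the cell-body/vessel
exclusion mask (by default, at all) is dropped. A pair belongs to the ROI
containing its *pre* centroid — a deterministic ownership rule. Density is
count / analyzed volume × 10⁹.

Two quantitative properties hold at the scales the methods target
(512 × 512 × 14 voxels at 0.0587/0.15 µm):

- with paired density 2.5e8/mm³ (offset sd 0.1 µm, SNR ≥ 5), the
  estimated density is within ±15% of truth on every tested seed (the
  residual −3 to −9% bias is segmentation merging of near-coincident
  puncta plus near-threshold misses);
- with *independent* channels, chance pairing is bounded by geometry:
  the expected fraction of puncta paired by accident is ≈ 1 − e^(−ρV)
  for single-channel density ρ and search volume V = (4/3)πr³. At the
  0.5 µm radius this stays below the 10% false-positive budget only for
  ρ ≲ 2e8/mm³; the independence control therefore runs at the inhibitory
  single-channel scale (1.6e8/mm³, the VGAT range), where measured
  chance-pair fractions are 7–9%. At 2.5e8/mm³ the geometric floor alone
  is ~12% — no correct implementation can beat it, which is worth
  remembering when interpreting densities of very abundant markers at
  generous pairing radii.

Subject-level aggregation is fixed: ROIs → stack → subject (mean over a
subject's stacks) → group. `group_stats()` reports n, mean, SEM and both
percent conventions — percent change `(ref − x)/ref × 100` and percent of
reference `x/ref × 100` — because published summaries mix the two, and
delegates the tests (Welch t, Mann–Whitney, one-way ANOVA,
Kruskal–Wallis) to `stats`. Post-hoc comparisons are off by default;
Tukey HSD (after ANOVA) and Holm-corrected pairwise Wilcoxon (after
Kruskal–Wallis) are available — the latter is this package's substitute
for a Dunn test, which adjusts pairwise rank tests rather than reusing
the pooled Kruskal–Wallis ranks.

## Morphometry conventions

Axon "crossings" of the 100 µm line are distinct foreground runs along
the rasterised segment — the closest automatable analogue of a manual
double-blinded count, and invariant to fiber thickness while fibers stay
disjoint on the line. The count is reported raw (per 100 µm), not
normalised: the normalisation behind "relative axonal density" is not
standardised, and raw counts compose with any later normalisation. The
perilesion band is an exact Euclidean distance transform in physical µm
(≤ 150 µm from the nearest lesion pixel); the three compartment masks are
pixel-exclusive and jointly exhaustive by construction. Signal-area
quantification can drop connected components larger than a soma-size
cutoff (default 20 µm²) so puncta-scale signal is measurable while cell
bodies are excluded; the cutoff is a convention, chosen an order of
magnitude above single-punctum footprints and below somatic areas.

## Mini-PSC detection

The template is the unit-peak triexponential
`w(t) = N (1 − e^(−t/τ_r)) (m e^(−t/τ_d1) + (1−m) e^(−t/τ_d2))`;
defaults τ_r = 0.5 ms, τ_d1 = 4 ms, τ_d2 = 12 ms, m = 0.7, 60 ms window —
ordinary cortical mini kinetics. With m = 1 the peak time has the closed
form τ_r ln(1 + τ_d1/τ_r), which the implementation reproduces within one
sample; slow-rise parameter sets and windows that do not let the waveform
decay below 1% of peak raise warnings, not errors.

At every lag the template is fit for scale and offset by least squares
(running sums plus one FFT cross-correlation, O(n log n) for the whole
trace) and the detection criterion is fitted scale / SD of the pointwise
residual — the conventional scaled-template statistic, invariant to
constant offsets and positive rescaling of the trace. Criterion maxima
above the threshold (4–7; default 5, the midpoint) are candidate onsets.

Two details matter in practice:

- **Refractory window.** The criterion re-crosses threshold on an event's
  own decay. A weaker maximum from one rise time before to the
  decay-to-20%-of-peak point after an accepted peak is treated as part of
  that event. Events closer than one rise time are never decomposed.
- **Subtraction passes.** An event overlapping a neighbour inside the
  template window inflates the residual and can suppress both criteria.
  `detect_events()` therefore subtracts fitted events and re-scans
  (default 3 passes, stopping early); at 2 Hz this raises recall from
  ~0.88 to ~0.97 with precision staying at 1.0. `max_passes = 1` restores
  plain single-pass matching.

The baseline-noise SD is estimated from event-free stretches via first
differences (sd or MAD estimator; differencing keeps slow drift out), and
candidates with fitted amplitude below 3 × that SD are discarded. The
reported amplitude is the fitted, baseline-subtracted peak (the
least-squares scale of a unit-peak template), which is unbiased — the raw
sample maximum inside a window would be biased upward by extreme-value
selection on the noise. Per-event charge integrates the event's own
fitted component plus unexplained residue over its window, minus the
local baseline offset, so overlapping neighbours are not double-counted;
total charge is the sum of per-event magnitudes over the 5-minute window,
which is robust to drift in a way a whole-trace integral is not.

On the reference condition (300 s, 2 Hz, 20 ± 5 pA truncated-normal
amplitudes, 2 pA noise, threshold 5) the test suite measures recall and
precision ≥ 0.90 at ±2 ms onset tolerance, frequency within 10% and total
charge within 15% of the injected charge. The residual misses are
sub-threshold by construction: an amplitude near 10 pA has criterion
≈ amplitude/noise ≈ 5 and sits at the stated detection limit.

## Numerical choices and degenerate inputs

- All generator randomness flows through one seeded RNG; identical config
  + seed gives bit-identical images, traces and truth.
- Truncated-normal amplitudes are resampled until positive (no sign
  flips); paired post puncta are resampled until inside the field, so
  truth coordinates always lie in the stated extent.
- A constant image thresholds to an empty mask (strict inequality with a
  relative tolerance); an all-excluded ROI grid has zero analyzed volume
  and density computation refuses it; an empty event list summarises to
  zeros with an empty interval list.
- Pairing tie-breaks are lexicographic (distance, pre id, post id), so
  results are order-independent; `run_pipeline()` sorts its file table
  and is invariant to input order, and reruns are bit-identical.

## Problem sizes

The shipped checks use desk-scale versions of the acquisition geometry:
512 × 512 × 14-voxel stacks at the native pixel pitch (a 30 µm field
rather than the full 184.58 µm, 5 seeds per condition) and one 300 s
recording, which together keep the full suite within a few minutes while
preserving the native voxel and sampling scales. Field-size effects enter
only through edge truncation of the pairing search volume, which the
chance-pairing analysis above accounts for.

## What passing tests do and do not show

The generators reproduce the statistical structure the analysis assumes —
Poisson-placed puncta with Gaussian blur and controlled colocalization,
single-section flicker artifacts, Poisson mini trains with fixed kinetics
— but not everything real data contains: no spectral bleed-through, no
registration error or section loss in ribbons, no spatial clustering of
synapses, no correlated (1/f) recording noise, no amplitude–kinetics
correlations. Recovery results therefore validate the implementation
under its stated model; they do not certify parameter choices (threshold,
window, radius) for any particular tissue or rig, which remain the
analyst's calibration duty.
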