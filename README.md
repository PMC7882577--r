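# synaptiq

Quantitative analysis of structural and functional synapse loss in cortical
tissue, for imaging and electrophysiology labs that measure:

- **volumetric synapse densities** from multi-channel confocal z-stacks or
  array-tomography section series, where a structural synapse is a
  pre-synaptic punctum (e.g. VGAT, SYN1) and a post-synaptic punctum
  (e.g. gephyrin, PSD95) with object centers within a set physical distance
  (1 µm for human material, 0.5 µm for mouse);
- **field morphometry**: interneuron densities (cells/mm²), thresholded
  marker areas (µm²), pan-axonal (SMI312) fibers crossing a 100 µm line,
  and lesion / 150 µm perilesion-band partitions of demyelinated cortex;
- **miniature postsynaptic currents** (mEPSC/mIPSC) from voltage-clamp
  traces, detected by scaled template matching and summarised as frequency,
  amplitude and charge transfer, with whole-cell quality-control gates.

Every stage has a seeded synthetic-data generator with full ground truth
(puncta stacks with controlled colocalization, single-section "flicker"
artifacts, cell/fiber fields, Poisson mini trains with triexponential
kinetics), so the pipeline is testable end to end by parameter recovery.

## The core methods

**Segmentation → persistence → pairing → density.** Each section is
thresholded adaptively (foreground iff intensity > local mean + *k*·local
SD over a (2r+1)² window; Niblack-style, per-channel parameters constant
across sections). Per-section footprints (8-connected) are linked across
consecutive sections by pixel overlap into 3D objects; objects not present
in ≥ 2 consecutive sections are removed as false-positive signal. Pre/post
objects are matched greedily one-to-one by ascending center distance within
the pairing radius, and pairs are counted over a grid of 10 × 10 µm
neuropil ROIs (excluding cell bodies/vessels via a mask):

```
density [mm⁻³] = n_pairs / analyzed_volume [µm³] × 10⁹
```

**Mini detection (Clements–Bekkers).** A unit-peak template
`w(t) = N (1 − e^{−t/τ_r}) (m e^{−t/τ_{d1}} + (1−m) e^{−t/τ_{d2}})`
is fit at every lag for scale *s* and offset *c* by least squares; the
detection criterion is `s / SD(fit residual)`, thresholded at 4–7
(default 5). Accepted events must exceed 3 × the baseline-noise SD; fitted
events are subtracted and the trace re-scanned so overlapping events are
recovered. Per-event charge is ∫(signal − local baseline) dt.

## Worked example

```r
library(synaptiq)

# a two-channel confocal stack with known ground truth
cfg <- sim_image_config(field_size_um = c(15, 15), seed = 7)
sim <- simulate_puncta_stack(cfg)
sim$truth
#> <synq_truth> pre: 142, post: 114 in 472 um^3; 114 pairs (2.41e+08 /mm^3); 0 flickers

pre  <- extract_objects(sim$stack, "pre",  seg_params()) |> persistence_filter()
post <- extract_objects(sim$stack, "post", seg_params()) |> persistence_filter()
pairs <- pair_puncta(pre, post, max_dist_um = 0.5)
grid  <- make_neuropil_rois(c(15, 15), depth_um = 14 * 0.15, roi_size_um = 5)
glance(compute_densities(pairs, list(pre = pre, post = post), grid))
#> # A tibble: 1 × 5
#>   n_pairs synapse_density_per_mm3 analyzed_volume_um3 pre_per_mm3 post_per_mm3
#>     <int>                   <dbl>               <dbl>       <dbl>        <dbl>
#> 1     109              230687831.                472.  285714286.   237037037.
```

The estimated synapse density (2.31e8/mm³, from 109 recovered pairs in
472 µm³ of neuropil) matches the simulated truth (2.41e8/mm³, 114 pairs)
within 5%; `pre_per_mm3`/`post_per_mm3` are the single-channel puncta
densities over the same analyzed volume.

Miniature currents:

```r
es <- simulate_mpsc_trace(sim_ephys_config(duration_s = 60, seed = 15))
tm <- make_template(tau_rise_ms = 0.5, tau_decay1_ms = 4,
                    tau_decay2_ms = 12, decay_mix = 0.7)
ev <- detect_events(es$recording, tm, threshold = 5)
summarize_events(ev)[, 1:5]
#> # A tibble: 1 × 5
#>   n_events frequency_hz mean_amplitude_pA mean_iei_s total_charge_pC
#>      <int>        <dbl>             <dbl>      <dbl>           <dbl>
#> 1      113         1.88              20.4      0.527            18.6
```

113 events over 60 s (1.88 Hz against the simulated 2 Hz; the shortfall
is events below the detection criterion), mean amplitude 20.4 pA against
the simulated 20 pA, and 18.6 pC of total charge.

Study-level runs (`run_pipeline()`) average stacks per subject and
`group_stats()` adds per-group mean ± SEM, percent change versus the
reference group and the usual subject-level tests (Welch t, Mann–Whitney,
ANOVA, Kruskal–Wallis), with `tidy()`/`glance()`/`autoplot()` methods.

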