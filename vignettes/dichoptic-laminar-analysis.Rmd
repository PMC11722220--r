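---
title: "Analysing laminar responses to conflicting dichoptic stimuli"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing laminar responses to conflicting dichoptic stimuli}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dlamr)
```

## The problem this package addresses

When the two eyes receive conflicting images, binocular visual cortex must
decide what to do with the disagreement. Small interocular phase disparities
are the raw material of stereopsis; a 180° spatial phase offset is a large
disparity; orthogonal gratings in the two eyes are the classic
binocular-rivalry stimulus. In mouse binocular V1 (bV1), these conditions
leave distinct signatures in laminar recordings: phase conflict suppresses
the early part of the evoked response (roughly 40–80 ms after each phase
reversal), while orientation conflict leaves the early response intact but
elevates activity later (100–200 ms), in both regular-spiking (RS, putative
excitatory) and fast-spiking (FS, putative PV+) units, with
somatostatin-positive interneurons instead suppressed under rivalry.

`dlamr` implements the complete analysis chain needed to measure those
signatures from raw data: LFP conditioning, visually evoked potential (VEP)
component measurement, current-source-density (CSD) laminar alignment,
multiunit activity envelope (MUAe) with interblock z-scoring, RS/FS
classification with windowed firing statistics, neuropil-corrected calcium
ΔF/F, and repeated-measures inference. Because the in vivo recordings behind
these effects are not publicly deposited, the package also ships a
first-class synthetic generator that encodes the condition effects with
known ground truth; every stage is validated by parameter recovery against
that generator.

## The experimental structure the package assumes

Four dichoptic conditions are presented in pseudorandomly interleaved
blocks separated by gray-screen interblock intervals:

* **Monocular** — contralateral eye only;
* **Concordant** — same grating to both eyes;
* **Phase offset** — same orientation, 180° spatial phase difference;
* **Orthogonal** — gratings rotated 90° between the eyes.

The acute-recording protocol is 100 s blocks with 30 s interblock gray,
five blocks per condition, phase-reversing gratings at one reversal per
second — 500 trials per condition. Calcium imaging uses 10 s blocks with
10 s gray and 24 blocks per condition at ~14.9 Hz frames. All interblock
gray periods serve as the baseline for every z-score and for ΔF/F.

## Signal chains

### LFP conditioning (`preprocess_lfp`)

DC removal → anti-aliased downsampling to 1 kHz → third-order 1–300 Hz
Butterworth band-pass → local linear detrend (0.5 s windows sliding by
0.1 s) → third-order 58–62 Hz Butterworth notch. All IIR filters are applied
forward–backward (zero phase) so evoked-component latencies are preserved;
the anti-alias low-pass is an order-4 Butterworth at 0.4 × the target rate,
giving an 8th-order magnitude response after the two passes. The local
detrend averages overlapping per-window least-squares lines; edges are
padded with the linear extrapolation of the first/last window fit, which is
exact for trends up to linear and low-variance for noise (anti-symmetric
reflection, which we tried first, corrupts the trend estimate at the edges
of noisy traces). Every step is recorded in the trace's provenance and can
be replayed bit-identically with `replay_lfp()`.

### VEP components (`extract_trials`, `normalize_and_smooth`, `measure_components`)

Trials are aligned at phase-reversal events; each trial is normalized by
subtracting its first 10 ms; trials are averaged and smoothed with a 10-ms
moving Gaussian. We interpret the "10 ms" width as the FWHM of the kernel,
truncated at ±3σ and renormalized, and we fix the order as baseline →
average → smooth. The negativity is the minimum in a 25–100 ms search
window; the positivity is the maximum in a 60–250 ms window constrained to
follow the negativity; magnitude is peak-negative-to-peak-positive voltage.
The search windows are configurable; the defaults bracket the early
(40–80 ms) and late (100–200 ms) response periods that the windowed
statistics use.

### CSD and laminar alignment (`compute_csd`, `find_l4_sink`, `laminar_alignment`)

The trial-averaged LFP is smoothed in time with a 20-ms (FWHM) Gaussian,
spatially with a normalized five-point Hamming window
(0.08, 0.54, 1.00, 0.54, 0.08), and the central second spatial difference is
scaled by −1/h² so current sinks are negative. The composed spatial kernel
has half-width 3, so three channels are dropped at each probe end rather
than extrapolated.

Identifying layer 4 operationalizes "the earliest and deepest sink
immediately below the superficial source", which is a description, not an
algorithm. The package's rule: per channel, a baseline mean and SD are taken
over a 250 ms pre-reversal stretch (a 0–20 ms post-reversal baseline holds
roughly one independent sample of 20-ms-smoothed CSD and makes the SD
estimate meaningless); a sink crossing is the first sustained (≥ 5 ms)
excursion below mean − max(k·SD, 0.5 × peak |CSD|), with k = 2. The absolute
floor matters: without it the k·SD rule is degenerate for noise-free data
and is triggered by the slow negative shoulders that detrending and the
1 Hz high-pass leave on source-side channels. Crossing times are refined by
linear interpolation to the threshold level; crossings within 10 ms count as
simultaneous and are resolved in favor of the deepest (most negative) sink,
its magnitude averaged over ±10 ms around the map's trough; exact magnitude
ties go to the deeper channel. Candidates must lie below a channel with a
significant source. On 20 synthetic sessions with randomized sink channels
at default noise this recovers the true channel in 20/20; the literal
earliest-crossing-then-deeper-channel reading recovered 0/8 under the same
conditions, which is why the package does not use it.

Depths are signed relative to the L4 sink (positive superficial) and layers
follow the boundary table L2/3 +300…+60, L4 +60…−80, L5 −80…−260,
L6 −260…−460 µm. The shared endpoints are assigned half-open,
upper-exclusive: +60 µm belongs to L2/3, −80 µm to L4, −260 µm to L5,
−460 µm to L6; anything outside ±(300/−460) is `"out"`.

### MUAe (`common_median_reference`, `notch60_iir`, `compute_muae`, `zscore_interblock`)

The wide-band 25 kHz data are common-median referenced (per-channel median,
then per-timepoint cross-channel median), notched at 60 Hz with a
second-order IIR whose 10-dB bandwidth is 10 Hz, band-passed 500–5000 Hz
(third-order Butterworth), rectified, low-passed below 250 Hz (third order)
and decimated to 1 kHz by stride (the low-pass already anti-aliases).
Low-pass undershoot is clamped at zero so the envelope stays nonnegative.
Envelopes are z-scored per channel against the mean and SD over all
interblock samples, so z = 1.96 marks the conventional visual-response
bound. `condition_response()` aligns the z-scored envelope to reversals,
groups channels by layer, and differences each condition against monocular;
`window_means()` collapses the early/late windows across in-cortex channels.

### Units (`classify_units`, `compute_psth`, `window_rates`, `zscore_unit`)

Spike sorting is consumed, not performed. Classification uses the template's
trough-to-peak latency: the trough is the global minimum, the peak the
global maximum strictly after it; latencies under 0.4 ms are FS, over
0.4 ms RS, and exactly 0.4 ms — which falls between the two defining
clauses — is assigned RS with a warning. PSTHs bin spikes at 1 ms across
trials with rate = count/(n_trials × bin width); at 500 trials this is the
"multiply by 2" rule. Early/late rates average the half-open windows
[40, 80) and [100, 200) ms, avoiding double-counted boundary bins. Per-unit
z-scores bin at 1 ms, smooth with the same 10-ms Gaussian used for display,
and standardize against the interblock rate; units silent during every
interblock interval have an undefined baseline and are flagged for exclusion
rather than imputed.

### Calcium (`neuropil_correct`, `dff_vs_gray`, `qc_session`, `condition_responses`)

True somatic fluorescence is the ROI trace minus 7/10 of its surrounding
neuropil trace. ΔF/F is measured against the session-wide average interblock
gray fluorescence ((F − F_gray)/F_gray); a per-block gray baseline would
also be defensible, but the session-wide average is what the aggregate
statistics use, and the choice only matters in the presence of slow drift
the generator does not model. Sessions with fewer than 100 curated ROIs are
excluded (the QC rule). Per-ROI condition means average all in-block frames
over all blocks of a condition — blocks weigh equally because the protocol
makes them equal length — and population means average ROIs.

### Inference (`rm_anova_oneway`, `sidak_adjust`, `paired_contrasts`)

The one-way repeated-measures ANOVA uses the standard within-subject
decomposition, with the Greenhouse-Geisser ε̂ computed from the
double-centered condition covariance, bounded in [1/(k−1), 1], scaling both
degrees of freedom. Pairwise comparisons are paired t tests with the exact
Šídák family-wise adjustment 1 − (1 − p)^m. Contrasts whose within-pair
differences have (numerically) zero variance are reported as degenerate with
`NA` statistics rather than a fabricated p value; identical columns report
p = 1. Missing cells are refused — imputation is out of scope. Fits carry
broom-style `tidy()`/`glance()` methods.

A property worth knowing: with few subjects the GG correction is
conservative, because ε̂ is biased downward even when sphericity holds
(empirically, type-I error ≈ 0.02 at n = 6 and ≈ 0.033 at n = 12 for k = 4
under our Poisson-derived null). The null-calibration experiment in the
acceptance suite therefore uses 24 subjects, where the realized rate
(≈ 0.043) is statistically indistinguishable from the nominal 0.05.

## The synthetic generator, and what it does and does not emulate

`generate_session()` prescribes a CSD depth profile — a Gaussian sink at the
L4 channel and a balanced source 2–4 channels above — and integrates it
twice along depth (zero-mean, unit-peak), so the CSD stage has an exact
inverse target. The trial time course is a difference of Gaussians peaking
near 65 ms (yielding the canonical negativity-then-positivity at the sink)
plus a smooth 100–200 ms plateau, with per-condition early/late gains.
Defaults encode the qualitative effects: concordant g_E = 1.5, monocular
1.0, phase offset 0.5 (early enhancement/suppression), orthogonal g_L = 1.5
versus 0.3 elsewhere (late elevation). Background is 1/f (spectrally
shaped Gaussian) noise at 30 µV RMS per channel plus a common 20 µV 60 Hz
line component; these defaults were chosen once as representative of awake
mouse recordings and exercise the notch and detrend stages.
`generate_units()` draws inhomogeneous Poisson spikes with
rate(t) = base·(1 + g_E·k_E(t) + g_L·k_L(t)), where k_E and k_L are
unit-peak bumps supported exactly on 40–80 and 100–200 ms, with biphasic
templates at 0.5–0.8 ms (RS) or 0.2–0.3 ms (FS) trough-to-peak.
`generate_calcium()` convolves condition-gained Poisson spiking with an
exponential indicator kernel (default amplitude 8 F-units/spike, τ = 0.7 s),
mixes in a shared neuropil background plus a fraction of the population
signal, and adds shot noise; the `"excitatory"` and `"som"` presets encode
the opposite orthogonal-versus-monocular orderings of the two cell classes.

The reversal-rate ambiguity in the source protocols (whether "2 Hz" counts
reversals or cycles) is resolved by making the rate a parameter with a
default of 1 reversal/s, which makes 5 × 100 s blocks yield the canonical
500 trials per condition.

The generator does **not** emulate: biophysical volume conduction (the LFP
is the exact double integral of the prescribed CSD, so inverse consistency
is by construction); running-state or eye-movement artifacts; display
crosstalk; drifting baselines in calcium; correlated noise across channels
beyond the common line component; or bursting and refractoriness in spike
trains. Passing parameter-recovery tests on this generator therefore
demonstrates that the analysis chain is a correct implementation of its own
contracts, not that it is robust to every pathology of real recordings.

A single global seed fans out deterministically to per-stream child seeds
(schedule, LFP noise, spikes, calcium), so identical seeds and parameters
give bit-identical datasets and any stream can be regenerated independently.

## Problem sizes used by the tests and acceptance script

Full-protocol sessions (64 channels × 25 kHz × ~44 min) are far larger than
needed to validate correctness, so the validation experiments use reduced
sizes, chosen once:

* **Sink recovery**: 20 sessions, 32 channels, 1 kHz, one 30 s block per
  condition (120 trials total), noise at generator defaults, sink channel
  randomized.
* **Effect-sign and inference recovery**: 50 replicates of an 8-subject
  experiment, 20 units/subject, one 30 s block per condition, 10 Hz base
  rate.
* **Null calibration**: 500 replicates, 24 subjects, 1 unit each, 4 s
  blocks, all condition gains equal.
* **MUAe monotonicity**: single-channel 25 kHz traces, four 20 s blocks,
  five inserted spike trains at 5/10/20 Hz.
* **Calcium presets**: 20 seed-matched pairs, 30 ROIs, 6 blocks per
  condition.

`run_pipeline()` accepts the full protocol via `session_params()` defaults
when the compute budget allows.

## Worked example

```{r example, eval = FALSE}
library(dlamr)

cfg <- pipeline_config(
  seed = 1,
  params = session_params(n_channels = 32, fs = 1000,
                          n_blocks_per_condition = 1, block_s = 30,
                          interblock_s = 5),
  n_units = 20, base_rate_hz = 10,
  run_muae = FALSE,
  calcium = list(n_roi = 120, n_blocks_per_condition = 6)
)
res <- run_pipeline(cfg)

res$alignment          # L4 channel, depths, layer labels
res$vep                # per-condition VEP components
tidy(res$anova_early)  # RM-ANOVA on early-window rates
res$contrasts_early    # Sidak-adjusted contrasts vs monocular
```

The README shows the printed output of this exact call. Result objects have
`autoplot()` methods (`vep_waveform`, `csd_map`, `psth`,
`condition_response`) for quick inspection.

## Known limitations

* Only the one-way RM-ANOVA with Šídák contrasts is implemented; two-way
  designs and Tukey/Dunnett families are out of scope.
* Fractional-ratio resampling is refused; input rates must be integer
  multiples of 1 kHz.
* The sink detector assumes channels ordered superficial → deep with
  uniform spacing, and needs a pre-reversal baseline stretch for stable
  statistics.
* Spike sorting and ROI segmentation are consumed as inputs; their quality
  is outside the package's control.
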