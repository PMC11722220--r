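# dlamr

Analysis of laminar electrophysiology and two-photon calcium imaging from
mouse binocular visual cortex (bV1) under **dichoptic** stimulation —
independent gratings shown to the two eyes. The package measures how
concordant versus conflicting binocular input shapes cortical responses:
interocular **phase** conflict suppresses the early evoked response
(40–80 ms after each phase reversal), while **orientation** conflict (the
binocular-rivalry stimulus) elevates activity late in the response
(100–200 ms).

It is written for systems neuroscientists who have raw laminar recordings
(or want a fully synthetic testbed) and need the complete chain from raw
voltage to condition-level inference:

* **LFP conditioning** — DC removal, anti-aliased downsampling to 1 kHz,
  third-order 1–300 Hz Butterworth band-pass, local linear detrend (0.5 s
  window, 0.1 s step), 58–62 Hz notch; all zero-phase.
* **VEP components** — trial alignment at phase reversals, first-10-ms
  baseline normalization, 10-ms Gaussian smoothing, and the peak-negative to
  peak-positive magnitude `M = V_pos − V_neg`.
* **CSD laminar alignment** — 20-ms temporal Gaussian, five-point Hamming
  spatial smoothing, second spatial difference
  `CSD_i = −(φ_{i−1} − 2φ_i + φ_{i+1})/h²` (sinks negative); the layer-4
  sink anchors signed depths and the layer table
  L2/3 +300…+60, L4 +60…−80, L5 −80…−260, L6 −260…−460 µm.
* **MUAe** — common median reference, 60 Hz notch (10-dB bandwidth),
  500–5000 Hz band-pass, rectification, <250 Hz low-pass, 1 kHz decimation;
  z-scored against all interblock (gray screen) intervals so z = 1.96 marks
  a visual response.
* **Units** — RS/FS classification by template trough-to-peak latency
  (FS < 0.4 ms), 1-ms-bin PSTHs with rate = count/(n_trials · bin), early
  [40, 80) and late [100, 200) ms window rates, per-unit interblock
  z-scores, laminar assignment.
* **Calcium** — neuropil correction `F_true = F_roi − 0.7·F_np`, ΔF/F
  relative to interblock gray `(F − F_gray)/F_gray`, the ≥ 100-ROI session
  QC rule, per-ROI and population condition means.
* **Inference** — one-way repeated-measures ANOVA with Greenhouse-Geisser
  correction (ε̂ from the double-centered condition covariance) and paired
  contrasts with the exact Šídák adjustment `p_adj = 1 − (1 − p)^m`;
  `tidy()`/`glance()` methods included.
* **Synthetic data** — a laminar-session generator with known ground truth
  (prescribed CSD sink/source, condition-dependent early/late gains,
  Poisson spiking, calcium transients with neuropil contamination, 1/f and
  60 Hz noise) used for the parameter-recovery test suite.

## Worked example

```r
library(dlamr)

cfg <- pipeline_config(
  seed = 1,
  params = session_params(n_channels = 32, fs = 1000,
                          n_blocks_per_condition = 1, block_s = 30,
                          interblock_s = 5),
  n_units = 20, base_rate_hz = 10, run_muae = FALSE,
  calcium = list(n_roi = 120, n_blocks_per_condition = 6)
)
res <- run_pipeline(cfg)

res$alignment
#> <laminar_alignment: L4 at channel 8 of 32 (h = 20 um)>

dplyr::select(res$vep, condition, negativity_V, magnitude_V)
#> # A tibble: 4 × 3
#>   condition    negativity_V magnitude_V
#>   <chr>               <dbl>       <dbl>
#> 1 monocular     -0.00000678  0.0000127
#> 2 concordant    -0.0000150   0.0000304
#> 3 phase_offset  -0.00000325  0.00000614
#> 4 orthogonal    -0.00000364  0.0000187

tidy(res$anova_early)
#> # A tibble: 1 × 6
#>   term      statistic    df df_error epsilon   p.value
#>   <chr>         <dbl> <dbl>    <dbl>   <dbl>     <dbl>
#> 1 condition      9.70  2.59     49.2   0.863 0.0000841

res$contrasts_early
#> # A tibble: 3 × 7
#>   contrast                 estimate statistic    df p.value degenerate p.adjusted
#>   <chr>                       <dbl>     <dbl> <dbl>   <dbl> <lgl>           <dbl>
#> 1 concordant - monocular      4.54      3.84     19 0.00110 FALSE         0.00330
#> 2 phase_offset - monocular   -1.08     -1.34     19 0.196   FALSE         0.481
#> 3 orthogonal - monocular      1.58      1.25     19 0.225   FALSE         0.535
```

The measurements carry the encoded effects: the concordant VEP magnitude
(30.4 µV) is about 2.4x monocular (12.7 µV) and phase offset about half of
monocular (6.1 µV); the early-window RM-ANOVA is strongly significant and
the concordant-vs-monocular contrast survives the Šídák adjustment. In this
single 30-trial-per-condition session the phase-offset suppression shows
the right sign but not significance, and the orthogonal effect appears only
in the late window (`res$contrasts_late`: +6.6 spikes/s vs monocular,
adjusted p = 1.4e-7) — exactly the early/late dissociation the windowed
statistics are built to detect. The 50-replicate acceptance experiment runs
this design at full power.

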