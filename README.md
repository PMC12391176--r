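# pinprickEEG

EEG analysis of somatosensory evoked potentials (SEPs) elicited by
mechanical pinprick stimulation of the hand, as used to characterise
somatosensory and motor impairment after stroke. The package is aimed at
clinical neurophysiology groups who record pinprick SEPs at the central
electrodes (C3/C4) and want a tested, reproducible implementation of the
full analysis chain — plus a synthetic-cohort generator with known ground
truth so every stage can be validated without clinical data.

## What it computes

* **Synthetic cohorts** with the study protocol (10 sets × 8 hand-dorsum
  compartments × 2 rounds = 160 pinpricks per hand at 256 Hz), 1/f
  background EEG, biphasic evoked responses with configurable group means,
  band-limited oscillatory modulations in the five canonical time-frequency
  windows, and clinical scores generated as linear functions of the injected
  effects.
* **Preprocessing**: zero-phase 1–35 Hz windowed-sinc FIR (forward-backward),
  robust bad-channel detection, common-average re-reference, peak-to-peak
  bad-segment excision with event re-indexing.
* **Time domain**: epochs −0.5–1.5 s, baseline −500–0 ms, trial averages per
  hand, and the SEP negative-positive peak complex
  (amplitude = positive − negative peak, latency of the positive peak).
* **Time-frequency**: complex Morlet wavelets
  `exp(i2πtf) · exp(−t²/(2σ_t²))` with `σ_t = 10/(2πf)` on 30 logarithmic
  frequencies `f_k = 35^(k/29)` (1–35 Hz); power = squared magnitude of the
  convolution, trial-averaged, then dB-normalized:
  `dB(f,t) = 10·log10(power(f,t) / mean power(f, −0.4…−0.1 s))`.
* **Region-of-interest discovery**: per-bin one-sample t of dB against each
  participant's pre-stimulus baseline, a 2000-iteration circular-shift
  surrogate null over time and frequency, inclusion at the 95th percentile
  of each bin's own null (two-sided on |t|), and sign/band-aware connected
  component labelling with Jaccard matching against the five canonical
  windows (delta/theta synchronization, alpha/beta desynchronization, beta
  resynchronization).
* **Statistics**: one-way ANOVA of SEP amplitude on group with
  Tukey-corrected post-hocs and Cohen's d (pooled-SD, (n−1)-weighted);
  linear mixed model `power ~ group × feature + (1 | participant)`
  (Satterthwaite df); and backward-stepwise clinical regressions (features ×
  stroke-type, marginality-respecting elimination at α = 0.05) for scores at
  baseline and for their short-term change.

## Worked example

A reduced cohort (11 participants, 64 pinpricks per hand) runs in under half
a minute and exercises the whole chain:

```r
library(pinprickEEG)
spec <- cohort_spec(n_healthy = 4, n_motor = 3, n_sensorimotor = 4,
                    protocol = stimulus_protocol(n_sets = 4, n_rounds = 1),
                    seed = 42)
res <- run_pipeline(spec, mask_cfg = mask_config(n_iterations = 500),
                    run_stats = FALSE)
res
#> <pinprick_pipeline> 11 participants
#>   mask: 221/6150 bins included, 5 region(s)
res$rois
#> <roi_set> 5 region(s)
#>   delta_sync      3.41- 3.41 Hz       0-   234 ms    31 bins  mean t  11.46
#>   beta_desync    13.13-21.43 Hz     133-   492 ms   135 bins  mean t -11.21
#>   alpha_desync    8.04- 8.04 Hz     367-   523 ms    21 bins  mean t  -9.57
#>   theta_desync    5.56- 5.56 Hz     531-   672 ms    19 bins  mean t  -9.55
#>   beta_sync      13.13-13.13 Hz    1133-  1227 ms    13 bins  mean t   8.74
```

The mask recovers the cores of the injected phenomena: early delta
synchronization, the alpha/beta desynchronization complex, and the late beta
rebound (`beta_sync`, 1133–1227 ms). SEP measurements and the group
comparison:

```r
round(tapply(res$sep_table$np_amplitude, res$sep_table$group, mean), 2)
#>      healthy        motor sensorimotor
#>         3.90         5.73         2.98
tukey_posthoc(anova_amplitude(res$sep_table))
#>                 contrast  estimate        SE df         t    p_tukey   cohens_d
#> 1        healthy - motor -1.832822 0.8522192  8 -2.150646 0.14062488 -1.3429680
#> 2 healthy - sensorimotor  0.913329 0.7890017  8  1.157575 0.50859265  0.9601936
#> 3   motor - sensorimotor  2.746151 0.8522192  8  3.222352 0.02933884  2.6981779
```

The sensorimotor group's smaller peak-to-peak amplitude (2.98 µV vs 3.90 µV
in controls at this reduced size, Cohen's d ≈ 0.96) reflects the generator's
group defaults (1.36 vs 2.81 µV) plus peak-picking noise at 32 trials; the
full 160-trial protocol gives tighter estimates. At the full default cohort
(`cohort_spec()`, 26 participants) the pipeline runs in about a minute.

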