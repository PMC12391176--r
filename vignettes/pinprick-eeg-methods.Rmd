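---
title: "Pinprick SEP and time-frequency analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pinprick SEP and time-frequency analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pinprickEEG)
```

# The problem

Mechanical pinprick stimulation of the hand dorsum evokes a somatosensory
response measurable in the EEG over the contralateral central cortex (C3/C4):
a biphasic negative-positive evoked potential, and a stereotyped pattern of
oscillatory power changes — low-frequency (delta/theta) synchronization,
alpha- and beta-band desynchronization, and a late beta resynchronization
("beta rebound"). In stroke, the amplitude of the evoked complex and the
depth of these modulations carry information about somatosensory and motor
impairment. This package implements the full analysis chain for such studies
— preprocessing, evoked-peak measurement, Morlet time-frequency
decomposition, data-driven region-of-interest discovery, and the group-level
and clinical-association statistics — together with a synthetic-cohort
generator with known ground truth, so that every stage can be validated
without access to clinical recordings.

# The synthetic cohort generator

The generator reproduces the study conditions end to end.

**Protocol.** Ten sets of 8 pinpricks (one per hand-dorsum compartment, random
order within set), both hands in set-by-set alternation, all repeated twice:
160 stimuli per hand. Inter-stimulus intervals are 3 s with ±0.5 s uniform
jitter — the interval is a repository choice (stimulus timing is rarely
printed in study reports); at this spacing the −1.5 to 2.2 s epochs of
consecutive same-hand stimuli do not overlap.

**Background EEG.** Gaussian noise with a 1/f power spectrum (exponent 1 by
default), 10 µV RMS, an inter-channel correlation of 0.5 emulating volume
conduction, and a ±12% per-channel gain jitter emulating electrode
heterogeneity. Synthesis is spectral (FFT shaping at a 5-smooth padded
length).

**Evoked response.** A difference of two Gaussian lobes (negative lobe at 60%
of the positive latency, 20 ms lobe SD), calibrated on a fine grid so the
continuous-time negative-to-positive excursion equals the configured
amplitude exactly. Group defaults are the reported group means: healthy
2.81 ± 1.30 µV at 202.69 ms; motor 3.22 ± 2.68 µV at 169.09 ms; sensorimotor
1.36 ± 0.54 µV at 161.46 ms. Only the two peak metrics matter downstream, so
lobe shape is a free implementation detail.

**Oscillatory modulations.** Multiplicative amplitude gains on the
band-passed background within the five canonical frequency/time windows
(raised-cosine tapered), so the ground-truth effect at the taper plateau is
exactly `20·log10(gain)` dB. Default gains correspond to about ±3 dB — the
tens-of-percent power changes typical of stimulus-locked ERD/ERS — with two
sources of between-participant variability: a responsiveness factor shared
across all five windows (SD 0.3 on the log-gain scale; people who
desynchronize more also rebound more) and an independent 0.75 dB jitter per
window. Early drafts used ±5 dB with little between-subject spread; the
resulting t-fields (|t| ≈ 45 at n = 26) are unphysiological and were revised
to the present values.

**Clinical linkage.** Scores are linear functions of the injected magnitudes
plus Gaussian noise, clipped to instrument ranges (FMA 0–66, EmNSA
exteroception 0–32, proprioception 0–8, star cancellation 0–54): motor score
worsens with weaker beta desynchronization; the somatosensory score improves
with beta rebound, with a delta association confined to the sensorimotor
group; the touch threshold depends on evoked amplitude in the sensorimotor
group only. Change scores (T2 − T1) link baseline beta rebound to motor
change and baseline amplitude to somatosensory change. The linear-Gaussian
form mirrors the regression models used downstream, so parameter-recovery
tests are meaningful.

**What the generator does not emulate:** ocular/muscle artifacts, realistic
head-model topographies, non-stationary background states, alpha spectral
peaks, or hardware differences between acquisition systems. Passing tests
therefore demonstrate the correctness of the computations under the stated
generative model, not robustness to every property of clinical recordings.

All randomness flows from one master seed through fixed affine substreams
(`derive_seed()`), so any single participant is reproducible in isolation.

# Preprocessing

A 1–35 Hz Hamming windowed-sinc FIR (order ≈ 3.3·fs, ~1 Hz transition at the
low edge) applied forward and backward (zero phase, squared magnitude
response; ≥ 80 dB at DC and above the upper edge). Bad channels are flagged
on robust log-variance z-scores (threshold 3.5, MAD floored at 0.15
log-units so near-identical montages do not degenerate) or on a best
absolute correlation below 0.4 with every other channel; flagged channels
are dropped, not interpolated, and the common average reference is computed
over the retained channels. The central analysis electrodes C3/C4 are
retained even when flagged (with a warning) because every downstream
measurement needs them; `preprocess(keep_central = FALSE)` disables this. Bad segments are marked by a 1 s sliding-window
peak-to-peak threshold (200 µV), excised exactly (retained samples are
bit-identical), and events whose −1.5 to 2.2 s epoch touches a marked span
are dropped and logged. The channel and segment criteria are deterministic,
documented stand-ins for proprietary artifact-rejection tools; no ICA stage
is included because the generator produces no ocular or muscle components (a
no-op hook marks where one would go).

# Time-domain measurement

Epochs span −0.5 to 1.5 s (half-open sample windows, 0-based indexing, the
stimulus at t = 0), baseline-corrected to the −500 to 0 ms mean. After
trial-averaging per hand, the negative peak is the minimum in 50–250 ms and
the positive peak the maximum after it up to 500 ms; the search windows are
configuration-exposed because published reports typically leave them
implicit — the defaults bracket the reported healthy positive latency
(202.69 ± 70.62 ms). Stroke participants are measured at the ipsilesional
central electrode for impaired-hand stimulation; controls at the electrode
contralateral to the dominant hand.

# Time-frequency decomposition

Complex Morlet wavelets `exp(i2πtf)·exp(−t²/(2σ_t²))` with `σ_t = 10/(2πf)`
at 30 logarithmic frequencies `f_k = 35^(k/29)` (1–35 Hz). Kernels are
truncated at ±3.5 σ_t and unit-energy scaled — the scale cancels in the dB
normalization and is fixed only for bit-reproducibility. Epochs span −1.5 to
2.2 s; power is the squared magnitude of the convolution, averaged across
trials, then dB-normalized to the frequency-specific mean power in −0.4 to
−0.1 s.

Three numerical safeguards matter here:

* **Epoch taper.** A 0.25 s raised-cosine ramp at each epoch end suppresses
  the broadband leakage an abrupt edge would inject.
* **Edge-bias correction.** Near the edges the finite epoch truncates the
  kernel; raw power would fall off by a deterministic, data-independent
  factor. Each bin is divided by the fraction of kernel energy overlapping
  the (tapered) epoch, making edge bins unbiased at the cost of variance.
  Without this, surrogate statistics on shifted matrices reach |t| > 100
  purely from the shared rolloff. Bins whose estimates remain
  edge-dominated are flagged in metadata, not removed; at 1–2 Hz the kernel
  exceeds the pre-stimulus padding, which is inherent to this wavelet family
  on this epoch length.
* **Decimation.** Inside the pipeline the band-passed (≤ 35 Hz) data are
  decimated to 128 Hz before decomposition; nothing below the new Nyquist
  frequency is lost and the time-frequency grid halves. Tests that feed
  broadband signals to `tfr_power()` directly run at the native rate.

The trial-averaged power is normalized (not per-trial); per-trial
normalization is available as an option.

# Region-of-interest discovery

The mask procedure: (1) stack all participants' dB matrices (all groups,
both hands' conditions averaged per participant — pooling mitigates
circularity between discovery and the statistics computed inside the mask);
(2) at each bin in 0–1.6 s, a one-sample t across participants of the dB
value minus that participant's mean pre-stimulus baseline dB at that
frequency; (3) 2000 surrogate iterations, each drawing one `(Δf, Δt)` shift
uniformly over the grid and applying it with wrap-around to every
participant's matrix; (4) a bin enters the mask when its |t| reaches the
95th percentile of its own bin's 2000 surrogate values (two-sided on |t| by
default — a literal one-sided rule on signed t can never find
desynchronizations; the one-sided variant is a config switch).

**The surrogate reference.** The package's default keeps each participant's
*unshifted* pre-stimulus baseline as the reference for shifted values, so
the surrogate destroys the event alignment of the tested values but not of
the reference. Re-deriving the reference from the wrapped matrix (available
as `shift_baseline = TRUE`) is degenerate: whenever a shift rotates a
post-stimulus effect plateau under the baseline columns, entire frequency
rows acquire coherent offsets whose mean/SD ratio across participants
matches — and, for sync-minus-desync pairings, exceeds — that of any
genuinely aligned effect, at every effect size. Under that variant no real
response can reach the inclusion percentile, which is why it is not the
default.

**A capacity limit worth knowing.** Because the surrogate values are
(approximately) exchangeable relabelings of the time-frequency plane, the
per-bin 95th-percentile rule can admit only about 5% of the plane's bins.
A configuration of phenomena that genuinely occupies much more than that —
the five canonical windows cover roughly 39% of the 0–1.6 s analysis plane —
can therefore never be recovered in full at high overlap by this procedure,
regardless of effect size; what the mask returns are the *cores* of the
strongest phenomena. The recovery figures reported by
`scripts/acceptance.R` quantify exactly this. Pipelines needing full-window
features fall back, per canonical window without an overlapping discovered
region, to the window rectangle itself (flagged in the output).

**Labelling.** Connected components are computed under 4-connectivity within
cells defined by effect sign (synchronization vs desynchronization) and by
the standard EEG band taxonomy (splits at 4, 7 and 13 Hz): band-adjacent
same-sign phenomena are contiguous on a 30-bin log grid and would otherwise
always merge into single components. Components under 10 bins are dropped.
Plain maximal components are available via
`mask_config(split_sign = FALSE, split_bands = NULL)`. The inclusion
percentile uses the `ceiling(p/100·n)`-th smallest null value, so the rule
is exact under full enumeration (tested against a brute-force oracle on a
4×8 grid).

# Statistics

* **Amplitude:** one-way fixed-effects ANOVA on GROUP; Tukey-corrected
  pairwise contrasts (via *emmeans*) are available regardless of the omnibus
  p. Cohen's d uses the (n−1)-weighted pooled SD — stated explicitly because
  published effect sizes often leave the convention implicit.
* **ROI power:** linear mixed model `power ~ group × feature +
  (1 | participant)` via *lmerTest*, Satterthwaite denominator degrees of
  freedom, backward reduction of fixed effects, Tukey-corrected cell
  contrasts on the final model. A singular random intercept triggers a
  prominent warning and an OLS refit.
* **Clinical associations** (stroke subset): linear models of each outcome
  (at T1, or the T2−T1 change) on the six EEG features, stroke type, and all
  feature×type interactions, reduced by backward elimination: drop the
  highest-p eliminable term (marginality respected — a main effect never
  leaves while its interaction remains; aliased or untestable terms count as
  p = 1 and go first) until every retained term has p < 0.05. With 6
  motor-stroke participants the full interaction block is exactly aliased
  (7 interaction columns cannot be independent on 6 rows), which is why the
  aliasing rule exists. p-based removal at α = 0.05 is the default; ties
  break by formula order, so selection is deterministic.

Backward selection at α = 0.05 with ~12 candidate terms retains each inert
term with probability ≈ α, so the probability of ending with *exactly* the
generating terms is only ≈ 0.95^12 ≈ 0.54 — a property of stepwise selection
itself, not of this implementation; the package reports it rather than
hiding it, and `scripts/acceptance.R` measures it (~50–60% at n = 50).
Estimator-level recovery is clean: coefficient estimates are unbiased within
Monte-Carlo error at n = 200.

# Problem sizes used in the tests

The test-suite simulations are sized for a laptop-class run: unit tests use
reduced protocols (1–2 sets); the end-to-end recovery check runs one full
default cohort (26 participants, 160 stimuli/hand, 2000-iteration null); the
type-I calibration uses 200 stationary 16-participant stacks at 500
iterations; model-selection recovery uses 25 seeds at n = 50. These sizes
give Monte-Carlo error well inside the asserted tolerances.

# Known limitations

* At 1–2 Hz the wavelet support exceeds the pre-stimulus padding; estimates
  there lean on the edge-bias correction and are flagged.
* The mask's ~5% capacity limit (above) bounds how much of an extensive
  effect configuration it can return; treat discovered regions as cores.
* Stepwise model selection inflates selection-level type-I error; final
  models from n = 16 cohorts are exploratory, as in the study design this
  package serves.
* The generator's clinical noise and effect sizes are repository defaults
  chosen for realism, not fitted to any dataset.
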