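---
title: "Methods: two-level 1-D CNN QRS detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-level 1-D CNN QRS detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qrscnn)
```

## The detection problem

A single-lead ECG records one heartbeat as a P wave, a QRS complex (the Q,
R and S deflections of ventricular depolarization) and a T wave. Beat
detection means localizing the R-peak of every QRS complex. `qrscnn`
implements a detector whose only preprocessing is temporal differencing and
block averaging, whose features are learned by a small two-level 1-D
convolutional network, and whose output is a per-sample 4-class posterior
(Q wave, R wave, S wave, non-QRS) that a simple decision stage converts
into beat locations.

## Preprocessing

Two derived signals are computed from the raw ECG $s_r[n]$:

* the **difference signal** $s_d[n] = s_r[n] - s_r[n-1]$, which accentuates
  the steep QRS slopes and suppresses baseline drift;
* the **averaged-difference signal**: $s_r$ is averaged over non-overlapping
  blocks of $N_i$ samples (downsampling by $N_i$) and then differenced,
  $s_{ad}[n] = s_a[n] - s_a[n-1]$, giving a coarse timebase that spans a
  whole beat with few samples.

Both differences define `out[0] = 0` instead of dropping a sample, so all
three signals stay index-aligned; the trailing partial averaging block is
discarded rather than zero-padded to avoid edge bias. No normalization or
filtering of any kind is applied — the difference operation already removes
the DC level, and the network is trained on un-normalized inputs.

$N_i$ is not a free-floating tuning knob: the published window geometry (a
56-sample window that spans 0.16 s on the fine timebase and 0.78 s on the
coarse one at 360 Hz) forces $N_i = 5$, which is the package default. It
remains a parameter of `average_difference()` for other sampling rates.

## Segmentation

At every detection point the classifier sees a pair of 56-sample windows —
22 samples before the point, the point, and 33 samples after it:

* the **object-level window** on the averaged-difference timebase
  (0.78 s at 360 Hz, `n_i = 5`): a whole-beat context;
* the **part-level window** on the difference timebase (0.16 s): the QRS
  complex at full resolution.

Detection points enumerate the averaged timebase (stride of one averaged
sample, i.e. $N_i$ raw samples); the part window is slaved to the object
window through `center_raw = center_avg * n_i + floor(n_i / 2)`, so both
windows are co-centered on the same physical time. Points whose windows
would cross a record edge are skipped, so roughly the first and last
third of a second of every record are unscanned — the warm-up inherent to
any windowed detector (this is what caps synthetic sensitivity just below
100% on short records: the edge beats are unreachable by construction).

Training labels are assigned per detection point: `R` within one averaged
sample (±14 ms) of an annotated R-peak; `Q`/`S` within 2 raw samples of the
beat's Q/S landmark; `NONQRS` farther than 0.2 s from every R-peak. Points
in the ambiguous band in between get no label and are excluded from
training, so the classifier is never asked to draw an arbitrary boundary
inside the QRS complex. When annotations carry only the R fiducial (the
usual case for clinical databases), Q and S landmarks are derived as the
raw-signal minima within 0.06 s before/after each R (`locate_qs()`). Note
that on a composite waveform this trough sits a few samples away from the
center of the underlying Q/S deflection, because the rising R flank
overlaps it; labels are therefore internally consistent but not identical
to a generator's component centers.

## Network and training

Both branches use valid (unpadded) 1-D cross-correlation with 5-tap
kernels, 5 feature maps per layer, ReLU activations, and mean-subsampling
by 2 (each non-overlapping pair of activations replaced by its mean):

| branch | layers | feature lengths | features |
|---|---|---|---|
| object | conv5 ×5, mean2, conv5 ×5, mean2 | 56 → 52 → 26 → 22 → 11 | 55 |
| part | conv5 ×5, mean2 | 56 → 52 → 26 | 130 |

The 185 concatenated features feed a 20-neuron ReLU layer and a 4-neuron
softmax output. These counts are recomputed and asserted every time a
`network_spec()` is constructed, so an architecture regression fails at
object creation, not in a test.

The trained objective is the **squared error on the softmax outputs**,
$E = \sum_j (t_j - y_j)^2$, with $t$ one-hot over {Q, R, S, non-QRS}. The
gradients are derived by hand and propagate through the full softmax
Jacobian (not the cross-entropy shortcut); cross-entropy is available
behind `train_config(loss = "cross_entropy")` for comparison but is not
the default. Mean-subsampling back-propagates `1/factor` to each pooled
input; the ReLU subgradient at exactly 0 is taken as 0; the second
convolution layer is fully connected across its 5 input maps.

SGD uses the initial learning rate $\eta_0 = 0.005$ with a multiplicative
decay of $1 - 10^{-6}$ per mini-batch iteration (a 0.0001% decrement read
multiplicatively: an absolute decrement of the same size would drive the
rate negative within a million iterations, whereas the multiplicative
schedule gives the closed form $\eta_t = \eta_0 (1-10^{-6})^t$, about
$\eta_0/e$ after $10^6$ iterations). Choices the objective and schedule do
not pin down are set as follows: He-style Gaussian initialization
($\sigma = \sqrt{2/\mathrm{fan~in}}$, ReLU-appropriate) with zero biases;
batch size 16; at most 200 epochs; a 10% validation split with early
stopping at patience 20, returning the best-validation parameters.
Training is deterministic given the seed: initialization, the validation
split, and every shuffle derive from sub-streams of `train_config()$seed`.
"1-D convolution" is implemented as cross-correlation without kernel flip;
with learned kernels the two conventions are equivalent up to
re-parameterization, and fixing one makes saved models reproducible.

## Decision stage

The sliding scan emits a 4-class posterior per detection point. Only the R
posterior forms events (the evaluation protocol scores beats, i.e. R
events; Q and S posteriors are exposed in the stream for downstream wave
delineation). The decision policy — not something the learned classifier
defines — is:

1. contiguous runs with R posterior above `threshold` (default 0.5) become
   candidate events at the run's argmax center;
2. events closer than the refractory period (default 0.2 s, the
   physiological minimum RR interval) keep only the higher-confidence one;
3. each event is refined to the maximal-|amplitude| raw sample within
   ±0.05 s, moving only on strict improvement so the operation is
   idempotent and leaves flat signals untouched.

## Synthetic data: what it emulates and what it does not

`generate_record()` renders each beat as five Gaussian deflections (P
+0.15 mV/45 ms at −0.2 s; Q −0.15 mV/15 ms at −0.04 s; R +1.0 mV/20 ms;
S −0.2 mV/15 ms at +0.04 s; T +0.3 mV/70 ms at +0.3 s — widths are
Gaussian standard deviations and offsets are relative to the R apex),
qualitatively matching a normal lead-II morphology at 360 Hz. RR intervals
are $60/\mathrm{HR}$ times lognormal multiplicative jitter (5% by
default), clipped to the physiological range 0.3–2.0 s; per-beat amplitude
jitter (5%) scales all five waves jointly; optional sinusoidal baseline
wander (0.05 mV at 0.33 Hz by default) emulates respiration-band drift.
One master seed is split into independent sub-streams (schedule,
morphology, wander phase, noise) so noise realizations can vary while the
beats stay fixed.

`add_gaussian_noise()` injects white Gaussian noise whose variance is set
from the mean square of the mean-removed whole record:
$\sigma^2 = P_\mathrm{signal} / 10^{\mathrm{SNR}/10}$. This whole-record
power reference and white-noise bandwidth are this package's convention —
the quantity "SNR" is not otherwise fully specified — and the realized SNR
is verified to within 0.2 dB at $10^5$ samples.

What the generator deliberately does **not** emulate: pathological
morphologies (ectopic beats, bundle-branch blocks, atrial fibrillation),
colored physiological noise (muscle artifact, electrode motion), lead
placement variation, or amplitude quantization. Passing the synthetic
recovery criteria therefore shows that the pipeline is implemented
correctly and learns the intended discriminative structure; it does not
certify clinical-database performance, which depends on exactly the
morphological variability the generator omits. The published per-record
evaluation tables are shipped as data (`reference_counts()`) so the metric
arithmetic — but deliberately not the detector itself — can be validated
against them.

## Evaluation protocol

Predicted and reference beats are matched one-to-one by greedy
nearest-neighbor assignment within a tolerance window (default 0.15 s, the
standard beat-matching window); greedy equals optimal assignment whenever
beats are more than twice the tolerance apart, which the 0.2 s refractory
guarantees. From TP/FP/FN counts:

$$\mathrm{Sen} = \frac{TP}{TP+FN},\quad
  \mathrm{PPR} = \frac{TP}{TP+FP},\quad
  \mathrm{DER} = \frac{FN+FP}{TP+FN},\quad
  \mathrm{Acc} = \frac{TP}{TP+FP+FN}$$

all reported as percentages, rounded half-up to 2 decimals only at report
time. Multi-record summaries pool the counts and recompute (never average
percentages) — verified self-consistent against the published overall
rows. SNR sweeps reuse the same noise-seed list at every SNR level, a
paired design that keeps the degradation trend free of seed-to-seed
variance.

## Problem sizes and numerical checks

The test suite builds everything it needs at run time: unit fixtures use
10–100-beat corpora, and the end-to-end study conditions are a 400-QRS
balanced corpus (1600 segment pairs, seed 7) evaluated on ten held-out
60 s records, with the noise sweep at {40, 20, 10, 5} dB over five paired
seeds. Convolution and pooling are checked against brute-force loop
oracles (tolerance 1e-10, 200 random shapes); every gradient tensor is
checked against central finite differences (step 1e-5, relative tolerance
1e-4, five seeds); matching is checked against an exhaustive assignment
oracle on well-separated instances; model serialization round-trips the
forward pass to 1e-12.

## Known limitations

* Labels beyond the R event are only as good as the Q/S landmark rule;
  biphasic or slurred QRS morphologies would need annotated landmarks.
* The decision stage is intentionally simple (single threshold plus
  refractory); no search-back or adaptive thresholding is attempted, so
  very low-amplitude beats below the posterior threshold are missed rather
  than rescued.
* Records shorter than about one second cannot be scanned at all, and
  beats within ~0.35 s of either record edge are structurally undetectable.
* The WFDB binary format is not parsed; signals enter via the documented
  CSV + JSON-sidecar format (or any reader that can produce a
  `raw_signal`).
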