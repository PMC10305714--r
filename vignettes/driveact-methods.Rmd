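---
title: "Methods: synthetic driver-activity recordings and their classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic driver-activity recordings and their classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(driveact)
```

## The problem and the model

Smart glasses with EOG electrodes and an inertial unit observe two things
that differ systematically across driving activities: where the eyes move
(saccades while scanning mirrors, a sustained gaze during a turn, large
vertical excursions when bending or drinking) and how the head accelerates
(lateral bursts during turns, slow trunk motions during distractions).
`driveact` classifies sixteen such activities — twelve primary manoeuvres
and four secondary distractions — from seven channels: EOGL, EOGR, the
derived horizontal channel EOGH = EOGL − EOGR, the derived vertical channel
EOGV = −(EOGL + EOGR)/2, and tri-axial acceleration.

The classifier is a one-dimensional convolutional network: three blocks of
128 length-5 kernels with batch normalisation and ReLU, max pooling of size
3 after the first block, global average pooling, dropout 0.4, and a dense
softmax over the 16 classes. It is trained with Adam at learning rate
2×10⁻⁴, batch size 32, on categorical cross-entropy. Global average pooling
makes the decision depend on *time-averaged* local pattern activations —
an assumption worth keeping in mind when interpreting both the synthetic
generator and the results (see "Design choices").

## The synthetic generator: what it emulates, and what it does not

The recordings the original analysis was developed on are private, so the
package ships a generator that emulates their statistical structure:

* channel identities hold exactly (EOGH/EOGV are derived from the
  electrode pair *after* electrode-level noise is added);
* native rates 200 Hz (EOG) and 100 Hz (acceleration), ±2 g clipping with a
  clip count in the manifest, durations 2.06–60.26 s with class-specific
  ranges (a glance over the shoulder is seconds; a full roundabout loop can
  be a minute);
* noise the preprocessing chain is designed to remove: mains pickup
  (50/60 Hz sinusoid), slow baseline drift (sum of two low-frequency
  sinusoids, 0.01–0.12 Hz), sparse 1–2-sample spikes, and white sensor
  noise.

Each class is a fixed grammar over four closed-form event primitives:
`saccade` (raised-cosine rise, plateau, exponential return), `blink`
(biphasic pulse), `head_turn` (Gaussian-windowed single-cycle sinusoid) and
`reach` (raised-cosine bump). Every template starts and ends at exactly 0
and peaks at exactly the requested amplitude, which keeps unit tests
closed-form. Event positions, amplitudes and durations carry ±12 % seeded
jitter so recordings within a class differ.

The grammar (amplitudes relative to the configured saccade amplitude A and
head-motion amplitude M):

| class | eye signature | acceleration signature |
|---|---|---|
| crossroad L/R | 2 check + 1 sustained saccade toward the side | single lateral yaw cycle toward the side |
| crossroad straight | left-right check pair | small longitudinal bump |
| parking (6) | side-biased scan saccades, 3 (diagonal) / 6 (parallel) / 4 (perpendicular) per recording | alternating yaw bursts, a sustained lateral arc toward the parking side, and subtype-specific shunting: 2 bumps / 3 alternating / 1 long reverse |
| roundabout L/R/S | gaze oscillation of 3 / 1 / 2 cycles plus one glance per exit | matching lateral oscillation; straight brakes at both islands |
| bending | one large slow downward vertical excursion | large downward + forward trunk reach |
| drinking | two tilt-back vertical excursions | two upward pulses |
| eating | train of five bite pulses | three small vertical oscillations |
| turning back | one very large horizontal sweep plus an over-the-shoulder vertical excursion | large single yaw/roll cycle and a trunk twist on the vertical axis |

All classes additionally blink at the configured spontaneous rate.

A consequence of the preprocessing chain worth stating explicitly: EOG
channels are detrended **by differencing**, which attenuates a component of
frequency f by a factor ≈ 2πf/f_s. Slow gaze excursions (≈0.1 Hz) are
therefore essentially invisible in the processed EOG — only sharp
transients (saccade edges, blinks) survive. The grammar reflects this by
carrying the slow within-group distinctions in the acceleration channels,
which are *not* differenced. Likewise, global average pooling cancels
zero-mean alternating patterns, so laterality is encoded in features with a
nonzero time average (the sustained lateral arc during parking, the biased
scan amplitudes), not only in signed alternations.

What the generator does **not** model: physiologically calibrated µV
amplitudes (z-scoring makes scale immaterial), vehicle dynamics,
subject-level variability beyond seeds, gyroscope channels, or label noise.
A green end-to-end test therefore establishes that the pipeline can recover
the class structure it states — not that it would reach the same accuracy
on real drivers.

## Preprocessing: parameters, units, defaults

| parameter | default | why |
|---|---|---|
| EOG low-pass cut-off | 20 Hz | preserves saccadic content; removes 50/60 Hz mains before decimation to 50 Hz |
| Butterworth order | 2 (4 effective) | the forward–backward pass squares the magnitude response and zeroes the phase |
| detrend | first difference | removes electrode-polarisation drift; an optional 0.05 Hz high-pass (`eog_detrend = "highpass"`) is provided because a band-pass description and a differencing description both exist for this step |
| median kernel | 5 samples | suppresses 1–2-sample spikes; unstated in the source, chosen for that width |
| FIR | Hamming, 31 taps, 20 Hz | linear phase, integer group delay (compensated exactly), ≥40 dB stopband; the acceleration filter is implemented as a low-pass *removing components above* 20 Hz — the physically coherent reading of an ambiguous description of head-rotation bandwidth |
| sync rate | 50 Hz | EOG decimated ×4, acceleration ×2, after an order-4 anti-alias low-pass at 0.4×50 Hz |
| z-score | population σ | Eq.-style normalisation to mean 0, sd 1; constant channels map to zeros with a warning |
| windows | T = 280, stride 140 | 5.6 s at 50 Hz, 50 % overlap; lengths are truncated to a multiple of the stride before windowing |
| model length | 3000 | "resampled at a rate of 3000" is read as a *length* (3000 Hz would contradict the 50 Hz synchronisation); linear interpolation preserving endpoints and monotonicity |

The source describes both sliding windows and resampling to 3000 without
stating how they compose; both are implemented (`segmentation_mode`), with
`whole_resampled` the default because recordings are variable-length and
one fixed-length input per recording matches the training setup. After
resampling, the z-score is reapplied so model inputs are exactly
standardised.

## The network: numerical choices

* Optimiser: Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e−8). The optimiser is not
  named in the source; Adam is the standard choice at the stated learning
  rate.
* The dense layer width is the number of classes (16); the architecture
  table's literal "Dense 2" is treated as a template value.
* Max pooling appears once, after block 1, exactly as tabulated.
* Epochs default to 100 with an optional early-stopping patience; the
  scaled benchmark uses 30 (its stated cap).
* Batch norm: population statistics with momentum 0.1, ε = 1e−5. The conv
  biases are retained for fidelity to the layer definition even though batch
  norm makes them redundant (their gradient is exactly zero).
* All randomness (He-normal initialisation, shuffling, inverted-scaling
  dropout masks) is drawn from R's RNG under the config seed; the compiled
  forward/backward passes are deterministic, so training is bit-reproducible.
* Ties in the argmax break toward the lowest class code.
* Degenerate inputs: empty train/validation sets error; a non-finite loss
  aborts with a diagnostic rather than continuing.

Splits are stratified: the 9:1 and then 8:2 stage targets are apportioned
across classes by largest-remainder rounding, so the global 72/18/10
fractions are met exactly while classes stay balanced.

## Scaled-down benchmark

`run_scaled_benchmark()` is the package's end-to-end measurement: 20
recordings per class (320 total) at default noise, inputs resampled to 600
samples, the standard architecture trained ≤30 epochs. On seeds 1–3 it
measures held-out 16-class accuracy and the binary primary/secondary
accuracy on 32 test recordings per seed; `scripts/acceptance.R` reports the
medians. Input length 600 (rather than 3000) and ≤30 epochs (rather than
100) keep a single-CPU run within minutes; they reduce — not inflate — the
achievable accuracy, so the benchmark bounds the pipeline from below.

## Known limitations

* The generator's class grammar is a stated world: separability is designed
  in, and the benchmark validates the pipeline, not the difficulty of the
  real task. Parking left/right mirror pairs are deliberately the closest
  classes and dominate residual confusions.
* The CNN is CPU-only and dense-matrix based; it is sized for the
  benchmark, not for large-scale training.
* The windows segmentation mode shares one label across all windows of a
  recording and has no overlap-aware aggregation at prediction time.
* `read_jins_csv()` accepts only the dialect defined here (plus optional
  gyro columns, which are ignored); vendor binary formats are out of scope.
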