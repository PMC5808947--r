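---
title: "Passive Doppler sensing: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Passive Doppler sensing: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The sensing problem

`pdsense` implements a passive bistatic radar pipeline for contactless
e-health monitoring. A third-party DSSS transmitter in the sub-1 GHz ISM
band (915 MHz) illuminates a room; one receive chain (the *reference*
channel) captures the transmitted waveform, a second (the *surveillance*
channel) captures reflections from the monitored area. Correlating the two
channels over delay and Doppler -- the cross-ambiguity function (CAF) --
reveals moving reflectors. Two branches share this front end:

* **Breathing detection** (static person): chest-wall motion of a few
  millimetres modulates the surveillance channel; a per-frame
  center-weighted Doppler statistic recovers the respiration waveform, which
  is smoothed (Savitzky-Golay) and Fourier-analysed for the rate.
* **Activity recognition** (moving person): whole-body motion produces
  Doppler signatures of tens of Hz; 4-second spectrogram windows are reduced
  to SVD, PCA or physical feature vectors and classified by a one-against-one
  SVM over six activities of daily living (walking, running, jumping,
  standing up, sitting down, turning).

A motion indicator -- a threshold on the non-zero-Doppler spectrogram power
-- switches between the branches automatically.

Because no public recordings exist for this kind of system, the package
ships a first-class scene simulator (`breathing_scene()`,
`activity_scene()`, `generate_experiment_corpus()`) that generates paired
reference/surveillance IQ recordings with known ground truth, and every
stage is tested against it.

## Signal model

The reference channel carries the illuminator waveform $x(t)$: a stream of
random-phase chips shaped by a root-raised-cosine pulse (roll-off 0.25; the
true transmitter's pulse shape is unknown, and an RRC is the standard
choice). The surveillance channel is a sum over propagation paths

$$y(t) = \sum_l A_l\, x(t - \tau_l)\, e^{j(\phi_l + 2\pi f_c \int f_{d,l}(t)\,dt)} + w(t),$$

with attenuation $A_l$, delay $\tau_l$, baseband carrier phase $\phi_l$ and
*fractional* Doppler $f_{d,l}(t) \approx 2 v_l(t)/c$, so the instantaneous
shift in Hz is $f_c f_{d,l}(t)$ and all user-facing axes are in Hz. A
time-varying profile is realized by phase accumulation, which reduces to the
constant-shift narrowband model when $f_d$ is constant. Noise is complex
AWGN; hardware impairments (CFO, IQ imbalance) are out of scope.

At 915 MHz the carrier phase of a path, $-2\pi f_c \tau$, wraps every 33 cm
of path length: it is effectively random by geometry. This matters for
breathing (next section) and is why `path_spec()` exposes it.

## The batched CAF and why it is exact

`compute_caf()` evaluates

$$\mathrm{CAF}(\tau, f_d) = \sum_t y(t)\, x^*(t-\tau)\, e^{-2\pi i f_d t / f_s}$$

on a delay grid (one bin per sample) and a Doppler grid at $1/T$ spacing for
integration time $T$. The window is split into $n_b$ batches (odd, so one
bin is exactly zero Doppler); an FFT across the batch index resolves the
Doppler bins and an intra-batch twiddle correction makes the batched result
*identical* to the direct double-loop evaluation, to machine precision --
the classic batching approximation (constant phase per batch) is not
needed, and the unit tests compare against a brute-force oracle at
`1e-6` relative tolerance.

Per-mode defaults: activity $T = 1$ s (1 Hz bins, span $\pm 60$ Hz,
rectangular taper, non-overlapping frames), breathing $T = 2$ s (0.5 Hz
bins, span $\pm 5$ Hz, Hann taper, 0.25 s frame hop). Breathing mode
resolves finer Doppler than activity mode; the finer bins are still far
coarser than the sub-0.1 Hz chest Doppler, which is exactly why the
micro-Doppler statistic, not peak tracking, reads the breathing. The Hann
taper in breathing mode controls the leakage of the dominant zero-Doppler
component into the neighbouring bins, where the interference mechanism
described below lives; activity mode keeps the rectangular window of the
plain ambiguity sum. The range resolution $c/2B$ is 7.5 m at the 20 MHz
illuminator bandwidth -- too coarse for indoor ranging, so the pipeline
never localizes in range and only uses the strongest range cell.

CLEAN (`clean_caf()`) subtracts the reference self-ambiguity surface scaled
by the complex ratio of zero-Doppler peaks (aligned at the direct-path
delay), optionally iterated with a 0.1 dB stopping tolerance. It suppresses
a direct-path-only peak by far more than 20 dB while moving echo peaks
change by well under 1 dB.

## The micro-Doppler statistic: literal weights, not centered ones

Each breathing-mode frame is collapsed to
$\Psi(n) = \sum_i D[i, n]\, w_i$. For an odd number of bins $2M+1$, the
ceiling-ramp weights of the original statistic equal a centered
antisymmetric ramp **plus one**:

$$w = (-M, \dots, 0, \dots, M) + 1.$$

The two parts measure different physics:

* The *antisymmetric ramp* reads the positive/negative Doppler imbalance, a
  first-order **velocity** signal. Over full breathing cycles a velocity
  waveform is orthogonal to the displacement waveform
  ($\int x \dot x\,dt = 0$), so this part alone cannot correlate with a
  displacement reference.
* The *+1 offset* adds the total column magnitude, dominated by the
  zero-Doppler bin $|A_s + A_c e^{j(\chi + \beta x(t))}|$ -- the
  interference of the aggregate static field $A_s$ with the chest echo. For
  small phase modulation $\beta x(t)$ this is linear in the chest
  **displacement** $x(t)$ with gain $\propto \sin\chi$.

`extract_micro_doppler()` therefore defaults to the literal weights
(`weights = "literal"`), which is what lets the recovered waveform reach
$R > 0.9$ against the displacement belt reference; `weights = "centered"`
isolates the pure asymmetry (and satisfies the exact symmetry identity
$\Psi \equiv 0$ for columns symmetric about zero Doppler).

The gain $\sin\chi$ depends on the chest path's carrier phase $\chi$
relative to the static field -- the classic *null point* of CW Doppler
vital-sign monitoring: at $\chi = 0$ or $\pi$ the modulation vanishes to
first order, at quadrature it is maximal. Since $\chi$ is geometry-random at
UHF, `chest_motion_path()` defaults to the optimum demodulation point
$\chi = -\pi/2$ (sign chosen so inhale gives a positive swing), and
`breathing_scene()` jitters it by $\pm \pi/6$ as inter-scene variation.
Scenes at a null point would need the diversity techniques (frequency or
spatial) that real deployments use; they are out of scope here and this is
the main optimistic simplification of the breathing simulator.

Breathing mode deliberately does **not** CLEAN its CAF frames: CLEAN nulls
the zero-Doppler peak per frame and would erase precisely the
interference modulation that carries the displacement. The motion indicator
is unaffected, since it excludes the zero-Doppler bin from its power sum.

## Breathing-rate estimation and belt evaluation

The raw $\Psi(n)$ is smoothed by a Savitzky-Golay filter (window 2 s,
polynomial order 3, via `signal::sgolayfilt`, whose edge rows evaluate the
first/last window's polynomial off-center). The window reproduces
polynomials up to degree 3 exactly and preserves peak shape within a
breathing cycle at 12-20 breaths/min. The rate is the argmax of a
zero-padded FFT magnitude within a 6-30 bpm search band; a constant series
or a flat in-band spectrum flags the estimate invalid.

`evaluate_against_reference()` resamples the radar waveform down onto the
belt's time grid, z-scores it, scales the belt to the same convention and
reports Pearson $R$ and the MSE of the aligned pair (on that scale
$\mathrm{MSE} = 2(1-R)$). The simulated belt is the chest displacement
ground truth plus optional sensor noise; correctness of a rate estimate is
$|\hat r - r| \le 1$ bpm, since only percent-correct figures without a
stated tolerance exist for the original system.

## Motion indicator

Per frame, the Doppler power is the squared-magnitude sum over
non-zero-Doppler bins (the zero bin holds the static residual). Frames above
`min + 0.10 (max - min)` of a rolling 30 s context are labelled moving and
merged into segments. Two caveats are handled explicitly:

* A session with a *single* state has no internal contrast, so the 10% line
  needs an external amplitude reference; `motion_indicator()` accepts one
  (`reference_range`), mirroring a deployed system's fixed reference level,
  and the trace-level discrimination experiment pools the power range over
  the whole measurement campaign (the separation between breathing-only and
  walking traces is about three orders of magnitude).
* `run_pipeline()` additionally validates each segment with a scale-free
  statistic, the mean/median ratio of the non-zero-Doppler bin powers:
  noise-like (static) frames give values near 1.4, a Doppler ridge
  concentrates energy and pushes the ratio far above the cut at 5. This
  makes single-state recordings route to the correct branch without any
  calibration.

## Activity branch

Activity velocity templates are invented stand-ins constrained by the
described signatures: a gait-modulated 1.2 m/s trapezoid (walking), a
faster, stronger variant (running), a biphasic $\pm$3.6 m/s oscillation
with the widest Doppler excursion (jumping), and sub-second monotone or
biphasic transients (standing up, sitting down, turning). At 915 MHz,
1 m/s maps to 6.1 Hz. The 180-recording corpus (6 activities x 10
repetitions x 3 subjects) draws per-subject speed/tempo multipliers
(s.d. 8% / 10%) and small per-repetition jitter (3%); subjects therefore
differ only in these scalars, which is much less inter-subject variation
than real gait differences.

Features per 4 s window: the leading 10 singular values (SVD); projections
onto the PCA eigenbasis of the training frames' Doppler-profile covariance,
keeping components up to 90% eigenvalue energy and at most 10 (the basis
and the feature standardization are functions of the training split only,
re-computed inside every evaluation split -- the no-leakage property is
asserted in the tests); and six physical descriptors (active duration,
Doppler bandwidth, peak positive/negative Doppler, total energy,
positive/negative energy ratio). The exact feature table of the original
system is not public; these six follow its named examples plus standard
micro-Doppler descriptors and are an approximation.

Classification uses one linear soft-margin SVM per class pair
(15 classifiers for 6 classes, libsvm via `e1071`; `C = 1`), majority vote,
ties broken by the summed signed decision margins. Evaluation protocols:
repeated stratified 20-train/10-test splits (10 repeats), an accuracy
vs. training-size curve over {10, 15, 20, 25}, and leave-one-subject-out.
On the default corpus the best feature method exceeds 85% mean accuracy
comfortably and the mean-over-methods inter-subject accuracy stays below
the within-subject one; individual methods can saturate at 100% on this
synthetic corpus (the templates are cleanly separable), so the
within/inter-subject ordering is checked on the method mean. The relative
ranking of the three feature methods on real recordings is *not* expected
to be reproduced by the simulator.

## What passing tests do and do not show

The simulator emulates: DSSS illumination with realistic correlation
properties, multipath with geometry-random carrier phases, millimetre chest
motion at 12-20 bpm, activity Doppler up to tens of Hz, AWGN at
configurable SNR, inter-subject parameter jitter. It does not emulate:
antenna patterns, through-wall propagation, clutter motion (fans, pets),
non-ideal clock sharing, body scattering models beyond a point target, or
the real diversity of human movement. Passing the breathing and activity
benchmarks on synthetic scenes therefore validates the *signal processing*
-- not the field performance of a deployment, whose published headline
accuracies stem from hardware recordings that were never released.

## Problem sizes and numerical choices

Scenes are simulated at a 2 kHz IQ rate (chip rate 500 Hz): indoor delays
are far below one delay bin at any achievable bandwidth, so scene-level
work needs only the Doppler dimension, and the full-rate 20 MHz/1 MHz
defaults of `source_spec()` are exercised where the bandwidth itself is
under test. The test batteries use 100-seed localization and breathing
runs, a 10-seed CLEAN monotonicity sweep and the full 180-recording corpus.
Other numerical choices: the Doppler axis always has an odd bin count so
bin 0 is exactly zero; trailing samples that do not tile into batches are
trimmed with a warning; an all-zero self-ambiguity surface makes CLEAN a
no-op; the positive/negative energy ratio is regularized by `1e-12` so an
empty window reports 1; zero-variance features standardize with unit scale;
SVM vote ties fall back to margins. All generators are pure functions of
their parameters and a seed.
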