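# pdsense

Passive bistatic Doppler radar signal processing for contactless e-health
monitoring: breathing-rate detection and human activity recognition from
paired reference/surveillance complex-baseband (IQ) recordings of a
third-party 915 MHz DSSS illuminator.

**Who it is for:** researchers in RF sensing / device-free physiological
monitoring who need a tested, end-to-end reference implementation of the
passive-radar vital-sign pipeline, together with a scene simulator that
makes every stage verifiable without radio hardware.

## The method

A reference channel captures the illuminator waveform `x(t)`, a
surveillance channel the reflections `y(t)`. The core operator is the
batched cross-ambiguity function

    CAF(τ, f_d) = Σ_t y(t) x*(t − τ) e^(−2πi f_d t / f_s)

computed per integration window T (Doppler bins at 1/T) with an FFT across
sub-window batches plus an intra-batch correction that keeps the result
exact. A CLEAN step subtracts the scaled reference self-ambiguity to remove
the direct path and static clutter from the zero-Doppler line. Stacking the
Doppler profile at the strongest range cell of each window yields the
Doppler spectrogram `D(f_d, n)`; the range resolution c/2B (7.5 m at
B = 20 MHz) is too coarse for indoor ranging, so everything downstream is
Doppler-only. A 10% threshold on the non-zero-Doppler power trace switches
between:

* **Breathing branch** — per-frame center-weighted statistic
  `Ψ(n) = Σ_i D[i, n] w_i` whose ceiling-ramp weights read the
  respiration-modulated interference at and around zero Doppler;
  Savitzky–Golay smoothing (2 s window, order 3); FFT rate estimate in
  6–30 bpm; Pearson-R/MSE evaluation against a chest-belt reference.
* **Activity branch** — 4 s spectrogram windows reduced to SVD singular
  values, PCA projections (90% energy, ≤ 10 components, basis trained on
  the training split only) or six physical descriptors, classified by a
  one-against-one linear SVM (15 pairwise classifiers for the six
  activities: walking, running, jumping, standing, sitting, turning) with
  majority voting.

Since no public recordings of such a system exist, the package includes a
deterministic scene simulator (DSSS source, multipath with geometry-random
carrier phases, millimetre chest motion, six activity velocity templates,
AWGN) used by all tests; see the methods vignette
(`vignettes/passive-doppler-sensing.Rmd`) for the model, parameter and
design-choice discussion.

## Worked example

```r
library(pdsense)

# --- breathing: simulate a 30 s scene of a person at 40 cm, 17 bpm ---
scene    <- breathing_scene(chest = chest_motion_model(rate_bpm = 17), seed = 42)
spec     <- scene_spectrogram(scene$ref, scene$surv, caf_config("breathing"))
waveform <- sg_smooth(extract_micro_doppler(spec))
estimate_rate(waveform)
#> <breathing_estimate: 16.99 bpm>
ev <- evaluate_against_reference(waveform, scene$truth$belt)
sprintf("belt correlation R = %.3f, MSE = %.3f", ev$r, ev$mse)
#> "belt correlation R = 0.918, MSE = 0.163"

# --- activity: a small corpus, PCA features, repeated 10-train/5-test splits ---
corpus <- generate_experiment_corpus(repetitions = 5, seed = 1)
corpus
#> <activity_corpus: 90 recordings (6 activities x 5 reps x 3 subjects)>
cw  <- corpus_windows(corpus)
res <- evaluate_splits(cw$windows, cw$labels, n_train_per_class = 10,
                       n_test_per_class = 5, repeats = 5, method = "PCA")
res$accuracy
#> [1] 1
res$confusion
#> <confusion_matrix: overall accuracy 1.000>  (diagonal 5s on this corpus)

# --- or let the pipeline route automatically ---
run_pipeline(scene$ref, scene$surv)
#> <pipeline_result>
#> <motion_segments: 1 segment(s)>
#>    -0.02 ..  29.98 s  static
#>   breathing 0.0-30.0 s: 16.99 bpm (R = 0.918)
```

The estimate lands within 0.01 bpm of the 17 bpm ground truth; the
recovered waveform correlates at R ≈ 0.92 with the simulated chest belt
(the displacement ground truth); the synthetic activity corpus is cleanly
separable at this SNR, so the small-split accuracy saturates at 1.0.

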