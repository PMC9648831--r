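---
title: "Classifying like/dislike from EEG during cream application: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying like/dislike from EEG during cream application: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

`eegpref` implements a subject-independent pipeline for classifying the
valence of a tactile experience — liking or disliking a cosmetic cream being
applied to the forearm — from 19-channel scalp EEG recorded around the
application period. Each trial carries a preference score on a 1–9 scale;
scores 1–4 define the *negative* (dislike) class, 8–9 the *positive* (like)
class, and the neutral midrange 5–7 is excluded. The scientific question the
pipeline addresses is whether spectral EEG features carry enough
subject-invariant information to classify the preference of a subject the
model has never seen.

The pipeline has five stages:

1. **Preprocessing** — 58–62 Hz zero-phase band-stop (order-4 Butterworth,
   forward–backward), extraction of the −15…55 s segment around the
   application trigger, and Morlet-wavelet time–frequency decomposition on a
   1–120 Hz, 1 Hz grid with 0.05 s time bins.
2. **Featurization** — 3 s sliding windows with 2 s overlap over the 0–30 s
   application span (28 windows per trial), averaging into four bands
   (alpha 7–15, beta 15–33, low gamma 33–70, high gamma 70–120 Hz),
   arrangement of the 19 channel values on a 5×5 scalp-layout grid, and
   merging of the four band grids into one 10×10 matrix.
3. **Dataset assembly** — labeling, exclusion of single-class subjects,
   per-subject class balancing by random oversampling, and per-subject
   two-class baseline correction.
4. **Classification** — seven small CNNs (an inception-style and a stacked
   network on the merged 10×10 input, a four-branch parallel network and
   four single-band networks on 5×5 inputs), trained with Adam.
5. **Evaluation** — leave-one-subject-out cross-validation with a rotating
   validation subject, post-hoc checkpoint selection, 7 s median filtering
   of the predicted label sequence, and per-subject aggregation.

Because no public recordings exist for this paradigm, the package ships a
synthetic-EEG cohort generator as a first-class, tested module; every stage
of the pipeline is exercised end to end on generated data.

# Morlet decomposition

The filter bank uses a fixed cycle count $C = 14$ at every center frequency
$f$, giving spectral bandwidth $\sigma_f = 2f/C$ and wavelet duration
$\sigma_t = 1/(2\pi\sigma_f)$, so $\sigma_t \sigma_f = 1/(2\pi)$ at every
frequency. Wavelets are unit-energy, which makes power comparable across
frequencies; power is kept linear (µV²), with no log transform — the
baseline correction is scale-normalizing anyway. The Gaussian envelope is
truncated at $\pm 4\sigma_t$, and output bins sit at integer multiples of
0.05 s relative to the trigger.

Edge effects: power within roughly $3\sigma_t$ of a segment end is
attenuated by envelope clipping. $\sigma_t$ is largest at 1 Hz
(≈ 1.11 s, so ≈ 3.3 s of edge), and the analysis span 0–30 s sits more than
11 s inside the −15…55 s segment at every frequency, so no analyzed window
touches the invalid region. A test asserts both the interior flatness and
the edge attenuation of a constant tone.

# Layout and band conventions

The 19 channels (10–20 system; T5/T6 are the classical names of P7/P8) are
placed on a 5×5 grid by scalp position; the six empty corner-row cells are
filled with the arithmetic mean of their neighboring channels, e.g. the
front-left corner with mean(Fp1, F7, F3) and the back-center cell with
mean(Pz, O1, O2) — note the back-center fill deliberately uses Pz rather
than a purely occipital neighborhood. Fill cells are convex combinations, so
the grid range never exceeds the channel range.

The printed band edges touch (15, 33 and 70 Hz would belong to two bands),
so on the 1 Hz bin grid the package assigns boundary bins upward: alpha
occupies bins 7–14, beta 15–32, low gamma 33–69, high gamma 70–120. Bins
1–6 Hz belong to no band. The merged 10×10 matrix places alpha top-left,
beta top-right, low gamma bottom-left, high gamma bottom-right (reading
order); the quadrant map is attached to the object, and any fixed order is
information-equivalent for a convolutional classifier.

# Baseline correction and its leakage trade-off

Per subject, channel-cell, and band, features are corrected as
$f' = (f - \bar f_{neg}) / (\bar f_{pos} - \bar f_{neg})$ using the
subject's own class-conditional means, pinning the negative-class mean to 0
and the positive-class mean to 1 exactly (asserted to 1e-9). This removes
the per-subject gain and offset differences that otherwise dominate
cross-subject variation.

Two consequences are worth stating plainly. First, the correction requires
both classes from every subject — which is why single-class subjects must be
excluded — and it uses the *test* subject's labels when that subject's data
are corrected. This is faithful to the evaluated protocol but is a leakage
concern for deployment; a deployed system would need an alternative
calibration. Second, cells where the two class means coincide have an
undefined correction. The default policy raises an error; a `"zero"` policy
passes 0 through with a warning (used for null cohorts, where class means
can coincide up to noise). The degeneracy tolerance is
$10^{-12}\max(|\bar f_{pos}|, |\bar f_{neg}|, 1)$.

Whether the test subject's windows should be evaluated balanced or
unbalanced is ambiguous; the default evaluates the balanced set (a
`test_balanced = FALSE` switch drops augmented test duplicates first).

# The CNN family

All models share: stride-1 convolutions with `same` zero padding (spatial
size preserved through every layer — for even kernels the extra pad goes to
the bottom/right), ten filters per convolution, ELU activations
($\alpha = 1$), one dropout layer before the head (rate 0.5 by default; the
rate is not specified by the protocol and is configurable), a two-unit fully
connected layer, and a softmax. Weights are Glorot-uniform, biases zero.

The inception-style model stacks three modules on the 10×10 input. The
module wiring concatenates four ten-filter branches — 1×1 bottleneck → 2×2
conv, bottleneck → 3×3 conv, bottleneck → 5×5 conv, and 3×3 max pool
(stride 1) → bottleneck — to a 40-channel output, with ELU after the
bottlenecks and after the concatenation. This wiring uses each of the
listed kernel sizes exactly once and reproduces the documented 40×10×10
input of the second module; other wirings satisfying 4 × 10 = 40 channels
would be information-equivalent, and the chosen one is recorded in the model
summary. Max pooling (rather than average) follows the classic inception
design the architecture is modeled on.

Training follows the protocol: mini-batch 128, Adam at learning rate 2e-4
(β₁ = 0.9, β₂ = 0.999, ε = 1e-8 — standard defaults, recorded in the run
manifest), cross-entropy loss, shuffling every epoch, one validation pass
per epoch, no schedule, no early stopping: the full epoch budget always
runs, and two checkpoints are selected post hoc (highest validation
accuracy; lowest validation loss; ties to the earliest epoch). Only the two
running-best parameter sets are retained during training, which is
selection-equivalent to saving every epoch while keeping memory bounded.

The convolution engine computes in single precision (the usual deep-learning
precision) with persistent scratch buffers behind an im2col + GEMM path;
backpropagation is verified against central finite differences for every
layer type and every architecture family.

# Evaluation protocol

With $n$ subjects, the schedule enumerates all ordered (test, validation)
pairs: $n(n-1)$ folds, each a disjoint ($n-2$)/1/1 partition. A hard
subject-ID audit fails the run if any test or validation sample — including
augmented duplicates — reaches training. Per-fold seeds derive from the
master seed and fold index, so folds are independently reproducible.

Predicted labels are smoothed per trial with a 7-window sliding majority
(the windows hop 1 s, so the kernel spans 7 s), with replicated edge
padding, never crossing trial boundaries. The filter operates on hard
labels; a score-median variant would require a different tie-breaking
convention and is intentionally not the default. One caveat found during
development: the sliding majority can change the *overall* majority label
of a 28-window sequence for adversarial alternation patterns (about 1 % of
random Bernoulli sequences), so "filtering preserves the trial majority" is
only a tendency, not an invariant; unanimous and long-run sequences are
invariant, and the filter is verified against a brute-force majority oracle
on every binary sequence up to length 12.

Metrics per confusion matrix (positive = like): accuracy, sensitivity
$TP/(TP+FN)$, specificity $TN/(TN+FP)$; empty denominators yield `NA`,
excluded from averages with a warning. Reporting averages each test
subject's folds first, then takes the unweighted mean ± standard deviation
across subjects, per architecture × checkpoint criterion × filter state.

# The synthetic cohort: what it emulates, and what it does not

Each trial is 19-channel, 500 Hz EEG covering −16…56 s around the trigger,
built from:

* a $1/f^{\chi}$ background ($\chi = 1$) synthesized in the frequency
  domain (random-phase Gaussian process), calibrated to 10 µV RMS;
* a 10 Hz alpha rhythm (Gaussian spectral bump, σ = 1.5 Hz, 3 µV RMS);
* 60 Hz line contamination (2 µV, common phase across channels);
* a per-subject domain shift: per-channel log-normal gain
  (σ = 0.3 on the log scale) and DC offset (σ = 5 µV), fixed across a
  subject's trials — this is what makes the baseline correction
  consequential;
* a class-dependent power elevation on positive-scored trials, gated to the
  0–30 s application span. A fraction (`effect_global_frac`, default 0.15)
  of the effect is diffuse broadband power on every channel; the remainder
  is band-limited (default: low gamma) on a fronto-temporal channel set,
  partitioned so in-band power on the effect channels is multiplied by
  exactly $1 + \mathrm{effect\_size}$ in expectation. The diffuse component
  mirrors how valence effects in real recordings are broadly distributed
  across the scalp rather than confined to focal sites, and it keeps the
  two-class baseline correction well conditioned (with a purely focal
  effect, non-effect cells have identical class means and the correction
  amplifies pure noise there — a behavior real data does not show). It
  scales with `effect_size`, so a null cohort carries no class information
  anywhere.

Scores follow the labeling rule: positive-designated trials draw uniformly
from {8, 9}, negative from {1–4}; the default `"balanced"` model ties class
to cream identity (creams 1–2 disliked, 3–4 liked) so every subject has
both classes. A dedicated generator produces single-class subjects to
exercise the exclusion rule. One master seed drives counter-derived
per-subject and per-trial streams, so generation is bit-reproducible and
order-independent.

The generator deliberately omits: physiologically realistic neural mass
dynamics, artifacts (EMG, blinks, motion), non-stationary background
changes, volume-conduction correlation between channels, and any real
texture differences between creams. Passing tests on synthetic cohorts
therefore demonstrate that the pipeline's machinery is correct and can
recover a planted band-power effect across subjects — not that the planted
effect sizes, or the resulting accuracies, match what real cream-application
EEG would yield. Synthetic accuracies near 1.0 at `effect_size = 1` reflect
a clean, artifact-free effect and should not be compared with accuracies on
real recordings.

# Problem sizes used by the test suite

The package's own checks run at desk scale, chosen once and stated here:
the end-to-end recovery check uses 8 subjects × 4 trials (2 creams × 2
sessions), 50 epochs, the full 56-fold schedule at `effect_size = 1`, and a
16-fold subset (two per test subject) for the null cohort; the
reproducibility check runs the demonstration configuration (4 subjects × 4
trials, 2 architectures, 20 epochs) twice and compares reports byte for
byte. Statistical invariants of the generator (effect recovery, spectral
shape, null separation) use shortened segments and reduced replicate counts
relative to an exhaustive Monte-Carlo design. The cohort defaults themselves
(16 subjects × 8 trials) follow the study protocol and are not scaled.

# Known limitations

* The baseline correction's use of test-subject labels (above) limits the
  protocol to retrospective evaluation.
* Single-precision training means results can differ across BLAS builds at
  the last few bits; determinism is guaranteed for a fixed build.
* The Morlet bank's 1 Hz grid under-resolves the alpha band's lower edge at
  short windows; this matches the protocol rather than optimal practice.
* Global class counts depend on the realized score distribution and are not
  meaningful targets on synthetic data.
* Persistence uses R-native serialized containers plus plain CSV manifests.

# Reproducing a run

```{r, eval = FALSE}
library(eegpref)
out <- run_pipeline(demo_config(seed = 1), out_dir = "demo_run",
                    progress = TRUE)
print(out$report)
```

`scripts/acceptance.R --seed 1 --out results/acceptance.json` recomputes the
structural reference quantities (inception module output channels; merged
matrix side length) from a fresh model build and featurization pass.
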