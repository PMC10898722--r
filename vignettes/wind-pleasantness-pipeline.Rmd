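---
title: "Decoding the pleasantness of wind from EEG source band power: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding the pleasantness of wind from EEG source band power: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Wind provides *instantaneous* thermal pleasantness that steady-state comfort
indices cannot capture. The experiment this package models exposes seated
participants in a hot, humid chamber to 10 s gusts at one of four velocities
(0.44, 1.0, 2.0, 4.0 m/s) while 64-channel EEG is recorded at 512 Hz; after
each gust the participant rates pleasantness on a 1.0--9.0 visual-analog
scale (VAS) in 0.1 steps. Each of three sessions holds 40 trials
(2 s rest, 10 s wind, 6 s report), 120 trials in total, with no velocity
repeated on consecutive trials. The analysis question: can a within-
participant classifier tell *pleasant* (VAS > 5.0) from *unpleasant*
(VAS < 5.0) trials from source-localized EEG band power -- without the
answer being driven by wind velocity itself, which is strongly (and
non-monotonically: group mean ratings 4.3, 5.5, 6.9, 5.3) tied to
pleasantness?

Because no recordings of the original study are publicly deposited, the
package pairs the analysis pipeline with a fully synthetic experiment
generator, so that every stage is verifiable offline against known ground
truth.

# The synthetic experiment generator

## Head model

A three-shell concentric spherical conductor (brain/skull/scalp radii
0.087 / 0.092 / 0.100 m; conductivities 0.33 / 0.0042 / 0.33 S/m -- the
classical 1/80 skull ratio) carries 64 electrodes placed by the 10/10
construction rules on the scalp sphere. Each cortical hemisphere is a
closed octahedron-subdivision mesh scaled onto a 3 cm shell inside the
brain compartment; at subdivision level $\ell$ it has $4^{\ell} + 2$
vertices, so level 6 gives the 4098 vertices per hemisphere of a standard
template source space. Dipoles sit at the vertices with orientation fixed
along the outward surface normal. Scalp potentials are the analytic
per-harmonic series solution of the three-shell conductor, solved from the
interface conditions degree by degree (80 terms; the dipole enters through
its radial and tangential multipole coefficients).

A nearest-seed partition on each hemisphere shell stands in for the
68-region Desikan--Killiany parcellation: 34 seed directions per
hemisphere, of which the three pleasantness regions of interest (rostral
anterior cingulate, medial and lateral orbitofrontal cortex) and the
superiorparietal confound site have fixed canonical coordinates and the
remaining 30 are drawn from the atlas seed. This surrogate replaces a
template MRI brain so that nothing needs downloading.

## Signal model

Per trial, source activity has three parts:

* **1/f background** at every vertex, unit RMS (the amplitude unit of the
  generator). Because every vertex carries an independent Gaussian 1/f
  process, the projected sensor field is a Gaussian field with spatial
  covariance $G G^{\top}$; the generator synthesises it directly at the
  sensors through the exact Cholesky identity, which is distributionally
  identical to projecting per-vertex noise and roughly halves the cost.
* **Pleasantness carrier**: a band-limited (default alpha, 8--13 Hz)
  Gaussian oscillation, coherent across the vertices of each of the six
  ROIs (one independent driver per region), active during the wind period
  with 0.25 s cosine ramps, amplitude
  $a_0\,(1 + \beta\,(\mathrm{VAS} - 5))$ with $a_0 = 2$ background-RMS
  units and $\beta = 0.15$ per VAS unit. The carrier band is configurable;
  alpha is the default because no single band is known to dominate this
  effect.
* **Velocity confound**: a beta-band (14--30 Hz) oscillation in bilateral
  superiorparietal cortex -- far from the frontal ROIs -- with amplitude
  $\gamma v$, $\gamma = 0.5$ per (m/s), so the strongest wind drives a
  confound source as strong as the pleasantness carrier. It models any
  stimulus-locked, velocity-dependent neural or somatosensory activity the
  design must not confuse with pleasantness.

Sensor data are lead field times sources plus 2 uV white sensor noise. The
lead field is rescaled once so the background alone produces a 7 uV mean
channel RMS -- resting-EEG scale, chosen so that clean epochs stay under
the 150 uV peak-to-peak rejection threshold by construction. Reported
scores follow
$\mathrm{clip}_{[1,9]}(\mathrm{round}_{0.1}(\mu_v + o_p + \varepsilon))$
with condition means $\mu_v = (4.3, 5.5, 6.9, 5.3)$, a per-participant
offset $o_p \sim N(0, 0.3)$ (the study reports no per-participant spread;
0.3 keeps most participants' grand means within half a VAS point of the
group means, matching the reported distributions qualitatively) and trial
noise $\varepsilon \sim N(0, 1)$.

The reporting period carries no simulated EEG (it is never analysed);
source synthesis covers a 13 s task window per 18 s trial and the rest of
the recording is silent. `simulate_recording()` materialises the full
continuous recording with events; `simulate_epochs()` is a fused
generate-filter-epoch path that is byte-identical to running
`simulate_recording()`, `bandpass_filter()` and `extract_epochs()` in
sequence (a unit test asserts the identity), and is what `run_cohort()`
uses.

## What the generator does not emulate

No ocular, muscle or line-noise artifacts by default (a synthetic EOG
channel is optional); no session non-stationarity; no realistic cortical
geometry or BEM conductor; no velocity dependence of the *pleasantness*
carrier beyond what the score mediates. Passing tests therefore certify
the pipeline's correctness and its behaviour under a controllable ground
truth -- not performance on real recordings, whose artifact structure and
effect sizes are unknown here.

# Preprocessing

Fixed stage order: band-pass filter, epoch extraction (-1 to +10 s around
wind onset, 5632 samples), bad-channel detection and interpolation,
peak-to-peak artifact rejection, optional ocular regression, average
re-reference, baseline/analysis crop. Interpolation must precede
re-referencing, otherwise bad-channel noise is folded into every channel.

* **Filter**: 0.5 Hz high-pass and 45 Hz low-pass with exactly zero phase.
  The implementation multiplies the spectrum by the squared magnitude of an
  order-4/order-10 Butterworth cascade -- the response a forward-backward
  pass of those filters would have -- with reflection padding. Realised
  response: under 1 dB ripple in 1--40 Hz, more than 20 dB attenuation at
  0.1 Hz and at 60 Hz. (A time-domain IIR cascade and an equivalent-spec
  FIR were both an order of magnitude slower at recording length for no
  accuracy benefit; the frequency-domain form is also free of edge
  transients.)
* **Bad channels**: robust variance z-score across channels (median/MAD),
  threshold 5; flagged channels are rebuilt by Perrin-style
  spherical-spline interpolation (order m = 4, Legendre series truncated at
  degree 7, diagonal smoothing 1e-6 -- without the smoothing term the
  63-electrode Gram system is numerically singular). An error is raised if
  more than 20% of channels flag.
* **Rejection**: epochs whose peak-to-peak amplitude exceeds 150 uV on any
  channel are flagged; an automatic surrogate for the study's visual
  inspection, exposed as a threshold parameter.
* **Ocular stage**: least-squares regression on an EOG reference, disabled
  by default (the default generator has no ocular activity). It replaces
  manual independent-component selection, which is not reproducible.
* **Crop**: baseline = 1 s pre-wind (noise covariance); analysis = seconds
  2--10 of the wind period (4096 samples) -- the first two seconds are
  excluded because the wind velocity is still stabilising.

# The eLORETA inverse

The baseline covariance is pooled over all retained trials' pre-wind
windows and shrunk toward a scaled identity,
$(1-\lambda) C + \lambda\,\overline{\mathrm{tr}}\, I$ with $\lambda = 0.1$
(average-referenced EEG has a singular covariance; at 512 baseline samples
per trial the shrunk estimate is stable). The solver whitens the lead
field, projects it onto the average-reference subspace (sensor data are
average-referenced, so the model must live there too), and iterates the
fixed-orientation eLORETA weights
$w_i \leftarrow \sqrt{l_i^{\top} (L W^{-1} L^{\top} + \alpha H)^{+} l_i}$
to a relative tolerance of 1e-6, with
$\alpha = \mathrm{tr}(L W^{-1} L^{\top}) / (n_{ch}\,\mathrm{SNR}^2)$
recomputed each iteration (SNR = 3 by default, the common convention; the
self-consistent $\alpha$ makes the kernel invariant to the overall
covariance scale). The defining property -- exact zero localization error
for noiseless point sources -- is verified exhaustively over a
258-vertex-per-hemisphere space in the tests. Baseline correction
(subtracting each channel's pre-wind mean) is applied at inversion time,
immediately before the kernel, matching the stage order of the original
processing chain; pooled (not per-session) baselines are used.

# Features

Per trial and vertex, Welch PSD over the 8 s analysis window (Hann window,
512-sample segments, 256 overlap: 15 segments, 1 Hz bins; one-sided
density scaling verified by a Parseval oracle). Vertex powers are averaged
per atlas region in linear power units, then averaged over inclusive
integer bins into theta (4--7 Hz), alpha (8--13), beta (14--30), gamma
(31--45), and the six ROI x four band matrix is natural-log-transformed
into the 24 feature columns (fixed order: bands within ROI, left before
right within each region pair). Logarithm base and linear-vs-dB averaging
are immaterial downstream because features are z-scored per fold.

# Classification protocol

Labels: VAS > 5.0 pleasant, < 5.0 unpleasant, exactly 5.0 dropped (the
class definitions are strict inequalities and silent on the neutral
anchor). Participants with fewer than 30 trials in either class are
excluded. Folds leave one velocity out: train on three velocities, test on
the fourth, four folds; a fold is skipped if either class has fewer than
30 training trials before undersampling. Per repetition (5 total) the
majority class is undersampled to balance, with the constraint that the
same discarded subset is never reused across repetitions while distinct
subsets remain (a warning marks the degenerate fallback). Features are
z-scored with the statistics of the undersampled training data only.

Hyperparameters are tuned per fit on a stratified 80/20 validation split
by seeded uniform random search (the original work used a sequential
Parzen-based optimiser; no such implementation exists in this package's
dependency set, and the search interface is pluggable). Ranges: C and
gamma log-uniform on [1e-3, 1e3]; hidden units 4--64; learning rate
log-uniform [1e-4, 1e-1]; weight decay log-uniform [1e-6, 1e-2]; batch
size {8, 16, 32}; epochs 10--200. Budget defaults to 50 evaluations; the
validation cohorts below use 5.

Families: L2 logistic regression (glmnet, with lambda = 1/(nC) mapping the
C parameterisation), linear- and RBF-kernel SVM (e1071), and a
one-hidden-layer network with ReLU hidden units, sigmoid output, binary
cross-entropy loss and AdamW with decoupled weight decay -- implemented in
the package because no installed dependency offers that exact
configuration. Hyperparameters are re-tuned in every repetition (the
protocol text orders tuning inside the repetition loop). The participant's
accuracy per family is the mean over feasible folds, then over
repetitions. A master seed derives one child seed per (repetition, fold,
family), recorded in the result, so runs are bit-reproducible.

Band-ablation importance re-runs the protocol with one band's six columns
removed from training and test data under the *same* master seed -- so
undersampling draws and search points coincide and the drop reflects
feature removal, not resampling noise -- and reports full minus ablated
accuracy; the RBF SVM is the scorer.

# Group statistics

Per family, a one-tailed one-sample t-test of participant accuracies
against chance (0.5), Holm-Bonferroni corrected across families; across
families, a one-way repeated-measures ANOVA with Greenhouse-Geisser
correction, with epsilon estimated from the biased (divide-by-n) sample
covariance of the conditions through an orthonormal contrast basis and
clipped to its theoretical range [1/(k-1), 1]. The same machinery serves
the importance scores (one-tailed against 0; ANOVA across bands).

# Validation scale and reproducibility

The cohort-level validation that ships in the test suite uses the full
study design per participant (3 x 40 trials, 512 Hz, the level-3 source
space) with cohorts of 18 (chance calibration), 10 (confound immunity) and
10 (signal recovery) synthetic participants at search budget 5 -- sizes
chosen so the whole suite completes in tens of minutes on a single core;
`scripts/acceptance.R` re-runs the same experiments from scratch at
comparable sizes and writes every headline number to JSON. All randomness
descends from explicit seeds; identical seeds give byte-identical results
end to end.

Three design points where the open choices were resolved:

* Chance calibration and confound immunity run the RBF SVM only (the
  family the original analysis used for importance scoring); the protocol
  machinery is family-agnostic and signal recovery exercises all four.
* The confound cohort keeps the generator's default confound strength
  (source as strong as the pleasantness carrier at 4 m/s) -- "strong" is
  defined at the source level, not tuned to the classifier's behaviour.
* Velocity counts are balanced at 30 per condition (the original order is
  described only as pseudo-random; balance makes fold feasibility a
  design property rather than a draw).

# Known limitations

The spherical surrogate head and coarse source spaces make eLORETA
cross-talk between regions larger than with a realistic template brain, so
some velocity-confound power leaks into the frontal ROI features; the
leave-one-velocity-out design prevents that leak from inflating accuracy
above chance (extrapolating a velocity-keyed feature to an unseen velocity
cannot reproduce the non-monotone velocity-pleasantness mapping), but it
can push accuracy slightly below chance for strong confounds. Real-data
accuracies cannot be reproduced here at all -- the study data were never
deposited -- which is precisely why the validation is property-based:
chance behaviour under null generators, confound immunity, signal
recovery, exact localization, spectral and statistical oracles.
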