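---
title: "Methods: bilateral gait asymmetry, 1D SPM inference and SVM gait classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bilateral gait asymmetry, 1D SPM inference and SVM gait classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitsym)
```

## The problem

During over-ground running, each foot contact produces a three-axis ground
reaction force (GRF) waveform: a vertical component (Z) with an early
impact peak and a larger mid-stance active peak, an anterior-posterior
component (Y) with a braking lobe followed by a propulsion lobe, and a
small medial-lateral component (X). Healthy runners are measurably
asymmetric between limbs, and fatigue can worsen that asymmetry. `gaitsym`
quantifies bilateral asymmetry over the whole stance phase, tests where in
stance the limbs (or the pre- and post-fatigue states) differ, and trains
maximum-margin classifiers to recognise left-vs-right and
pre-vs-post-fatigue gait from the waveforms alone.

## Preprocessing

Raw force-plate series (1000 Hz, newtons) are reduced to 101-node
body-weight stance curves by three rules:

* **Stance detection.** Foot contact is the longest run of samples with
  vertical force ≥ 30 N. The comparison is inclusive at both ends; 30 N
  "equals" is ambiguous for discrete samples, and ≥ keeps the boundary
  samples. Runs shorter than `min_duration` (default 0.1 s) are discarded
  — they are plate-edge grazes or aiming steps, not stances. All three
  axes are cropped with the *same* window, taken from the vertical axis.
* **Time normalisation.** The cropped segment is resampled onto 101 evenly
  spaced nodes (0–100% of stance) with an interpolating cubic spline
  (`stats::spline`). Because the window is cropped inclusively,
  extrapolation is never required; interpolating splines reproduce the
  endpoint samples exactly and linear segments to machine precision.
* **Body-weight scaling.** Forces are divided by ten times the body mass
  in kilograms, so 1 BW ≈ the subject's weight (with g ≈ 10 m/s²). A 700 N
  force on a 70 kg runner is 1.0 BW.

No smoothing or filtering is applied before normalisation; none is assumed
by the downstream statistics, and a disabled-by-default low-pass hook
would be the natural place to add one.

## The Symmetry Function

For paired right/left stance curves \(x_R(t), x_L(t)\) the Symmetry
Function is the pointwise field

\[ SF(t) = A\,\lvert x_R(t) - x_L(t)\rvert, \qquad
   A = \frac{2}{\mathrm{range}(x_R) + \mathrm{range}(x_L)} . \]

`SF = 0` is perfect symmetry; the conventional threshold deems nodes with
`SF > 0.05` (strict) asymmetric, and maximal runs of such nodes are
reported as asymmetric stance intervals. The amplitude `A` makes SF
invariant to common rescaling of both limbs — but *not* to adding a
constant to one limb, which changes the pointwise difference while leaving
both ranges unchanged. Because the medial-lateral ranges are small, the
same absolute bilateral difference produces a much larger SF in X than in
Z; medial-lateral asymmetry therefore dominates the SF picture under the
default dominance profile.

SF is exposed both as the 101-node field (the primary object: the
asymmetry is time-varying and the interesting findings are *where* in
stance it occurs) and as its trapezoidal integral over normalised time, a
scalar summary. Degenerate inputs (two constant curves) have no defined
amplitude and raise a classed error rather than returning infinity.

**Pairing rule.** Left and right stances are recorded in separate passes
over the plate, so there is no intrinsic pairing; the i-th successful left
trial is paired with the i-th right trial within each (subject,
condition). Both per-trial SF curves and trial-mean summaries are
available; trial-mean is the default aggregation for figures and for the
SPM fatigue comparison.

## 1D statistical parametric mapping

Node-wise paired t-statistics form a 1D random field:
\(t_q = \bar d_q / (s_{d_q}/\sqrt n)\) with \(\nu = n - 1\) degrees of
freedom, where \(d\) are the paired differences (subject means by
default, so \(\nu = 13\) for a 14-subject cohort). Testing all 101 nodes
at α would inflate the familywise error; the random-field-theory (RFT)
correction raises the threshold according to the field's smoothness:

* **Smoothness.** The residual-gradient estimator: residuals are scaled to
  unit variance per node, differentiated along the node axis, and
  \(\mathrm{FWHM} = \sqrt{4\ln 2 / \overline{(\nabla r)^2}}\). For fields
  generated by Gaussian-kernel smoothing this recovers the kernel FWHM
  (the package's generator-to-estimator link test requires agreement
  within 25% at n = 20 curves). The estimate is clipped to [1, 1000]
  nodes; an all-zero residual field returns the upper clip (infinitely
  smooth). Zero-variance nodes (flagged ±∞ in the t-field) are excluded.
* **Threshold.** The critical value `t*` solves
  \(\mathbb E[\mathrm{EC}](t^*) = \alpha\) (α/2 per tail when two-tailed)
  by bisection on [0, 100], with
  \(\mathbb E[\mathrm{EC}](t) = P(T_\nu \ge t) + R\,
  \tfrac{\sqrt{4\ln2}}{2\pi}(1 + t^2/\nu)^{-(\nu-1)/2}\) and resel count
  \(R = 100/\mathrm{FWHM}\). As \(R \to 0\) this reduces to the ordinary
  Student quantile.
* **Clusters.** Maximal runs with \(|t| > t^*\), reported as inclusive
  stance percentages. Edges snap to nodes — published intervals are
  integer percentages, and fractional-node interpolation would suggest
  spurious precision.
* **Cluster p-values.** The primary backend is sign-flip permutation:
  under the paired null the difference signs are exchangeable, so the null
  distribution of the *maximum* suprathreshold cluster extent is built
  over random sign assignments and each observed cluster receives
  \(p = (1 + \#\{\text{null} \ge \text{obs}\})/(n_{perm}+1)\). When the
  requested permutations reach \(2^n\) the full set is enumerated and the
  p-value is exact. Permutation was chosen over the RFT expected-cluster
  formula because it is assumption-light and testable by exhaustive
  enumeration at small n. Note a structural floor: the all-flipped mirror
  pattern always reproduces the observed extent, so the minimal
  enumerated p is \(2/2^n\), not \(1/2^n\).

Inference is two-tailed by default (differences in either limb's favour
are of interest), configurable to one tail.

## Kernel SVM classification

Two tasks are built from the curve tables: **left vs right** (rows are
per-trial 101-node GRF curves of one axis, both conditions pooled; left =
feature 1 = −1, right = feature 2 = +1) and **fatigue** (rows are
per-trial SF curves; pre = −1, post = +1). The soft-margin dual

\[ \min_\beta\; -\textstyle\sum_i \beta_i + \tfrac12 \beta^\top D \beta,
   \qquad D_{ij} = y_i y_j K(x_i, x_j),\quad
   0 \le \beta_i \le C,\; \textstyle\sum_i \beta_i y_i = 0 \]

is solved by a deterministic SMO (sequential minimal optimisation) written
for this package in C++: indices are scanned in order, the partner index
maximises \(|E_i - E_j|\) with a full-scan fallback, alphas within
epsilon of the box bounds count as bound, and the solver stops at a KKT
violation tolerance of 1e−6 or a pair-update budget (5·10⁵ by default).
Decisions are \(f(x) = \mathrm{sign}(\sum_i \beta_i y_i K(x_i, x) + b)\);
a decision value of exactly zero is assigned +1 by convention.

Kernels: linear \(u \cdot v\); RBF
\(\exp(-\lVert u-v\rVert^2 / 2\sigma^2)\) with the libsvm-style width
mapping \(\sigma^2 = 1/(2G)\), i.e. \(K = e^{-G\lVert u-v\rVert^2}\)
(published tables report "Best G", the kernel formula uses σ; this mapping
is the fixed convention here); polynomial \((u \cdot v + 1)^d\) with
default order d = 3 (configurable; an often-cited gait-classification
precedent used order 2).

Model selection and evaluation:

* features standardized per node with **training-fold statistics only** —
  standardizing before splitting would leak held-out information;
* stratified five-fold cross-validation with seeded fold assignment;
* grid search over C ∈ 2^{−5, −3, …, 15} and (RBF only) G ∈
  2^{−15, −13, …, 3}, ties broken toward smaller C then smaller G;
* a stratified hold-out test set (default fractions 0.2 for left/right
  and 2/7 for fatigue, echoing test sets of 34 of 168 and 24 of 84 at the
  default cohort size). Trial-level splitting lets the classifier see
  other trials of a test subject; a subject-grouped split flag
  (`grouped = TRUE`) is provided for leakage-free evaluation, off by
  default to mirror the conventional trial-level protocol.

Metrics follow the cross-denominator convention of the gait-recognition
literature: ACC = (T1+T2)/n, **SEN = T1/(T1+F2)**, **SEP = T2/(T2+F1)**,
where T1/T2 count correct and F1/F2 incorrect recognitions of features 1
and 2. A zero denominator yields NA ("undefined"), never 0.

**Auditing published tables.** Because these three metrics plus the test
size overdetermine the four confusion counts, `recover_confusion()`
exhaustively enumerates all non-negative integer matrices consistent with
printed values at their printed precision. The outcome is a certificate:
a unique matrix, an explicit list of consistent alternatives, or a proof
that the printed triple is internally inconsistent. Two printed metrics
sometimes suffice for uniqueness but not always — at n = 24,
ACC = 62.5% with SEN = 66.7% admits seven matrices and only the third
printed value resolves them — so the solver always reports multiplicity
rather than assuming uniqueness.

## The synthetic data generator

No public raw recordings accompany the analysis this package
re-implements, so validation uses a generator whose defaults define the
study conditions: 14 subjects × 3 trials × 2 sides × 2 conditions, masses
drawn from a truncated normal (mean 70.17, sd 6.57 kg, clipped to
[50, 95]) matching an amateur-runner cohort, 1000 Hz sampling, 0.25 s
stances with 0.1 s sub-30 N flight pads (5–20 N ripple, so the threshold
logic is genuinely exercised).

* **Templates** are per-axis Gaussian-bump sums tapered to zero at the
  stance endpoints: Z — 0.9 BW impact bump at 13% plus 2.5 BW active bump
  at 45%; Y — −0.3 BW braking at 25%, +0.3 BW propulsion at 75%; X — two
  low bumps ≤ 0.15 BW. The functional form is this package's choice (no
  canonical parametric GRF model exists); the amplitudes are
  physiologically typical rather than fitted to any dataset.
* **Asymmetry** applies to the left limb only: a global amplitude ratio,
  a small time shift, and axis-specific regional Gaussian bumps. The
  `dominance` profile (ratio 1.05, shift 1%, two X bumps of 0.10 and
  0.08 BW) concentrates asymmetry in the medial-lateral axis, reproducing
  the qualitative field pattern in which X-axis SF dominates.
* **Fatigue** adds one narrow X bump (0.08 BW, width 2% of stance) only
  when condition = post. It is placed at template fraction 0.80, which the
  30 N crop maps to roughly node 86–90 of the detected stance across the
  mass range — a late-stance medial-lateral worsening. At the default
  noise level and cohort size the detection floor for such a bump is
  about 0.05 BW; the default sits comfortably above it so that the
  injected effect is unambiguous.
* **Noise** is white Gaussian convolved with a Gaussian kernel
  (FWHM 10 nodes by default, sd 0.02 BW), scaled analytically to the
  target marginal sd. Gaussian-smoothed noise makes the RFT smoothness
  assumptions true by construction, which is precisely what a validation
  harness for SPM needs.

What the generator does **not** emulate: musculoskeletal dynamics,
treadmill-vs-overground differences, inter-subject waveform *shape*
variability (subjects differ in mass and noise realisation, not in
template shape), within-session drift, or force-plate artefacts. Passing
tests therefore demonstrate that the analysis chain recovers known
injected structure under its own assumptions — not that those assumptions
hold for any particular laboratory's data.

## Reproducibility and numerical choices

All randomness flows from one root seed through a deterministic
string-hash derivation per stage, trial and fold; the same configuration
and seed reproduce byte-identical reports. Degenerate cases are explicit:
no-contact series, too-short spline segments, constant curve pairs,
zero-variance nodes, single-class folds and undefined metric denominators
each raise or flag a classed condition instead of propagating NaN.

Problem sizes used by the validation suite were chosen to balance
statistical resolution against desk-scale runtime: 500 smooth-noise
simulations for the familywise calibration band [0.02, 0.09] at α = 0.05,
50 replicate cohorts for the fatigue-detection rate (≥ 80% required, with
≤ 10% spurious Y/Z detections), 3 asymmetry magnitudes × 10 seeds for the
dose-response monotonicity of classifier accuracy (Spearman ρ > 0.8), and
full 2⁴ enumeration for the exact-permutation oracle.

## Known limitations

* The RFT threshold uses the two-term expected-Euler-characteristic
  approximation; for very rough fields (FWHM near 1 node) it is
  conservative relative to permutation maxima.
* The SF amplitude couples the two limbs' ranges, so a regional bump also
  rescales SF globally (slightly *lowering* it away from the bump); SF
  differences are not purely local even when the injected effect is.
* Trial-level hold-out splits share subjects between train and test; use
  `grouped = TRUE` when subject-level generalisation is the question.
* The SMO update budget makes worst-case fits (huge C on heavily
  overlapping classes) return the best iterate with a warning rather than
  iterating indefinitely; cross-validation is unaffected in practice but
  extreme grid corners may be approximate.
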