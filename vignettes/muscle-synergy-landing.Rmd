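---
title: "Muscle synergy analysis of landing EMG: models, choices and limits"
author: "emgsynergy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Muscle synergy analysis of landing EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgsynergy)
```

## The problem

During a single-leg landing the central nervous system does not command ten
leg muscles independently: it recruits a small number of *modules* (muscle
synergies), each a fixed spatial pattern of relative muscle weights driven
by a time-varying activation coefficient. Comparing these modules between
people with chronic ankle instability (CAI) and healthy controls asks two
questions: do the groups use the *same number* of modules, and do the
*weights within* a module shift (e.g. more gluteus maximus in the hip
module, more tibialis anterior in the ankle module)?

`emgsynergy` implements that analysis end to end for 10-muscle surface EMG
(SL, MG, LG, TA, PL, RF, VM, VL, BF, GM at 1000 Hz), and ships a synthetic
generator with known ground truth so that every stage can be verified
without access to subject data.

## Models and procedures

### Envelope preprocessing

Per channel, in order: 50 Hz notch (mains), zero-phase 30 Hz high-pass
(motion artifact), full-wave rectification, zero-phase 5 Hz low-pass (the
muscle's own low-pass behaviour), then division by the muscle's processed
MVC peak (100% activation). Numerical choices where the procedure leaves
room:

* High/low-pass are 4th-order Butterworth filters applied
  forward–backward (zero phase, effective 8th order); the notch is an IIR
  biquad with quality factor Q = 30, also run forward–backward so the whole
  envelope chain adds no lag. Orders and corners are arguments of
  `preprocessEMG()`.
* Normalized EMG above 1 (task EMG exceeding MVC) is capped at 1 by default
  (`clip` in `mvcNormalize()`) because the activation model below assumes
  inputs in [0, 1].
* Trials are expected pre-segmented to the landing phase; segmentation and
  onset detection are out of scope. Curves are time-normalized to 101
  points (0–100% of the phase) by linear interpolation, which preserves the
  endpoints exactly.

### Activation dynamics

Neural activation follows a recursive second-order discrete filter with
electromechanical delay `d` (default 10 ms):

u(t) = alpha·e(t − d) − beta1·u(t − 1) − beta2·u(t − 2)

with beta1 = C1 + C2, beta2 = C1·C2 and alpha = 1 + beta1 + beta2, so the
DC gain is exactly 1: a sustained 100% EMG drives u to 1. Stability needs
|C1| < 1 and |C2| < 1 — the constraints are stated one-sidedly in parts of
the literature, but only the magnitude bound keeps the recursion stable, so
that is what `activationParams()` enforces. C1 and C2 themselves are rarely
reported; the defaults C1 = C2 = −0.5 give a critically-damped-like,
unit-gain smoother with a non-negative impulse response (so activation is
monotone in its input), and both are configurable. The recursion starts
from zero state, and u is clipped to [0, 1] before the next stage because
admissible parameter pairs can transiently overshoot.

Muscle activation applies the exponential shape function
a = (e^(An·u) − 1)/(e^(An) − 1) with An = 1.5 by default: an exact
monotone bijection of [0, 1] onto itself (a(0) = 0, a(1) = 1). An = 0
(the linear limit) is rejected rather than special-cased.

Activation is computed at the native sampling rate — the 10 ms delay is a
physical quantity — and only then time-normalized to 101 points.

### Synergy extraction (NNMF)

For each subject the three trial activation matrices (10 × 101) are
concatenated into V (10 × 303) and factorized as V ≈ W C with W, C ≥ 0
by the standard multiplicative updates for the squared Frobenius loss:

* W ← W ⊙ (V Cᵀ) ⊘ (W C Cᵀ + eps), then C ← C ⊙ (Wᵀ V) ⊘ (Wᵀ W C + eps),
  one pair of updates per iteration, eps = 1e−12 guarding the denominators.
* Initialization is uniform random in (0, 1]; 20 restarts by default, best
  final loss wins; convergence when the relative loss change drops below
  1e−6 (up to 1000 iterations). The loss trace is recorded and is
  non-increasing at every step.
* Columns of W are rescaled to unit Euclidean norm with compensating row
  scaling of C, which leaves W C — and therefore every VAF — unchanged and
  puts weights on the 0–1 scale on which they are conventionally reported.

The synergy number is selected by the dual-VAF protocol: iterate k = 1, 2,
… and take the first k whose global VAF (1 − ‖V − WC‖²_F/‖V‖²_F) reaches
90% while *every* muscle's row-wise VAF reaches 75%. Thresholds are
compared at a 1e−12 margin (i.e. ≥); if no k up to `kMax` qualifies the
selection is flagged rather than silently accepted. The compiled
(RcppArmadillo) update loop is bit-compatible with the exported R update
step; a test holds them to 1e−10 of each other.

### Sorting into reference synergies

Synergy vectors from all healthy-group subjects are pooled column-wise and
clustered by K-means (Lloyd's algorithm on squared Euclidean distance,
ties to the lowest cluster index, distortion tracked every iteration, 50
random initializations, an emptied cluster re-seeded at the point farthest
from its assigned centroid without ever stealing a singleton's last
member). The cluster count i is chosen over 2..8 to maximize the mean
silhouette coefficient S = (b − a)/max(a, b), where b uses the *minimum*
over other clusters of the mean distance (the textbook reading of an
ambiguous definition); singleton points score 0, ties in i go to the
smallest value. The winning centroids are the *reference synergies*.

Every subject synergy (both groups) is then matched to the
highest-Pearson-correlation centroid and classified when r > 0.6; its
activation-coefficient curve (averaged across the subject's trials)
inherits the assignment. The per-group *similarity rate* is the percentage
of pooled subject synergies classified — a per-synergy definition, since
the per-subject alternative is not specified anywhere authoritative.

### Group statistics

Weight comparisons run per (reference synergy, muscle) on the classified
subjects' weights: Shapiro–Wilk on each group and Levene's test (deviations
from the mean) route to a pooled-variance t-test when all pass at 0.05,
otherwise to the Wilcoxon rank-sum test (exact for n ≤ 25 without ties).
Effect sizes use Cohen's d with the pooled SD. The conventional band
0.5–0.8 is labelled "medium-large": the coarser published bands skip it.
No multiplicity correction is applied across the 40 cells, matching common
practice in this literature; users can correct `weightComparison$p`
themselves.

Coefficient curves are compared by one-dimensional statistical parametric
mapping. Rather than a random-field-theory threshold — whose smoothness
estimation step is rarely reported in enough detail to reproduce — the
package uses an assumption-free permutation scheme: the field-wide critical
threshold is the 95th percentile of the maximum absolute pointwise t over
group-label permutations (10,000 by default, observed labeling included),
and supra-threshold clusters get p-values from the permutation distribution
of the maximal supra-threshold run length. A test holds the empirical
field-wide type-I error over 500 null simulations inside [0.03, 0.07] at
alpha = 0.05.

## The synthetic generator

`synthesizeDataset()` emulates the study design: 22 CAI-like + 22
healthy-like subjects, 3 landing trials each, 10 muscles, 101 phase points,
SNR 20 dB. Its structure, and what each choice is grounded in:

* **Weight templates.** Per-group module templates derive from the
  tabulated group-mean weights of the four landing modules (hip: BF+GM;
  knee: RF+VM+VL+MG+LG+SL; ankle at initial contact: MG+LG+TA; whole-limb:
  GM+RF+VM+VL+LG+SL+PL). Group means are averages over unit-norm subject
  vectors and are therefore much flatter than any individual subject's
  vectors; the generator restores subject-level contrast by cubing the
  means before renormalization. Without this, the generative signal is
  nearly rank-2 and no method could (or should) find four modules in it.
* **Temporal profiles.** Gaussian bursts centred at 25, 50, 8 and 78% of
  the phase (widths 8, 14, 5, 9%): the ankle module confined to initial
  contact, hip and knee bursts mid-phase, the whole-limb module late. Gains
  of 0.79/1/0.67/0.95 balance the modules' effective energies so the
  noiseless rank-3 reconstruction ceiling sits near 90% and rank 2 near
  77% — the ordering reported for real landing data, where three synergies
  reconstruct ~85–86% and four ~90%.
* **Between-subject variability.** Each subject's weights are the group
  template plus Gaussian jitter with per-cell SD set to half the tabulated
  between-subject SDs, floored at a small positive weight (0.005, so no
  muscle is ever fully silent and per-muscle VAF stays well defined) and
  renormalized. Half, because the
  tabulated spread includes trial noise and factorization estimation error,
  which the simulation adds again itself; attributing it all to stable
  subject identity would double-count. The CAI-like group's larger
  tabulated SDs carry over, which is what drives its lower similarity rate.
* **Noise.** Per trial, each module's profile is scaled by log-normal
  amplitude jitter (sdlog 0.1), then V = W C receives multiplicative
  log-normal and additive Gaussian noise split evenly in power and
  calibrated *per muscle row* so every muscle's SNR equals the nominal
  value — matching the uniformly high per-muscle VAFs observed in real
  data. (A single absolute noise floor instead leaves the weakest muscle
  unreconstructable at any rank.) Entries are clipped to [0, 1].
* **Raw EMG.** `synthesizeRawEMG()` amplitude-modulates a 30–450 Hz
  band-limited Gaussian carrier with the activation envelope and adds a
  50 Hz mains component plus baseline noise, so the preprocessing chain can
  be tested end to end; the recovered envelope correlates > 0.95 with the
  generating one at default settings.

What the generator does **not** emulate: electrode crosstalk, fatigue or
electrode-lift nonstationarity, inter-muscle noise correlation,
trial-to-trial changes in burst timing, and any kinematics or kinetics. A
green test suite on this generator shows the pipeline recovers the
structure the model family assumes — it does not certify performance on
real EMG, where the factorization model itself is only an approximation.

## Problem sizes used in the checks

The packaged tests run the full rank-selection on 40 synthetic subjects
(20 seeds × both groups), the clustering stage on a complete 22-subject
healthy group (88 pooled synergy vectors), recovery checks at 20 dB and in
the noise-free limit, and 500 null simulations (1000 permutations each) for
the SPM error-rate check. The acceptance script reruns the full healthy-arm
analysis — generation, per-subject dual-VAF selection, pooling, silhouette
search over i = 2..8 with 50 initializations — from a single seed.

## Known limitations

* The dual-VAF thresholds (90/75) make rank selection sensitive to the
  noise model near the boundary; with real EMG the selected number can
  legitimately vary between 4 and 6 across subjects, as it does in the
  study population.
* Reference synergies come from the healthy group only (a
  `referenceGroup = "both"` option exists); with few subjects the
  silhouette criterion can prefer coarser clusterings.
* The permutation SPM tests a global null over the whole curve; it does not
  provide RFT-style cluster inference semantics, only permutation cluster
  p-values.
* Pearson matching ignores the activation coefficients; two synergies with
  similar weights but different timing are grouped together, as in the
  original procedure.
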