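---
title: "Context-invariant ensemble coding: models, conventions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-invariant ensemble coding: models, conventions, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`caensemble` analyzes how neuronal populations recorded with
microendoscopic calcium imaging encode behavioral variables — social
interaction, anxiety-related avoidance — across different environmental
contexts. This vignette is the package's methodological account: the
generative model behind the synthetic sessions, the statistical
conventions of each analysis stage, the defaults and why they were
chosen, and what the validation suite does and does not establish.

## The scientific question

A population of ~80 prefrontal neurons is imaged at 20 Hz while a mouse
engages in social interaction in one or two environments (four epochs
A–D, each a 5-minute pre-introduction period followed by a 5-minute
interaction window), or explores a home cage alternating with three
mazes (EZM, EPM, T-maze). Four hypotheses about the joint coding of
behavior and context can be distinguished: (1) disjoint ensembles for
behavior and context; (2) shared neurons with context-invariant
behavioral tuning; (3) shared neurons whose behavioral code fails to
generalize; (4) remapping — a different behavioral ensemble in each
context. The package's analyses discriminate these cases, and its
generator can plant each of them, so the discrimination itself is
testable.

## The synthetic-session generator

Events are independent Bernoulli draws per neuron per frame with

rate = baseline × context gain × behavior gain (× arm gain × drift),

gains composing multiplicatively and the product clipped at 0.95 to
avoid saturation (a warning reports clipping). Defaults, chosen once as
the package's study conditions:

| parameter | default | rationale |
|---|---|---|
| neurons | 80 | typical microendoscopic field-of-view yield |
| frame rate | 20 Hz | standard miniscope acquisition; one frame = 50 ms |
| epoch layout | 4 epochs × (6000 + 6000) frames | 5-min pre-introduction period plus 5-min interaction window per conspecific |
| baseline event rate | 0.02 / frame | produces sparse rasters (~2% of frames active) with the silent and highly active (>7.5%) tails seen in real data |
| social plant | gains {2, 0.5} on 20% of neurons | moderate bidirectional modulation: recoverable but not trivial |
| context plant | gains {1.6, 0.625} on 30% of neurons | population-level reorganization between contexts without silencing |
| transient kinetics | instant rise, τ = 0.5 s decay, amplitude 4–8 × noise SD | generic GCaMP-like transient; no published kinetics were assumed |
| noise SD | 0.05 dF/F | transient SNR 4–8, typical of neuropil-subtracted traces |
| maze blocks | 10-min home cage before and after each 10-min maze | alternating HC/maze layout |
| arm occupancy | Markov chain, geometric dwell, mean 100 frames (5 s) | first-order occupancy statistics only |

Social bouts are drawn as alternating bout (200–600 frames) and gap
(100–400 frames) intervals inside each interaction window, scaled down
proportionally for short windows so every window contains at least one
bout. Behavior labels distinguish `alone` (pre-introduction),
`present` (conspecific present, not interacting), and `social`; the
default nonsocial definition is their union minus social, with
alone-only and present-only alternates selectable.

Two switches embody the competing hypotheses. `remap = TRUE` redraws
the social ensemble independently per context (hypothesis 4).
`context_link = "shared_sign"` makes the context plant reuse the social
ensemble with matching sign, producing *correlated* (non-orthogonal)
codes; the default `"independent"` draws the two ensembles
independently, which makes them orthogonal in expectation. For trace
fixtures used by the event-detection tests, the event rate is set to
0.004/frame (~5 transients/min), since there the raster represents
discrete transient onsets rather than active frames.

What the generator deliberately does **not** emulate: temporal
autocorrelation of event trains beyond the transient kernel (events are
conditionally independent given the rate), behavioral kinematics beyond
the arm chain, spatial footprints and crosstalk, nonstationarity other
than the optional geometric drift ramp, and correlations between
neurons beyond those induced by shared masks. Passing tests therefore
establish the *correctness and calibration of the estimators under the
stated model*, not their robustness to every property of real data.

## Event detection

Traces are low-pass filtered with an equiripple FIR designed to a
passband edge of 0.5 and stopband edge of 0.65 — interpreted as
fractions of Nyquist (at 20 Hz: 5 and 6.5 Hz) — with ≤1 dB passband
ripple and ≥25 dB stopband attenuation. The design order is forced even
so the linear-phase group delay is an integer number of frames. The
default application mode is causal filtering followed by removal of
that known delay, keeping detected onsets aligned with the raw traces
(a pure single-pass mode and a zero-phase forward–backward mode are
selectable). If the design frequencies were instead meant in Hz they
can be passed directly to `design_lowpass()` after normalization.

The baseline is a running 20th percentile over a 30-s window (evaluated
on a coarse grid and interpolated; the baseline varies slowly by
construction). Candidate onsets are frames where the one-frame rise of
the filtered trace reaches `derivative_min`; consecutive candidates
collapse to one onset, and a candidate is accepted when the deflection
above baseline reaches `amplitude_min` at its peak and `auc_min` in
area before returning to baseline or yielding to a new onset. Splitting
at new onsets lets stacked transients be resolved individually. In the
default `extent` mode the accepted transient marks every frame from
onset to return-to-baseline as active — matching the downstream use of
"fraction of frames active" — while `onset` mode marks only the onset
frame.

Threshold tuning maximizes min(sensitivity, specificity) over a user
grid, with sensitivity scored by one-to-one onset matching within ±2
frames and specificity scored frame-wise outside the true transient
extents (onset + 3τ). On the package's trace fixtures the tuned
detector reaches ~98–99% on both, comfortably above the 95% criterion;
with zero true events sensitivity is reported as undefined (`NA`)
rather than silently perfect.

## Population vectors and similarity

A population vector is the per-neuron mean over a condition's frames —
for binary rasters, the fraction of frames active. Conditions are
compared by Pearson correlation. All neurons enter each pairwise
correlation (constant vectors are flagged, not silently dropped), and
within/between-context summaries average the off-diagonal entries over
epoch pairs in the same vs different contexts, separately per vector
type. Frames are 0-based and masks half-open in the file formats.

## Circular-permutation modulation indices

The null model for per-neuron modulation preserves each neuron's event
count and autocorrelation while breaking alignment to behavior: the
scope-restricted activity row (epochs concatenated, one circular shift
across the concatenation) is rotated by a uniformly random offset and
the statistic recomputed. Two statistics are used: mean activity in a
mask (epoch-specific index), and a difference of means (social −
nonsocial, or context set 1 − set 2). The index is the percentile of
the observed statistic in the null, with mid-rank treatment of ties, so
a neuron with constant activity lands at 50 rather than 0 or 100.

Three numerical conventions matter. First, the sampled null always
includes the identity shift as one of its draws — the observed
statistic is a member of its own permutation distribution — which
bounds indices to [50/n, 100 − 50/n] and makes the exhaustive and
sampled modes consistent. Second, for binary data the statistic at
every shift is an integer count divided by the mask size; the full
shift profile is computed exactly via FFT cross-correlation in
O(T log T) per neuron and rounded back to integers, so exhaustive
enumeration is bit-exact against direct shifting (this is asserted in
the tests) and tie counting is reliable. Third, neurons with no events
in either statistic mask carry no index and are flagged excluded. The
default 10,000 shuffles match the full-scale analysis; tests use 1,000
(or exhaustive enumeration) with correspondingly widened tolerances.

Under the null (nothing planted) the indices are uniform on (0, 100):
the suite checks a Kolmogorov–Smirnov distance below the 5% critical
value in at least 9 of 10 seeds and ~10% of neurons above the 90th
percentile. With the default plant the index separates planted from
unplanted neurons with AUC > 0.9 over a full-length session.

## Decoding

Single frames are classified from the raw binary population vector with
a linear maximum-margin classifier (hinge loss, regularization constant
1, no scaling), the configuration pinned in `fit_linear_svm()` and
backed by libsvm via the `e1071` package. Classes are balanced by
downsampling the majority class each iteration; the held-out fraction
(default 25%; 500 iterations) is split per class, and in transfer mode
the *test* frames are balanced as well, so 50% is the exact chance
level — a deliberate convention, since unbalanced test sets would make
"chance" depend on class prevalence. A `max_per_class` cap (default
1000 frames per class per iteration) keeps individual fits small;
because iterations resample and average, the cap trades iteration count
against per-fit sample size rather than discarding data. Precision,
recall, and F1 are computed from the confusion counts with undefined
ratios returned as `NA`, never as 0.

The chance control is a degree-preserving surrogate: event
neuron-identities are shuffled so that per-neuron and per-frame event
counts are both preserved, implemented as a checkerboard-swap Markov
chain (two events trade column assignments when the trade keeps the
matrix binary) run for 10 successful swaps per event, plus a random
extra swap so that both parity classes of very small matrices are
reachable. Margin preservation is asserted exactly on every fixture.
Balanced decoding of the surrogate sits within ±2 percentage points of
50% at 200 iterations.

## Ensemble geometry

Modulation vectors are compared by cosine similarity after
zero-centering. "Zero-centering" is ambiguous between subtracting the
null midpoint and subtracting the vector mean; the package implements
both — the default subtracts 50, the null expectation of a percentile
index, so unmodulated neurons contribute nothing, and
`metric = "pearson"` mean-centers, which equals the ordinary
correlation (an identity the tests verify numerically). The null
distribution permutes the neuron assignment of one vector (default
10,000 draws) and the observed value is reported as a mid-rank
percentile; pairs are aligned on the pairwise intersection of
non-excluded neurons, with the alignment size reported.

Overlap structure uses strict cutoffs: positive >90, negative <10,
middle otherwise, cross-tabulated 3×3. A chosen cell is compared
between two tables by the 2×2 Pearson χ² without continuity correction
(the correction is a toggle); the test suite pins the statistic to the
closed form N(ad−bc)²/((a+b)(c+d)(a+c)(b+d)). The exact 2×2
construction — in-cell vs not, day A vs day B — is documented here
because other constructions of the same comparison exist.

## Pipelines, determinism, and sizes

Every stochastic step takes an explicit seed; the pipeline drivers
derive stage seeds from one master seed, and a repeated run is
byte-identical (asserted in the tests down to the written tables).
Bundles carry a manifest with the config hash, seed, and package
version.

The validation suite runs the oracle and property checks at small sizes
(enumerable scopes of 12–50 frames; sessions of 40–80 neurons and
4,800–12,000 frames; 200–1,000 resamples) and the headline checks at
the full study conditions: detector tuning on 50 neurons × 12,000
frames of traces, and surrogate decoding on 80 neurons × 48,000 frames
over 200 iterations — the same computations `scripts/acceptance.R`
reproduces from scratch.

## Known limitations

* Event detection assumes transients dominate a slowly varying
  baseline; heavy drift or dense stacking beyond the resolved-onset
  case degrades sensitivity before specificity.
* The circular-shift null preserves autocorrelation but not
  cross-neuron correlation; strongly correlated populations would need
  a joint null.
* The surrogate chain's mixing is asserted only through its design
  (10 swaps per event) and the tiny-matrix reachability check, not by a
  formal mixing diagnostic.
* Group-level inference (mixed-effects models, multiple-comparison
  corrections across many similarity cells) is intentionally out of
  scope; the package emits per-session summaries and simple tests (KS,
  signed-rank, χ², Pearson) only.
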