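---
title: "Measuring bradykinesia from finger-tapping kinematics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring bradykinesia from finger-tapping kinematics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tapscore)
```

## The measurement problem

The MDS-UPDRS finger-tapping item asks a clinician to watch ten
index-to-thumb taps and compress what they see — how wide, how fast, whether
the movement decays, whether it stalls — into one ordinal score from 0
(normal) to 4 (severe). `tapscore` formalizes each of those visual
judgements as a measured quantity over a hand-landmark time series and keeps
every stage inspectable: the features are the clinical criteria, and the
classifier over them is a shallow decision tree that can be read node by
node.

The package deliberately starts *after* pose estimation. Video enhancement
and hand-landmark tracking are solved by external tools (any estimator
emitting 21 landmarks per frame in the MediaPipe convention works, through
`read_keypoints()` or `hand_pose_series()`); everything from landmarks to
score is implemented and tested here.

## Signal model and preprocessing

The tapping signal is the per-frame thumb–index distance
$I(t) = \lVert K_4(t) - K_8(t) \rVert$, divided by the palm size
$\mathrm{Palm}(t) = \lVert K_0(t) - K_9(t) \rVert$. The quotient is
dimensionless, so camera distance, image resolution, and hand size cancel
exactly; a property test multiplies all coordinates by $c \in \{0.1, 1,
10\}$ and requires every downstream feature to agree within $10^{-6}$
relative. Degenerate frames (palm below $10^{-6}$ of the series median,
or non-finite landmarks) are interpolated from neighbours; dropout runs
longer than 0.5 s reject the recording, mirroring the manual quality
screening such studies apply.

**Empirical mode decomposition.** The normalized signal is decomposed by
standard sifting: cubic-spline envelopes through local maxima and minima
(two extrema mirrored about each record end to tame boundary divergence),
stopping each sift at the conventional Cauchy threshold 0.2. The identity
$\sum_k \mathrm{IMF}_k + \mathrm{residual} = \mathrm{input}$ holds to
floating-point precision on every input and is asserted on 50 varied
signals. The three highest-frequency IMFs are retained as the movement
content. The slow residual is *excluded* and replaced by its median: the
amplitude of a tap is then measured against a constant baseline rather
than a drifting one. A `keep_residual` flag restores the full trend for
sensitivity analysis — and, with smoothing disabled and all IMFs kept,
turns preprocessing into an exact identity, which is how the
generator-closure tests isolate peak detection and feature arithmetic
from reconstruction bias.

**Smoothing.** "Denoise and smooth" is realized as order-2 Savitzky–Golay
regression with a default window of 0.25 s (forced odd), chosen over a
moving average because local polynomial fits preserve peak amplitudes,
and $A_n$ feeds every kinematic feature. Edges are handled by evaluating
the boundary-window polynomial, so the filter is exact on quadratics end
to end.

**A measured limitation.** The retained-IMF + smoothing chain carries a
fixed reconstruction bias of roughly 3 % of the tap amplitude (peak
attenuation plus the constant baseline). Consequently cleaning only
*reduces* error relative to the raw signal once measurement noise exceeds
about 3 % of the amplitude — at the 2–6 % noise levels of realistic
recordings it helps (the test suite asserts the median improvement over
20 seeded runs at 4 % noise); on near-noiseless input it is neutral at
best. Classification is unaffected because the bias is common to all
recordings. Relatedly, EMD ordering is noise-dependent: on a heavily
noisy slow signal the "first three IMFs" can be noise modes, so the rule
presumes the tapping oscillation dominates the high-frequency content,
which holds for 1–3 Hz tapping sampled at tens of frames per second.

**Peak detection.** Local maxima gated by topographic prominence of at
least 10 % of the signal range (scale-free by construction) and separated
by at least 0.1 s — taps above 10 Hz are physiologically implausible; when
two candidates collide the taller wins. Zero detected peaks is an error:
the recording is unusable, the analogue of manual exclusion.

## Features

All trend fitting uses the continuous two-segment model
$y = \alpha_0 + \alpha_1 x + \alpha_2 (x - bp)\,\mathbb{1}[x > bp] + \epsilon$
against the *tap ordinal* $x = 1..N$, not wall time, because the clinical
wording localizes decrement by position in the 10-tap sequence ("near the
end", "midway", "after the first tap"). The breakpoint is found by
exhaustive search over interior ordinals $\{2..N-1\}$ with an OLS solve per
candidate — with at most a few dozen taps the brute-force definition *is*
the implementation — and ties break to the earliest breakpoint for
determinism. Fewer than four peaks degrade to a flagged single-line fit.

Amplitude and velocity statistics use population (divide-by-$N$) variances,
matching the defining formulas rather than the sample convention. The
velocity $V_n = (A_n + A_{n-1})/\Delta t_n$ sums the closing and reopening
sweep distances over the inter-peak interval.

The halt/hesitation count compares each interior peak with the fitted
amplitude trend: flag tap $n$ when $\hat{y}_n - A_n \ge \alpha \cdot
(A_{n-1} + A_{n+1})/2$ with $\alpha = 0.2$, i.e. a drop of at least 20 % of
the surrounding amplitude. Three choices deserve note:

* only *downward* deviations count — an unusually wide tap is not a halt;
* the count (not a binary indicator) is reported, since the rating bands
  need "1–2", "3–5", "more than 5";
* the trend is fitted on *all* peaks, so a deep dip drags the fit slightly
  toward itself. With up to two dips among a dozen taps the drag is far
  smaller than the 20 % threshold (50 % dips are always flagged, 10 % dips
  never, verified over 100 seeded constructions); a leave-one-out variant
  was considered and rejected as needless complexity at these sequence
  lengths.

Tapping frequency is $(N-1)/(t_N - t_1)$, robust to padding before the
first and after the last tap. A single-peak recording (the task barely
attempted) reports zero frequency and zero velocity features, flagged by a
warning rather than an error, so that severe recordings still reach the
classifier.

## Classifiers

**Decision tree.** CART with Gini impurity, depth ≤ 5, at least 2 samples
per leaf. The depth cap is not only regularization: a five-level tree over
clinically named features remains readable, which is the point of the
white-box design. Candidate thresholds are midpoints between consecutive
distinct values; ties break by lower feature index then lower threshold, so
training is bit-for-bit deterministic. Impure nodes split even at zero
immediate Gini gain, because interaction structure (XOR-like) only pays off
a level deeper. All fifteen features are kept even though frequency and
velocity correlate strongly — each carries distinct clinical meaning, and
redundancy does not harm an axis-aligned tree. Models serialize to JSON
with feature names and thresholds in clear text.

**Rule cascade.** `baseline_sp()` encodes the rating table literally:
interruption bands, decrement-onset position (last third → 1, middle → 2,
after the first tap → 3, given a second-segment slope below the decrement
cutoff), slowing bands on mean velocity, and a "barely performs" override
(fewer than 4 taps or mean amplitude below the floor) that forces 4; the
worst triggered criterion wins. The clinical text names no numeric
thresholds for "slight/mild/moderate slowing" or the amplitude floor, so
these are configuration, calibrated once as midpoints between the expected
class means of the default severity profile
(`calibrate_baseline_cutoffs()`). The cascade is intentionally strict at
class boundaries — it mirrors the letter of the rating text rather than
smoothing it — and its held-out accuracy sits far below the tree's, which
is the expected and reported behaviour, not a defect.

## The synthetic world

Real recordings of this task are patient data and rarely shareable, so the
generator is the package's reference instrument, not a test fixture. A recording is a
train of raised-cosine open/close cycles (smooth at the closures — triangle
waves would seed spurious high-frequency IMFs) whose cycle maxima follow
the same piecewise-linear envelope the features estimate, with taps
suppressed by injected halts, plus a 4–6 Hz tremor sinusoid and white
measurement noise. The generator returns analytic ground truth (peak
locations and amplitudes, envelope parameters, halt count, rate), and
closure tests require the pipeline to reproduce it: exactly for counts,
within $10^{-6}$ for the arithmetic features, on noiseless specs through
the identity preprocessing configuration.

The default severity profile maps the rating anchors to parameter
distributions, fixed before any acceptance measurement and not revisited:

| class | rate (taps/s) | amplitude (palm) | decrement | halts | duration |
|---|---|---|---|---|---|
| 0 | 2.8 ± 0.25 | 1.25 ± 0.10 | none | 0 | 4 s |
| 1 | 2.3 ± 0.20 | 1.10 ± 0.10 | late (bp 70–85 %), −0.04/tap | 0–2 | 4.5 s |
| 2 | 1.8 ± 0.20 | 0.95 ± 0.10 | midway (40–60 %), −0.06/tap | 3–5 | 5.5 s |
| 3 | 1.3 ± 0.15 | 0.80 ± 0.10 | early (10–20 %), −0.05/tap | 6–8 | 7.5 s |
| 4 | 0.8 ± 0.12 | 0.30 ± 0.06 | shallow | 1–2 | 6 s |

Rates and amplitudes descend with severity per the "slight/mild/moderate
slowing" ladder; healthy rapid tapping sits near 3 taps/s in older adults
and the class-0 duration yields the canonical ~10 taps. Class 4 is defined
by inability — near-floor amplitude and very slow tapping leaving ~2–5
taps — so it *cannot* carry more than five interruptions; the
halts-monotone-in-class invariant is therefore enforced over classes 0–3
only. Halt depths are drawn from 0.5–0.85 so injected events are
unambiguous dips, and noise rises from 2 % to 6 % of amplitude with
severity. Demographics (age ≈ 70 ± 8, ~62 % male) match a typical
movement-disorders cohort and are deliberately uninformative about the
label: the tree should not, and in practice does not, select them.

What a green end-to-end test establishes: that the full chain — simulation,
EMD cleaning, peak detection, feature arithmetic, tree training — separates
*well-separated* severity classes (held-out exact accuracy ≥ 0.9, within-one
accuracy ≥ 0.98 at 100 recordings per class, fixed seed). What it does not
establish: performance on real patients, whose class overlap, pose-estimator
failure modes, and annotator noise the generator does not emulate. No claim
about clinical-cohort accuracy is made or implied by these tests.

## Numerical choices and degenerate inputs

* Breakpoint ties → earliest ordinal; split ties → lowest feature index,
  then lowest threshold; leaf ties → lowest class. All paths deterministic.
* Piecewise fits with < 4 points, single-peak recordings, constant signals
  (zero IMFs), and fewer IMFs than requested all degrade to flagged,
  well-defined results rather than errors; zero *detected* peaks and
  all-degenerate palms are hard errors because no meaningful score exists.
* Random draws (simulation, splits) run under explicit seeds through a
  local RNG scope that restores global state; preprocessing and training
  are seed-free and deterministic.
* Peak amplitude is read directly at the maximum (no trough subtraction),
  matching the definition of $A_n$; the residual-median baseline keeps that
  reading on the original scale.

## Known limitations

Beyond the smoothing bias and EMD ordering caveats above: the halt detector
cannot flag a *fully* suppressed tap (depth-1 halt) as a dip — the peak
simply never exists — so such events surface through the peak count and
frequency instead; ground truth still counts them as interruptions. The
rule cascade's calibrated cutoffs are only as good as the profile they were
calibrated on. And the ordinal structure of the score is exploited only
through the within-one accuracy metric, not by the tree itself.
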