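---
title: "Quantifying dyadic social behavior in optogenetic assays: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dyadic social behavior in optogenetic assays: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flydyad)
```

## The measurement problem

A tester fly whose candidate neurons express an optogenetic actuator is
paired with a wild-type target fly in a circular arena and filmed at
60 frames/s for 10 min: 1 min of pre-stimulation, then three 1-min LED
blocks separated by 2-min inter-stimulus intervals (ISIs). Upstream
tools produce per-frame fly ellipses (position, heading) and
machine-classified behavior bouts (lunges, wing extensions, headbutts).
`flydyad` covers everything downstream of that: the interaction metric,
bout post-processing, stimulation-aligned window statistics, responder
classification, classifier evaluation, and post-registration voxel
morphometry.

## Time orienting

Orienting is a per-frame predicate with three conditions on the tester:
the target centroid within ±60° of its heading (inclusive), the
centroid distance at most 5 mm (inclusive; about two fly body lengths),
and a speed above 0.1 mm/s (strict). The distance and speed gates
remove frames where a stationary, often grooming, tester happens to
face a passing target. The inclusive/strict reading follows the wording
of each rule ("within" vs "above"); boundary frames at exactly 60° or
5 mm count, a frame at exactly 0.1 mm/s does not.

The bearing is computed from centroid to centroid with `atan2`, and the
angular difference is wrapped to (−π, π] before taking its absolute
value. If the centroids coincide the bearing is undefined; since the
distance condition is then trivially satisfied we treat the angular
condition as met and emit a message, rather than dropping or failing on
a frame that plainly represents maximal proximity.

Speed is the backward finite difference of the centroid track scaled by
the frame rate, with the first frame copying the second so every frame
has a value. An optional centered boxcar (odd width, shrinking at the
edges) is exposed because no smoothing scheme is prescribed for the
0.1 mm/s gate; the default is unsmoothed (`smooth_window = 1`), which is
what the threshold is applied to throughout.

Maximal runs of qualifying frames become bouts; runs shorter than
200 ms are discarded as head/tail-flip tracking artifacts. The rule
discards strictly sub-threshold runs, so a 12-frame run at 60 fps
(exactly 200 ms) is kept. Thresholds are converted to frames as
`ms * fps / 1000` with a 1e-9 slack so exact boundaries are not lost to
floating-point rounding.

## Bout filtering and binning

Classifier bouts shorter than 50 ms (lunges, headbutts) or 100 ms (wing
extensions) are discarded — again a strict "less than", so
boundary-duration bouts survive. A behavior with no configured
threshold is a hard configuration error; silently passing unknown
labels through a false-positive filter would bias any downstream count.

Amounts are binned per minute: bout *counts* for momentary actions
(attributed to the minute of the start frame — a lunge lasts
50–200 ms, so splitting a count across bins would double-count),
*seconds* for duration-scored actions, split across minute boundaries
by frame membership so the bins conserve the total exactly. The same
two attribution rules are used when pooling into analysis windows.
Overlapping same-behavior intervals are merged on input; merging is
idempotent, and strictly adjacent bouts (`[a,b)` then `[b,c)`) remain
distinct.

## Stimulation windows

Frames are aligned on the first frame in which the infrared indicator
LED exceeds a threshold. Windows are then fixed by paradigm arithmetic:
window 1 is the pre-stimulation minute and window 2 the union of the
three LED-on minutes. The ISI minutes admit two published-figure
conventions, and the methods text fixes only windows 1–3 (with the ISI
pooled); we therefore support both and record the choice in every
output row. The default, `isi_split`, puts the first minute of each ISI
in window 3 and the second in window 4 — the only four-window partition
of the 10 minutes consistent with distinguishing early from late
post-stimulation effects — giving windows of 1 + 3 + 3 + 3 minutes that
partition the recording. `isi_pooled` pools all six ISI minutes into
window 3 and leaves window 4 empty (reported as `NA`, never as 0).
Because windows have unequal total durations, pooled amounts are always
normalized to per-minute rates before comparison.

## Statistics

Per behavior, per-window rates across flies are zero-inflated and far
from normal, so the scheme is nonparametric throughout: a
Kruskal–Wallis omnibus over windows 1–3 (or over genotypes), and post
hoc — only when the omnibus raw p < 0.05 — paired Wilcoxon signed-rank
tests between windows or Mann–Whitney U tests of the tester genotype
against each control, with Bonferroni correction over the `m`
comparisons actually performed. Every result records its `m`, and a raw
p < 0.05 whose corrected value is not significant is flagged `marginal`
(the convention of showing such values in parentheses). Degenerate
inputs — all values identical, or all paired differences zero — return
p = 1 with a `degenerate` flag instead of an arbitrary number; the
all-zero lunge vectors that motivate this arise routinely in control
genotypes.

The omnibus delegates to `stats::kruskal.test` (tie-corrected H against
χ²). The paired and unpaired rank tests are implemented here because
their small-sample paths need exact null distributions *with ties*,
which the standard implementations decline: the signed-rank null is
built by convolution over the (possibly tied, half-integer) ranks —
exactly equivalent to enumerating all 2ⁿ sign assignments — whenever
the number of nonzero differences is below 26; the rank-sum null is
built by subset-sum counting over the pooled ranks for untied samples
below 20 per group. Both cutoffs keep the exact computation well under
a second. Larger or tied (unpaired) samples use the tie-corrected
normal approximation without continuity correction, matching the
conventional MATLAB implementations of these tests. Two-sided p-values
are twice the smaller tail, capped at 1. Fisher's exact test sums
hypergeometric probabilities at most that of the observed table, with a
small relative slack (1e-7) against floating-point equality failures.
All exact paths are verified against brute-force enumeration oracles in
the test suite, and against `stats::wilcox.test`/`stats::fisher.test`
where those are applicable.

How many comparisons enter one Bonferroni family is not prescribed;
we correct within one behavior × one comparison family (all window
pairs, or tester vs each control) and record `m` so any other
accounting can be reconstructed.

## Responder classification

A tester is a responder for a behavior when its window-2 rate exceeds
1.5× a reference rate from window 1 *or* window 3 (a disjunction — the
literal reading of "relative to window 1 or three"), or, when both
reference windows are empty, when window 2 exceeds an absolute floor
(1 lunge/min; 0.5 s/min of wing extension). The relative rule applies
only against a strictly positive reference: a zero reference would make
any nonzero window-2 rate an infinite relative increase and the floor
rule dead code, which contradicts its stated purpose. With this
reading the classification is monotone in the window-2 rate, which the
tests verify. Responder frequencies are compared against anatomical
frequencies with Fisher's exact test.

## Classifier evaluation

Recall is `tp / n_true`. Precision is kept in its as-printed form
`tp / (n_detected + fp)` — the denominator counts false positives on
top of all detections, so it is conservative relative to the
conventional `tp / n_detected`, which is reported alongside (the two
coincide when `fp = 0`). Bout matching needs a criterion the protocol
does not state: by default one frame of overlap marks a true bout as
detected (the weakest defensible reading), with an optional minimum
overlap fraction of the true bout; a predicted bout overlapping no true
bout by at least one frame is a false positive. Overlap is computed
with IRanges.

## Morphometry

Registered stacks are averaged together with their left–right mirror
images, voxel by voxel; the result is exactly x-flip symmetric (the
flip pairs each voxel with its mirror partner and IEEE addition
commutes) and the operation is idempotent. Structure volume is the
count of voxels at or above an intensity threshold — default 800 on the
stack's native 12/16-bit scale, interpreted as ≥ — times the voxel
volume, optionally within a segmentation mask supplied as a label
array (interactive segmentation cannot be automated faithfully, so
masks are inputs). The NRRD reader/writer supports what this workflow
needs — 3-D stacks, raw little-endian or ascii encodings, voxel sizes
from `spacings` or diagonal `space directions` — and refuses anything
that would require a silent axis permutation.

## The synthetic-data generator

Real recordings are videos; none are bundled. The generator produces
every input with known ground truth:

* **Dyad kinematics** — a correlated random walk for each fly (per-frame
  heading diffusion SD 0.3 rad, half-normal step lengths with SD
  0.15 mm ≈ 7 mm/s mean speed, reflective walls with a 0.5 mm margin)
  in the 20 mm arena, with a two-state Markov "approach" process
  (enter 0.01/frame, exit 0.02/frame) steering the tester toward the
  target to create genuine orienting episodes. The per-frame orienting
  truth is computed from the generated kinematics by code independent
  of the pipeline's implementation.
* **Scripted dyads** — piecewise-constant relative geometry with both
  flies drifting together, so bearing and distance are exact constants
  and the tester's backward-difference speed equals the scripted speed
  on every frame; the orienting truth per segment is analytic. These
  drive the exact-recovery tests (e.g. a script with exactly 37.5 s of
  qualifying geometry).
* **Bouts** — homogeneous Poisson onsets within each analysis window at
  that window's rate, log-normal durations (lunge median 120 ms, wing
  extension median 800 ms — deliberately above the false-positive
  filters so filtering is exercised by dedicated sub-threshold
  scenarios, not by accident), truncated at the recording end.
* **Voxel stacks** — rasterized spheres of known voxel count plus
  optional clipped Gaussian noise; an indicator-LED trace completes the
  alignment inputs.

Default per-window rates (e.g. lunges 0.2/3/0.8/0.4 per min in windows
1–4) emulate a stimulation-responsive tester: near-silent baseline,
strong LED-on elevation, partial ISI persistence. Determinism is by
explicit seed plumbing through R's Mersenne-Twister — R ships its own
generator, so a fixed seed reproduces results bit-for-bit across
platforms — and the global RNG state is saved and restored around every
generator call. What the generator does *not* emulate: real fly gait
and pose, tracking noise and identity swaps, head/tail flips, classifier
errors correlated with behavior intensity, or pharmacological carryover
between blocks. Passing tests therefore certify the computation chain,
not the upstream tracking.

## Numerical and scale choices

Frames are 0-based with half-open `[start, end)` intervals, so
durations are exactly `(end − start) / fps` and adjacent bouts cannot
double-count a frame. All geometry is in mm and seconds; pixel inputs
are converted at read time. CSV output uses shortest-round-trip
formatting so written results re-read identically, which is what makes
cohort reruns byte-identical.

Test and validation problem sizes were chosen to estimate each quantity
comfortably: 100 dyads × 10,000 frames for predicate-oracle agreement,
2,000 null cohorts for the type-I error of the gated suite (Monte-Carlo
SE ≈ 0.005 at the nominal 0.05), 100 twelve-pair cohorts for power
against a five-fold window-2 effect, complete enumeration of 2×2
tables with margins ≤ 15 for the Fisher oracle, and exhaustive
small-sample sweeps (n ≤ 10 paired, ≤ 8 per group unpaired) for the
exact rank tests.

## Known limitations

* Window 4's composition under `isi_split` is a reconstruction of a
  figure convention, not a stated definition; the mode travels with
  every result so analyses can be redone under `isi_pooled`.
* The suite applies the Kruskal–Wallis omnibus across windows 1–3 even
  though window rates are within-fly repeated measures — preserved
  deliberately as the published analysis scheme, with the gate + paired
  post-hoc structure validated empirically by the null simulations.
* Manual curation steps (excluded pairs, hand-removed false-positive
  lunges) are inputs (exclusion lists, pre-curated bout tables), never
  inferred.
* `cell_count_ttest()` covers parametric cell-count comparisons; cell
  counting itself, registration, and interactive segmentation are out
  of scope.
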