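---
title: "Anchor-based alignment of GCxGC-TOF peak tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchor-based alignment of GCxGC-TOF peak tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcxgcalign)
```

## The problem

Comprehensive two-dimensional gas chromatography with time-of-flight mass
spectrometry (GCxGC-TOF) characterizes every detected compound by two
retention times — the first-dimension time `rt1` (seconds on the primary
column) and the second-dimension time `rt2` (seconds within the modulation
period) — plus a unit-mass electron-ionization spectrum. Retention times
drift between runs: slowly through column ageing and flow changes within one
instrument configuration, and abruptly when a column is replaced. Before
peak tables from different runs can be compared compound-by-compound, the
drift must be corrected.

`gcxgcalign` performs this correction pairwise: a peak table is aligned to a
fixed reference table in six steps — *find anchor peaks, check elution
order, export anchor points, correct the retention-time shift, export the
peak map, export the time-corrected chromatogram* (`align_pair()` runs them
all; `align_dataset()` repeats the procedure for every sample against one
reference). Anchors are peaks confidently identified in both tables; the
per-dimension warp is estimated from them and applied to every peak of the
aligned table. Spectra and row order are never modified — only retention
times change.

## Spectral similarity

All algorithms gate candidate matches on the similarity of their mass
spectra. Two conventions are offered (`similarity_config()`):

* **cosine similarity** of the two spectra expanded over the union of their
  m/z grids (absent fragments contribute zero intensity, as in library
  search), which lies in [0, 1] for non-negative spectra;
* **Pearson correlation** over the same union grid, in [-1, 1]; negative
  values are floored at 0 before threshold comparison so that thresholds
  live on one 0–1 scale for both methods.

An optional power transformation is applied to both spectra first: each
intensity `I` at mass `m` becomes `I^0.53 * m^1.3`. This up-weights heavier
fragments, which discriminates members of homologous series whose low-mass
fragments are nearly identical. On a manually identified standard mixture
this transformation raises the F1 score of spectrum-only matching
substantially (the package recomputes these scores in
`scripts/acceptance.R`: Pearson 0.61 raw vs 0.87 transformed; cosine 0.90
transformed). The package default is cosine on transformed spectra with
threshold 0.90 for every algorithm — cosine trades a little precision for
recall, and the elution-order check (below) removes the resulting false
positives cheaply. Raw spectra are never mutated; transformation happens on
copies at comparison time.

## The six anchor algorithms

All algorithms return an `anchor_set`, a one-to-one matching with the
gating similarity and a selection score per pair. Where an algorithm selects
one match per reference peak, conflicts (two reference peaks claiming one
aligned peak) are resolved deterministically: higher selection score wins,
ties broken by smaller total-retention-time difference, then lower
reference index.

**BiPACE 2D** (`find_anchors_bipace`) scores every pair by
`f2d = exp(-dt1^2 / (2 D1^2)) * exp(-dt2^2 / (2 D2^2)) * s`, the product of
two Gaussian retention-time penalties and the spectral similarity, and keeps
*best bidirectional hits* — pairs that are mutually each other's argmax.
`T1`/`T2` are lower cutoffs on the penalty terms, turning the soft penalty
into a hard search window: a pair is discarded when either penalty falls
below its cutoff, i.e. when `|dt| > D * sqrt(-2 log T)`. Defaults are
`D1 = 100` s, `D2 = 0.8` s and `T1 = T2 = 0.5`: the implied windows
(±118 s, ±0.94 s) cover the drift scale the `D` defaults describe. A cutoff
of 0.99 — also a documented operating point — implies very tight ±0.14·D
windows and suits near-identical runs only; since the cutoff semantics vary
between implementations of this penalty family, the package treats `T` as
an explicit, documented parameter rather than hard-coding either reading.

**DISCO** (`find_anchors_disco`) z-scores the retention times of each table
on its own statistics (so any affine drift cancels), and for each reference
peak inspects only its `ceiling(fraction * N)` nearest aligned peaks in
z-space (Euclidean distance; `fraction = 0.20` by default — `ceiling` so a
non-empty table always yields at least one candidate). The candidate with
the highest spectral similarity at or above the threshold is the match.

**MSort** (`find_anchors_msort`) uses a static window in raw seconds
(defaults ±25 s in dimension 1, ±0.5 s in dimension 2) and picks the most
similar peak inside it. Fast and precise when drift is small; the window
must stay below the spacing of spectrally similar elution regions, or the
algorithm anchors on the wrong homologue.

**PAM** (`find_anchors_pam`) has no window: every pair is considered, gated
by the spectral threshold *before* any distance computation (the
short-circuit that keeps the exhaustive comparison tractable), then scored
by `M = w / (1 + D) + (1 - w) * S` with `D` the Canberra distance between
z-scored coordinates (by default) and `S` the similarity. Matching is
greedy one-to-one by descending `M`. Higher `w` prioritizes peak distance,
lower `w` spectral similarity; `w = 0.8` is the documented default.

**TNT-DA** (`find_anchors_tntda`) combines the DISCO discrimination rule
(20% nearest neighbors in z-space, Canberra distance by default) with the
PAM selection rule (`M` as above, default `w = 0.4`). With `w = 0` and
Euclidean distance it reduces exactly to DISCO — a property the test suite
checks on twenty random synthetic pairs.

**Smith–Waterman** (`smith_waterman_anchors`) sorts both tables by total
elution time (`rt1 + rt2`) and fills a local-alignment matrix with the
recurrence `max(0, diag + match/mismatch, up + gap, left + gap)`, where a
cell is a "match" when the spectral similarity of its pair reaches the
threshold. The path is traced back from the global maximum until a zero
cell; diagonal match steps become anchors. The match/mismatch/gap scores are
not standardized anywhere for this use, so they are configurable with
conventional defaults (+1, −1, −1).

PAM and TNT-DA compute distances on z-scored coordinates (stated behaviour
for the DISCO family; for PAM the raw-versus-z-scored choice is not
documented anywhere we know of, and z-scores were chosen for consistency
and affine invariance).

## Elution-order check and warp correction

Spurious anchors typically violate the elution order shared by the two
runs. The check sorts anchors by reference total retention time and keeps
the largest subset whose aligned total times are strictly increasing — a
longest-increasing-subsequence computation, which provably removes the
fewest anchors (a brute-force subset enumeration confirms maximality in the
tests). Total time is used rather than per-dimension order because peaks
can legitimately tie in one dimension; exact ties in *total* time are
treated as violations. Checking order on totals, with anchors from a
threshold of 0.3, routinely removes hundreds of false matches while leaving
genuine anchor sets untouched.

The warp is fitted per dimension, independently, on (aligned RT, reference
RT) anchor pairs:

* `piecewise_linear` (default): linear interpolation through the anchor
  knots — exact at every anchor — with linear extrapolation from the two
  outermost knots on each side; knots sharing an aligned RT are averaged.
  Chosen as the default because drift late in a temperature program is
  often not globally linear.
* `global_linear`: one least-squares line per dimension, mirroring the
  classic linear-fit correction; exact when the anchors are collinear
  (noiseless affine distortion), which is how the warp-recovery tests and
  the acceptance script verify it.

A single anchor degenerates to a pure offset map. Zero anchors abort with a
message advising threshold/window relaxation. Corrected times that
extrapolate below zero are clamped to 0 with a warning — tables stay valid
and no peaks are dropped silently. `rt2` is treated as within-modulation
seconds; wrap-around is never generated by exported tables and is not
modelled.

Column-bleed regions — characteristic elution areas of stationary-phase
degradation — can be excluded up front as rectangles in (rt1, rt2) space
(`filter_exclusion_regions()`).

As an alternative to time warping, `kovats_index_transform()` re-expresses
retention times as retention indices against a ladder of reference
homologues per dimension (linear interpolation between bracketing ladder
points, the temperature-programmed convention; linear extrapolation from
the outer segments). Tables in index coordinates are comparable without any
further manipulation and still support every anchor algorithm; identifying
and marking the ladder compounds is a manual step outside this package.

## Evaluation

`ks_per_dimension()` reports the two-sample Kolmogorov–Smirnov statistic —
the supremum gap between the empirical distribution functions, computed
exactly over the pooled sample points — for `rt1` and `rt2` separately.
It is used as a fit metric (lower is better), so no p-value is attached.
With a known ground truth, `confusion_counts()` audits an anchor set
(a wrong match counts as a false positive, an unmatched true pair as a
false negative, a truly absent and unmatched compound as a true negative)
and `precision_recall_f1()` computes `F1 = TP / (TP + (FN + FP) / 2)`,
identically the harmonic mean of precision and recall. Undefined ratios are
reported as `NA`, never as 0.

## The synthetic benchmark generator

Real GCxGC peak tables are large, instrument-bound and rarely shipped with
a known ground truth, so the package carries a generator that emulates
their structure at desk scale.
`make_spectrum_library()` draws sparse unit-mass spectra (6–14 fragments in
m/z 40–350, one dominant fragment at intensity 999, distinct dominant
fragments across the library) and rejection-samples until all pairwise raw
cosine similarities stay below 0.5, so synthetic compounds are as
distinguishable as distinct real compounds. `make_reference_table()` places
them uniformly over 60–1800 s x 0.8–5 s. `distort_table()` applies a known
affine warp per dimension, Gaussian RT jitter, Bernoulli peak dropout,
spurious insertions with fresh spectra, and multiplicative log-normal
spectral noise (keeps intensities positive and mimics abundance scaling and
imperfect deconvolution); it returns the distorted table together with the
exact correspondence and warp coefficients.

`make_benchmark_pair()` bundles two presets over 60 peaks (default seed
42):

| parameter | same_system | cross_system |
|---|---|---|
| warp dim 1 | rt1 + 6 s | 1.006 rt1 + 8 s |
| warp dim 2 | rt2 + 0.05 s | 0.97 rt2 + 0.1 s |
| RT jitter (s) | 0.2 / 0.01 | 0.5 / 0.02 |
| dropout | 0.02 | 0.10 |
| insertions | 1 | 5 |
| spectral noise (sd, log scale) | 0.05 | 0.10 |

`same_system` mimics consecutive runs on one column set; `cross_system`
mimics a column replacement — a mild stretch plus a larger offset, sized to
the regime the documented default windows are designed for (peak-level
shifts up to roughly 20 s in dimension 1), with more dropout, insertions
and spectral noise. What the generator deliberately does **not** model:
modulation-grid quantization of `rt1`, peak shapes and co-elution,
deconvolution artifacts that split one compound into several table rows,
and nonlinear (non-affine) drift. Tests passing on these pairs therefore
demonstrate correctness of the matching and warping machinery under known
affine drift — not performance on pathological real-world deconvolution.

## Numerical and design notes

* Determinism: every stochastic function takes a seed; the benchmark
  bundles are byte-stable under a fixed seed.
* One-to-one matching is enforced everywhere (duplicated anchors would
  corrupt the warp); the resolution rule is deterministic (score, then
  total-RT difference, then index).
* Raising the similarity threshold can only shrink the candidate sets, so
  anchor counts are non-increasing in the threshold; the tests check the
  0.3 / 0.8 / 0.9 levels for all six algorithms.
* Degenerate inputs: empty tables yield empty anchor sets; z-scoring
  refuses tables with fewer than two peaks or zero variance (naming the
  dimension); two empty spectra cannot be compared; Canberra 0/0 terms
  contribute 0.
* Problem sizes in the tests (60-peak tables, 4x4 Smith–Waterman
  enumeration grids, 10–12-anchor subset enumerations) are chosen so the
  brute-force oracles stay exact and the whole suite runs in seconds.

## Known limitations

Pairwise alignment only: multi-sample clique building (BiPACE) and
iterative reference reduction over a whole dataset (DISCO) are out of
scope — a dataset is aligned sample-by-sample against one fixed reference.
Pixel-level warping of raw 2D signal is not attempted; the unit of work is
the exported peak table. The Smith–Waterman variant is included for
completeness but is known to misalign unequally populated chromatograms and
is quadratic in table size.
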