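---
title: "Aligning GC-FID peak lists: method, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning GC-FID peak lists: method, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtalign)
```

## The model

GC-FID peak lists record, per sample, a set of retention times (minutes) and
intensity measures. The alignment problem is to decide which peaks in
different samples are the same substance, using retention times only. The
method assumes:

* retention-time error decomposes into a *systematic per-sample component*
  (linear drift, shared by all peaks of a run) plus *independent per-peak
  noise* much smaller than the spacing between distinct substances;
* homologous substances elute in the same order in every sample (no
  crossovers);
* a substantial subset of substances is shared between samples, so that a
  nearest-neighbour score against a reference carries signal.

The three steps target these components in order: a grid search over linear
shifts removes the systematic part; a row-wise pass over the retention
matrix groups peaks whose residual deviation from the running row mean is
within `a`; and complementary adjacent rows closer than `b` are merged,
absorbing the occasional peak whose noise exceeded `a`.

## Parameters

* `max_diff_peak2mean` (`a`, minutes, default 0.02): tolerated deviation of
  a focal peak from the mean retention time of the previous peaks in its
  row. Should comfortably exceed the per-peak noise scale (several standard
  deviations plus the residual shift quantisation of half a grid step) while
  staying below the typical substance spacing. Too small over-splits; too
  large pulls neighbouring substances into one row.
* `min_diff_peak2peak` (`b`, minutes, default 0.08): minimum expected
  spacing between distinct substances. Split rows closer than `b` are merged
  when no sample occupies both. `b` must exceed `a` — otherwise rows split
  by the partial step can never be re-merged, which is exactly the regime
  where error rates rise in the threshold sweep. A `b` above the true
  substance spacing merges distinct substances with complementary presence
  patterns, so small datasets (where complementarity arises by chance)
  warrant stricter values.
* `max_linear_shift` (minutes, default 0.05): half-width of the shift search
  window. Must cover the drift of each sample *relative to the reference*,
  i.e. up to twice the absolute per-run drift.
* `shift_step` (minutes, default 0.01): grid interval of the shift search;
  recovered shifts are quantised to this grid, so residual systematic error
  after full alignment is at most half a step.
* `reference`: `"auto"` selects the sample minimising the median over other
  samples of the mean nearest-neighbour deviation of its peaks. The verbal
  description of this selection rule (a "median deviation score weighted by
  the number of peaks") and its displayed formula (a per-pair mean over the
  candidate's peaks) can be read several ways; we compute the per-pair score
  as the mean over the candidate's peaks — which normalises away the
  candidate's peak count — and aggregate per candidate by the median over
  pairs, which is robust to a few aberrant samples. Ties go to the candidate
  with more peaks, then to the lexicographically first identifier. Blanks
  are never candidates (they are sparse, unrepresentative runs) but do serve
  as comparison samples and are themselves shifted and aligned, which is what
  later allows blank-shared substances to be identified and removed.
* `blanks`, `delete_single_peak`: post-alignment filters. Blank-shared rows
  are removed before singletons so that a blank peak cannot rescue an
  otherwise sample-unique row.

## Numerical and procedural choices

* The shift grid includes both endpoints; among tied scores the smallest
  absolute shift wins (then the more negative), so identical samples are a
  fixed point of full alignment.
* The partial-alignment inequalities are strict: equality with `mu ± a`
  keeps the focal cell in place. Zeros (absences) never enter the running
  mean. The pass is single and top-to-bottom — the procedure is defined
  operationally, not as a fixed point — and when a demotion lands on an
  occupied cell the whole column tail below it is pushed down, growing the
  matrix, which preserves within-column retention order.
* Row merging scans adjacent pairs only and iterates to a fixed point,
  recomputing row means between scans; the mean comparison is strict, so
  `b = 0` never merges.
* Conservation is asserted at run time: before the filter steps, the aligned
  matrix holds exactly one non-zero cell per input peak, each column in
  strictly increasing retention order.
* Degenerate inputs: empty samples pass through as all-zero columns
  (flagged by `check_input()` as warnings); a single-sample dataset skips
  reference selection and emerges with one row per peak; an alignment whose
  rows are all filtered away still writes valid empty tables.
* The core pipeline contains no randomness; only the simulator is seeded.

## What the simulator emulates

`simulate_peaks()` draws true substance positions uniformly subject to a
minimum spacing `min_spacing`, then gives every sample a uniform drift in
`±drift_range`, per-peak Gaussian jitter (`jitter_sd`), Bernoulli
presence/absence (`presence_prob`), a fixed number of sample-unique peaks
placed at least `min_spacing` from every true substance, and log-normal
abundances. Blanks contain only a designated subset of contaminant
substances under the same noise model. Samples whose jittered peak order
differs from the true substance order are redrawn, so the emitted ground
truth is always order-consistent.

The defaults — 30 samples, 40 substances, 0.15 min spacing, 0.005 min
jitter, ±0.04 min drift, 90% presence, 3 unique peaks per sample — describe
a clean, medium-sized study in which the method should be essentially
error-free, and the validation suite holds it to exactly that: zero mode-row
error and all 40 substances recovered as distinct rows across 20 seeds.

What the simulator does *not* emulate: nonlinear (retention-time-dependent)
drift, co-eluting peaks and shoulders, intensity-dependent retention shifts,
detector saturation, or missingness correlated with abundance. Passing the
synthetic checks therefore demonstrates correctness of the algorithm under
its own assumptions, not performance on any particular empirical dataset —
on real data the thresholds must be tuned with the diagnostics and heatmap.

Two validation conventions are worth noting. First, only drift *relative to
the reference* is identifiable, so shift recovery is scored against
`-(drift_s - drift_ref)`; with jitter present, samples missing peaks can
legitimately pull the arg-min one grid step away when the true relative
drift sits near a grid midpoint, so the half-step recovery guarantee is
checked on drift-only data (all substances present, no unique peaks).
Second, "recovered substances" counts the distinct aligned rows occupied by
the known substances rather than the total row count: sample-unique peaks
from different samples occasionally fall within `b` of each other and form
legitimate chance rows that survive the singleton filter, and the evaluation
of the *known* substances should not depend on them.

## Evaluation metric

`error_rate()` locates every known occurrence in the aligned matrix (adding
the applied per-sample shift to its input-coordinate retention time),
takes each substance's mode row — the row holding most of its occurrences,
earlier row on ties — and scores all other occurrences as misaligned. The
metric is label-free: substances systematically assigned to a "wrong" but
single row are not penalised. Occurrences deleted by the blank or singleton
filters are excluded from numerator and denominator and reported separately,
since the metric presumes an unfiltered alignment; occurrences that cannot
be located at all raise an error, as they indicate a bookkeeping bug rather
than a misalignment.

## Problem sizes used in validation

The packaged checks use 30 × 40 simulations over 20 seeds for recovery and
shift accuracy, an exhaustive enumeration of all ~70,000 retention matrices
with up to 4 samples × 4 grid positions against an independent list-based
oracle of the row operations, a 6 × 6 threshold sweep with 5 replicates of a
20 × 30 dataset, and a packaged 14-sample fixture for the blank/singleton
workflow. These sizes keep the full suite around a minute while exercising
every code path; larger simulations change none of the qualitative
conclusions.

## Limitations

* A single linear shift per sample cannot correct retention-time
  compression or expansion along the run; strongly nonlinear drift requires
  warping approaches instead.
* The row operations process samples left to right, so pathological column
  orders can produce different (though conservation-preserving) splits; in
  practice rows are dominated by the running mean of many samples.
* The merge criterion relies on complementary presence patterns, which
  arise by chance in very small datasets; there `b` should be tightened.
* The mode-row error rate requires externally known substance identities
  and says nothing about substances with no ground truth.
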