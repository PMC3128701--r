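---
title: "Control-referenced voxel-based lesion-symptom mapping with anacom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Control-referenced voxel-based lesion-symptom mapping with anacom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anacom)
```

## The problem

Voxel-based lesion-symptom mapping asks which brain locations, when
damaged, are associated with a behavioural deficit. Classic VLSM splits
*patients* at every voxel into lesioned and spared groups. The AnaCOM
variant implemented here instead compares, at every location, the
patients lesioned there against an independent *healthy control* sample.
This matters when lesion coverage is sparse: a voxel damaged in only a
handful of patients still admits a meaningful comparison because the
reference group is the full control cohort, not the remaining patients.

The package covers three things end to end: (1) the mapping procedure
itself on binary lesion masks in a shared standard (MNI) space; (2)
scoring of the prospective-memory task battery whose measures the maps
are built from; (3) a synthetic cohort generator with known ground truth,
so that the whole chain is testable without any patient data.

## The mapping procedure

Let $M_1, \dots, M_n$ be binary lesion masks on one grid. The procedure:

1. **Overlap map.** For every voxel $v$, count
   $c(v) = \#\{i : v \in M_i\}$ (`buildOverlapMap()`).
2. **Coverage-pattern subregions.** Group voxels by the *exact set* of
   patients covering them: $v \sim w$ iff
   $\{i : v \in M_i\} = \{i : w \in M_i\}$
   (`partitionSubregions()`). Each equivalence class is one subregion —
   the natural unit of testing, since all its voxels carry identical
   patient-group information. Only subregions with at least `minOverlap`
   (default 3) covering lesions are tested.
3. **Subregion tests.** For each subregion, the scores of its covering
   patients are compared to the control scores with a two-sided Wilcoxon
   rank-sum test (`testSubregion()`), reported as the usual $U$, $z$, $p$
   triple.
4. **Family-wise correction.** All raw p-values of one map (one
   behavioural measure) form one family, corrected by the
   Bonferroni–Holm step-down procedure at level $\alpha$ (default 0.05;
   `holmCorrect()`). Families are never pooled across measures.
5. **Outputs.** A per-voxel statistical map (each voxel inherits its
   subregion's raw $p$; voxels under the overlap minimum stay untested)
   plus a region report: MNI coordinates of the subregion centroid,
   raw $p$, patient count and size (`runAnacom()`).

### The Holm threshold *H*

Clinical reports commonly print a single "Holm threshold" per map. The
step-down procedure has no unique such number, so the package defines
$H = \alpha / (m - k + 1)$ evaluated at the first non-rejected rank $k$:
the critical value a raw p had to undercut at the point the procedure
stopped ( $H = \alpha$ when everything is rejected). Because published
tables are ambiguous about whether the boundary is strict, the largest
actually rejected p is reported alongside `H` in every report.

### Decisions where the design was open

* **Disconnected subregions.** Voxels with the same coverage pattern are
  pooled into one subregion even when spatially disconnected: the
  pattern alone determines the test, and any split would only duplicate
  identical tests. For reporting, `connectedComponents()` can split a
  subregion into 26-connected pieces.
* **Sidedness.** Tests are two-sided, matching the $z$/$p$ reporting
  convention of the field's tables.
* **Missing scores.** A patient lacking the measure keeps contributing
  their anatomy (to overlap counts and coverage patterns — the lesion is
  known even when the score is not) but is excluded from every test; a
  subregion left with fewer than `minOverlap` scored patients is skipped
  with a warning and excluded from the Holm family size $m$.
* **Reported coordinate.** The voxel-count centroid of the subregion
  mapped through the grid affine, rounded to integer millimetres,
  neurological orientation (positive x = right).
* **Score-weighted volumes.** `weightByScore()` provides the classic
  dense representation (score value over the lesion, zero elsewhere) for
  visualisation and interoperability. The statistics consume the raw
  score lists directly — numerically equivalent, since the subregion test
  only needs each covering patient's score.

## Statistical kernel

`rankSumTest()` computes the Mann–Whitney $U$ of the first sample, a
tie-corrected normal deviate $z$ with 0.5 continuity correction, and a
two-sided $p$. When the pooled sample is at most `exactThreshold`
(default 12) and tie-free, $p$ comes from the exact null distribution of
$U$ instead. Since both $U_a$ and $\min(U_a, U_b)$ conventions circulate,
both are returned. `signedRankTest()` follows the same scheme on the
sign-flip distribution (zero differences dropped). Pearson chi-square
(`chiSquareTest()`, no Yates correction) and Spearman rank correlation
(`spearmanTest()`) wrap the standard R implementations with explicit
validation; an exhaustive comparison against brute-force enumeration
backs all of these in the test suite.

A note on accuracy: with groups of at least 3 and pooled size at most
10, the continuity-corrected approximation stays within 0.05 of the
exact permutation p over *every* configuration (the worst case,
0.0375, occurs at $n_1 = n_2 = 3$). With singleton groups it can be off
by 0.13 — one reason the mapping never tests fewer than 3 patients.
In a typical map (3–10 patients against 50–107 controls) the
approximation is conservative at the extreme tails, which protects the
family-wise error at the cost of some power for the very smallest
subregions.

## Behavioural scoring

Raw sessions are event logs (`t_ms`, `kind`, target flag, correct
side). The measures:

* **Ongoing trials** (`scoreOngoing()`): percent correct and mean RT of
  two-alternative forced-choice trials, self-paced with a 3 s cap; the
  first 10 trials of an ongoing-only phase are orientation trials and
  are discarded (leaving 20 analysed).
* **Event-based PM** (`scoreEventPM()`): of the 15 scheduled targets, a
  target is credited if a spacebar press falls between its onset and the
  end of the *following* trial. Participants are explicitly instructed
  to respond even after the cue has disappeared; one following trial is
  the narrowest window consistent with that instruction. PM RT is the
  first press minus target onset over credited targets.
* **Time-based PM** (`scoreTimePM()`): the headline measure is the mean
  interval between successive presses (instructed interval 30 s). With
  fewer than two presses it is undefined and propagates as missing —
  never as zero. The press count is also expressed as a percentage of
  the ideal `floor(duration / 30)` (flooring chosen as the conservative
  reading where the convention is unstated), and clock checks are
  counted as clock-box openings.
* **Time estimation** (`scoreTimeEstimation()`): four trials of ten
  externally paced numerals followed by silent counting; the produced
  duration runs from the last paced numeral to the key press. Both
  variants have ideal per-trial durations 10 + 20 + 30 + 40 = 100 s
  (TE1: 1 s pace counting to 20/30/40/50; TE2: 2 s pace to 15/20/25/30).
  A missing press leaves that trial's duration missing and flags the
  total as partial.

The event-phase design arithmetic is checked, not assumed: the fixed
inter-target schedule (30 24 22 16 14 8 6 2 4 10 12 18 20 26 28) plus
two terminal trials gives 242 ongoing trials and 15 targets, a 5.9%
target rate over the 255 counted trials
(`eventScheduleSummary()`, `validateEventSchedule()`).

## The synthetic cohort generator

`cohortSpec()` / `generateCohort()` produce lesion masks as unions of
1–3 axis-aligned random ellipsoids per patient (mild anisotropy,
per-patient total volume log-uniform over a configurable range) plus a
behavioural score table. Defaults mirror the target study population:
45 patients, 107 controls, an MNI-like 79×95×79 grid at 2 mm, volumes
1–100 cm³, and a time-based inter-press measure with controls at
Normal(32.9 s, 9.6 s) and deficit carriers at Normal(48.1 s, 5.1 s),
truncated to 5–120 s.

A planted deficit region is a voxel set; *designated carriers* receive a
lesion that includes the whole region (a deficit region is, by
construction, its patients' common damage), while any other patient
whose random lesion overlaps the region by at least `carrierMinVoxels`
also becomes a carrier by rule. Carrier status then selects the score
distribution per measure, so a second measure with carrier mean equal to
the control mean serves as a matched null. All randomness fans out from
one seed through per-subject substreams, so subject $k$ is identical
regardless of cohort size.

What the generator deliberately does **not** emulate: vascular-territory
or tumour-growth lesion geometry, spatial correlation between lesion
site and behavioural noise, scanner artefacts, or registration error.
Passing recovery tests therefore demonstrate the *procedure's*
correctness and calibration — not that real lesions of this size would
yield the same power.

## Numerical choices

* Grids must match exactly in dimensions and to 1e-4 in the affine;
  mismatched inputs are rejected rather than resampled, since inputs are
  assumed pre-normalised to one template.
* Voxel indices are 0-based; world coordinates arise only through the
  affine; the voxel-to-world round trip is tested to 1e-6 mm.
* Untested voxels are written to NIfTI as the sentinel −1 (recorded in
  the file's description field) and restored as missing on read.
* Mask binarisation accepts exactly two distinct values {0, v>0};
  anything else is rejected as not being a mask.
* Tie handling: mid-ranks with tie-corrected variance; the exact branch
  engages only for tie-free pooled samples of at most 12.
* p-values are capped into (0, 1]; Holm rejection uses
  `stats::p.adjust` internally so the step-down is the textbook one.

## Validation scale

The test suite and the acceptance script validate at desk scale, chosen
to finish in minutes on one core while preserving the study's relative
proportions: a 20³ grid at 2 mm with lesion volumes log-uniform over
0.25–16 cm³ (the same span relative to the sampled volume as 0.8–465
cm³ of a brain). Family-wise error control is estimated over 200 null
cohorts of 30 patients and 50 controls; deficit recovery over 50
replicates of 45 patients (8 designated carriers, the size of the
study's key patient subgroup) against 107 controls with the
paper-anchored effect (48.1 ± 5.1 s vs 32.9 ± 9.6 s). Exact-test
equivalence is enumerated exhaustively up to pooled size 10, and the
partition is checked against brute-force membership grouping on grids
up to 8³.

## Known limitations

* No atlas labelling: report rows locate subregions by MNI coordinates
  only; the `label` column is a hook for downstream lookup.
* No covariate adjustment (age, lesion volume) in the subregion tests;
  the region-vs-rest contrasts (`regionVsRest()`) are the provided means
  of probing specificity.
* The normal approximation is conservative for very small subregions
  against large control samples; genuinely tiny-sample maps should be
  read with that in mind.
* Continuous lesion probability maps and lesion-network approaches are
  out of scope: masks are strictly binary.
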