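---
title: "Counting HRD scars: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting HRD scars: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrdscars)
```

## The problem

Tumors deficient in homologous recombination (HRD) — most prominently
high-grade serous ovarian carcinoma and triple-negative breast cancer with
*BRCA1/2* inactivation — accumulate characteristic chromosomal "scars":
allelic imbalances (AIs) whose sizes and positions differ systematically
from those of HR-proficient (HRP) tumors. Because HRD predicts response to
platinum and PARP inhibition, counting these scars from allele-specific
copy-number profiles is a clinically used biomarker.

`hrdscars` implements the full scar-quantification stack: the three event
counters (LOH, LST, TAI) under parametric selection criteria, the published
preset criteria, the statistical machinery used to *derive* such criteria
from an annotated cohort, cohort agreement/concordance statistics, survival
comparison of HR classes, and a synthetic cohort generator that makes every
step testable without access-controlled data.

## Segment model

A sample is an ordered table of allele-specific copy-number segments with
1-based inclusive coordinates (the seg-file convention), a major and a minor
copy number (`minor <= major`), and lengths computed as
`(end - start + 1)/1e6` Mb. Three input dialects are read
(`generic_seg`, GDC allele-specific, ASCAT output); the writer emits
`generic_seg` with a bit-exact round trip.

**Smoothing.** Fragments strictly shorter than 50 bp are removed and
adjacent same-state segments merged. The 50 bp default follows the
convention quoted for this method family; it is deliberately configurable
because the cited precedent smooths much larger variations — we do not
silently change the default. Smoothing is idempotent, and splitting any
segment at an interior breakpoint followed by smoothing reproduces the
original profile, which is the invariance the test suite exercises.

**AI classification.** Two conventions are exposed: `allele_specific`
(AI iff `major != minor`; includes copy-neutral LOH) and `total_cn`
(AI iff `major + minor != 2`; the pan-cancer landscape convention). Scar
counting defaults to allele-specific, the landscape module to total-CN,
matching the two analyses they reproduce.

**Telomere and centromere geometry.** Array- and WGS-derived segmentations
never reach physical telomeres, so telomere contact is defined against the
*covered extent* of each chromosome in the profile (first/last covered bp).
A segment touching both covered ends spans the whole chromosome; such
segments are counted by neither LOH nor TAI. A segment crosses the
centromere iff it starts before and ends after the centromere interval.
Bundled hg19/hg38 tables use the cytoband acen intervals as the centromere
model; chrY is excluded by default (the target diseases are female
cancers), and custom assemblies are plain-text TSVs.

## The three counters

All length comparisons are strict (`>`/`<`), per the wording that defines
the criteria; the HR-status comparison is inclusive (`levels >= cutoff`).

* **LOH** — segments with `minor = 0` and `major >= 1` (homozygous
  deletions are loss, not retained-allele imbalance), length strictly
  inside `(l_min, l_max)`, not spanning a whole chromosome.
* **LST** — breakpoints between consecutive copy-number states, evaluated
  per chromosome arm with segments clipped to the arm (the centromere
  interval belongs to neither arm, so transitions across it never count).
  Both flanks must exceed `s` within the arm and the uncovered gap between
  them must be below `m`. Any state change qualifies, not only AI-to-AI:
  "large-scale transition" is a property of the breakpoint, not of the
  flanking states.
* **TAI** — AI segments touching exactly one covered chromosome end, not
  crossing the centromere, longer than `k`.

The presets are `telli2016` (LOH 15–50 Mb, LST s = 12/m = 1 Mb, TAI
k = 1 Mb, cutoff 42), `takaya2020` (same criteria, cutoff 63),
`ovaHRDscar` (same criteria, cutoff 54) and `tnbcHRDscar` (LOH 10–30 Mb,
LST s = 5/m = 2 Mb, TAI k = 1 Mb, cutoff 53). The first three share
selection criteria exactly and differ only in cutoff, which the test suite
asserts as a levels-identity. The engine is fully parametric, so corrected
or re-derived criteria are one `criteria_set()` away.

## Deriving criteria from an annotated cohort

**Ground truth.** A sample is annotated HRD when it carries a pathogenic
somatic/germline mutation, a strong deletion signal, or promoter
hypermethylation (mean beta ≥ 0.75 within 1500 bp of the TSS) in BRCA1/2
or a RAD51 paralog; HRP when it has none of these, all three omics layers
available, and no deletion in any HR-pathway gene; everything else — and
any manually excluded outlier — is `undefined`. The promoter window is
implemented "downstream of the TSS" as written, with a signed-window
option because promoter probes conventionally flank the TSS; the gene sets
are arguments, not hard-coded biology.

**Scoring.** For a candidate criteria configuration the per-sample counts
are compared between annotated classes by (1) a one-tailed Mann–Whitney U
test (HRD greater) and (2) a decision stump: the threshold maximizing
balanced accuracy BA = (TPR + TNR)/2 under the rule `count >= split` ⇒
HRD. The selection score is `-log10(p) * BA`. Two numerical choices are
deliberate:

* the original work used an impurity-based tree package for the stump;
  we fix the stump as the exhaustive maximum-BA threshold with ties broken
  toward the lowest qualifying split — equivalent on clean 1-D splits and
  fully deterministic. All distinct partitions are examined, including the
  two degenerate ones, so the optimal BA is never below 0.5.
* the U test uses exact enumeration over all group assignments when both
  classes have ≤ 8 samples (correct under ties) and the normal
  approximation with tie and continuity correction otherwise. The score is
  invariant under strictly monotone transforms of the counts.

**Grid search** extracts the per-sample feature primitives once (LOH
lengths; LST breakpoint flank/gap pairs; TAI lengths) and scans the grid
over them, which makes the exhaustive scan cheap. Degenerate LOH points
(`l_min >= l_max`) are skipped with a warning. Ranking ties break toward
smaller parameter values (`l_min`/`s`/`k`, then `l_max`/`m` — the spec
fixes the first group; the second is our analogous choice).

**Cutoff selection** resamples 29 samples per class with replacement
10,000 times (both defaults configurable) and, per candidate cutoff,
reports the median and percentile 95% CI of the replicate balanced
accuracies, selecting the highest median. On a separable plateau every
candidate ties at BA 1; the tie is broken toward the candidate closest to
the intersection of the two classes' kernel density estimates between the
class medians (this mirrors how the TNBC cutoff 53 was chosen from the
47–53 plateau), falling back to the largest tied candidate when the
densities do not cross there.

## Concordance, purity, and patient-level calls

Lin's concordance correlation coefficient uses population (n-denominator)
moments: `ccc = 2*cov/(var_x + var_y + (mean_x - mean_y)^2)`, so
`|ccc| <= |r|` always. Cohen's kappa uses marginal-product expected
agreement. Tumor purity from the truncal TP53 variant allele fraction is
`2/((CN/VAF) - (CN - 2))`; note that for valid inputs (VAF ≤ 1, CN > 0)
the denominator is ≥ 2 and the estimate is always in (0, 1] — the
defensive clamp at 1.05 specified for noisy VAF inputs is retained but
unreachable through the validated interface. Patient-level calls drop
samples below a 0.30 purity floor (applied here, not at raw
quantification: the floor is a reliability bound, not a counting rule),
then prioritize anatomical sites (adnexal-first or omental-first) and
average levels within the chosen site.

## Survival

Log-rank and Cox proportional hazards are delegated to the `survival`
package (Efron tie handling; the HR is reported HRD vs HRP). The KM median
is the smallest time at which the product-limit curve drops to ≤ 0.5,
undefined under heavy censoring; the bootstrap fold-change procedure
resamples the pooled patient list (group labels travel with patients; a
stratified option exists), computes KM-median(HRD)/KM-median(HRP) per
replicate, and drops-and-counts replicates with undefined medians,
erroring when more than half are dropped.

## The synthetic cohort generator

The generator plants four event types on a balanced 1/1 diploid baseline:
interstitial LOH (2/0), interstitial non-LOH AI (2/1), adjacent
different-state pairs (2/1 next to 3/1 with a short uncovered internal
gap — the canonical LST generator), and telomere-anchored AIs. Events are
Poisson in number, log-normal or uniform in length, placed uniformly within
chromosome arms, widest first, with configurable margins to arm boundaries
and spacing between events. Sub-50 bp AI fragments are added as noise and
must disappear under smoothing.

Design points worth knowing:

* **Default genome**: 3 chromosomes of 200/150/100 Mb with centromeres at
  40–45% of length — deliberately small so that the brute-force oracles in
  the test suite stay cheap. Scar levels scale with genome size, so
  default HRD-like samples score roughly 8–12 and HRP-like 0–3 (about
  450/3000 of realistic whole-genome levels); the published cutoffs are
  *not* meaningful on this toy genome.
* **Class defaults** mirror the empirical contrast: HRD-like samples carry
  15–50 Mb LOH, long adjacent state transitions and telomeric AIs;
  HRP-like samples carry mostly sub-megabase imbalances.
* **Determinism**: every sample derives its own RNG sub-stream from the
  cohort seed, its class and its index, so enlarging a cohort never
  reshuffles existing samples.
* **Capacity**: when a drawn event load cannot be placed (Poisson tail on
  a small genome), the sample is redrawn from the next derived sub-seed up
  to 20 times before a capacity error is raised. The generator therefore
  conditions mildly on placeability; the alternative — failing ~5–10% of
  samples on the default genome — would make cohort generation unusable.
* **Truth accounting**: with margins and spacing above the LST flank
  threshold, the scar counts implied by a placement are computable from
  the event geometry alone (`expected_scar_truth`), giving the tests an
  exact planted-truth oracle that never runs the counters.

What the generator does *not* emulate: replication-timing or
mutation-signature structure, probe-level noise, subclonality, purity
artifacts, and realistic chromosome-arm length distributions. A green test
therefore establishes that the counters implement their definitions and
that the derivation machinery recovers planted structure — not that the
presets are clinically valid on real cohorts.

**The window-recovery world** (acceptance criterion 7) deserves a note:
HRD samples receive LOH uniformly enriched over 15.5–49.5 Mb on a small
shared short-LOH background, while HRP samples concentrate their LOH below
15 Mb and above 50 Mb with only a thin in-window rate. The asymmetry
mirrors the observed short-event excess of HR-proficient tumors, and it is
statistically necessary: with a background common to both classes the
rank-sum p saturates at complete separation and the fitted window edges
become noise-driven. This was established by design-time power analysis
(39/40 recovery across held-out seed batches) before the test seeds were
frozen.

## Numerical conventions

* Strict inequalities for all length criteria; inclusive cutoff.
* Exact U-test enumeration for ≤ 8 per class; tie- and
  continuity-corrected normal approximation otherwise.
* Stump ties → lowest qualifying split; grid ties → smallest parameters;
  cutoff plateau ties → KDE intersection, then largest candidate.
* KM median: first time with survival ≤ 0.5 (no plateau averaging — this
  differs from `survfit`'s convention exactly on knife-edge 0.5 plateaus).
* Skewness: Fisher–Pearson g1 with n-denominator moments, pooled AI
  lengths by default.
* Differential length bins are `[low, high)`; fold change is
  `mean(A)/mean(B) - 1`, undefined when B has zero abundance.

## Limitations

Segmentation, purity/ploidy fitting, variant pathogenicity classification
and the external comparator algorithms (SigMA, HRDetect, CHORD) are out of
scope; agreement statistics accept their pre-computed calls as plain
tables. The "three consecutive AIs" LST variant is not implemented
(reported inferior and under-specified). Published cohort-level numbers
require controlled-access data and are not reproduced here.
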