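# hrdscars

Quantification of homologous-recombination-deficiency (HRD) genomic scars
from allele-specific copy-number segments, and the statistical machinery
for deriving and validating scar-based HR classifiers.

## What it does, and for whom

Tumors that cannot repair double-strand breaks by homologous recombination
(typically through *BRCA1/2* inactivation) accumulate characteristic
chromosomal scars. Three scar families are counted from allele-specific
copy-number profiles:

* **LOH** — loss-of-heterozygosity segments (`minor_cn = 0`,
  `major_cn >= 1`) with length inside a window `(l_min, l_max)`;
* **LST** — large-scale state transitions: breakpoints between adjacent
  copy-number states, per chromosome arm, with both flanks longer than `s`
  Mb and an uncovered gap below `m` Mb;
* **TAI** — telomeric allelic imbalances longer than `k` Mb that reach one
  covered chromosome end without crossing the centromere.

The per-sample **scar level** is `n_LOH + n_LST + n_TAI`; a sample is
called HRD when `levels >= cutoff`. Four published parameterizations ship
as presets (`telli2016`, `takaya2020`, `ovaHRDscar`, `tnbcHRDscar`). For
method development, the package also implements the derivation pipeline:

* multi-omics ground-truth annotation (pathogenic mutations, strong
  deletions, promoter hypermethylation at mean beta >= 0.75 near the TSS);
* criteria scoring by one-tailed Mann–Whitney U test plus a decision-stump
  balanced accuracy, combined as `score = -log10(p) * BA`,
  `BA = (TPR + TNR)/2`, with exhaustive grid search;
* bootstrap cutoff selection (29 per class, 10,000 resamples, highest
  median BA, KDE-intersection tie-break);
* agreement (percent agreement, Cohen's kappa), Lin's concordance
  `ccc = 2*cov(x,y)/(var(x)+var(y)+(mean(x)-mean(y))^2)`, intra/inter-patient
  pairwise level differences, TP53-VAF purity
  `purity = 2/((CN/VAF) - (CN - 2))`, patient-level site prioritization;
* survival comparison of HR classes (log-rank, Cox PH with covariates,
  1000x bootstrap of the median-survival fold change);
* a seeded synthetic cohort generator so that all of the above is testable
  offline.

Audience: bioinformaticians working with ASCAT/GDC-style allele-specific
segment tables who need reproducible scar scores, and methodologists who
want to re-derive or stress-test selection criteria on controlled inputs.

## Worked example

```r
library(hrdscars)

cfg <- sim_config()                      # 3-chromosome toy genome
cohort <- simulate_cohort(cfg, n_hrd = 5, n_hrp = 5, seed = 42)
counts <- quantify_cohort(cohort$profiles, cfg$assembly,
                          get_preset("ovaHRDscar"))
counts
#>    sample_id n_loh n_lst n_tai levels
#> 1    HRD_001     1     5     1      7
#> 2    HRD_002     0     3     2      5
#> 3    HRD_003     1     7     0      8
#> 4    HRD_004     2     6     2     10
#> 5    HRD_005     2    13     1     16
#> 6    HRP_001     0     0     3      3
#> 7    HRP_002     0     0     0      0
#> 8    HRP_003     0     0     0      0
#> 9    HRP_004     0     0     0      0
#> 10   HRP_005     0     0     0      0
```

Each row is one simulated sample: the three scar counts and their sum
(`levels`). HRD-like samples score visibly higher. The toy genome is ~450
Mb, so levels are roughly 450/3000 of realistic whole-genome values and
the published cutoffs (42/54/63/53) do not apply to it; classify against a
cutoff on the same scale instead:

```r
classify_hr_status(counts, criteria_set("toy", 15, 50, 12, 1, 1, cutoff = 6))
#>    sample_id levels cutoff status
#> 1    HRD_001      7      6    HRD
#> 2    HRD_002      5      6    HRP
#> ...
```

Real data enters through `read_segments()` (`generic_seg`, GDC
allele-specific, or ASCAT dialects) with `genome_assembly("hg38")` or
`"hg19"`, and the same two calls above.

A command-line front end mirrors the pipeline
(`quantify`, `simulate`, `cutoff`, `concordance`, `survive`):

```sh
Rscript inst/cli/hrdscars quantify --segments segs.tsv --dialect ascat_output \
    --assembly hg38 --preset ovaHRDscar --out calls.tsv
```

## Documentation

The methods vignette (`vignettes/hrd-scars.Rmd`) describes the segment
model, counter definitions and their strict-inequality conventions, the
optimizer's numerical choices, what the synthetic generator does and does
not emulate, and known limitations.
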