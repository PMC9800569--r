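Package: hrdscars
Title: Quantification of Homologous Recombination Deficiency Scars from
    Allele-Specific Copy-Number Segments
Version: 1.0.0
Authors@R: person("HRD", "Tools", email = "tools@example.org",
    role = c("aut", "cre"))
Description: Counts homologous-recombination-deficiency (HRD) specific
    allelic imbalances (loss of heterozygosity, large-scale state
    transitions, telomeric allelic imbalance) from allele-specific
    copy-number segment tables, classifies samples as HR-deficient or
    HR-proficient against published or user-supplied criteria
    (Telli2016, Takaya2020, ovaHRDscar, tnbcHRDscar presets), and ships
    the statistical machinery used to derive such criteria: multi-omics
    ground-truth annotation, decision-stump balanced accuracy, rank-sum
    grid search over selection criteria, bootstrap cutoff selection,
    agreement/concordance statistics, TP53-VAF purity estimation,
    survival comparison of HR classes, and a synthetic cohort generator
    for end-to-end testing without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
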