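Package: bimodalshift
Title: Pre- to Postoperative Speech Perception Change in Bimodal Cochlear
    Implant Users
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing longitudinal speech-audiometry cohorts of
    bimodal cochlear-implant users (a cochlear implant in one ear and a
    hearing aid in the other). Provides a Monte-Carlo binomial
    critical-difference engine for deciding whether two percent-correct
    speech scores based on possibly unequal numbers of items differ
    significantly, with an exact-enumeration counterpart; a longitudinal
    cohort data model with delimited-text readers, pure-tone averages, an
    effective-item-count registry, postoperative score aggregation and a
    cascade of inclusion filters; per-subject significance classification;
    group-level paired comparisons with a normality-gated choice between
    the paired t-test and the Wilcoxon signed-rank test; Pearson and
    first-order partial correlations for association screens; and a
    synthetic cohort generator so that every stage of the pipeline can be
    exercised and calibrated without access to patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
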