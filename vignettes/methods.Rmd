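---
title: "Methods: critical differences and the pre/post bimodal pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: critical differences and the pre/post bimodal pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bimodalshift)
```

## The problem

Bimodal cochlear-implant users hear with an implant in one ear and a hearing
aid in the other. After implantation, speech perception in the implanted ear
and in the bimodal condition typically improves, but a clinically important
question is whether the *nonimplanted*, acoustically aided ear holds steady.
Answering it per subject requires deciding whether two percent-correct speech
scores — one preoperative, one postoperative, often based on different numbers
of test items — differ by more than binomial measurement error. Answering it
at the group level requires a pipeline that aggregates repeated postoperative
sessions, excludes sessions where the hearing aid may not have been working or
where the ear's pure-tone sensitivity changed materially, and then applies
paired tests and correlation screens. This package implements that pipeline,
together with a synthetic cohort generator so every stage can be exercised and
calibrated without patient data.

## The critical-difference statistic

A speech score is a proportion correct `p` observed on `n` scored items, so a
score's sampling error is binomial: the attainable values form the grid
`0, 1/n, ..., 1` (`possible_scores()`). To compare a score `(p1, n1)` with a
score `(p2, n2)` the engine considers the difference of two independent
binomial proportions, `d = X1/n1 - X2/n2` with `X1 ~ Bin(n1, p1)` and
`X2 ~ Bin(n2, p2)`, and forms a z statistic from the Monte-Carlo (or exact)
moments of `d`. Two constructions are provided:

* **Signed** (default): `z = mean(d) / sd(d)`. Its exact value is the familiar
  unpooled two-proportion statistic
  `(p1 - p2) / sqrt(p1 q1 / n1 + p2 q2 / n2)`; a pair is significantly
  different when `|z| > 1.96` (two-tailed 5%).
* **Absolute**: `z = mean(|d|) / sd(|d|)`, thresholded at the same cutoff.
  When `p1 = p2` this statistic equals about 1.32 (the mean-to-sd ratio of a
  half-normal), so identical scores are never significant; it grows with the
  separation of the two proportions.

Why the signed construction is the default: calibration. Integrating exactly
over true proportions uniform in `[0.2, 0.8]` at `n1 = n2 = 50` (the test
suite performs this integration), the probability that a null pair — equal
true proportions — is flagged as a significant *decrease* is about 2.8% for
the signed statistic, close to the nominal 2.5% per direction implied by a
two-tailed 5% test, while the absolute construction flags about 3.8% per
direction. The absolute variant is retained
(`crit_diff_config(statistic = "absolute")`, `exact_abs_diff_z()`,
`simulate_abs_diff_z()`) because its mean-of-absolute-differences form is
how the procedure is often described, and because comparing the two makes the
calibration cost of that description explicit. The residual excess of the
signed construction over 2.5% comes from evaluating the variance at the
observed rather than pooled proportions; no continuity correction is applied,
because the Monte-Carlo construction the engine mirrors has none.

### Exact enumeration versus simulation

For each statistic both an exact and a Monte-Carlo path exist. The exact path
enumerates all `(n1 + 1)(n2 + 1)` outcome pairs with their binomial
probabilities (for the signed statistic the moments collapse to closed form);
the Monte-Carlo path draws `iterations` pairs (default 40,000). `compare_scores()`
selects the exact path automatically whenever the outcome-pair count is at
most `exact_guard` (default 1e6), making per-subject verdicts deterministic at
every realistic item count; the simulation path exists for arbitrarily large
`n` and as a cross-check of the enumeration. With a seed in the
configuration, one seeded stream covers a whole comparison or table call and
the seed is recorded in the output.

Numerical contracts, chosen once:

* Degenerate spread (both scores certain, e.g. `p` of 0 or 1 on both sides):
  z is 0 when the mean difference is also 0 — identical certain scores are
  never significant — and infinite when the mean difference is non-zero, so
  maximally distant certain scores always are.
* Off-grid scores (averages over sessions) are evaluated directly at the
  observed proportions rather than snapped to a table row; the z construction
  is well defined for any `p` in `[0, 1]`, and snapping would discard
  information. Exported tables remain available for users who want the
  classical table workflow.
* The Monte-Carlo path uses the sample (n − 1) standard deviation; the exact
  path uses the population value. At 40,000 iterations the difference is
  negligible.

### Properties worth knowing

Exhaustive checks over grids with `n1, n2 ≤ 25` show that the absolute
statistic is *not* strictly monotone as `p2` moves away from `p1`: near the
far boundary of the grid the spread of `|d|` shrinks faster than its mean
grows, producing dips of up to about 0.23 in z. The dips are reported by the
test suite rather than repaired; every affected value lies far above the 1.96
cutoff, and the resulting critical ranges remain contiguous for all grids
checked, so no significance verdict is affected. Critical-range tables store
the literal set of non-significant grid values and report contiguity as a
column instead of assuming it.

The Monte-Carlo and exact paths agree to within sampling error everywhere,
but note that the sampling error of the simulated z is proportional to z
itself (it is dominated by the error in the estimated standard deviation, so
about `z / sqrt(2 * iterations)`). At corner pairs such as a certain score
against a near-certain one, where z is about 24, a 0.1 absolute agreement
band corresponds to only about two simulation standard errors at 1e5
iterations — agreement there is a coin flip even though the verdict is
unambiguous. The acceptance suite asserts the literal band and documents this.

## Effective item counts

Word tests contribute `lists × items-per-list` independent items. Keywords
within a sentence are not independent, so sentence keyword tests use a
conservative effective N of 40 regardless of the nominal keyword count
(100+ per list for typical sentence materials); this convention follows
published comparisons showing N = 40 to be an appropriately conservative
assumption for keyword-scored sentence tests. The registry
(`default_test_registry()`) maps each test id to its scoring unit, items per
list and override, and is user-extensible.

## Aggregating postoperative sessions

Two conventions are implemented and reported side by side, because both are
used in practice: `latest` takes the chronologically last usable score with
its own effective N; `average` takes the unweighted mean of session
proportions with effective N equal to the sum of per-session Ns (an average
of three 50-word lists behaves like a 150-item score). Averaging is
unweighted even when list counts differ across sessions — matching the
pooled-N convention — and ties in session timing are broken by file order
with a logged warning. A preoperative score recorded as "could not test" is
never coded as 0%: the subject is excluded from that condition's comparison,
since such entries mean open-set testing was impossible, not that the true
score was zero.

## The inclusion-filter cascade

Analyses of the nonimplanted ear run over nested subsets of increasingly
strict criteria:

1. all subjects, with the baseline rule that a postoperative datapoint is
   excluded when its pure-tone average (PTA) *differs* from the preoperative
   PTA by more than 25 dB (absolute difference);
2. additionally requiring evidence of correct hearing-aid function
   (sessions whose verification route is unknown are dropped);
3–5. additionally excluding datapoints whose PTA *increased* by more than
   20, 10 or 5 dB.

The deliberate asymmetry — absolute difference at 25 dB, increase-only at
20/10/5 dB — mirrors the wording of the protocols these cascades come from:
the baseline rule guards data integrity in both directions, while the strict
rules target progressive hearing loss specifically. Exclusion is evaluated
per session (datapoint level), not per subject; a subject with no surviving
postoperative datapoint for a condition drops out of that condition's
comparison. Every removal is written to an exclusion log with its reason, so
the N of every downstream row is auditable. Tightening any criterion can only
shrink the surviving cohort, and the test suite asserts this monotonicity.

The PTA is the mean of unaided thresholds at 500, 1000 and 2000 Hz by
default — the most common clinical convention; the frequency set is
configurable, and a missing threshold at a requested frequency is an error,
never silently imputed.

## Per-subject classification and chance expectations

`classify_subject()` builds the pre and aggregated post observations, runs
the critical-difference comparison, and maps the outcome to
higher / lower / no-change, or not-testable when a constituent is missing.
With a two-tailed 5% criterion applied to `N` subjects,
`expected_false_positives(N)` returns the chance expectation per direction,
`round(0.025 N)` with halves rounded up — 3 for N = 132. Nearest-integer
rounding is used (2.5% of 132 is 3.3, reported as 3); subjects ruled
not-testable after filtering are excluded from the denominators of any
percentage summaries.

## Group-level comparisons

`paired_group_test()` compares paired percent-correct vectors: a
Shapiro-Wilk test on the paired differences at alpha 0.05 gates the choice
between the paired t-test and the Wilcoxon signed-rank test (both
two-tailed). The gate test and level are configurable; no specific normality
test is canonical here, and Shapiro-Wilk is the common default for samples of
this size. Zero differences are dropped in the signed-rank branch (the
signed-rank convention) and counted in the output; an all-zero difference
vector returns p = 1 rather than an error. Percentages (0–100) are the
analysis unit throughout. `nested_subset_analysis()` applies the filter
cascade and both aggregation conventions, producing the familiar
subsets-by-stringency outcome table.

## Association analyses

The nonimplanted-ear score change (post − pre, in percentage points, so a
drop is negative) is correlated with the PTA change in the same ear, the
implanted-ear advantage (implanted minus nonimplanted postoperative score),
and the average postoperative implanted-ear score; the advantage correlation
is recomputed after partialling out the postoperative hearing-aid score,
because both variables contain it. Only hearing-aid-verified datapoints enter
these analyses — the verified filter is applied before any variable is built,
and its exclusion log is attached to the result. The first-order partial
correlation is computed from the closed form
`(r_xy − r_xz r_yz) / sqrt((1 − r_xz²)(1 − r_yz²))` with a two-tailed p from
the t distribution on n − 3 degrees of freedom; the test suite verifies it
against the residual-regression construction to 1e-10. A control collinear
with either variable is refused rather than returning an indeterminate 0/0.
The demographic screen codes binary variables 0/1 (point-biserial) with the
coding documented in the output, and skips — with a log entry — variables
that are constant or entirely missing. Whether the change variable uses the
average or the latest postoperative score is an explicit argument (default
average).

## The synthetic cohort generator

`sim_config()` parameterizes a generative model of the cohort the pipeline
expects; `generate_cohort()` draws from it. Per subject: a true preoperative
hearing-aid-ear proportion (truncated normal, mean 0.44, sd 0.20), a low
preoperative and high postoperative implanted-ear proportion, a bilateral
proportion slightly above the better ear, and a nonimplanted-ear change (in
percentage points) that is linear in the implanted-ear advantage:
`change = β0 + β1 · advantage + ε`. The defaults (β0 = −2.5, β1 = −0.18,
sd(ε) = 8) produce a mean change near −7.5 points and a qualitative
advantage-linked decline; `null_config()` zeroes the whole decline model and
the PTA progression, so any observed change is pure measurement noise.
Session counts are `1 + Poisson(1.5)` truncated at 11 (mean ≈ 2.5); the last
follow-up is gamma with mean 37 months; PTA progression is zero-inflated
exponential (probability 0.5, mean 5.5 dB at the last follow-up, accruing
proportionally to time), giving a mean near 2.5 dB with a heavy right tail so
that a small fraction of subjects crosses the 20 dB exclusion bound.
Preoperative could-not-test rates (29/132 implanted ear, 41/132 bilateral)
and the verification mix (81/132 threshold-verified, 41/132 clinician report,
10/132 unknown) are applied at the subject level.

Critically, observed scores are binomial draws at each session's effective
item count divided by that count — the generator's measurement noise is
*exactly* the noise model the critical-difference procedure assumes. That is
what makes the calibration and parameter-recovery tests meaningful: a null
cohort should be flagged at close to the nominal rate, and a built-in decline
of −7.5 points should be recovered by the group analysis without bias beyond
the slight shrinkage caused by truncating true proportions at the `[0, 1]`
bounds.

What the generator does **not** emulate — and therefore what passing tests do
not establish about real data: per-frequency audiogram shapes beyond a fixed
slope (only the PTA matters to the filters), audiometric test-retest noise,
hearing-aid gain or fitting quality, session-to-session drift in true ability
(each subject has one pre and one post true score per condition), site- or
test-specific difficulty differences, correlated missingness, and any
mechanism linking PTA progression to speech decline (the two are independent
in the generator, so the PTA-change correlation is near zero by
construction). Distribution families — truncated normal for scores, gamma for
follow-up, zero-inflated exponential for progression — are implementation
choices documented here, not claims about the field; the preoperative score
variance has no published value and its default is a free parameter chosen to
give a realistic spread.

## Reproducibility and problem sizes

Every stochastic component takes an explicit seed: the generator through
`sim_config(seed = )`, the comparison engine through
`crit_diff_config(seed = )`, run manifests record both. Because the exact
path covers all realistic item counts, per-subject verdicts are deterministic
given the data. The test suite exercises the engine exhaustively on grids up
to n = 25 (with Monte-Carlo cross-checks at 1e5 iterations), calibrates the
classifier on 10,000 null pairs at n = 50, and checks parameter recovery on
50 replicate cohorts of 132 subjects; these sizes were chosen as the smallest
at which the sampling error of each check is well below the effect it
guards.

## Known limitations

* The critical-difference construction treats the observed proportions as
  the true ones when computing the variance; at n = 50 this leaves the
  per-direction null rate slightly above 2.5% (about 2.8%) even for the
  signed statistic.
* Effective-N pooling for averaged sessions assumes independence across
  sessions; real repeated tests on the same material violate this to an
  unknown degree, making pooled comparisons anti-conservative for subjects
  retested with identical lists.
* The subsets-by-stringency bookkeeping reports whatever N the filter rules
  produce. Published cascades of this design sometimes print Ns that
  disagree by one between text and tables (e.g. 92 vs 91 for a ≤5 dB
  subset); the pipeline makes no attempt to reconcile such discrepancies and
  instead exposes the exclusion log so each N can be audited.
* No multiple-comparison correction is applied across subjects; following
  the design this package implements, chance expectations are reported
  instead (`expected_false_positives()`).
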