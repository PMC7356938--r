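# bimodalshift

Analysis of pre- to postoperative speech-perception change in **bimodal
cochlear-implant users** — people who hear with a cochlear implant (CI) in
one ear and a hearing aid (HA) in the other. The package is aimed at
audiology and hearing-science researchers who track longitudinal
percent-correct speech scores in three conditions (implanted ear,
nonimplanted ear, bimodal) and need to decide, per subject and at the group
level, whether the acoustically aided, nonimplanted ear declined after
implantation.

## What it computes

At its core is a **binomial critical-difference engine** for comparing two
proportion-correct scores observed on possibly unequal item counts. A score
is `(p, n)`: proportion correct on `n` effectively independent items. For the
difference of proportions `d = X1/n1 − X2/n2`, `Xi ~ Bin(ni, pi)`, the engine
forms

```
z = mean(d) / sd(d)        (signed, default; exactly
                            (p1 − p2) / sqrt(p1 q1/n1 + p2 q2/n2))
z = mean(|d|) / sd(|d|)    (absolute variant)
```

from exact enumeration of the outcome space when feasible (deterministic) or
Monte-Carlo simulation (default 40,000 iterations), flagging a pair as
significantly different when the magnitude exceeds a critical value (default
1.96, two-tailed 5%). Critical-difference *tables* — for each attainable
first score, the range of second scores statistically compatible with it —
can be built for any `(n1, n2)`, including averaged scores (three 50-word
lists behave as one 150-item score). Sentence keyword tests use a
conservative effective N of 40.

Around the engine sits the cohort pipeline:

* a longitudinal data model (subjects + sessions CSVs, wide `thr_<freq>hz`
  audiogram columns) with validation, pure-tone averages and a test registry;
* an inclusion-filter cascade (hearing-aid verification; PTA-change caps of
  25 dB absolute, then 20/10/5 dB increase-only) with a full exclusion log;
* per-subject classification (higher / lower / no change / not testable) and
  chance expectations (`expected_false_positives(132)` is 3 per direction);
* group-level paired comparisons with a Shapiro-Wilk-gated choice between the
  paired t-test and the Wilcoxon signed-rank test, over the nested subsets;
* Pearson and first-order partial correlations linking the nonimplanted-ear
  change to PTA change, implanted-ear score and implanted-ear advantage, plus
  a demographic screen;
* a fully parameterized synthetic cohort generator
  (`sim_config()` / `generate_cohort()`) so every stage is testable and
  calibratable without patient data.

See `vignettes/methods.Rmd` for the statistical details and design choices.

## Worked example

Compare one 50-word list at 60% with the average of three 50-word lists at
38%:

```r
library(bimodalshift)
compare_scores(score_observation(0.60, 50), score_observation(0.38, 150))
#> <critical difference: z = 2.756 (exact), significant at |z| > 1.96, direction lower>
```

The drop exceeds binomial measurement error at these item counts, so this
subject's nonimplanted ear would be classified "lower".

A full synthetic-cohort run (132 subjects, study-scale defaults):

```r
co  <- generate_cohort(paper_like_config(seed = 42))
co
#> <bimodal cohort: 132 subjects, 483 sessions (132 pre, 351 post)>
run <- run_full_analysis(co, cfg = crit_diff_config(seed = 42))
run$classification$summary
#>     condition  method higher lower no_change not_testable   n
#>     implanted average     91     0         4           37 132
#>     implanted  latest     89     0         6           37 132
#>  nonimplanted average      5    28        82           17 132
#>  nonimplanted  latest      6    21        88           17 132
#>     bilateral average     46     2        31           53 132
#>     bilateral  latest     44     0        35           53 132
```

The implanted ear improves almost universally; the nonimplanted ear shows a
decline in far more subjects (21–28) than the 3 expected by chance
(`expected_false_positives(132, 0.05)`), because the generator's defaults
build in an advantage-linked decline. The nested-subset table shows the group
effect surviving increasingly strict PTA criteria:

```r
head(as.data.frame(run$group_table), 4)
#>        subset  method   n pre_mean post_mean difference test_used statistic   p_value
#>  All subjects average 132    43.92     38.22     -5.705  paired-t    -5.238 6.304e-07
#>  All subjects  latest 132    43.92     38.98     -4.943  paired-t    -4.354 2.666e-05
#>    HA working average 115    44.16     38.54     -5.621  paired-t    -4.736 6.334e-06
#>    HA working  latest 115    44.16     39.24     -4.913  paired-t    -3.978 1.223e-04
```

and the association table recovers the built-in link between the
implanted-ear advantage and the drop (r = −0.43 here; the sign is negative
because change is post − pre, so a bigger advantage predicts a bigger drop):

```r
run$associations
#>      x_label   y_label control_label      r  p_value   n
#>   pta_change ha_change          <NA>  0.219 1.90e-02 115
#>    advantage ha_change          <NA> -0.429 1.75e-06 115
#>  ci_post_pct ha_change          <NA> -0.155 9.73e-02 115
#>    advantage ha_change   ha_post_pct -0.194 3.89e-02 115
```

`run_full_analysis(co, out_dir = "results/run1")` writes every table, the
exclusion log and a manifest as delimited text. Small example CSVs (marked
synthetic) live in `inst/extdata/`.

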