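---
title: "Surname-list cohort identification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surname-list cohort identification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(namecohort)
```

## The method

A surname-list classifier assigns ethnicity from a registry's surname
field alone. Its entire model is a set of lists: one list of canonical
surnames per target ethnic group, screened so that every retained name is
believed unique to that group. Assignment is exact whole-surname equality
on canonical form — a resident is South Asian if and only if their
normalized surname is on the South Asian list, Chinese if on the Chinese
list, and otherwise falls to the residual General Population. There is no
prefix, substring, or phonetic matching. That restraint is deliberate:
the classifier's purpose is assembling *pure* minority cohorts from
secondary data, so the design maximizes positive predictive value and
accepts the sensitivity loss from excluding every name shared with other
populations.

Validation treats the classifier as a diagnostic test. Self-reported
ethnicity from a weighted cross-sectional survey is the gold standard,
and the classifier's quality is summarized by sensitivity, specificity,
PPV and NPV, computed from the weighted cross-tabulation of
surname-derived against self-reported group.

## Normalization

Registry and survey spellings vary in case, diacritics and punctuation,
so all matching happens on a canonical form: transliterate to ASCII
(`é → E`), uppercase, delete apostrophes and periods (`D'Souza → DSOUZA`
— deleting rather than splitting keeps the name intact), convert any
other non-letter to a space, collapse whitespace, trim, and keep hyphens.
Hyphens are kept so compound surnames stay distinct from their
components; a compound name matches only as the full string. The
transformation is idempotent, so stored lists and incoming names can be
normalized independently and repeatedly without drift. Input with no
letters at all cannot name a person: list construction treats it as an
error, while bulk roster assignment routes it to the residual group with
a warning counter, because an assignment file must be total over the
roster.

Whether the original Ontario study matched raw or normalized spellings is
not something a reusable implementation can recover; the canonical-form
pipeline above is this package's definition, chosen to maximize match
robustness across registry spellings without merging distinct names.

## The gold standard

Two survey questions are used, both allowing multiple responses: ethnic
ancestry, and cultural/racial background. A respondent triggers a target
group when at least one question carries exactly one response equal to
that group's token (case-insensitively); everyone else — including anyone
listing a target group among several ancestries — is General Population.
Two choices are left open by that per-group formulation and are fixed
here as package policy:

* **Duplicated answers** collapse before the single-response test
  ("Chinese;Chinese" is one response): a repeated identical answer is
  still a single ethnic response.
* **Conflicts** (one question a single "South Asian", the other a single
  "Chinese") go to the residual group with a warning. The rules are
  stated per group with a residual "all others", and the conservative
  reading protects PPV: a conflicted record is not confident evidence of
  either group. `conflict = "precedence"` is available when a forced
  resolution is preferred.

Person-level weights are the number of population members a respondent
represents; pooling k survey cycles divides every weight by k so the
weighted total counts the population once. All four test characteristics
are ratios of weighted sums, so they are invariant to this (or any)
global rescaling — pooling matters for weighted *totals*, never for the
metrics, and the test suite asserts exactly that invariance.

## Test characteristics

The k×k crosstab collapses to 2×2 per target: TP is the diagonal cell,
FP the rest of the target row, FN the rest of the target column, TN the
remainder. A metric whose denominator is zero is reported as *undefined*
(`NA`), never 0: a stratum containing no predicted positives has no PPV,
and writing 0 would corrupt any stratified table it appears in.
Percentages print half-up to one decimal, the convention of published
validation tables; raw proportions are kept at full precision
internally, and all equality testing happens on the raw values at
tolerance 1e-12 against a brute-force per-respondent oracle.

Bootstrap intervals are percentile intervals over respondent-level
resampling with weights carried along (B = 1000 by default). The survey's
own design-based replicate-weight machinery is not publicly available,
and within this package's data model weights are population-representation
constants, not sampling probabilities, so respondent resampling is the
honest variance model. An interval is refused (with advice to enlarge the
sample) when the metric is undefined in more than half the replicates.

## The synthetic generator

Restricted registry and survey microdata cannot ship with a package, so
everything is validated on synthetic data with known ground truth. Each
respondent is drawn as:

1. **true group** from `prevalence` (defaults 5.4% South Asian, 4.0%
   Chinese — unweighted sampling proportions);
2. **strata**: immigration category, sex, age band from group-specific
   distributions matching the published baseline profile of the Ontario
   validation population (73.7% of the general population native-born
   versus 7.0% of South Asians, etc.);
3. **surname source**: walking the target lists in collection order, a
   person bears a name from list t with conditional probability
   `capture[t]` if a member, `contamination[t]` otherwise, both
   multiplied by the per-immigration-stratum `strata_effects`; anyone
   left bears a general-population name. The surname itself is drawn
   from the packaged 200-name fixtures with emission frequencies
   proportional to the ten printed Ontario counts per group, extended by
   a Zipf tail (`count_r = count_10 · 10/r`) over the remaining 190
   ranks — realistic name skew without inventing unpublished counts;
4. **self-report**: members answer their own token on both questions
   with probability `1 − misreport`, otherwise distractor tokens
   ("Southeast Asian", "Aboriginal", "Other" — the confusions a survey
   plausibly produces); residual-group respondents answer from European
   ancestry pools, occasionally (2%) listing a target token among
   several ancestries, which the single-response rule correctly ignores;
5. **weight** lognormal (meanlog `log(130)`, sdlog 0.6, i.e. a median
   respondent representing ~130 people), independent of group — the
   survey's weighting does not use ethnicity — and a cycle label from
   three equally mixed cycles.

Default capture is 0.504 / 0.802 and default contamination is
back-solved from the PPV identity so the expected overall PPV sits at
0.893 / 0.919, reproducing the published headline regime of the Ontario
validation. These calibration values are generator *inputs* describing
the emulated study conditions, never test targets: tests compare
pipeline output against the closed-form oracle, not against published
numbers. The back-solve uses the aggregate identity and ignores the tiny
sequential-draw cross terms, so the realized expected PPV can differ
from the calibration value in the third decimal (e.g. 0.9203 for the
Chinese list).

The default `strata_effects` multiply contamination by 2.0 for the
native-born, 0.5 for immigrants within 10 years and 1.5 for immigrants
beyond 20 years. The published nativity gradient (native-born PPV of
58.7% / 77.8% against 95%+ for recent immigrants) is qualitative
motivation only: no quantitative model of *why* native-born PPV is low
(marriage-acquired surnames, mixed parentage, identification drift) is
available, so the multipliers are a stylized stand-in. Much of the
gradient emerges from composition alone — minority prevalence among the
native-born is tiny, so even unchanged contamination dilutes PPV there.

`expected_metrics()` computes the exact characteristics implied by the
generative model by enumeration over (group × immigration stratum ×
surname source), conditioning on a stratum when one is requested. With
one target group and flat strata it reduces to

```
sensitivity = s        PPV = πs / (πs + (1 − π)c)
```

which the unit suite pins at `π = 0.05, s = 0.5, c = 0.003 → PPV ≈
0.8977`. Because the report draw is independent of the surname draw
given membership, misreporting moves gold labels (and hence FP counts)
without touching the member detection rate.

```{r oracle}
p <- simulation_params(n = 1000, target_groups = "South Asian",
                       prevalence = 0.05, capture = 0.5,
                       contamination = 0.003)
expected_metrics(p, "South Asian")
```

### What the generator does not emulate

The generator draws respondents independently; it does not model the
survey's multi-frame sampling, non-response calibration or household
clustering, name changes over time, first names, or intergenerational
intermarriage dynamics. Passing the recovery suites therefore shows that
the *mechanics* — normalization, matching, resolution, weighting,
tabulation — are correct under a known model, not that any particular
list will achieve these characteristics on real registry data, and not
that the bootstrap reproduces design-based survey variance.

## Problem sizes and numerical choices

The validation suites run at sizes chosen to make Monte-Carlo error
small relative to the assertions: 100 random 200-respondent fixtures for
exact oracle equivalence (tolerance 1e-12); n = 50,000 per point on an
8-point (π, s, c) grid for pipeline-versus-closed-form recovery, asserted
within 3 Monte-Carlo standard errors using Kish effective sample sizes
for the weighted denominators; and n = 50,000 for the stratified
nativity-gradient check. Seeds are fixed per case; the generator is
fully deterministic given its seed and restores the caller's RNG state.

Other fixed choices: list files are UTF-8; set semantics everywhere
(duplicate names collapse, answer sets deduplicate); overlapping lists
refuse to classify unless an explicit precedence is declared, because
silent precedence would quietly change PPV semantics; rounding for
display is half-up (base R's `round()` is half-to-even and would print
published-style tables differently).

## Limitations

A screened list systematically excludes subgroups whose names are shared
across populations — for South Asia, most Muslim and Christian names —
so cohorts it builds are unrepresentative by construction, and any
heterogeneity between included and excluded subgroups biases downstream
research. Performance degrades among the native-born and will not
transfer across jurisdictions with different immigration histories. The
packaged 200-name starter lists are demonstration fixtures: real
deployments should build full lists with `build_list()` and
`screen_exclusions()` from their own candidate sources.
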