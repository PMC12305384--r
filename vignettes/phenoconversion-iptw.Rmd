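---
title: "CYP2D6 phenoconversion and IPTW analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CYP2D6 phenoconversion and IPTW analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoconv)
```

## The scientific problem

Hydrocodone, tramadol and codeine are prodrugs: CYP2D6 converts them into
the metabolites that carry most of their analgesic activity (oxycodone is
metabolized by both CYP2D6 and CYP3A4, and its parent compound is itself
active). A patient's CYP2D6 activity is determined jointly by genotype —
the pair of star alleles they carry — and by drug interactions: strong
CYP2D6 inhibitors (bupropion, fluoxetine, paroxetine, terbinafine,
quinidine) abolish enzyme activity, and moderate inhibitors (abiraterone,
cinacalcet, mirabegron, duloxetine, lorcaserin, rolapitant) roughly halve
it. A genotypic normal metabolizer taking fluoxetine is therefore a
*phenotypic* poor metabolizer — a phenomenon called phenoconversion — and
may get little analgesic benefit from a codeine prescription.

`phenoconv` implements the full observational pipeline for studying this
question in EHR + genomic data: consensus genotype calling, activity-score
phenotyping with phenoconversion, prescription-era construction, cohort
assembly with a pain-related emergency-department (ED) visit outcome, and
inverse-probability-of-treatment-weighted (IPTW) logistic regression.
Because the motivating patient-level data are access-restricted, the
package ships a calibrated synthetic generator with counterfactual ground
truth, so every estimator can be validated end to end.

## Phenotype model

Each star allele has an activity value: 1 for fully functional alleles
(\*1, \*2, \*35), 0.5 for \*9/\*17/\*29/\*41, 0.25 for \*10, and 0 for
the nonfunctional alleles (\*3 through \*8, \*11, \*15). A duplication
suffix ("xN") multiplies the base value by N, following the CPIC
activity-score convention (the source table is silent on duplications; we
adopt the CPIC rule). The diplotype activity score is the sum over the
two alleles, and the phenotype follows the printed cut-points:

| phenotype | activity score |
|---|---|
| ultrarapid (UM) | > 2.25 |
| normal (NM) | 1.25 – 2.25 (both boundaries NM) |
| intermediate (IM) | strictly between 0 and 1.25 |
| poor (PM) | exactly 0 |

Phenoconversion multiplies the genotype score by an inhibitor factor — 1
(none), 0.5 (moderate), 0 (strong) — and re-derives the phenotype from
the adjusted score. All three tables (allele values, cut-points, factors)
are configuration, so CPIC updates need no code change
(`pgx_config("my.yaml")`).

### Consensus calling

Genotypes arrive as per-caller reports from up to four tools. The
consensus is the canonical diplotype (alleles sorted by numeric id, so
"\*4/\*1" equals "\*1/\*4") that is reported by at least 2 tools *and* is
a strict majority of the tools that produced a call; otherwise the person
is Indeterminate and excluded downstream. The source rule names both
conditions but not how a 2–2 split resolves; we read "majority" strictly,
so a 2–2 split is Indeterminate. Whether the majority denominator is
tools-that-called (default) or all tools run is a config switch
(`consensus$majority`). Alleles absent from the activity table also yield
an Indeterminate person rather than an error at table level, mirroring
the exclusion of unresolvable genotypes.

## Exposure eras

Prescription instructions are typically missing in dispensing feeds, so
days' supply is imputed as `ceiling(quantity / 4)` — four tablets a day,
the most common direction for these drugs — and intervals include both
endpoints. The same rule is applied to inhibitor prescriptions, for want
of drug-specific information (flagged here because it is an assumption,
not a data fact). Refills of the same drug are stitched into exposure
eras: opioids merge across gaps of *fewer than 14* uncovered days,
inhibitors only across gaps of *at most 3* days; the gap is counted
exclusively (`next start − previous end − 1`). The 3-day rule is stated
for antidepressant inhibitors in the source; we apply it to all CYP2D6
inhibitors (most are antidepressants), configurable per class.

One wrinkle: an era's end is defined as "the end of the last
prescription", but a small refill can be nested inside a longer earlier
fill, in which case the literal reading would shrink the era and break
monotonicity of coverage. We therefore take the **latest imputed end**
over the era's constituents — identical to the literal rule in every
non-nested case, and the unique choice under which stitching equals
interval union with gap closure (the oracle our property tests check
against) and is idempotent.

Concomitancy requires at least 3 consecutive days of overlap between an
inhibitor era and the assessment window, which we take to be the opioid
*follow-up* window (index date through follow-up end), since the
phenoconverted phenotype is meant to describe metabolism while outcomes
are ascertained. When both a strong and a moderate inhibitor qualify, the
strong one applies (the minimum factor). A person is "inhibitor-free"
only if no inhibitor era touches the interval from 180 days before the
opioid start (inclusive — the boundary day counts as exposure, a
convention the source does not pin down) through the end of the study
period.

## Cohort and outcome

The index date is 3 days after the start of the person's first stitched
opioid era; follow-up runs to the earlier of index + 60 days and the era
end. Inclusion requires age ≥ 18 at index, an era of at least 7 days'
imputed supply, and a determinate consensus genotype; a cancer-coded
encounter within 180 days before index excludes (we operationalize
"6 months" as 180 days throughout). The outcome is the first ED
encounter carrying a pain-related diagnosis code inside the closed
follow-up window. The 24 baseline covariates — age, sex, race/ethnicity,
seven pain-diagnosis flags, seven comorbidity flags, five
medication-history flags, opioid dose (MME/day, carried as a number) and
the prior-ED-visit count — are assessed over the 180 days before index.
The shipped diagnosis/medication code lists are deliberately small,
illustrative stand-ins (the real lists are site-specific); they are
configuration, not logic.

Three analyses are labelled on the cohort: **A** (primary) contrasts
phenotypic IM/PM against phenotypic NM/UM over everyone; **B** contrasts
inhibitor exposure against inhibitor-free within genotypic NMs (so
genotype cannot confound); **C** contrasts genotypic IM/PM against NM/UM
within inhibitor-free persons (so inhibitors cannot confound). B is
implemented as a partition of the genotypic NMs by inhibitor-free status:
a person whose inhibitor era overlaps follow-up by fewer than 3 days is
not phenoconverted in A, sits in B's exposed arm (they had an inhibitor
prescription), and is excluded from C. Drug subgroups split
hydrocodone/tramadol/codeine from oxycodone.

## The IPTW estimator

`iptw_fit()` fits the propensity of exposure by logistic regression
(IRLS, convergence when the coefficient change drops below 1e-8, at most
100 iterations; singular designs error naming the collinear columns,
suspected separation warns). Weights are `1/p` for the exposed and
`1/(1−p)` for the comparison arm — the ATE weights, targeting the
population-averaged (marginal) odds ratio. No stabilization or truncation
is applied by default (both available), matching the source's silence.
Balance is assessed by the standardized mean difference,
`|m1 − m0| / sqrt((v1 + v0)/2)`, with p(1−p) variance for binaries and
fully weighted moments after weighting; SMD < 0.1 is called balanced.

The weighted outcome model is a weighted logistic regression of the
outcome on the exposure alone; its confidence interval uses the HC0
sandwich variance, the standard choice when the source does not name its
CI method — weights are estimated, and the sandwich interval is known to
be conservative-to-nominal for ATE weighting. A seeded nonparametric
bootstrap (`ci = "bootstrap"`) is provided for sensitivity; the two can
differ in the second decimal. The unweighted OR with its Wald interval
is always reported alongside.

## The synthetic generator

`simulate_pain_ed()` draws the latent person-level truth first and then
emits raw tables that realize it exactly, so the pipeline's output can be
compared field-by-field against the generating state:

* **Genotypes** under Hardy–Weinberg from a configurable allele pool.
  The default frequencies are realistic for a mixed US cohort (e.g. \*4
  at 15%, \*41 at 8%, duplications at 1%) and were chosen once so that
  genotypic IM+PM ≈ 43% of persons and the primary contrast splits
  roughly 50/50 — the structure of the motivating cohort. Four
  pseudo-callers report the truth, a perturbed diplotype (3% default) or
  a no-call (5% default), independently.
* **Prescriptions**: one opioid per person (45/25/22/8% across
  hydrocodone/tramadol/oxycodone/codeine), 1–3 fills with refill gaps
  straddling the 14-day stitching boundary; 15% of persons receive an
  inhibitor course (60% strong), of which 90% overlap the follow-up
  window by ≥ 3 days and the rest by 1–2 days; 2% of persons get a
  sub-7-day supply and 2% a baseline cancer code, to exercise attrition.
* **Covariates**: the five confounders (depression, anxiety,
  benzodiazepine use, back pain, age) are drawn with arm-specific
  distributions — the headline shifts are the published per-arm
  prevalences (e.g. depression 13.0% vs 20.9%) — while the remaining 19
  covariates are exposure-independent noise, so balance diagnostics
  should flag only true confounders.
* **Outcomes** follow a logistic model whose intercept is root-found so
  the comparison-arm event rate is 1.8%, and whose exposure coefficient
  is root-found so the **true marginal OR** — computed by counterfactual
  standardization over the simulated population — equals the configured
  target (1.19 for the primary phenotype effect; the
  `"inhibitor_effect"` preset carries 1.49 on inhibitor exposure
  instead). Ground truth stores both counterfactual probabilities per
  person, so the estimand is known exactly, not approximately.

The covariate outcome effects (log-odds 0.35/0.30/0.20/0.30 for
depression/anxiety/benzodiazepine/back pain and −0.40 per decade of age)
were fixed once: the published arm rates and weighted-vs-crude estimates
imply near-zero *net* confounding, and a negative age effect (younger
adults use the ED more) offsetting the positive psychiatric-comorbidity
effects reproduces that — the headline crude OR sits near 1.19 and the
exposed-arm rate near 2.1%. Because near-zero net confounding cannot
demonstrate bias correction, the `"confounded"` preset keeps the same
structure but uses strong one-directional shifts and effects (crude OR
≈ 2.4 against a truth of 1.19); the parameter-recovery test runs on that
preset.

**What the generator does not emulate**: real diagnosis vocabularies,
care fragmentation and missingness, dose tapering, multiple concurrent
opioids, time-varying inhibitor exposure within follow-up, and — by
construction of the arm-conditional covariate draw — the independence of
genotype from behavior: on generated data even analysis C is mildly
confounded, unlike the real contrast it mimics. Passing tests therefore
validate the estimators and the plumbing, not the clinical conclusions.

## Numerical choices and test scales

Dates are handled as integer day offsets from an arbitrary epoch
(2014-01-01), avoiding timezone and leap-second complications. Activity
scores are multiples of 0.25, so phenotype boundaries are compared
exactly. Root-finding uses `uniroot` at tolerance 1e-12; an unattainable
target OR raises a calibration error. Same-day opioid ties are broken
alphabetically and recorded.

The shipped validation uses problem sizes chosen to give each check real
statistical teeth while keeping the suite quick: parameter recovery on
the full pipeline at n = 30 000; CI coverage over 600 replicates of
n = 5 000 (93–97% band); headline calibration checked at n = 60 000
against the published 2.1%/1.8% arm rates within 3 binomial standard
errors; and the stitching oracle over 1 000 random prescription sets.
The acceptance script regenerates the headline quantities at
n = 100 000–200 000.

## Known limitations

* The consensus rule's 2–2 handling and the washout boundary are
  documented interpretations of under-specified rules; both are config
  switches.
* SMDs for the race/ethnicity factor are computed on its dummy columns.
* The weighted-OR sandwich CI ignores the estimation of the propensity
  scores; for ATE weights this is conservative, and the coverage test
  confirms 93–97% empirical coverage at the study's event rates.
* `analyze_cohort()` refits the propensity model within each subgroup,
  which is the usual practice but means subgroup ORs are not nested
  within the overall fit.
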