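---
title: "Methods: claims-based safety analysis of rhubarb-containing Kampo laxatives in pregnancy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: claims-based safety analysis of rhubarb-containing Kampo laxatives in pregnancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the design

Constipation affects a large share of pregnancies, and in Japan two oral
laxative options dominate: magnesium oxide (MgO, an osmotic laxative,
WHO-ATC A02AA02) and traditional Kampo formulations, several of which
contain rhubarb rhizome (KRR). Rhubarb rhizome carries sennoside A, and
product labelling discourages its use in pregnancy, but individual-level
evidence on malformation risk is thin. `kampopreg` implements an
active-comparator cohort analysis over administrative health-insurance
claims: mothers prescribed KRR in the first trimester (Group 2) are compared
with mothers prescribed MgO in the first trimester (Group 1) on the odds of
a major congenital malformation (MCM) diagnosed in the infant's first year.
Comparing two treated groups rather than treated versus untreated limits
confounding by indication, since both groups were treated for the same
condition. Mothers prescribed senna glycosides (SG, WHO-ATC A06AB06) in the
first trimester are excluded from the comparison outright because senna
shares sennoside A with rhubarb and would contaminate both arms.

The estimand is reported two ways: a crude odds ratio from the 2×2 table
with a Woolf 95% interval,

$$\widehat{OR} = \frac{ad}{bc}, \qquad
\exp\!\Big(\ln \widehat{OR} \pm 1.96\sqrt{\tfrac1a+\tfrac1b+\tfrac1c+\tfrac1d}\Big),$$

and an adjusted odds ratio from a maximum-likelihood logistic regression of
MCM on the exposure indicator plus maternal age band, delivery-year band,
preterm birth, epilepsy, diabetes, obesity and first-trimester teratogen
prescription, with a Wald interval on the exposure coefficient. In a
saturated exposure-only model the two routes coincide, which the test suite
checks to 10^-6^.

## Dating pregnancies from claims

Administrative claims record neither conception nor delivery dates, so both
are estimated:

* **Onset.** Japanese antenatal claims annotate some diagnoses with a
  gestational age (GA) in weeks (and sometimes days). Onset is the
  annotated diagnosis date minus `7 * weeks + days`, taking the **most
  recently dated** annotation, which is staged most accurately. A
  weeks-only annotation counts the days component as zero. If two
  annotations on the same latest date disagree, we take the smaller GA —
  the later implied onset — which is conservative for first-trimester
  exposure classification; the conflict is logged. This tie-break is a
  package decision; the underlying algorithm is silent on ties.
* **Delivery.** A tiered rule: the latest *specific delivery procedure*
  entry if one exists; otherwise the latest other delivery-related entry;
  otherwise the 15th of the infant's birth month (claims expose births at
  month granularity only). Entries dated outside the birth month ±1 month
  are implausible and ignored with a warning.
* **Cap.** If the implied gestation exceeds 294 days — the threshold at
  which labor induction is recommended — onset is moved to delivery − 294
  days and the episode flagged. The cap is applied *before* trimester
  construction, so trimester windows always sit inside the capped episode.

Trimesters are closed calendar-day windows over gestational days 0–97
(onset to week 13 day 6), 98–195 (week 14 day 0 to week 27 day 6) and
196–delivery, each clipped at delivery. A pregnancy shorter than 196 days
simply has no third trimester. Property tests label every day of 1,000
random episodes and verify the windows partition the episode exactly, with
boundaries at days 97/98 and 195/196.

## Cohort and covariates

Eligibility is applied as an ordered cascade, and every dropped mother gets
exactly one exclusion reason (the first stage she fails), so the attrition
report's stage counts are monotone and the reasons sum to the total dropped:

1. a linked infant enrolled with the insurer **from its birth month** (the
   linkage signal that the enrollee is this mother's newborn);
2. a datable pregnancy (at least one GA annotation);
3. continuous maternal enrollment from 3 months before onset through
   delivery, checked at month granularity because the database exposes only
   year-months;
4. delivery between 2010 and 2019;
5. infant enrollment for at least 12 months from the birth month;
6. singleton delivery (multiple births carry their own malformation risk);
7. no chromosomal abnormality (ICD-10 Q90–Q99) in the infant — these are
   not exposure-related and would dilute any exposure signal.

Condition covariates (hypertension, diabetes, obesity, epilepsy,
phenylketonuria, caesarean) are flagged from any matching ICD-10 diagnosis
between 3 months before onset and delivery. The window and the prefix lists
are configurable (`covariate_codelists()`): the validated lists used on the
original database are not public, so chapter-level defaults ship in their
place (I10–I15; E10–E14 + O24; E66; G40; E70.0; O82). Maternal age uses
completed years at delivery (mid-month convention for the birth month) and
is banded ≤24 / 25–29 / 30–34 / ≥35; delivery year is banded 2010–2012 /
2013–2015 / 2016–2019. Preterm birth is gestation under 259 days (37
weeks, the WHO convention — the analysis lists it as a covariate without
defining a threshold). Each retained mother contributes exactly one
analysis row; the generator produces one pregnancy per mother, so no
first-episode selection among multiple pregnancies is ever exercised.

## Exposure

Prescriptions are classified by a configurable dictionary: MgO and SG by
ATC code, the 17 rhubarb-containing Kampo products and daikenchuto by
product name, since Kampo formulations carry no WHO-ATC laxative codes.
Each prescription's exposure start date follows a fallback chain —
dispensing date, else admission date, else the 15th of the claim month —
and extends for its days of supply (end = start + supply − 1). A class is
exposed in a trimester iff any of its intervals **overlaps** the trimester
window; overlap, not dispensing-date membership, is the faithful reading of
an exposure *period* derived from days of supply, but a
`rule = "dispense_date"` switch is provided for sensitivity. As-needed
(PRN) prescriptions get the same interval; the fourth sensitivity analysis
removes mothers whose index-class first-trimester fills were all PRN.

Group assignment from the first-trimester flags: SG exposure excludes;
otherwise KRR puts the mother in Group 2 even with concomitant MgO;
otherwise MgO alone gives Group 1; otherwise unexposed. An exhaustive
8-combination test pins this truth table.

## Outcomes

An infant is MCM-positive iff at least one diagnosis matches an included
organ-system code (ten systems across Q00–Q89), does not match the
minor-malformation exclusion list, and falls within the first-year window:
the birth month through the eleventh month after it, at month granularity
because exact birth dates are unavailable. The shipped code list is a
EUROCAT-style prefix set and is explicitly editable
(`read_mcm_codelist()`); the test suite deliberately exercises outcome
logic with the generator's own codes, so correctness never rests on the
default list's clinical fidelity. The source description conflates "minor
malformations" with the full Q00–Q89 range in one sentence; we implement
the only consistent reading — major subset of Q00–Q89 included, minor
subset excluded, Q90–Q99 handled as a cohort exclusion.

## Statistics

* `crude_or()` — Woolf method above; zero cells error by default, with an
  optional 0.5 continuity correction (the primary analysis has no zero
  cells).
* `fit_logistic()` — `stats::glm` (binomial, tight convergence tolerance),
  factor bands with youngest/earliest reference, degenerate columns dropped
  with a warning, explicit separation error when the exposure estimate is
  unbounded.
* `cochran_armitage()` — trend in prescription prevalence across trimesters
  scored 1, 2, 3: $z = T/\sqrt{\operatorname{Var} T}$ with
  $T = \sum_i s_i (x_i - n_i \bar p)$; $z^2$ equals the 1-df trend
  chi-square, verified against `stats::prop.trend.test` to 10^-10^. A
  mother prescribed in several trimesters contributes to each trimester's
  numerator (the prevalence rows are not mutually exclusive categories).
  The third-trimester denominator is restricted to pregnancies reaching
  gestational day 196 — the only reading we found that reproduces a
  published denominator smaller than the cohort, exposed as a rule rather
  than asserted as intent. For small tables the tests compare the
  asymptotic p to an exact conditional enumeration oracle; the mid-p exact
  value agrees to ~0.003 on moderate tables, while the plain exact p is
  conservative on very sparse ones — a discreteness effect, not an
  implementation artifact.
* `compare_groups()` — Pearson chi-square without continuity correction for
  categorical covariates (this reproduces the published preterm-birth p of
  0.0077 exactly, fixing the variant), two-sample t-test for continuous
  ones, with a flag when any expected cell is below 1. Two-sided tests,
  α = 0.05, no multiplicity correction anywhere — matching the original
  analysis.
* `run_sensitivity()` — the four published variants: (1) drop
  teratogen-exposed mothers; (2) keep mothers with **more than 30**
  first-trimester supply days of the index class, measured as summed
  calendar-day overlap of index-class intervals with the first-trimester
  window (consistent with the interval-based exposure definition); (3)
  drop dual MgO+KRR-exposed mothers; (4) drop PRN-only mothers.

## What the synthetic generator emulates — and what it does not

`generate_bundle()` is truth-first: true onset/delivery dates, exposure
intervals and outcomes are laid down consistently, and only then is
missingness injected, so the truth table stays exact. Its defaults encode
the published study conditions:

| parameter | default | basis |
|---|---|---|
| gestation length | truncated normal, mean 270.7 d, SD 12.9, range 119–294 | published cohort moments |
| delivery-entry shares | 49.4% specific / 9.4% other / 41.2% none | published dating-method shares |
| per-trimester prescription propensity | MgO 13.90/21.28/22.45%, SG 2.11/2.86/4.86%, KRR 0.63/0.61/0.60%, daikenchuto 0.18/0.20/0.26% | published prevalence table |
| KRR product mix | weights from the published per-product counts | published prevalence table |
| MCM base rate | 6.1% | published whole-population prevalence |
| covariate prevalences | hypertension 1.7%, diabetes 4.5%, obesity 0.7%, epilepsy 0.9%, phenylketonuria 0, teratogen 0.4%, caesarean 22.7% | published comparator-group column |
| maternal age | normal(32.3, 4.6), clamped 16–49 | published cohort moments |
| delivery-year mix | band weights 11.3% / 35.8% / 53.0% spread within bands | published group composition |

Where the source is silent, values were chosen once as field-plausible and
are not tuned: antenatal GA-annotated visits at weeks 8, 12, 20, 30 and 38
(only visits before delivery occur); 10% of laxative dispensing dates
missing, half of those retaining an admission date; 20% of fills PRN; fills
per prescribed class-trimester 1 + Poisson(1), because refills are routine
for chronic laxative use and a single-fill world could never exceed 30
first-trimester supply days; supply per fill 7/14/30 days (35/45/20%);
enrollment churn 5%; twins 2%; chromosomal diagnoses 0.3%. Covariate
effects on MCM are null except modest preterm-birth and obesity effects of
log(1.5) — only *recovery* of the exposure effect is tested, never these
values. The exposure effect itself (`true_log_or_krr`) acts on the **true**
first-trimester KRR flag through a logistic model on top of the base rate.

Deliberate non-features, hence what passing tests do *not* show: trimester
prescription events are independent within mother (real prescribing is
strongly autocorrelated, so the generator's *overall* prevalence exceeds
the published 34.6% for MgO even though every per-trimester marginal is
calibrated); there is one pregnancy per mother, no stillbirths or
abortions (unobservable in the source data), no seasonality, no
product-level dosing, and no coding idiosyncrasies of any particular
insurer. Calibration tests therefore pin the per-trimester marginals and
the delivery-entry shares (within 3 binomial standard errors at n =
10,000), not joint behavior.

## Numerical and validation choices

Dates are `Date`s; year-months are `"YYYY-MM"` strings with integer month
indices internally, so month arithmetic is exact. CSV round-trips are
byte-stable (ISO dates, empty string for missing), which makes the full
pipeline reproducible byte-for-byte under a fixed seed — asserted by
running it twice. Validation problem sizes were chosen to keep the full
suite comfortably under half an hour on a single core while leaving the
Monte-Carlo tolerances meaningful: null-effect coverage of the adjusted 95%
interval uses 200 replicate cohorts of 10,000 mothers (the ~2% of
replicates with zero events in the small exposed arm have effectively
unbounded Wald intervals and are excluded from the coverage denominator);
effect recovery uses 100 replicate cohorts of 20,000 mothers with a true
log odds ratio of log 2 and checks the mean estimate to within 0.05.

## Known limitations

The default ICD-10 code lists are plausible but unvalidated stand-ins; real
analyses must supply their own. Exposure is prescription-based: dispensing
does not imply ingestion, and over-the-counter purchases are invisible —
both attenuate true effects in real data and are not modelled. The
generator's independence assumptions make it a correctness instrument, not
a realism benchmark: it demonstrates that the pipeline recovers known
truth under the study's published marginals, not that any particular real
database would behave identically.
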