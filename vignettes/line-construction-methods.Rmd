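---
title: "Lines of therapy, resource use, and costs from CML claims: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lines of therapy, resource use, and costs from CML claims: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmllines)
library(data.table)
```

## The problem

Patients with chronic myeloid leukemia in chronic phase (CML-CP) are treated
with tyrosine kinase inhibitors (TKIs): first-generation (1G) imatinib,
second-generation (2G) dasatinib, nilotinib and bosutinib, third-generation
(3G) ponatinib, and the protein-synthesis inhibitor omacetaxine. A
substantial minority cycle through several of these drugs. Administrative
claims — pharmacy fills with days supply, medical claims with diagnosis and
procedure codes, enrollment spans — are the only large-scale record of how
these patients are actually treated, but claims carry no explicit "line of
therapy" field. This package reconstructs lines of therapy from raw claims,
selects an analyzable third-line-or-later (3L+) cohort, and computes
descriptive treatment-pattern, healthcare-resource-utilization (HRU), and
per-patient-per-month (PPPM) cost outcomes.

Everything is validated against a bundled synthetic-claims generator that
knows the true trajectory of every simulated patient, so the whole pipeline
is testable without access to proprietary claims databases.

## Data model and day conventions

Claims tables are plain delimited files with ISO-8601 dates. All intervals
in the data model are closed; a hospital stay from `start_date` to
`end_date` covers `end - start + 1` days, while durations *between* events
(line durations, person-time) are `end - start` days. Analysis windows are
treated as half-open `[start, end)` when counting days inside them, so
adjacent periods never double-count a day.

Month-denominated design quantities use fixed conversions: 6 months =
183 days, 3 months = 91 days, 1 month = 30 days, 1 year = 365 days. The
PPPM month is 365.25/12 = 30.4375 days and person-years use 365.25 days.
These constants live in `study_config()` and exist so that every result is
reproducible from the configuration alone.

Diagnosis/procedure code lists are prefix stems ("205.1" matches "205.11"),
mirroring how ICD family codes are written in study appendices. All code
lists — CML diagnosis (ICD-9 205.1x / ICD-10 C92.1x; registry histology
9863/9875 for the Medicare-style population), remission (205.11/C92.11),
relapse (205.12/C92.12), clinical trial (V70.7/Z00.6), HSCT procedures,
non-CML-CP chemotherapy, comorbidity and severity maps — are configuration,
not code.

## Line construction

`build_lines()` is the analytical core. Therapy events are CML-CP drug
fills (conditioned on each drug's FDA approval date: imatinib 2001-05-10,
dasatinib 2006-06-28, nilotinib 2007-10-29, bosutinib 2012-09-04,
omacetaxine 2012-10-26, ponatinib 2012-12-14), omacetaxine procedure
claims, HSCT procedures, and non-listed chemotherapy administrations
signalling progression to accelerated phase / blast crisis (AP/BC).
Hydroxyurea is pretreatment only and never defines a line.

A line starts at the first fill for a drug and ends at the earliest of:

* **switch** — the first fill of a different CML-CP drug; the next line
  starts the same day;
* **AP/BC chemotherapy** or **HSCT** — these also terminate sequencing;
* **discontinuation** — no further therapy fill and at least 90 consecutive
  days off supply before the observation end; the line ends at the supply
  end of its last fill;
* **censoring** at the end of observation.

A gap of ≥ 90 days followed by resumption of the *same* drug is a treatment
interruption: it increments `interruption_count` but does not end the line.
Gaps are measured from the running supply end (`fill_date + days_supply`),
not the fill date, because the relevant clinical quantity is time without
drug on hand.

Deterministic tie-breaks, chosen once and documented rather than left to
row order: on a shared date HSCT outranks AP/BC chemotherapy outranks a
fill; when two different drugs are first filled on the same day, the larger
days supply defines the line and ties break alphabetically. A
different-drug fill ends the previous line as a *switch* even when the
intervening gap exceeds 90 days — treatment-free periods between lines can
be long, and the published convention treats the next fill as the next
line's start rather than retroactively calling the previous line
discontinued.

One consequence of these rules worth stating plainly: a
discontinuation-ended line is necessarily the patient's last line, because
a later fill of a different drug would have been a switch and a later fill
of the same drug an interruption. The end-event taxonomy is therefore
`switch` (iff a next line exists), `discontinuation`/`censored`/`hsct`/
`apbc_chemo` (all line-final).

Duration buckets in the per-line summary reproduce the publication
convention: `≤3`, `>3 to ≤6`, `>6` months partition the cohort, while
`>6` and `>12` are cumulative (the `>12` group is a subset of `>6`). A
duration of exactly 3.0 months sits in `≤3`. Censored lines contribute
their censored duration to the plain means/medians — no survival
adjustment is attempted, which matters for interpreting last-line
durations (see *Generator* below).

## Cohort selection

`apply_selection()` applies a fixed ten-step cascade: (1) ≥ 1 CML diagnosis
(payer-appropriate code list) in the data window; (2) adult at 1L; (3) 1L
drug is one of the four TKIs used first-line, on/after approval; (4) 1L
initiation within −30/+91 days (commercial) or −30/+365 days (Medicare) of
first diagnosis; (5) a 183-day washout before 1L with continuous enrollment
and no CML-CP therapy (hydroxyurea allowed); (6) continuous enrollment from
washout start through 365 days post-diagnosis — waived for Medicare
patients who die inside that window; (7) no HMO (Part C) coverage in that
interval (Medicare); (8) no remission/relapse code on/before 1L start;
(9) no clinical-trial claim on/before the index date; (10) reached 3L. The
index date is the 3L start; baseline is the 183 days before it; follow-up
runs from index to the earliest of data end, enrollment end, HSCT, or
AP/BC chemotherapy.

Two genuinely open design points are resolved as follows. Diagnosis codes
qualify in any claim position, since claim-position conventions differ
across extracts and the stricter reading cannot be verified from a code
list alone. The remission/relapse exclusion is anchored at 1L start and the
clinical-trial exclusion at the index date — the conservative reading of a
cascade whose code lists, but not windows, are fixed; both windows are
configurable.

## Outcomes

HRU and costs are computed over three periods per patient: 3L+ (the whole
follow-up), 3L, and 4L (each clipped to follow-up). Annual incidence rates
are cohort aggregates — total events over total person-days, times 365.25 —
rather than means of per-patient rates; with heavily skewed person-time the
two differ, and the aggregate is the standard incidence-rate estimator.
Inpatient admissions are merged across overlapping claims before counting;
outpatient days and ED visits are distinct calendar dates with at least one
claim. A claim is CML-related if it bears a CML diagnosis code or an
omacetaxine procedure code; an admission is CML-related if any of its
claims is, which keeps CML-related admission counts a subset of all-cause
counts even when CML and non-CML claims chain into one merged stay.

Costs are payer-paid amounts, inflated to 2019 dollars with the medical-care
CPI (annual factors, no monthly interpolation; the bundled table is
replaceable). Inpatient paid amounts are pro-rated by the fraction of stay
days inside the period — configurable to whole-stay-at-admission-start —
so 3L and 4L never double-count a stay spanning their boundary; pharmacy
fills attach wholly to the fill date. PPPM divides each patient's period
total by their person-months before summarising. CML-related pharmacy costs
are restricted to the five TKIs, so omacetaxine fills count as all-cause
only. HSCT event costs sum all inpatient claims of the admission containing
the procedure date (flagged fallback: the procedure claim alone), and the
sensitivity analysis removes exactly those claims and recomputes everything.

## Baseline characteristics

The modified Charlson comorbidity index uses the original 17-condition
weights with CML removed from the malignancy code list and map-declared
hierarchy rules (complicated diabetes supersedes uncomplicated, metastatic
disease supersedes other malignancy, severe liver disease supersedes mild).
The weight revision is configurable; the original weights are the default
because no more specific choice is derivable from the study design. The
CML-severity classifier is a max-over-tiers rule (mild unless a moderate or
severe code appears); its bundled tier lists are illustrative placeholders,
user-configurable, and *not* the published disease-complexity code lists.
HSCT-unfitness is age ≥ 75 at index or baseline congestive heart failure,
cirrhosis, or end-stage renal disease.

## The synthetic generator

`generate_cohort()` draws, per patient: diagnosis year (2008–2014 by
default), demographics, an enrollment span beginning ≥ 183 days before
diagnosis and extending 24–96 months after it (observation from diagnosis
then averages ≈ 58 months, matching the observation durations typical of
this study design); a line count (defaults follow the observed attrition:
70.5% one line, 20.3% two, 6.6% three, and so on); drugs from a first-line
distribution (imatinib 64.9%, dasatinib 21.6%, nilotinib 13.5%) and a
switch transition matrix restricted to drugs approved at the switch date;
and per-line durations from lognormals whose medians (8.47 / 4.24 / 8.32 /
8.39 months) and dispersions are calibrated to the commercial 3L+
treatment-pattern table this pipeline is designed to produce. Fills are
laid at a 30-day cadence with 30-day supplies; interruption gaps (90 days
plus an exponential tail) and sub-threshold refill jitter are carved into a
line with configurable probabilities so the 90-day boundary is exercised
from both sides. Last lines end by HSCT (probability 0.085 after 3L),
AP/BC progression (0.08), discontinuation, or censoring, with infeasible
draws (an event beyond the observation end) degrading to censoring by the
same definitions the analysis uses. HSCT emits a procedure claim inside a
synthetic admission whose three claims average ≈ \$222k in 2019 dollars.

Utilization is drawn per patient over the enrollment window: outpatient
service days and ED visits as Poisson numbers of *distinct days* (so the
distinct-date counting rule recovers the set rate without collision bias),
inpatient admissions as a Poisson process with 1 + Poisson(7.5) lengths of
stay, kept mutually non-overlapping. Default annual rates — 0.4 admissions,
8.5-day mean stay, 30.8 outpatient days, 1.2 ED visits, with CML-related
shares per setting — and gamma cost levels per component are the
commercial-population calibration. Paid amounts are drawn on the 2019
scale and deflated to service-year dollars through the same CPI table the
analysis inflates with, so cost recovery is exact in expectation.

What the generator does **not** emulate: real claim layouts or code
dictionaries, actuarially realistic cost levels, dose/titration structure,
combination therapy, or mortality dynamics beyond an optional
death-at-enrollment-end flag for the Medicare waiver. Passing tests
demonstrate that the pipeline implements its stated rules exactly and
recovers known parameters — not that it would reproduce any particular
real-world estimate.

Two properties of the *study design* (not defects of the code) show up in
synthetic results exactly as they do in published ones and are worth
keeping in mind:

* **Censored last lines inflate duration summaries.** A patient still on
  3L at the end of data contributes `observation end − 3L start`, which can
  be far larger than the underlying treatment episode.
* **Cohort conditioning truncates early-line durations.** Requiring 3L
  within the data window selects against very long 1L/2L durations.

Because of these, the parameter-recovery experiment used in the tests and
the acceptance script generates 2,000 patients who all reach ≥ 4 lines
(making 1L–3L fully observed interior lines), uses 2008–2010 diagnosis
years with 84–144-month enrollment so truncation is negligible, and turns
gap insertion off so durations carry only the calibrated lognormals. Under
those conditions the pipeline recovers all three medians within 10%
(typically within 5%). The line-builder equivalence test instead uses a
mixed 1,000-patient scenario with interruptions, jitter, HSCT, AP/BC,
discontinuation and censoring all active, and requires exact agreement
with ground truth on every field of every line. Rate recovery uses the
recovery cohort's ≥ 1,500 person-years of 3L+ follow-up and
cluster-robust (ratio-estimator) standard errors, since inpatient days
arrive in stays, not independent days.

## Suppression and reporting

`format_percent()` rounds half-up to one decimal — the convention that
reproduces every checkable published percentage from its printed counts
(e.g. 192/296 → 64.9, 154/296 → 52.0). `apply_suppression()` masks counts
in [1, threshold−1] (threshold 11 by default, the CMS small-cell rule;
zero is displayable), and applies complementary suppression within groups
whose totals are displayed: a single masked cell would be recoverable by
subtraction, so the smallest remaining cell is masked too. Suppression is
off by default and enabled for Medicare-style outputs.

## Problem sizes and numerical notes

The test suite builds all fixtures in code: engineered single-patient
bundles for rule probes, 60–150-patient cohorts for module checks, and the
1,000/2,000-patient scenarios above for the end-to-end suites; the full
suite runs in a few minutes on one core. Degenerate inputs are defined, not
special-cased: empty event streams yield empty line tables, zero-length
follow-up windows are allowed, zero person-days make a rate `NA` (absent,
not zero) and exclude a patient from PPPM denominators, and terminal events
before any therapy fill leave no line to end. All date arithmetic is whole
days; no timezones appear anywhere.

## Known limitations

Combination therapy is out of scope (lines are monotherapy by
construction); there are no adherence metrics; the severity classifier's
published code lists are not replicated; registry linkage for the
Medicare-style population is represented abstractly by a histology code
list; and statistical output is descriptive only, mirroring the analysis
this package implements.
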