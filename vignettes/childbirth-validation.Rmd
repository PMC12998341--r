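---
title: "Validating claims-based childbirth identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating claims-based childbirth identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(claimsbirth)
```

## The estimation problem

A claims database records, per insured woman and per month, the
diagnosis, procedure and medication codes billed for reimbursement. A
*phenotyping algorithm* for childbirth is a Boolean rule over code sets
that classifies each woman as having given birth (and dates the event)
from claims alone. Two features of Japanese claims make this hard:

1. **Silent deliveries.** An uncomplicated normal vaginal delivery is
   typically not covered by medical insurance and generates no claim,
   so claims-based sensitivity has a structural ceiling well below 1.
2. **Code echoes.** Delivery-related diagnosis codes recur at
   prepartum check-ups and postpartum visits, and a *suspected flag*
   marks provisional/rule-out diagnoses; both blur the event date and
   create false positives among women who never gave birth.

Where insurer family-relationship registries are available, a
parent–child identifier — assigned only for live births — links each
child's month of birth to the insured mother. That linkage is the gold
standard here: a woman is gold-positive when at least one linked child
was born inside the observation window while she was aged 15–49
completed years, and her reference month is the most recent such birth.
The cohort is restricted to women whose husband can be identified:
otherwise a child may be linked only to the father and a genuine birth
would be unverifiable, which would wrongly count algorithm detections
as false positives.

## Conditions, algorithms and dating

Six condition symbols are evaluated per woman:

| symbol | meaning |
|---|---|
| `A` | delivery diagnosis code, suspected flag absent |
| `A_susp` | delivery diagnosis code, flagged or not (a superset of `A`) |
| `A_pre`, `A_pre_susp` | the same with the preterm-excluded diagnosis set |
| `B` | delivery procedure code (exact match) |
| `C` | delivery medication code (exact match) |

The diagnosis set is the 34 ICD-10 categories spanned by O14–15,
O32–34, O42, O45, O48, O60–69, O70–72, O74–75, O80–84, O86–87, O90,
O99 and Z37–38; matching is at three-character category level because
the published ranges are category ranges (full codes such as `O80.1`
normalise by dropping the dot and truncating). The preterm-excluded
variant removes O45, O60 and O69 (placental abruption, preterm labour,
cord complications), whose presence can misdate a preterm delivery.
Procedure and medication code values differ across national fee
schedules and are therefore configuration, not constants; the package
defaults are clearly-labelled synthetic placeholders used by the
generator.

Algorithms 1–18 are the AND/OR combinations of `[A+susp]`/`[A]`, `[B]`
and `[C]`; algorithms 19–32 repeat the fourteen diagnosis-referencing
ones with the preterm-excluded set (the four diagnosis-free rules have
nothing to substitute). Two interpretations deserve a note because the
source material leaves them open:

* **`[A+susp]` is the permissive reading** — flagged *and* unflagged
  diagnosis records qualify. Only this superset reading is consistent
  with `[A+susp]` algorithms detecting more true positives than their
  `[A]` counterparts, which the published counts show.
* **AND is woman-level by default** (`and_mode = "anytime"`): each
  condition must hold somewhere in the window, not in the same month.
  The dating rule — the event month is the *latest* month recorded for
  any referenced condition — already treats codes from different
  months as one event, so woman-level AND is the consistent reading. A
  stricter `"same-month"` co-occurrence mode is provided for
  sensitivity analysis.

## Matching and metrics

Delivery claims may be billed in the discharge month, one month after
the birth; they cannot precede it. Matching is therefore asymmetric:
an algorithm month `m` matches a gold month `g` when `g == m` or
`g == m − 1`. Classification is at woman level, and a gold-positive
woman who is detected but dated outside tolerance is a false negative
only — she is not additionally a false positive. This keeps the gold
marginals (TP+FN, TN+FP) identical across all algorithms on one
dataset, which is both how the published tables behave and a useful
invariant the test suite checks.

From the confusion table the package computes sensitivity,
specificity, PPV and NPV with binomial confidence intervals, Cohen's
kappa with the standard two-rater marginal-product expected agreement,
and the Youden index. The CI method is the Wald normal approximation
by default: at the cohort sizes this design targets (tens of thousands
of events) Wald and Wilson agree to well past the first decimal, and
Wald reproduces the published interval columns exactly at their
printed precision; Wilson is available via `ci_method = "wilson"` for
small-sample use. Presentation rounding is half-up (percentages to one
decimal, kappa/Youden to two); internal values are never rounded.
Metrics with zero denominators are returned as `NA` rather than
raising errors.

## Second births and the washout window

Because diagnosis echoes recur for months around one delivery, naively
re-running detection after a first birth misreads postpartum codes as
a new event. The washout scan re-runs each algorithm on claims
restricted to months `>= first + k` for k = 2..24 and tabulates
against the second-birth reference (the second-earliest qualifying
linked birth; `reference = "latest"` is available). Two anchoring
choices are deliberate:

* the **first-birth anchor is the gold birth month**, not an
  algorithm-detected first birth, isolating the washout question from
  first-birth detection error;
* the **second event is dated at the earliest qualifying month after
  the washout** — the next distinct event — because latest-month
  dating would alias onto third births.

The optimal k is the Youden argmax, ties broken toward the smaller k
(an earlier usable date). On any fixed dataset specificity is
non-decreasing in k (a longer washout can only remove detections among
single-birth women) — a structural property the acceptance tests
verify. Where the optimum lands is data-dependent: with postpartum
echoes of at most three months and inter-birth gaps of at least 18,
the argmax must fall strictly between the echo duration and the
minimum gap minus one, and the tests check exactly that band rather
than any particular k.

## The synthetic generator

No public claims extract with parent–child linkage exists, so the
package ships a generator (`synth_config()`,
`generate_synthetic_claims()`) that emulates the data-generating
features the validation depends on, with ground truth retained:

* births placed uniformly in the window, maternal age drawn from the
  seven five-year bands 15–49 with weights (1.0, 8.6, 24.1, 34.7,
  24.7, 6.6, 0.3)% — the age distribution reported for childbirth in
  this population — and a 4.4% per-woman birth rate matching the
  validation cohort;
* second births for 30% of mothers at a gap of round-normal mean 24,
  sd 6, truncated at 10 months (the national mean sibling age gap is
  about two years);
* **silent births**: 30% of deliveries emit no claims at all,
  reflecting uncovered normal deliveries — this is what caps Algorithm
  11-style sensitivity in the 60–70% band rather than near 100%;
* per-birth, independent domain emission (diagnosis 0.85, procedure
  0.60, medication 0.55), each record landing in the birth month or,
  with probability 0.3, the discharge month;
* diagnosis **echoes** at 0.15/month over the nine months before a
  non-silent birth and 0.05/month at +2 and +3; a 12% suspected-flag
  rate; 5.6% of birth diagnosis codes drawn from the preterm
  categories (the national preterm rate);
* rule-out **noise**: non-birthing women emit a delivery diagnosis at
  1e-4/month with a doubled suspected-flag rate; over a 106-month
  window this yields roughly 1% of never-birthing women carrying at
  least one delivery code, which holds specificity near 99%;
* a 95% husband-identification rate and a 0.2% chance a birth falls
  outside maternal age 15–49, so the eligibility filters are exercised.

Claims outside the extract window are not generated — an extract has
no claims beyond its submission range — so a birth in the final month
whose claims all shift to the discharge month is undetectable, a real
edge effect of order one part in the window length.

Domains are emitted independently, which admits a closed-form oracle:
`expected_sensitivity()` returns `(1 − p_silent) × P(expression)` with
`P(A_susp) = p_dx`, `P(A) = p_dx(1 − p_suspected)`,
`P(A_pre_susp) = p_dx(1 − p_preterm)`, `P(B) = p_proc`,
`P(C) = p_med`, products for AND and inclusion–exclusion for OR. The
oracle refuses configurations it cannot describe exactly — echoes on
(they land outside the 0/+1 tolerance), multiple births (claims from
different births can jointly satisfy an AND), or expressions mixing
two diagnosis conditions (they share one record and are not
independent) — rather than returning an approximation. Parameter
recovery is tested at 100,000 women: observed sensitivities must fall
within three Monte-Carlo standard errors of the oracle.

**What passing tests do and do not show.** The generator reproduces
the marginal structure of the problem (silent births, discharge
shifts, echoes, rule-out noise, age filtering), not real claims:
domain emissions are independent (no "caesarean implies oxytocin"
coupling), noise is uniform over the diagnosis set, there is no
insurance switching or censoring mid-window, and no stillbirths or
abortions are simulated (parent–child identifiers exist only for live
births, so they are absent from the gold standard by construction).
Agreement on synthetic data therefore validates the *pipeline
machinery* — detection, matching, tabulation, metrics — and the
qualitative behaviour of the algorithms, not their numeric operating
characteristics in any real database.

## Numerical and degenerate-input choices

* Month arithmetic is integer (`year × 12 + month − 1`); age is
  completed years by floor division, so the 15-and-49 boundaries are
  exact month-level checks.
* The observation window is half-open `[start, end)`; the default
  covers 2014-04 through 2023-01 inclusive.
* Empty claims tables, all-negative cohorts and zero-denominator
  metrics all return well-defined results (`NA` metrics, zero-count
  confusion cells), never errors; configuration errors (malformed
  ICD-10 ranges, probabilities outside [0,1], infeasible windows) fail
  fast with context.
* Problem sizes in the test suite — 100,000-woman cohorts for the
  marginal-constancy, recovery and washout checks, 1,000 random
  fixtures for oracle equivalence — were chosen to give Monte-Carlo
  standard errors far smaller than the tested tolerances while keeping
  a full run around a minute on one core.

## Known limitations

* Sensitivity of any claims-only rule is bounded by the silent-birth
  fraction; the package measures this, it cannot overcome it.
* The linkage gold standard itself can err (mis-assigned parent–child
  identifiers); the validation treats it as truth.
* Day-level dating, DPC inpatient episode structure, ICD-9/ICD-11 and
  the mapping from domestic claim disease codes to ICD-10 are out of
  scope (inputs are assumed already mapped).
* The washout optimum is a property of one dataset's echo and spacing
  structure; it should be re-estimated, not transplanted, when the
  claims source changes.
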