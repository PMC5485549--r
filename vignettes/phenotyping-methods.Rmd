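---
title: "Methods: rule-based ICD-9-CM phenotyping and its validation harness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based ICD-9-CM phenotyping and its validation harness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icd9phenotype)
```

## The classification model

A claims record is one hospital operation carrying an unordered set of
ICD-9-CM diagnosis codes and an ordered list of procedure codes whose
first element is the primary procedure. A phenotype rule set has four
pattern sets: inclusion diagnoses, inclusion procedures, exclusion
diagnoses, exclusion procedures. The label is

> positive ⇔ (some inclusion diagnosis pattern matches some diagnosis
> code) ∧ (some inclusion procedure pattern matches some procedure code)
> ∧ (no exclusion pattern of either axis matches any code of that axis).

Exclusion strictly overrides inclusion and is always evaluated on *all* of
a record's codes. This asymmetry is the point of the design: the
craniectomy phenotype was constructed by querying on stroke + operation
codes and then adding exclusions for every concept the query dragged in
that is not a supratentorial stroke decompression (tumors, trauma,
subarachnoid hemorrhage, the vertebrobasilar circulation, laminectomy as a
marker of suboccipital approach). A conservative veto mirrors that
construction. One deliberate non-exclusion: diagnosis 431 (intracerebral
hemorrhage) also encodes hemorrhagic conversion of an infarct, so
excluding on it would throw away true cases; it stays out of the rule set
and is instead assessed as a *secondary indicator*.

Assumptions worth stating: one record is one operation (no admission
windows, no patient linkage across visits); codes are exchangeable within
their axis except that the first procedure position is semantic; and the
gold standard is a per-record boolean from chart review.

### Code matching

Codes are normalized to the dotted canonical form (`43311` → `433.11`,
`0125` → `01.25`); diagnosis roots are 3 characters, procedure roots 2,
leading zeros preserved. V- and E-codes are rejected outright: none occur
in any rule set here, and accepting them silently would mask extraction
errors. Wildcard patterns (`191.x`, `800.xx`) match by pure prefix on the
canonical string up to the first wildcard, so `191.x` and `191.xx` denote
the same family — ICD-9-CM is hierarchical by prefix, and the printed
`.x`/`.xx` notation means "any subcode", not "exactly one/two further
digits". A wildcard pattern also matches its bare category root (`800.xx`
matches `800`): extracts sometimes record a category without a subcode,
and for exclusion codes the conservative reading is to exclude.

### Strict-primary mode

The validating institution extracted only the primary procedure code, so
on its data "match any procedure position" and "match the primary only"
coincide. The engine defaults to all-position matching, which generalizes
to richer extracts without changing any reproduction result; a
`strict_primary` flag restores primary-only inclusion matching for
fidelity experiments. Exclusion always sees every position.

## Accuracy metrics

`confusion_matrix()` compares predicted and true booleans;
`compute_metrics()` derives sensitivity, specificity, PPV, NPV and correct
classification. Numerical choices:

* **Undefined, not zero.** A metric with an empty denominator (e.g.
  sensitivity with no true cases) has estimate `NA` and display
  `"undefined"`. Small validation subsets legitimately produce these, and
  reporting 0 would be a silent lie.
* **Display rounding** is half away from zero to one decimal in percent
  (`37/38` → 97.4, `42/46` → 91.3), the convention under which the
  published panels reproduce digit for digit. The one exception is the
  headline NPV: the computed value is 10873/10874 = 99.99%, which displays
  as 100.0 under any half-rounding rule, while the source prints 99.9. We
  report the computed value and treat the printed figure as a lower bound;
  whether the original was truncated or used slightly different counts is
  not recoverable.
* **Confidence intervals** are exact Clopper–Pearson, computed from beta
  quantiles with the standard boundary conventions (lower 0 at 0
  successes, upper 1 at *n* of *n*). Counts as small as 8 appear in the
  secondary panels, so a normal approximation would be inappropriate. The
  source reports point estimates only, so intervals are an extension; the
  test suite cross-checks the beta-quantile form against an independent
  binomial tail-sum oracle.

## The deterministic validation cohort

`build_paper_cohort()` rebuilds the 10,925-operation cohort from its
published marginal counts so that the entire validation is reproducible at
desk scale in well under a second: 46 chart-confirmed cases (diagnosis
distribution 12/1/19/13 across the four stroke codes plus one case
miscoded 433.01; primary procedures 31/9/1/4/1), the six published
false-positive hematoma evacuations record for record, 33 posterior fossa
craniectomies (17 × 433.01, 8 × 433.21, 4 × 443.24 with procedure 01.25,
and 4 carrying 434.91 with procedures [01.25, 03.09]), and 10,840
background operations with a fixed non-neurovascular code pair (722.10 /
80.51).

Where the record-level linkage is unpublished the builder makes a fixed,
documented choice: diagnosis and procedure distributions are paired
lexicographically (any inclusion diagnosis × any inclusion procedure is
positive absent exclusions, so the pairing cannot affect any label); the
specific cases carrying diagnosis 431 or an excision-type primary are
pinned by index so the secondary confusion matrices come out (5, 1, 3, 37)
and (10, 2, 5, 29), and which particular case carries which label is
immaterial to every metric. The 17/8/4/4 split of posterior fossa
exclusion codes is likewise fixed but arbitrary: only "all 33 are
excluded" is load-bearing. Two calls produce byte-identical cohorts, and
the tests assert it.

## The random cohort generator

`generate_random_cohort(n_records, case_prevalence, miscoding_rate,
contamination_rate, seed)` exists to give the engine's statistical
properties something to converge on. Each record is a true case with
probability `case_prevalence`; a case is miscoded (near-miss diagnosis
433.01 or 433.10, hence a false negative) with probability
`miscoding_rate`; a non-case is a contaminant (inclusion-satisfying codes,
hence a false positive) with probability `contamination_rate`; a fifth of
the remaining non-cases carry stroke-like codes plus an exclusion code so
the veto arm is exercised, the rest are plain background. By construction
the expected sensitivity is `1 − miscoding_rate` and the expected
false-positive count is `n · (1 − prevalence) · contamination_rate`; the
test suite verifies both over 200 seeded replicates (n = 300 each,
prevalence 0.2, miscoding 0.06, contamination 0.01 — sizes chosen so
Monte-Carlo error is a few parts per thousand while the whole suite stays
fast) and at a realistic claims scale of 10,000 records with prevalence
0.005. Replicate *k* derives its seed as `seed + k`; the generator
restores the caller's RNG state.

What the generator emulates is the *error structure* of the validated
cohort — rare cases, rarer contamination, occasional near-miss miscoding —
not real claims: there is no demographic structure, no casemix among
background records, one diagnosis per synthetic record, and miscoding is
independent across records. Passing tests therefore demonstrate that the
engine measures what it should on data with known truth; they say nothing
about the phenotype's external validity at another institution, which can
only be established with that institution's charts.

## Degenerate inputs and edge policies

A record with no codes at all classifies negative with a warning note in
its trace. Malformed codes abort a strict-mode read (default), naming the
row and offending text; in lenient mode the record is flagged, logged, and
classified negative — silent misclassification of malformed claims being
the chief real-world failure mode. Duplicate record ids are an error, as
are rule sets with an empty inclusion axis or a pattern appearing on both
sides of the same axis. Rule-set YAML must quote its patterns: an
unquoted `324.0` would be parsed as the number 324 and silently lose its
trailing zero, so `load_ruleset()` rejects unquoted numerics instead.

## Known limitations

The phenotype is ICD-9-CM only (the source institution had no ICD-10 data
to validate a translation against). There is no temporal logic, no
multi-visit linkage, and no code-position weighting beyond the primary
procedure. The cohort reconstruction reproduces published counts, not
patients; analyses that depend on record-level covariates (age, laterality)
cannot be run against it. The excision indicator presumes the primary
procedure code is the operation's main descriptor — its published 62.5%
sensitivity is exactly the cost of that presumption.
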