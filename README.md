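# icd9phenotype

Rule-based phenotyping of ICD-9-CM administrative claims, built around a
validated algorithm for identifying **decompressive craniectomy for
space-occupying supratentorial infarction** in hospital billing data.

Large hemispheric strokes treated with decompressive craniectomy are rare at
any single center, so population-level outcome studies lean on
administrative claims. But billing codes are noisy: at the validating
institution the craniectomy procedure code (01.25) was recorded for only
67.4% of true craniectomy-for-stroke cases, with the rest coded as
craniotomy (01.24) or excision-type procedures (01.39, 01.53, 01.59). A
usable phenotype therefore combines inclusion and exclusion criteria:

* **Include** records carrying one of four acute ischemic stroke diagnosis
  codes (433.11, 434.01, 434.11, 434.91) **and** one of five neurosurgical
  procedure codes (01.24, 01.25, 01.39, 01.53, 01.59).
* **Exclude** any record carrying a diagnosis code for brain tumor
  (191.x, 198.3), intracranial abscess (324.0), subarachnoid hemorrhage
  (430), vertebrobasilar infarction (433.01, 433.21), unruptured aneurysm
  (437.3), Moyamoya disease (437.5), venous sinus thrombosis (437.6),
  vertebral artery dissection (443.24), congenital cerebrovascular anomaly
  (747.81) or head trauma (800.xx–854.xx), or the laminectomy procedure
  code (03.09), which removes posterior fossa decompressions.

Exclusion strictly overrides inclusion. Against chart-review truth on a
10,925-operation neurosurgical cohort this rule set attains

    sensitivity = TP/(TP+FN) = 45/46  = 97.8%
    specificity = TN/(TN+FP) = 10873/10879 = 99.9%
    PPV         = TP/(TP+FP) = 45/51  = 88.2%
    NPV         = TN/(TN+FN) = 10873/10874

The package is for claims/EHR researchers who want (a) the craniectomy
phenotype ready to run, (b) a general, explainable engine for rule sets of
this shape (wildcard code families, exclusion precedence, match traces),
and (c) the validation harness — confusion matrices, sensitivity /
specificity / PPV / NPV / correct classification with exact
(Clopper–Pearson) binomial intervals — to evaluate their own rule sets
against gold-standard labels.

## Worked example

Classify the bundled example claims file (delimited text; diagnosis codes
unordered, procedure codes ordered with the primary first; dotted and
undotted code dialects both accepted):

```r
library(icd9phenotype)

coh <- read_claims(system.file("extdata", "example_claims.csv",
                               package = "icd9phenotype"))
res <- classify_cohort(coh, builtin_ruleset())
res
#> Phenotype classification: 6 record(s), 2 positive, 4 negative
#>   positive: op-001, op-002
```

Every call is explainable — here a stroke-coded craniectomy is vetoed by a
traumatic subdural hemorrhage code:

```r
classify_record(coh[3, ], builtin_ruleset())
#> Record op-003: NEGATIVE
#>   inclusion matches:
#>     diagnosis 434.11 -> 434.11
#>     procedure 01.25 -> 01.25
#>   exclusion matches:
#>     diagnosis 852.xx -> 852.21
```

Rebuild the full validation cohort (46 true cases, 6 published false
positives, 33 posterior fossa craniectomies, 10,840 background operations)
and validate the phenotype against its chart-review labels:

```r
v <- validate_cohort(build_paper_cohort(), builtin_ruleset())
v$confusion
#>           truth
#> predicted  case non-case
#>   positive   45        6
#>   negative    1    10873
v$metrics
#>                  metric numerator denominator estimate pct_display ci_low ci_high
#>             sensitivity        45          46   0.9783        97.8 0.8847  0.9994
#>             specificity     10873       10879   0.9994        99.9 0.9988  0.9998
#>                     ppv        45          51   0.8824        88.2 0.7613  0.9556
#>                     npv     10873       10874   0.9999       100.0 0.9995  1.0000
#>  correct_classification     10918       10925   0.9994        99.9 0.9987  0.9997
```

So 51 records are flagged, 45 correctly; the one false negative is a true
case whose infarction was miscoded as basilar occlusion (433.01, an
exclusion code); the six false positives are intracerebral hemorrhage
evacuations that carry infarction codes. The display column rounds half
away from zero to one decimal; NPV shows 100.0 because 10873/10874 rounds
up. Secondary coding indicators (`excision_indicator()`,
`hemorrhage_indicator()`) assess, among confirmed cases, how well the
primary procedure code captures excision of infarcted tissue and how well
diagnosis 431 captures hemorrhagic conversion.

A command-line interface wraps the same functions
(`system.file("cli", "icd9phenotype.R", package = "icd9phenotype")`) with
subcommands `classify`, `validate`, `simulate` and `describe-ruleset`.

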