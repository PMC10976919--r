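---
title: "Rule-based TN staging of radiology reports: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based TN staging of radiology reports: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungtnm)
```

## The problem and the model

Staging lung cancer under the TNM classification (8th edition) requires
three pieces of information that radiology reports state in prose but
rarely as a label: the primary tumor's size and local extent (T), the
regional lymph-node status by IASLC station and laterality (N), and distant
metastasis (M, out of scope here). `lungtnm` is a deterministic, rule-based
pipeline that recovers `(T, N)` from free text, with one modality-specific
twist: on PET-CT, stated FDG avidity *overrules* the anatomical size
criterion for node pathology in both directions — an enlarged node without
uptake is treated as benign, a sub-centimeter avid node as malignant.

The pipeline is a composition of deterministic stages (sectionizing,
sentence splitting, measurement extraction, concept matching, assertion
assignment, finding aggregation, staging). There is no statistical
component anywhere; the same input always yields the same output, and every
decision is logged in a trace.

## Assertion semantics (ConText-style)

Concept mentions get exactly one assertion status: `affirmed`, `negated` or
`uncertain`. Modifier triggers come from the lexicon in four classes —
negation, uncertainty, pseudo, termination. Each non-pseudo trigger opens a
scope from the trigger to the sentence boundary in its direction, truncated
at the first termination trigger ("but", "however") or the next non-pseudo
trigger. Pseudo triggers ("cannot be excluded") are matched first and
suppress any trigger they textually contain. Negation takes precedence over
uncertainty, so "no suspicious nodes" is negated, not uncertain. Scopes
never cross sentence boundaries; linking information *across* sentences is
the finding layer's job, not the assertion layer's.

The downstream certainty policy is strict: only affirmed mentions
contribute pathology. Uncertain mentions ("suspicion of lymphadenopathy")
are tracked in the trace but excluded from staging, because hedged findings
must not raise a stage.

## Measurements and the blacklist

Sizes are parsed as `<num> mm`, `<num> cm`, two/three-dimensional
`a x b (x c) <unit>` forms and ranges. Internally everything is
millimeters: TNM thresholds are centimeter multiples, so integer
millimeters avoid floating-point boundary traps. Two conventions the
classification itself does not dictate:

* **Ranges take the upper bound** ("1–2 cm" → 20 mm): conservative
  staging.
* **Nodes use the short axis** of multidimensional measurements
  (radiological convention for lymphadenopathy), **tumors the long axis**.

A measurement is *blacklisted* when an anatomical blacklist concept
(adrenal gland, kidney, cyst, fluid collection, …) occurs in the same
sentence with no tumor/node concept nearer in characters. This prevents the
classic whole-body PET-CT failure where an adrenal or renal measurement is
mistaken for the tumor size, since the tumor size rule deliberately takes
the *largest* linked measurement in the report. An exact distance tie keeps
the measurement (missing a true tumor size is costlier than occasionally
keeping an organ size) and flags the trace.

Measurement-to-concept attachment is sentence-first: the nearest affirmed
tumor/node mention in the same sentence owns the measurement; a measurement
in a sentence with neither may attach to a tumor mention in an adjacent
sentence of the same section ("There is a spiculated mass … . It measures
42 mm."). A node-owned measurement is never stolen by an adjacent tumor
sentence.

## Staging rules and their encoding

The TNM-8 numeric content (size thresholds, the 10 mm node cutoff, the
station-by-laterality N map) is *configuration*, not code:
`inst/extdata/tnm8_rules.yaml`, versioned, so a revised edition can be
dropped in. Size boundaries are inclusive (a 30 mm tumor is T1c), matching
the edition's "≤" wording.

Feature overruling takes the maximum of the size stage and the
feature-implied stage. One wrinkle: a T2 feature (main-bronchus or
visceral-pleura invasion, obstructive atelectasis) with a *known* size
lifts the result to at least T2a; without any size it yields the generic
label `T2`. The generic label is reserved for the feature-without-size
case — with a size, T2 disease is always T2a or T2b.

Unresolvable situations degrade conservatively with a trace warning rather
than crash: a pathologic lateralized node with unknown tumor side maps via
the ipsilateral table (N2 for stations 2–9, N1 for 10–14); pathologic
"mediastinal" wording without a station maps to N2; a pathologic node with
neither station nor region contributes nothing. A report with no certain
tumor yields T0 — not a valid clinical gold label, but an auditable output
for degenerate input.

When CT wording and PET avidity disagree about the same node, the PET
statement wins regardless of sentence order. That is the point of the
metabolic layer; the trace records every such overruling.

## The synthetic generator: what it emulates, what it does not

The generator states a fixed world; its defaults were chosen once and are
not tuned to test outcomes:

* **Stage distribution** follows the training-cohort shape of the setting
  the method was developed for (63 reports, heavier T4, sparse T1/N1
  cells), so stress concentrates where real cohorts put it.
* **Modality mix** defaults to 60% PET-CT, matching that cohort (39/63).
* **Adversarial rates** default to 0.2 for negation, uncertainty and
  blacklist traps, 0.1 for missing subheadings, 0.2 for multidimensional
  sizes, implicit satellite/other-lobe mentions and PET/CT avidity
  conflicts.

Reports are written findings-first: the generator draws a structured
finding specification, *verifies with the staging rules that it maps
exactly to the requested gold `(T, N)`*, and only then renders text from
templates mirroring the usual report structure (clinical details,
technique, chest, abdomen/skeleton for PET-CT, impression). Gold labels
are therefore guaranteed by construction, which is what parameter-recovery
testing needs. Distractors are gold-neutral by design: a negated
contralateral node, an uncertain subcarinal node, an enlarged adrenal
measurement, an enlarged-but-non-avid conflicting node.

What a green round-trip does **not** establish: the templates share one
vocabulary with the default lexicon, sentences are short and declarative,
and there is no dictation noise, no prose-style variation, no typing
errors, no institution-specific hedging. Real-world accuracy is dominated
by exactly those factors. The synthetic benchmark validates the *logic*
(staging tables, overruling, assertion scopes, blacklist, sectionizing),
not clinical performance.

## Numerical and degenerate-input choices

* Spans are 0-based half-open character intervals into the raw text
  everywhere; text cleaning is strictly length-preserving (unicode
  space/dash folding, decimal comma → point between digits) so spans never
  shift.
* Sentence splitting is rule-based: punctuation plus a protected-token
  list. Decimals ("3.2 cm") and abbreviations ("St. 4R") do not split; a
  single letter before a period is a protected initial *unless preceded by
  a digit* — "station 5L." must end the sentence.
* Heading matching is case-insensitive and anchored at line starts; the
  colon is optional only for a heading alone on its line, so "Chest wall
  invasion…" at a line start does not open a section. A report without
  recognizable headings becomes one `unsectioned` section that *is*
  searched for evidence — the degraded path, not an error.
* Overlapping same-category concept matches resolve to the longer match;
  cross-category overlaps coexist ("without FDG uptake" is simultaneously
  an explicit negative-avidity concept and a negated positive-avidity
  mention; both routes agree that the node is non-avid, and the negative
  route wins on conflict).
* Evidence is only collected from chest, impression and unsectioned
  sections; other whole-body sections contribute blacklist context only.
  This is the defense against whole-body PET-CT sections donating organ
  measurements or non-regional nodes ("pathologic node in the mesentery")
  to the staging.

## Evaluation

`evaluate()` reports T, N and combined TN accuracies (TN correct iff both
axes correct), confusion matrices, and support-weighted one-vs-rest
precision/recall/F1 over the joint TN labels. Weights are gold supports;
classes absent from gold get zero weight, so weighted recall equals TN
accuracy by construction and `accuracy_tn <= min(accuracy_t, accuracy_n)`
always holds. The error report auto-tags each mismatch from the decision
trace (sectionizer fallback, blacklist tie, uncertainty exclusion or PET
overruling, station-less node) with `unclassified` as the honest residual
bucket; trace-based tagging is best-effort, not a gold error taxonomy.

## Known limitations

* No M stage, no stage grouping, no treatment logic.
* No temporality or experiencer axes in the assertion engine (history-of,
  family-of), and no cross-sentence coreference ("this node also shows…").
* The default English lexicon is a functional reconstruction; real
  deployments must retrain the vocabulary per institution, which is
  precisely the swappable-lexicon design's purpose.
* SUV values are not parsed; avidity is categorical.
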