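---
title: "Fine-grained phenotype modeling with phenossu: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fine-grained phenotype modeling with phenossu: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenossu)
```

## The model

Disease knowledge bases typically describe the clinical picture of a disease
as a bare list of phenotype concepts ("fever", "rash", ...). Guideline prose
is far richer: it says how often a phenotype occurs in the population, in
whom, how severe it is, how it starts, and where on the body it appears.
`phenossu` implements a *semantic structured unit* for phenotypes: an
entity–attribute–value model in which each phenotype mention is one unit
consisting of

* a phenotype concept, normalized to a SNOMED-CT code,
* zero or more *finding sites* (body structures linked to the phenotype via
  `locate` relations — deliberately modeled as separate linked entities, not
  attributes, because body structures form an open set of tens of thousands
  of concepts that cannot be configured as a closed value list), and
* a **total** assignment of twelve attributes, each with a closed,
  SNOMED-coded value set.

The twelve attributes fall into three categories:

| category | attributes |
|---|---|
| presence | assertion, frequency, age specificity, sex specificity, illness-severity specificity |
| manifestation | temporal pattern, severity, color, sensation |
| spatial | laterality, spatial pattern, quadrant pattern |

Every attribute has a *default*: `present` for assertion and `none` for all
others. Defaults are schema-level sentinels, not annotations — a guideline
sentence that simply names a phenotype asserts its presence and says nothing
else, and the default assignment encodes exactly that. Consequently a
fresh instance has zero non-default values, and corpus statistics such as
"number of non-default attribute values" measure how much contextual detail
the text actually carries.

The schema is entirely configuration-driven (`load_schema()` reads a YAML
file): attribute membership, value sets, SNOMED codes, trigger lexicons and
defaults can all be replaced without code changes. The shipped value sets
follow the SNOMED qualifier values the model is built around (severity
mild/moderate/severe, laterality unilateral/bilateral, temporal pattern
acute/chronic/intermittent/gradual, ...); codes we could not source reliably
are marked "best-effort" in the config and are meant to be replaced by a
curated set.

### Normalization: pre- and postcoordination

A phenotype with a finding site is treated as one integral concept. If the
(phenotype, site) pair has a single existing SNOMED concept, we
*precoordinate*: bleeding + nasal structure becomes `249366005|epistaxis`.
Otherwise we *postcoordinate*, combining the codes:
`"271807003|Rash": "33712006|Skin structure of hand"`. The precoordination
table is a user-supplied two-column mapping (a small example table ships
with the package); with an empty table every composite concept is
postcoordinated, so normalization is total: every valid input yields exactly
one of `precoordinated`, `postcoordinated` or `concept_only`.

## Attribute discovery by sentence-level co-occurrence

Which attributes belong in the schema is an empirical question about the
corpus. `build_cooccurrence_table()` implements the screening step: a
sentence supports attribute *a* iff it contains at least one phenotype
mention (dictionary matching against the phenotype lexicon) and at least
one trigger term of any value of *a*. `filter_candidate_attributes()` keeps
attributes supported by at least 2 distinct sentences corpus-wide — the
minimal-evidence threshold below which a single odd sentence could promote
an attribute. Co-occurrence requires nothing beyond same-sentence
membership; no proximity weighting is used. The output is a candidate list
for *human* curation; the subsequent manual filtering and iterative schema
refinement are editorial processes, out of scope by design.

We count supporting sentences per attribute (any of its values). A
per-value breakdown is available from `find_trigger_mentions()` when a finer
screen is wanted.

Sentence splitting is rule-based (`[.!?]` + whitespace, with an
abbreviation stop-list). The corpus is encyclopedic prose; a statistical
sentence model would add a heavy dependency for no measurable benefit at
this task, and a deterministic splitter keeps offsets reproducible.

## Annotation I/O and inter-annotator agreement

`parse_standoff()` / `write_standoff()` implement BRAT standoff annotation
bit-exactly: entity (`T`), attribute (`A`) and relation (`R`) records over
0-based, end-exclusive code-point offsets; discontinuous spans are stored as
multi-interval tables; unknown record types pass through opaquely.
Writing is canonical (T, A, R in numeric id order), so `write ∘ parse` is a
canonicalization and is idempotent, while `parse ∘ write` is the identity.
`generate_brat_config()` emits the annotation tool configuration for any
schema, including the two *virtual* attributes that never describe the
phenotype itself: `agreement` (dual-annotation consistency) and
`equal_to_original` (fidelity of the annotation to the source description).

`merge_annotations()` applies the consistency rule for double annotation:
two annotations of a phenotype are consistent iff their spans are identical
**and** all attribute values match. Overlapping-but-unequal spans are two
disagreeing annotations — the rule requires identical spans, so no fuzzy
alignment is attempted. `instance_kappa()` quantifies agreement over the
union of span-keyed items, each annotator's rating being its value tuple
(or "missing"): it reports both the raw agreement proportion (the fraction
of `agree` verdicts) and Cohen's kappa with chance agreement from the two
marginal rating distributions. Both are reported because the two statistics
answer different questions and are easy to conflate; treating unmatched
spans as items (rather than restricting to matched spans) penalizes missed
annotations, consistently with the merge rule.

## Automatic extraction

Extraction is a hybrid, two-stage pipeline (`extract_phenossu()`):

1. **Concept recognition.** The default engine is a dictionary matcher over
   a term→code lexicon: case-insensitive, whole-token, longest-match-first,
   non-overlapping. Any external recognizer can replace it through
   `ingest_external_spans()`, which validates spans against the document —
   the choice of recognition engine is orthogonal to the rest of the
   pipeline.
2. **Attribute value prediction.** One independent classifier per attribute.
   The context of a phenotype is its sentence (a narrower token `window` is
   exposed; the default is the whole sentence). Features are, per trigger
   term of the attribute's value set, a presence flag and the signed token
   distance of the nearest occurrence to the phenotype — negative when the
   trigger is to the left. Distance is the difference of facing token
   indices ("sudden onset of fever" gives the trigger distance −2), 0 on
   overlap, and 0 with presence 0 when absent; the presence flag
   disambiguates absence from adjacency. Internally the classifier augments
   this vector with per-*value* aggregates (presence of any trigger of the
   value, distance of the nearest one), derived from the schema's
   value→trigger mapping: a trigger term unseen in training then still
   projects onto value-level features its siblings trained, which is what
   makes exact parameter recovery possible on small corpora.

Class imbalance is severe by construction (defaults dominate), so training
data are rebalanced by SMOTE-style minority oversampling: synthetic
examples interpolate uniformly between random same-class pairs until all
classes match the majority count. The classifier is a support vector
machine (`e1071::svm`), with cost × kernel (linear, RBF) selected by 5-fold
cross-validated grid search on the training set only. All stochastic steps
(oversampling, fold assignment) are seeded; identical corpus + seeds give
identical models and predictions.

Two hard rules bound the learned behavior: an all-zero feature vector (no
trigger in context) always predicts the attribute's default, and a
degenerate training set (single class, or constant features) yields a
constant majority classifier with a warning. The reference model
(`default_baseline_predict()`) ignores context entirely and answers
`present`/`none`; any trained model must beat it to be worth using.
A neural alternative can be plugged in wherever an object honors the
`predict_value()` contract; none ships, as no pretrained encoder can be
bundled and the SVM is the stronger configuration at this corpus scale.

## Evaluation metrics

* `span_overlap_f1()`: a predicted span is a true positive if it can be
  aligned one-to-one with an overlapping gold span. We compute the
  *maximum-cardinality* matching of the overlap graph (Kuhn's augmenting
  paths, warm-started greedily by overlap size). A greedy-by-overlap pass
  can fail to attain maximum cardinality on chains of overlaps, which would
  under-report TP; the exact matching makes the metric
  permutation-invariant and order-free. With no true positives, precision,
  recall and F1 are all defined as 0.
* `weighted_accuracy()`: balanced accuracy — the mean of per-class recalls
  over the classes present in gold. This operationalizes
  "prevalence-weighted" accuracy: a constant-default predictor scores
  1/(number of gold classes) regardless of how dominant the default is, so
  rare values carry full weight. `average_weighted_accuracy()` (AWA) is the
  unweighted mean across attributes. Alternative weightings can be swapped
  in by computing per-attribute scores yourself and averaging.
* `precise_representation_rate()` and `compare_profiles()`: expressive
  power. An information-model *profile* is a named subset of the schema's
  attributes (the shipped defaults: the full twelve-attribute profile; a
  CEM-like profile {assertion, severity, laterality}; a FHIR-like profile
  {severity, laterality}; and the empty concept-only profile — the CEM/FHIR
  inventories are best-effort approximations of what those models share
  with this schema, and are config-driven). An instance is *precisely
  representable* under a profile iff its annotation fully captures the
  original description and all its non-default attributes are in the
  profile. Representability is monotone in the subset ordering by
  construction, which the tests also verify empirically.

## The synthetic-data generator

Real guideline corpora cannot ship with the package, so every pipeline
stage is exercised on generated corpora with exact gold annotations
(`generate_corpus()`). Sentences are template-assembled — opener, planted
trigger terms, one phenotype mention, optional finding site — so spans and
values are correct by construction; the generator makes no attempt to mimic
natural prose style. Knobs and their defaults:

* **Prevalence** of non-default values per attribute. The corpus-emulation
  defaults (assertion and frequency 0.25; age specificity, severity and
  temporal pattern 0.15; the rest 0.05) put the most weight on the
  attributes most used in guideline text and produce ≈1.3 non-default
  values per instance, matching the density observed in annotated guideline
  corpora.
* **Ambiguity**: the probability that a planted trigger appears while the
  gold value stays default. 0 makes the trigger→value mapping
  deterministic; raising it makes value prediction genuinely hard.
* **disagreement_rate**: for `generate_annotator_pair()`, the per-instance
  probability that the second simulated annotator deviates — an attribute
  flip within the value set with weight 0.9, a one-token span shift with
  weight 0.1 (flips are the dominant real disagreement mode; the shift
  exercises span alignment).

All randomness flows from one mandatory integer seed; generation is
deterministic across platforms.

What passing tests on this generator do **not** show: robustness to
paraphrase, negation scope, long-range context, misspellings, or triggers
the lexicons lack. Results in the unambiguous regime are a *correctness*
check of the machinery (can the pipeline recover planted structure
exactly?), not an estimate of real-corpus accuracy — on real guidelines,
concept recognition and value prediction are substantially harder.

### Experiment sizes

The parameter-recovery experiment used in the tests and the acceptance
script runs on 200 sentences (20 documents × 10), ambiguity 0, with every
attribute's prevalence at 0.3 and a 60:40 train/test document split. The
uniform 0.3 prevalence is chosen — once, as part of the experiment design —
so that every value of every attribute is represented on both sides of the
split at this corpus size; with the low corpus-emulation prevalences a
200-sentence corpus would leave rare values unseen in training and the
experiment would measure sampling noise rather than recovery. Under these
conditions the trained classifiers reach held-out AWA ≥ 0.95 and beat the
default-value baseline (which scores 0.268 here: the mean of 1/|value set|
over the twelve attributes, since every value occurs in the test gold).

## Numerical choices and degenerate inputs

* Offsets: 0-based, end-exclusive, counting Unicode code points (the
  annotation tool's convention). Token boundaries are Unicode word
  boundaries; hyphens and apostrophes inside words are literal.
* Dictionary matching resolves overlaps longest-match-first, then leftmost;
  trigger matches never overlap within an attribute but may across
  attributes.
* Grid-search ties resolve to the first grid point (lower cost, linear
  before RBF); k-fold folds are seeded; SVM features are not rescaled
  (flags and small token distances are already commensurate, and rescaling
  would break the all-zero → default rule's alignment with training space).
* Empty inputs: empty documents yield empty graphs; empty gold makes
  weighted accuracy an error (not 0) because silence about classes is not
  evidence; an empty item union makes agreement an error.
* Percentages are reported to one decimal place, proportions unrounded.

## Known limitations

* The shipped SNOMED codes outside the well-known qualifier values are
  placeholders pending a curated mapping; the schema config is the intended
  override point.
* The CEM- and FHIR-like profiles approximate only the attribute overlap
  relevant to guideline text; they are not re-implementations of those
  models' native structures, and the comparison is by attribute-subset
  projection of an already fully annotated corpus.
* The dictionary recognizer does no abbreviation expansion or
  disambiguation; recall on real text is bounded by lexicon coverage.
* Only categorical attributes are modeled; numeric attributes (body
  temperature, durations) are out of scope.
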