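# phenossu

Fine-grained phenotype knowledge graphs for disease guidelines, built on an
entity–attribute–value model of phenotypes.

## The problem

Disease knowledge bases usually represent the clinical picture of a disease
as a bare list of phenotype concepts. Guideline prose carries much more: the
sentence *"common symptoms include sudden onset of fever"* says that fever
is **possible** (not asserted for every patient), **frequent** in the
population, and **acute** in onset. A concept list drops all of that.

`phenossu` models each phenotype mention as a *semantic structured unit*:

```
phenotype concept  (SNOMED-CT code)
  ├─ finding sites (body structures linked by "locate" relations)
  └─ 12 attributes, each with a closed SNOMED-coded value set
       presence:       assertion | frequency | age specificity |
                       sex specificity | illness-severity specificity
       manifestation:  temporal pattern | severity | color | sensation
       spatial:        laterality | spatial pattern | quadrant pattern
```

Every attribute has a default (`present` for assertion, `none` otherwise),
so an instance is always a total assignment and "non-default values" measure
the contextual detail a text actually expresses. Phenotype + finding site
pairs are normalized to a single SNOMED concept when one exists
(bleeding + nose → `249366005|epistaxis`), and to a postcoordination
expression otherwise (`"271807003|Rash": "33712006|Skin structure of hand"`).

The package implements the full construction and evaluation pipeline:

* **Schema** — config-driven twelve-attribute schema with per-value trigger
  lexicons (`load_schema()`).
* **BRAT I/O** — bit-exact standoff annotation reader/writer, annotation-tool
  config generation, dual-annotation merging with agreement marking
  (`parse_standoff()`, `write_standoff()`, `merge_annotations()`).
* **Attribute mining** — sentence-level co-occurrence screening of candidate
  attributes (`build_cooccurrence_table()`,
  `filter_candidate_attributes()`).
* **Extraction** — dictionary concept recognition (plus an adapter for any
  external recognizer) and per-attribute SVM value classifiers over
  trigger-presence/distance features with SMOTE-style oversampling and
  grid-searched hyperparameters (`recognize()`, `extract_phenossu()`).
* **Evaluation** — overlap-based span F1 with exact maximum matching,
  balanced ("prevalence-weighted") accuracy and its average across
  attributes, instance-level agreement (raw proportion + Cohen's kappa), and
  precise-representation rates (`span_overlap_f1()`, `weighted_accuracy()`,
  `instance_kappa()`).
* **Expressiveness comparison** — representability of gold instances under
  information-model profiles (full schema vs CEM-like vs FHIR-like vs
  concept-only; `compare_profiles()`).
* **Synthetic corpora** — a seeded generator of guideline-like documents
  with exact gold annotations, so everything above is testable end to end
  (`generate_corpus()`).

Core metrics, in the usual notation: span F1 = 2PR/(P+R) with overlap-based
TP matching; per-attribute weighted accuracy = mean over classes *c* present
in gold of recall(*c*); AWA = mean of the twelve per-attribute weighted
accuracies; kappa = (p_o − p_e)/(1 − p_e).

## Worked example

Train attribute classifiers on a generated corpus and annotate a guideline
sentence:

```r
library(phenossu)
schema  <- load_schema()
lexicon <- load_lexicon()

cfg <- generator_config(n_documents = 20, sentences_per_document = 10,
                        prevalence = 0.3, ambiguity = 0, seed = 20260921)
corpus <- generate_corpus(cfg, schema, lexicon)
classifiers <- train_phenossu_classifiers(corpus[1:12], schema, seed = 7)

graph <- extract_phenossu("Common symptoms include sudden onset of fever.",
                          lexicon, classifiers, schema, doc_id = "guideline")
print(graph$instances[[1]])
#> <phenossu_instance 'fever' [40,45) 386661006>
#>    assertion=possible; frequency=frequent; temporal_pattern=acute
```

The extractor recognized `fever` (SNOMED 386661006) at characters 40–45 and
predicted three non-default attribute values from the sentence context:
"include" signals a possible (listed, not universal) phenotype, "common"
signals a frequent one, and "sudden onset" an acute temporal pattern. The
other nine attributes keep their defaults.

Compare the expressive power of information models on a gold corpus with a
known representability composition:

```r
instances <- generate_expressiveness_corpus(
  c(concept_only = 853, fhir_only = 61, cem_only = 1120,
    phenossu_only = 1723, partial = 443), schema)
compare_profiles(instances, load_profiles(schema = schema), schema)
#>        profile count_precise total percentage
#> 1     phenossu          3757  4200       89.5
#> 2          cem          2034  4200       48.4
#> 3         fhir           914  4200       21.8
#> 4 concept_only           853  4200       20.3
```

The full twelve-attribute model precisely represents 89.5% of the
descriptions; projecting the same gold corpus onto a CEM-like attribute
subset keeps 48.4%, a FHIR-like subset 21.8%, and a bare concept list only
20.3% — the cost of dropping attributes.

There is also a command-line interface (`inst/cli/phenossu`) wiring the
stages: `simulate`, `mine`, `preannotate`, `train`, `extract`, `evaluate`,
`compare-models`.

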