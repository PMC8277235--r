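test_that("minimal standoff records parse with verified spans", {
  doc <- parse_standoff("T1\tPhenotype 0 5\tfever", "fever is common.")
  expect_length(doc$entities, 1L)
  expect_equal(doc$entities[["T1"]]$text, "fever")
  expect_equal(doc$entities[["T1"]]$spans$start, 0L)

  expect_error(parse_standoff("T1\tPhenotype 0 5\tchill", "fever is common."),
               "line 1")
  expect_error(
    parse_standoff("T1\tPhenotype 0 5\tfever\nA1\tseverity T9 severe",
                   "fever is common."),
    "reference error")
})

test_that("discontinuous spans parse and store multiple intervals", {
  text <- "severe chest and back pain today"
  ann <- "T1\tPhenotype 0 6;22 26\tsevere pain"
  doc <- parse_standoff(ann, text)
  expect_equal(nrow(doc$entities[["T1"]]$spans), 2L)
  expect_equal(doc$entities[["T1"]]$text, "severe pain")
  expect_equal(write_standoff(doc), ann)
})

test_that("write/parse round-trips are identity up to canonical ordering", {
  tiny <- fixture_tiny_doc()
  doc <- parse_standoff(tiny$ann, tiny$text)
  written <- write_standoff(doc)
  expect_equal(written, tiny$ann)
  reparsed <- parse_standoff(written, tiny$text)
  expect_equal(write_standoff(reparsed), written)

  shuffled <- paste(rev(strsplit(tiny$ann, "\n")[[1]]), collapse = "\n")
  expect_equal(write_standoff(parse_standoff(shuffled, tiny$text)), tiny$ann)

  empty <- parse_standoff("", "some text.")
  expect_equal(write_standoff(empty), "")

  note <- paste0(tiny$ann, "\n#1\tAnnotatorNotes T1\tcheck this")
  expect_match(write_standoff(parse_standoff(note, tiny$text)),
               "AnnotatorNotes", fixed = TRUE)
})

test_that("generated gold annotations round-trip bit-exactly", {
  schema <- fixture_schema()
  cfg <- generator_config(n_documents = 4, sentences_per_document = 8,
                          seed = 5)
  corpus <- generate_corpus(cfg, schema, fixture_lexicon())
  for (doc in corpus) {
    written <- write_standoff(doc$ann)
    expect_equal(write_standoff(parse_standoff(written, doc$text,
                                               doc$doc_id)), written)
  }
})

test_that("BRAT config generation covers schema and virtual attributes", {
  schema <- fixture_schema()
  conf <- generate_brat_config(schema)
  attr_lines <- grep("Arg:Phenotype", strsplit(conf$annotation_conf,
                                               "\n")[[1]], value = TRUE)
  expect_length(attr_lines, 14L)  # 12 schema + agreement + equal_to_original
  expect_match(conf$annotation_conf, "severity\tArg:Phenotype.*mild.*moderate.*severe")
  expect_match(conf$annotation_conf, "agreement\tArg:Phenotype, Value:agree|disagree",
               fixed = TRUE)
  expect_match(conf$annotation_conf, "locate\tArg1:Phenotype, Arg2:FindingSite",
               fixed = TRUE)

  bare <- structure(list(version = "0", attributes = list()),
                    class = "phenossu_schema")
  bare_conf <- generate_brat_config(bare)
  expect_false(grepl("Arg:Phenotype", bare_conf$annotation_conf))
  expect_match(bare_conf$annotation_conf, "Phenotype")
})

test_that("to_instances builds one instance per phenotype with sites and values", {
  schema <- fixture_schema()
  tiny <- fixture_tiny_doc()
  doc <- parse_standoff(tiny$ann, tiny$text)
  insts <- to_instances(doc, schema, lexicon = fixture_lexicon(),
                        precoordination_table = load_precoordination_table(),
                        site_lexicon = load_lexicon(
                          system.file("extdata", "finding_sites.tsv",
                                      package = "phenossu")))
  expect_length(insts,
                sum(vapply(doc$entities, function(e)
                  e$type == "Phenotype", NA)))
  bleeding <- insts[[1]]
  expect_length(bleeding$finding_sites, 1L)
  expect_equal(bleeding$finding_sites[[1]]$surface_form, "nose")
  expect_equal(get_attribute(bleeding, "severity"), "severe")
  expect_equal(bleeding$normalized$kind, "precoordinated")
  rash <- insts[[2]]
  expect_equal(get_attribute(rash, "assertion"), "possible")
  expect_equal(count_nondefault_values(rash, schema), 1L)

  bad <- sub("severe", "catastrophic", tiny$ann)
  expect_error(to_instances(parse_standoff(bad, tiny$text), schema),
               "closed value set")
})

test_that("to_instances recovers exactly the generator's gold values", {
  schema <- fixture_schema()
  cfg <- generator_config(n_documents = 5, sentences_per_document = 8,
                          seed = 13)
  corpus <- generate_corpus(cfg, schema, fixture_lexicon())
  planted <- attr(corpus, "gold_summary")
  for (doc in corpus) {
    insts <- to_instances(doc$ann, schema)
    rows <- planted[planted$doc_id == doc$doc_id & !planted$ambiguous, ]
    for (inst in insts) {
      mine <- rows[rows$sentence == inst$sentence_ref$sentence, ]
      defaults <- schema_defaults(schema)
      nondef <- names(defaults)[inst$values[names(defaults)] != defaults]
      expect_setequal(nondef, mine$attribute)
      for (j in seq_len(nrow(mine))) {
        expect_equal(unname(inst$values[[mine$attribute[j]]]),
                     mine$value[j])
      }
    }
  }
})

test_that("merging identical annotations yields full agreement", {
  schema <- fixture_schema()
  tiny <- fixture_tiny_doc()
  doc <- parse_standoff(tiny$ann, tiny$text)
  merged <- merge_annotations(doc, doc, schema)
  verdicts <- vapply(to_instances(merged, schema), `[[`, "", "agreement")
  expect_true(all(verdicts == "agree"))
})

test_that("merge marks value conflicts and one-sided spans as disagreement", {
  schema <- fixture_schema()
  tiny <- fixture_tiny_doc()
  doc_a <- parse_standoff(tiny$ann, tiny$text)
  doc_b <- parse_standoff(sub("A1\tseverity T1 severe",
                              "A1\tseverity T1 mild", tiny$ann, fixed = TRUE),
                          tiny$text)
  merged <- merge_annotations(doc_a, doc_b, schema)
  insts <- to_instances(merged, schema)
  verd <- stats::setNames(vapply(insts, `[[`, "", "agreement"),
                          vapply(insts, function(x) x$concept$surface_form,
                                 ""))
  expect_equal(unname(verd[["bleeding"]]), "disagree")
  expect_equal(unname(verd[["Rash"]]), "agree")

  # symmetry of verdicts
  merged_ba <- merge_annotations(doc_b, doc_a, schema)
  verd_ba <- vapply(to_instances(merged_ba, schema), `[[`, "", "agreement")
  expect_equal(sort(verd_ba), sort(unname(verd)))

  only_a <- parse_standoff("T1\tPhenotype 24 32\tbleeding", tiny$text)
  both <- parse_standoff(paste("T1\tPhenotype 24 32\tbleeding",
                               "T2\tPhenotype 46 50\tRash", sep = "\n"),
                         tiny$text)
  merged2 <- merge_annotations(only_a, both, schema)
  insts2 <- to_instances(merged2, schema)
  verd2 <- stats::setNames(vapply(insts2, `[[`, "", "agreement"),
                           vapply(insts2, function(x)
                             x$concept$surface_form, ""))
  expect_equal(unname(verd2[["bleeding"]]), "agree")
  expect_equal(unname(verd2[["Rash"]]), "disagree")

  expect_error(merge_annotations(doc_a,
                                 parse_standoff("", "other text."),
                                 schema), "differing document texts")
})

test_that("simulated annotator pairs disagree at about the configured rate", {
  schema <- fixture_schema()
  cfg <- generator_config(n_documents = 60, sentences_per_document = 10,
                          seed = 99)
  corpus <- generate_corpus(cfg, schema, fixture_lexicon())
  pair <- generate_annotator_pair(corpus, disagreement_rate = 0.1,
                                  seed = 100, schema = schema)
  verdicts <- unlist(lapply(seq_along(corpus), function(i) {
    merged <- merge_annotations(pair$docs_a[[i]]$ann, pair$docs_b[[i]]$ann,
                                schema)
    vapply(to_instances(merged, schema), `[[`, "", "agreement")
  }))
  expect_gt(length(verdicts), 450L)
  frac <- mean(verdicts == "disagree")
  # expected ~0.1 (span shifts double-count slightly); binomial tolerance
  expect_lt(abs(frac - 0.1), 0.05)
})
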