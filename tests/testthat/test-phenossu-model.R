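test_that("shipped schema defines twelve attributes in three categories", {
  schema <- fixture_schema()
  expect_s3_class(schema, "phenossu_schema")
  expect_length(schema$attributes, 12L)
  cats <- table(vapply(schema$attributes, `[[`, "", "category"))
  expect_equal(as.integer(cats[c("presence", "manifestation", "spatial")]),
               c(5L, 4L, 3L))
  sev <- schema_attribute(schema, "severity")
  expect_setequal(setdiff(sev$values$label, "none"),
                  c("mild", "moderate", "severe"))
})

test_that("schema validation rejects malformed configurations", {
  good_attr <- list(name = "severity", code = "272141005",
                    category = "manifestation", default = "none",
                    values = list(list(label = "none", code = ""),
                                  list(label = "mild", code = "255604002")))
  bad_default <- good_attr
  bad_default$default <- "catastrophic"
  expect_error(load_schema(write_schema_yaml(list(bad_default))),
               "severity")
  expect_error(load_schema(write_schema_yaml(list(good_attr, good_attr))),
               "duplicate")
  empty_values <- good_attr
  empty_values$values <- list()
  expect_error(load_schema(write_schema_yaml(list(empty_values))),
               "value set")
  bad_cat <- good_attr
  bad_cat$category <- "misc"
  expect_error(load_schema(write_schema_yaml(list(bad_cat))), "category")
})

test_that("fresh instances carry the schema defaults", {
  schema <- fixture_schema()
  concept <- phenotype_concept("fever", 0, 5, "386661006", "Fever")
  inst <- new_instance(concept, schema)
  expect_equal(unname(inst$values[["assertion"]]), "present")
  others <- inst$values[setdiff(names(inst$values), "assertion")]
  expect_true(all(others == "none"))
  expect_equal(count_nondefault_values(inst, schema), 0L)
  expect_equal(inst$agreement, "agree")
  expect_equal(inst$equal_to_original, "full")
  expect_identical(inst$values, new_instance(concept, schema)$values)
})

test_that("set_attribute mutates exactly one value and is closed-vocabulary", {
  schema <- fixture_schema()
  inst <- new_instance(phenotype_concept("fever", 0, 5, "386661006"), schema)
  inst2 <- set_attribute(inst, "severity", "severe", schema)
  expect_equal(count_nondefault_values(inst2, schema), 1L)
  expect_equal(get_attribute(inst2, "severity"), "severe")
  expect_identical(inst2$values[setdiff(names(inst2$values), "severity")],
                   inst$values[setdiff(names(inst$values), "severity")])
  expect_error(set_attribute(inst, "severity", "catastrophic", schema),
               "closed value set")
  inst3 <- set_attribute(inst, "temporal_pattern", "acute", schema)
  expect_equal(get_attribute(inst3, "temporal_pattern"), "acute")
  inst4 <- set_attribute(inst3, "frequency", "frequent", schema)
  expect_equal(count_nondefault_values(inst4, schema), 2L)
})

test_that("concept normalization picks pre/postcoordination correctly", {
  lexicon <- fixture_lexicon()
  precoord <- load_precoordination_table()
  bleeding <- phenotype_concept("bleeding", 0, 8, "131148009", "Bleeding")
  nose <- finding_site("nose", 20, 24, "45206002", "Nasal structure")
  pre <- normalize_concept(bleeding, list(nose), precoord)
  expect_equal(pre$kind, "precoordinated")
  expect_equal(pre$display, "249366005|epistaxis")
  expect_length(pre$site_codes, 0L)

  rash <- phenotype_concept("rash", 0, 4, "271807003", "Rash")
  hand <- finding_site("hand", 10, 14, "33712006", "Skin structure of hand")
  post <- normalize_concept(rash, list(hand), precoord)
  expect_equal(post$kind, "postcoordinated")
  expect_equal(post$display,
               "\"271807003|Rash\": \"33712006|Skin structure of hand\"")
  expect_equal(post$site_codes, "33712006")

  fever <- phenotype_concept("fever", 0, 5, "", "fever")
  only <- normalize_concept(fever, list(), precoord, lexicon = lexicon)
  expect_equal(only$kind, "concept_only")
  expect_equal(only$phenotype_code, "386661006")

  unknown <- phenotype_concept("glorp", 0, 5, "", "glorp")
  expect_error(normalize_concept(unknown, list(), precoord,
                                 lexicon = lexicon), "glorp")
})

test_that("non-default counts match the generator's planted ground truth", {
  schema <- fixture_schema()
  cfg <- generator_config(n_documents = 6, sentences_per_document = 8,
                          seed = 11)
  corpus <- generate_corpus(cfg, schema, fixture_lexicon())
  planted <- attr(corpus, "gold_summary")
  expected <- sum(!planted$ambiguous)
  observed <- sum(vapply(corpus, function(d)
    count_nondefault_values(to_instances(d$ann, schema), schema), 0L))
  expect_equal(observed, expected)
})

test_that("graph serialization round-trips all fields", {
  schema <- fixture_schema()
  lexicon <- fixture_lexicon()
  inst <- new_instance(
    phenotype_concept("bleeding", 24, 32, "131148009", "Bleeding"),
    schema, sentence_ref = list(doc_id = "d1", sentence = 1L))
  inst <- set_attribute(inst, "severity", "severe", schema)
  inst$finding_sites <- list(finding_site("nose", 40, 44, "45206002",
                                          "Nasal structure"))
  inst$normalized <- normalize_concept(inst$concept, inst$finding_sites,
                                       load_precoordination_table())
  graph <- phenotype_graph("test disease", "d1", list(inst))
  back <- deserialize_graph(serialize_graph(graph), schema)
  expect_equal(back$disease_name, graph$disease_name)
  expect_equal(length(back$instances), 1L)
  expect_equal(back$instances[[1]]$values, inst$values)
  expect_equal(back$instances[[1]]$concept$start, 24L)
  expect_equal(back$instances[[1]]$normalized$display,
               "249366005|epistaxis")
  expect_equal(serialize_graph(back), serialize_graph(graph))

  empty <- phenotype_graph("empty", "d0", list())
  expect_length(deserialize_graph(serialize_graph(empty),
                                  schema)$instances, 0L)
  expect_error(deserialize_graph("{\"nope\": 1}", schema), "malformed")
})

test_that("randomly generated graphs survive the serialization round-trip", {
  schema <- fixture_schema()
  lexicon <- fixture_lexicon()
  for (seed in 1:3) {
    cfg <- generator_config(n_documents = 2, sentences_per_document = 6,
                            seed = seed)
    corpus <- generate_corpus(cfg, schema, lexicon)
    for (doc in corpus) {
      insts <- to_instances(doc$ann, schema, lexicon = lexicon)
      graph <- phenotype_graph(doc$doc_id, doc$doc_id, insts)
      json <- serialize_graph(graph)
      back <- deserialize_graph(json, schema)
      expect_equal(serialize_graph(back), json)
      expect_equal(lapply(back$instances, `[[`, "values"),
                   lapply(graph$instances, `[[`, "values"))
    }
  }
})
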