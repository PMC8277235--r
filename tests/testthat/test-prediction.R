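test_that("context encoding captures trigger presence and signed distance", {
  schema <- fixture_schema()
  attr_tp <- schema_attribute(schema, "temporal_pattern")
  toks <- tokenize("common symptoms include sudden onset of fever")$token
  v <- encode_context(toks, c(7L, 7L), attr_tp)
  expect_length(v, 2L * length(unlist(attr_tp$triggers)))
  expect_equal(unname(v[["sudden onset.presence"]]), 1)
  expect_equal(unname(v[["sudden onset.dist"]]), -2)  # ends 2 tokens left

  v0 <- encode_context(toks, c(7L, 7L), schema_attribute(schema, "color"))
  expect_true(all(v0 == 0))
  expect_length(v0, 2L * length(unlist(
    schema_attribute(schema, "color")$triggers)))

  # window clipping: the trigger is out of a 1-token window
  vw <- encode_context(toks, c(7L, 7L), attr_tp, window = 1)
  expect_true(all(vw == 0))
  # trigger to the right gets a positive distance
  toks2 <- tokenize("fever of sudden onset")$token
  v2 <- encode_context(toks2, c(1L, 1L), attr_tp)
  expect_equal(unname(v2[["sudden onset.dist"]]), 2)
})

test_that("minority oversampling balances classes deterministically", {
  set.seed(1)
  x <- matrix(rnorm(200), ncol = 2)
  y <- c(rep("default", 90), rep("acute", 10))
  bal <- oversample_minority(x, y, seed = 3)
  expect_equal(unname(table(bal$labels)["acute"]),
               unname(table(bal$labels)["default"]))
  expect_equal(nrow(bal$features), 180L)
  bal2 <- oversample_minority(x, y, seed = 3)
  expect_identical(bal$features, bal2$features)

  even <- oversample_minority(x, rep(c("a", "b"), 50), seed = 1)
  expect_equal(nrow(even$features), 100L)

  expect_warning(same <- oversample_minority(x, rep("a", 100), seed = 1),
                 "single-class")
  expect_equal(nrow(same$features), 100L)

  # uniform label marginals after oversampling, several random imbalances
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(30:80, 1)
    labs <- sample(c("a", "b", "c"), n, replace = TRUE,
                   prob = c(0.7, 0.2, 0.1))
    if (length(unique(labs)) < 2L) next
    feats <- matrix(rnorm(4 * n), ncol = 4)
    bal <- oversample_minority(feats, labs, seed = seed)
    expect_equal(length(unique(table(bal$labels))), 1L)
  }
})

test_that("classifier training handles separable and degenerate data", {
  schema <- fixture_schema()
  attr_sev <- schema_attribute(schema, "severity")
  triggers <- unlist(attr_sev$triggers)
  dim <- 2L * length(triggers)
  # separable synthetic data: one unique active trigger per value
  make_row <- function(i) { v <- numeric(dim); v[2 * i - 1] <- 1; v[2 * i] <- -2; v }
  x <- do.call(rbind, lapply(rep(c(1, 3, 5), each = 8), make_row))
  y <- rep(c("mild", "moderate", "severe"), each = 8)
  clf <- train_attribute_classifier(x, y, attr_sev, seed = 2)
  expect_equal(predict_value(clf, x), y)   # training accuracy 1.0

  const <- matrix(1, nrow = 10, ncol = dim)
  expect_warning(cc <- train_attribute_classifier(
    const, rep(c("mild", "mild", "severe"), length.out = 10), attr_sev,
    seed = 1), "constant")
  expect_equal(unique(predict_value(cc, const)), "mild")

  expect_warning(one <- train_attribute_classifier(
    x[1:5, ], rep("severe", 5), attr_sev, seed = 1), "single-class")
  expect_equal(predict_value(one, x[1, ]), "severe")

  expect_error(predict_value(clf, numeric(3)), "dimensionality")
})

test_that("all-zero context always predicts the default value", {
  schema <- fixture_schema()
  rec <- fixture_recovery()
  for (nm in c("assertion", "severity", "temporal_pattern")) {
    clf <- rec$classifiers[[nm]]
    zero <- numeric(2L * length(clf$triggers))
    expect_equal(predict_value(clf, zero),
                 schema_attribute(schema, nm)$default)
  }
})

test_that("the default-value reference model ignores context", {
  schema <- fixture_schema()
  expect_equal(default_baseline_predict(schema_attribute(schema,
                                                         "assertion")),
               "present")
  for (nm in setdiff(attribute_names(schema), "assertion")) {
    expect_equal(default_baseline_predict(schema_attribute(schema, nm)),
                 "none")
  }
})

test_that("trained classifiers annotate the worked guideline sentence", {
  schema <- fixture_schema()
  rec <- fixture_recovery()
  graph <- extract_phenossu("Common symptoms include sudden onset of fever.",
                            fixture_lexicon(), rec$classifiers, schema)
  expect_length(graph$instances, 1L)
  inst <- graph$instances[[1]]
  expect_equal(inst$concept$surface_form, "fever")
  expect_equal(get_attribute(inst, "assertion"), "possible")
  expect_equal(get_attribute(inst, "frequency"), "frequent")
  expect_equal(get_attribute(inst, "temporal_pattern"), "acute")
  expect_equal(inst$normalized$display, "386661006|Fever")

  empty <- extract_phenossu("", fixture_lexicon(), rec$classifiers, schema)
  expect_length(empty$instances, 0L)

  # without trigger occurrences every attribute falls back to its default
  plain <- extract_phenossu("Patients develop fever.", fixture_lexicon(),
                            rec$classifiers, schema)
  expect_equal(count_nondefault_values(plain, schema), 0L)
})

test_that("the pipeline is deterministic given corpus and seeds", {
  schema <- fixture_schema()
  lexicon <- fixture_lexicon()
  cfg <- generator_config(n_documents = 4, sentences_per_document = 6,
                          prevalence = 0.3, seed = 55)
  c1 <- generate_corpus(cfg, schema, lexicon)
  c2 <- generate_corpus(cfg, schema, lexicon)
  expect_identical(vapply(c1, `[[`, "", "text"),
                   vapply(c2, `[[`, "", "text"))
  expect_identical(write_standoff(c1[[2]]$ann), write_standoff(c2[[2]]$ann))

  m1 <- train_phenossu_classifiers(c1, schema, seed = 9,
                                   grid = list(cost = 1, kernel = "linear"))
  m2 <- train_phenossu_classifiers(c2, schema, seed = 9,
                                   grid = list(cost = 1, kernel = "linear"))
  g1 <- extract_phenossu(c1[[1]]$text, lexicon, m1, schema)
  g2 <- extract_phenossu(c2[[1]]$text, lexicon, m2, schema)
  expect_equal(serialize_graph(g1), serialize_graph(g2))
})

test_that("trained classifiers beat the default baseline on synthetic corpora", {
  schema <- fixture_schema()
  rec <- fixture_recovery()
  aa <- attribute_accuracy(rec$pred_test, rec$gold_test, schema)
  base_pred <- lapply(rec$gold_test, function(x) {
    y <- x
    y$values <- schema_defaults(schema)
    y
  })
  base <- attribute_accuracy(base_pred, rec$gold_test, schema)
  expect_gt(aa$awa, base$awa)
  expect_true(all(aa$per_attribute >= base$per_attribute - 1e-9))
})
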