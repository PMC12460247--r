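test_that("assignment is cardinality-aware", {
  models <- fixture_models()
  ctx <- test_ctx()
  pat <- new_instance_node(models, "Patient")
  hn1 <- new_instance_node(models, "HumanName")
  hn2 <- new_instance_node(models, "HumanName")
  fml_assign(hn1, "family", "A", ctx)
  fml_assign(hn2, "family", "B", ctx)
  fml_assign(pat, "name", hn1, ctx)
  fml_assign(pat, "name", hn2, ctx)
  expect_length(node_get(pat, "name"), 2)  # unbounded appends, order kept
  expect_identical(node_get(node_get(pat, "name")[[1]], "family")[[1]], "A")
  fml_assign(pat, "birthDate", "1980-01-01", ctx)
  fml_assign(pat, "birthDate", "1990-01-01", ctx)
  expect_identical(node_get(pat, "birthDate"), list("1990-01-01"))  # replace
  expect_error(fml_assign(pat, "bogus", "x", ctx),
               class = "fmlc_runtime_error")
})

test_that("primitive-model elements serialize from their stored lexicals", {
  models <- fixture_models()
  ctx <- test_ctx()
  obs <- new_instance_node(models, "Observation")
  fml_assign(obs, "status", "final", ctx)
  expect_match(write_xml_instance(obs, models), "<status value=\"final\"/>")
  expect_match(write_fhir_json(obs, models), "\"status\": \"final\"")
})

test_that("translate resolves through the fixture concept map", {
  ast <- parse_fml(example_map("cda_lab_bundle"))
  ctx <- test_ctx(ast)
  url <- "http://example.org/fhir/ConceptMap/lab-codes"
  expect_identical(translate_code(ctx, "L1", map_url = url), "718-7")
  coding <- translate_code(ctx, "L3", map_url = url, output = "Coding")
  expect_identical(node_get(coding, "system"), list("http://loinc.org"))
  expect_identical(node_get(coding, "code"), list("6690-2"))
  err <- expect_error(translate_code(ctx, "L99", map_url = url),
                      class = "fmlc_translate_error")
  expect_match(conditionMessage(err), "L99")
  expect_error(translate_code(ctx, "L1", map_url = "urn:unregistered"),
               class = "fmlc_runtime_error")
})

test_that("ambiguous concept-map matches are errors", {
  ctx <- test_ctx()
  register_conceptmap(ctx, list(
    url = "urn:amb",
    groups = list(
      list(source_system = "urn:a", target_system = "urn:t",
           elements = list(list(source_code = "X", relationship = "equivalent",
                                target_code = "1"))),
      list(source_system = "urn:b", target_system = "urn:t",
           elements = list(list(source_code = "X", relationship = "equivalent",
                                target_code = "2"))))))
  expect_error(translate_code(ctx, "X", map_url = "urn:amb"),
               class = "fmlc_translate_error")
  # a source system disambiguates
  expect_identical(
    translate_code(ctx, "X", source_system = "urn:b", map_url = "urn:amb"),
    "2")
})

test_that("the shared timestamp and uuid source behave as documented", {
  ctx <- test_ctx(now = NULL)
  expect_identical(shared_now(ctx), shared_now(ctx))
  expect_match(shared_now(ctx),
               "^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}[+-]\\d{2}:\\d{2}$")

  v4 <- paste0("^", fmlc:::UUID_V4_REGEX, "$")
  u1 <- new_uuid(ctx)
  expect_match(u1, v4)
  expect_false(identical(u1, new_uuid(ctx)))
  a <- test_ctx(seed = 99); b <- test_ctx(seed = 99)
  expect_identical(replicate(5, new_uuid(a)), replicate(5, new_uuid(b)))
  c2 <- test_ctx(seed = 100)
  expect_false(identical(new_uuid(test_ctx(seed = 99)), new_uuid(c2)))
})

test_that("dynamic navigation types values and tolerates unknown names", {
  models <- fixture_models()
  pat <- fixture_patient(models)
  expect_identical(dynamic_get(pat, "birthDate", models)[[1]],
                   structure("1980-04-12", class = c("fml_date", "character")))
  expect_identical(dynamic_get(pat, "active", models), list(TRUE))
  expect_identical(dynamic_get(pat, "nothere", models), list())
  obs <- new_instance_node(models, "Observation")
  ctx <- test_ctx()
  q <- new_instance_node(models, "Quantity")
  fml_assign(obs, "valueQuantity", q, ctx)
  expect_length(dynamic_get(obs, "valueQuantity", models), 1)
  # the abstract choice name is not addressable
  expect_identical(dynamic_get(obs, "value", models), list())
})

test_that("list modes select as specified and only_one is guarded", {
  items <- list("a", "b", "c")
  expect_identical(fml_listmode(items, "first"), list("a"))
  expect_identical(fml_listmode(items, "last"), list("c"))
  expect_identical(fml_listmode(items, "not_first"), list("b", "c"))
  expect_identical(fml_listmode(items, "not_last"), list("a", "b"))
  expect_error(fml_listmode(items, "only_one"),
               class = "fmlc_cardinality_error")
  expect_identical(fml_listmode(list("x"), "only_one"), list("x"))
  expect_identical(fml_listmode(list(), "first"), list())
})

test_that("casts follow the fixed conversion table", {
  ctx <- test_ctx()
  expect_identical(fml_cast(ctx, "42", "integer"), 42L)
  expect_identical(attr(fml_cast(ctx, "13.50", "decimal"), "lexical"), "13.5")
  expect_identical(fml_cast(ctx, "true", "boolean"), TRUE)
  expect_identical(fml_cast(ctx, 7L, "string"), "7")
  expect_error(fml_cast(ctx, "maybe", "boolean"), class = "fmlc_cast_error")
  expect_error(fml_cast(ctx, "x1", "integer"), class = "fmlc_cast_error")
  expect_error(fml_cast(ctx, TRUE, "decimal"), class = "fmlc_cast_error")
  # the statically-dispatched variant returns canonical lexicals
  expect_identical(fml_cast_lex("13.50", "decimal"), "13.5")
  expect_identical(fml_cast_lex("2024-01-02T10:00:00", "dateTime"),
                   "2024-01-02T10:00:00")
  expect_error(fml_cast_lex(TRUE, "decimal"), class = "fmlc_cast_error")
})

test_that("string transforms behave per their definitions", {
  expect_identical(fml_truncate("hello", 3L), "hel")
  expect_identical(fml_truncate("ab", 10L), "ab")
  expect_identical(fml_append("urn:oid:", "1.2.3"), "urn:oid:1.2.3")
  expect_identical(fml_append("a", 1L, "b"), "a1b")
})

test_that("cc and c construct coded values", {
  ctx <- test_ctx()
  coding <- fml_c(ctx, "http://loinc.org", "718-7", "Hemoglobin")
  expect_identical(node_get(coding, "display"), list("Hemoglobin"))
  cc2 <- fml_cc(ctx, "http://loinc.org", "718-7")
  expect_identical(node_get(node_get(cc2, "coding")[[1]], "code"),
                   list("718-7"))
  cc1 <- fml_cc(ctx, "free text")
  expect_identical(node_get(cc1, "text"), list("free text"))
})
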