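test_that("the zero-rule map interprets to an empty target root", {
  models <- fixture_models()
  ast <- parse_fml(example_map("noop"))
  out <- interpret_map(ast, lab_input(3, seed = 1), models, ctx = test_ctx(ast))
  expect_length(out$values, 0)
  expect_identical(out$type, "Bundle")
})

test_that("the order-catalog example places the routine literal exactly once", {
  models <- fixture_models()
  ast <- parse_fml(example_map("activity_supply"))
  out <- interpret_map(ast, activity_input(1), models, ctx = test_ctx(ast))
  expect_identical(node_get(out, "priority"), list("routine"))
  xml <- write_xml_instance(out, models)
  expect_identical(lengths(regmatches(xml, gregexpr("routine", xml))), 1L)
  expect_match(xml, "<priority value=\"routine\"/>")
})

test_that("compiled and interpreted outputs are canonically equivalent", {
  models <- fixture_models()
  ast <- parse_fml(example_map("cda_lab_bundle"))
  for (seed in c(2, 5, 8)) {
    both <- run_both_engines(ast, lab_input(3, seed = seed), seed = seed)
    for (fmt in c("xml", "json")) {
      d <- diff_canonical(serialize_node(both$compiled, fmt),
                          serialize_node(both$interpreted, fmt), fmt)
      expect_true(d$equivalent, info = paste(seed, fmt))
    }
  }
})

test_that("XML and JSON targets represent the same instance tree", {
  models <- fixture_models()
  ast <- parse_fml(example_map("cda_lab_bundle"))
  out <- interpret_map(ast, lab_input(2, seed = 3), models,
                       ctx = test_ctx(ast))
  via_xml <- read_xml_instance(write_xml_instance(out, models), models,
                               "Bundle")
  via_json <- read_fhir_json(write_fhir_json(out, models), models, "Bundle")
  expect_true(node_equal(via_xml, via_json))
})

test_that("only_one list-mode violations raise a cardinality error", {
  txt <- 'map "urn:oo" = "OnlyOne"
uses "urn:hl7-org:v3" alias ClinicalDocument as source
uses "http://hl7.org/fhir" alias Bundle as target
group G(source cda : ClinicalDocument, target b : Bundle) {
  cda.component as comp then {
    comp.structuredBody as body then {
      body.entry as en only_one -> b.type = \'collection\' "one";
    } "body";
  } "comp";
}'
  models <- fixture_models()
  ast <- parse_fml(txt)
  input <- lab_input(3, seed = 1)  # three entries violate only_one
  expect_error(interpret_map(ast, input, models, ctx = test_ctx(ast)),
               class = "fmlc_cardinality_error")
  env <- load_generated_program(compile_map(ast, models))
  expect_error(env$fml__run(input, test_ctx(ast)),
               class = "fmlc_cardinality_error")
  # a single entry satisfies it in both engines
  ok <- lab_input(1, seed = 1)
  expect_identical(node_get(interpret_map(ast, ok, models,
                                          ctx = test_ctx(ast)), "type"),
                   list("collection"))
})

test_that("where conditions filter identically in both engines", {
  # a condition that is false for every other observation code
  txt <- 'map "urn:f" = "Filter"
uses "urn:hl7-org:v3" alias ClinicalDocument as source
uses "http://hl7.org/fhir" alias Bundle as target
group G(source cda : ClinicalDocument, target b : Bundle) {
  cda.component as comp then {
    comp.structuredBody as body then {
      body.entry as en then {
        en.observation as obs where (code.code.startsWith(\'L1\')) ->
            b.entry as e, e.resource as rc, rc.Observation as fo,
            fo.status = \'final\' "obs";
      } "entries";
    } "body";
  } "comp";
}'
  models <- fixture_models()
  ast <- parse_fml(txt)
  input <- lab_input(10, seed = 6)
  both <- run_both_engines(ast, input)
  expect_identical(length(node_get(both$compiled, "entry")),
                   length(node_get(both$interpreted, "entry")))
  # oracle: count codes starting with L1 by scanning the generated document
  body <- node_get(node_get(node_get(input, "component")[[1]],
                            "structuredBody")[[1]], "entry")
  codes <- vapply(body, function(en) {
    node_get(node_get(node_get(en, "observation")[[1]], "code")[[1]],
             "code")[[1]]
  }, character(1))
  expect_identical(length(node_get(both$compiled, "entry")),
                   sum(startsWith(codes, "L1")))
})

test_that("the canonical diff ignores only whitespace and v4 uuids", {
  a <- '<?xml version="1.0" encoding="UTF-8"?>\n<Bundle xmlns="http://hl7.org/fhir">\n  <id value="7f9c24e5-1b1a-4c8e-9f6d-2a1b3c4d5e6f"/>\n</Bundle>\n'
  b <- gsub("7f9c24e5-1b1a-4c8e-9f6d-2a1b3c4d5e6f",
            "00112233-4455-4677-8899-aabbccddeeff", a)
  expect_true(diff_canonical(a, a, "xml")$equivalent)
  expect_true(diff_canonical(a, b, "xml")$equivalent)
  # extra whitespace is canonicalized away
  expect_true(diff_canonical(a, gsub("  <id", "      <id", b), "xml")$equivalent)
  c2 <- gsub("<id value=", "<type value=", b)
  d <- diff_canonical(a, c2, "xml")
  expect_false(d$equivalent)
  expect_match(d$differences[1], "type")
  expect_error(diff_canonical("<unclosed", a, "xml"),
               class = "fmlc_format_error")
})
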