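test_that("XML round trip is canonical for generated documents", {
  models <- fixture_models()
  for (cfg in list(c(0, 1), c(1, 2), c(3, 7))) {
    doc <- mini_cda_document(cfg[1], seed = cfg[2])
    node <- read_xml_instance(doc, models, "ClinicalDocument")
    expect_identical(canonicalize_xml(write_xml_instance(node, models)),
                     canonicalize_xml(doc))
    # writers are already canonical: byte equality holds directly
    expect_identical(write_xml_instance(node, models), doc)
  }
})

test_that("serialization is deterministic and respects structural equality", {
  models <- fixture_models()
  doc <- mini_cda_document(2, seed = 5)
  n1 <- read_xml_instance(doc, models, "ClinicalDocument")
  n2 <- read_xml_instance(doc, models, "ClinicalDocument")
  expect_true(node_equal(n1, n2))
  expect_identical(write_xml_instance(n1, models), write_xml_instance(n2, models))
  copy <- node_deep_copy(n1)
  expect_true(node_equal(n1, copy))
  expect_identical(write_xml_instance(copy, models), write_xml_instance(n1, models))
})

test_that("FHIR JSON projection follows the conventions and round-trips", {
  models <- fixture_models()
  pat <- fixture_patient(models)
  json <- write_fhir_json(pat, models)
  # resource roots carry resourceType first
  expect_match(strsplit(json, "\n")[[1]][2], "\"resourceType\": \"Patient\"")
  # repeating element with one item is still an array
  obs <- new_instance_node(models, "Observation")
  fml_assign(obs, "identifier", new_instance_node(models, "Identifier"),
             test_ctx())
  expect_match(write_fhir_json(obs, models), "\"identifier\": \\[")
  # read back: structural identity
  back <- read_fhir_json(json, models, "Patient")
  expect_true(node_equal(pat, back))
  expect_identical(write_fhir_json(back, models), json)
})

test_that("JSON primitives are typed, not strings", {
  models <- fixture_models()
  pat <- fixture_patient(models)
  json <- write_fhir_json(pat, models)
  expect_match(json, "\"active\": true")
  q <- new_instance_node(models, "Quantity")
  fml_assign(q, "value", fml_decimal("13.80"), test_ctx())
  expect_match(write_fhir_json(q, models), "\"value\": 13.8", fixed = TRUE)
})

test_that("cross-format serializations are consistent", {
  models <- fixture_models()
  for (seed in 1:3) {
    ad <- activity_input(seed)
    j1 <- write_fhir_json(ad, models)
    j2 <- write_fhir_json(read_fhir_json(j1, models, "ActivityDefinition"),
                          models)
    expect_identical(j1, j2)
  }
})

test_that("invalid inputs produce located errors", {
  models <- fixture_models()
  bad_elem <- '<ClinicalDocument xmlns="urn:hl7-org:v3"><bogus/></ClinicalDocument>'
  err <- expect_error(read_xml_instance(bad_elem, models, "ClinicalDocument"),
                      class = "fmlc_parse_error")
  expect_match(conditionMessage(err), "/ClinicalDocument/bogus")

  err <- expect_error(
    read_fhir_json('{"resourceType": "Patient", "nope": 1}', models, "Patient"),
    class = "fmlc_parse_error")
  expect_match(conditionMessage(err), "nope")

  # scalar where an array is expected
  expect_error(
    read_fhir_json('{"resourceType": "Patient", "name": {"family": "X"}}',
                   models, "Patient"),
    class = "fmlc_shape_error")

  # JSON projection is undefined outside the FHIR-style family
  cda <- read_xml_instance(mini_cda_document(1, seed = 1), models,
                           "ClinicalDocument")
  expect_error(write_fhir_json(cda, models), class = "fmlc_unsupported_model")
})

test_that("cardinality violations are serialization errors", {
  models <- fixture_models()
  pat <- new_instance_node(models, "Patient")
  fmlc:::node_append(pat, "birthDate", "1980-01-01")
  fmlc:::node_append(pat, "birthDate", "1990-01-01")
  err <- expect_error(write_xml_instance(pat, models),
                      class = "fmlc_serialization_error")
  expect_match(conditionMessage(err), "birthDate")

  obs <- new_instance_node(models, "Observation")
  fmlc:::node_append(obs, "valueQuantity", new_instance_node(models, "Quantity"))
  fmlc:::node_append(obs, "valueString", "x")
  expect_error(write_xml_instance(obs, models),
               class = "fmlc_serialization_error")
})

test_that("empty and small documents read as expected", {
  models <- fixture_models()
  empty <- read_xml_instance('<Patient xmlns="http://hl7.org/fhir"/>', models,
                             "Patient")
  expect_length(empty$values, 0)
  doc3 <- lab_input(3, seed = 4)
  body <- node_get(node_get(node_get(doc3, "component")[[1]],
                            "structuredBody")[[1]], "entry")
  expect_length(body, 3)
})
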