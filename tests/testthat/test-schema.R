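test_that("fixture schemas parse to exactly the hand-listed manifest types", {
  for (schema in c("mini-fhir", "mini-cda")) {
    models <- parse_schema(paste(readLines(
      fixture_path("schemas", paste0(schema, ".xsd"))), collapse = "\n"))
    manifest <- jsonlite::fromJSON(
      fixture_path("schemas", paste0(schema, "-manifest.json")),
      simplifyVector = FALSE)
    expect_identical(model_type_names(models),
                     vapply(manifest$types, as.character, character(1)),
                     info = schema)
    for (key in names(manifest$elements)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      expect_identical(resolve_element_type(models, parts[1], parts[2]),
                       manifest$elements[[key]], info = key)
    }
  }
})

test_that("cardinalities and extension semantics follow the declarations", {
  models <- fixture_models()
  name_el <- fmlc:::find_element(models, "Patient", "name")
  expect_identical(name_el$max_occurs, Inf)
  bd_el <- fmlc:::find_element(models, "Patient", "birthDate")
  expect_identical(bd_el$max_occurs, 1)
  # extension: inherited elements come first, in base declaration order
  eff <- fmlc:::effective_elements(models, "Patient")
  expect_identical(vapply(eff, function(e) e$name, character(1))[1], "id")
  # inherited element resolves through the derived type
  expect_identical(resolve_element_type(models, "Observation", "id"), "id")
})

test_that("choice members resolve by concrete name only", {
  models <- fixture_models()
  expect_identical(resolve_element_type(models, "Observation", "valueQuantity"),
                   "Quantity")
  err <- expect_error(resolve_element_type(models, "Observation", "value"),
                      class = "fmlc_type_resolution_error")
  expect_match(conditionMessage(err), "valueQuantity")  # candidates listed
  members <- fmlc:::effective_elements(models, "Observation")
  groups <- vapply(members, function(e)
    if (is.null(e$choice_group)) "" else e$choice_group, character(1))
  expect_identical(sum(nzchar(groups)), 2L)  # the two value[x] members
})

test_that("unsupported constructs and dangling references are rejected", {
  bad_any <- '<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema"
    targetNamespace="urn:t">
    <xs:complexType name="A"><xs:sequence><xs:any/></xs:sequence></xs:complexType>
  </xs:schema>'
  err <- expect_error(parse_schema(bad_any), class = "fmlc_schema_unsupported")
  expect_match(conditionMessage(err), "any")

  dangling <- '<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema"
    targetNamespace="urn:t">
    <xs:complexType name="A"><xs:sequence>
      <xs:element name="b" type="Missing"/>
    </xs:sequence></xs:complexType>
  </xs:schema>'
  err <- expect_error(parse_schema(dangling), class = "fmlc_resolution_error")
  expect_match(conditionMessage(err), "Missing")
})

test_that("merging schemas rejects duplicate type names", {
  xsd <- paste(readLines(fixture_path("schemas", "mini-cda.xsd")),
               collapse = "\n")
  models <- parse_schema(xsd)
  expect_error(parse_schema(xsd, models), class = "fmlc_schema_error")
})
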