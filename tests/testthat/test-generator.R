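test_that("the synthetic report generator is deterministic per configuration", {
  d1 <- mini_cda_document(5, seed = 3)
  d2 <- mini_cda_document(5, seed = 3)
  expect_identical(d1, d2)
  expect_false(identical(d1, mini_cda_document(5, seed = 4)))
  expect_false(identical(d1, mini_cda_document(6, seed = 3)))
  a1 <- mini_activity_definition(2)
  expect_identical(a1, mini_activity_definition(2))
  expect_false(identical(a1, mini_activity_definition(3)))
})

test_that("generated documents are valid for the tested sizes", {
  models <- fixture_models()
  for (n in c(0, 1, 3, 100, 1000)) {
    node <- read_xml_instance(mini_cda_document(n, seed = 1), models,
                              "ClinicalDocument")
    body <- node_get(node_get(node_get(node, "component")[[1]],
                              "structuredBody")[[1]], "entry")
    expect_length(body, n)
  }
  # n = 0 still carries the patient block
  empty <- read_xml_instance(mini_cda_document(0, seed = 1), models,
                             "ClinicalDocument")
  expect_length(node_get(empty, "recordTarget"), 1)
})

test_that("patient field flags control the emitted blocks", {
  doc <- mini_cda_document(1, seed = 2, patient_fields = c("id"))
  expect_false(grepl("<name>", doc, fixed = TRUE))
  expect_false(grepl("birthTime", doc, fixed = TRUE))
  expect_match(doc, "PAT-")
  full <- mini_cda_document(1, seed = 2)
  expect_match(full, "<given>")
  expect_match(full, "birthTime")
})

test_that("observation codes come from the committed table with matching units", {
  models <- fixture_models()
  node <- read_xml_instance(mini_cda_document(50, seed = 9), models,
                            "ClinicalDocument")
  body <- node_get(node_get(node_get(node, "component")[[1]],
                            "structuredBody")[[1]], "entry")
  tab <- fmlc:::LAB_CODE_TABLE
  for (en in body) {
    obs <- node_get(en, "observation")[[1]]
    code <- node_get(node_get(obs, "code")[[1]], "code")[[1]]
    unit <- node_get(node_get(obs, "value")[[1]], "unit")[[1]]
    row <- tab[tab$code == code, ]
    expect_identical(nrow(row), 1L)
    expect_identical(unit, row$unit)
  }
})

test_that("example maps load by name and nothing else", {
  expect_error(example_map("mystery"))
  expect_length(parse_fml(example_map("noop"))$groups[[1]]$rules, 0)
  expect_gte(length(parse_fml(example_map("cda_lab_bundle"))$concept_maps), 1)
  expect_silent(parse_fml(example_map("activity_supply")))
})

test_that("the case suite covers every supported function and operator", {
  cases <- fhirpath_case_suite()
  expect_gte(length(cases), 50)
  all_text <- paste(vapply(cases, function(c) c$expression, character(1)),
                    collapse = " ")
  for (fn in fmlc:::FP_FUNCTIONS) {
    expect_match(all_text, paste0(fn, "\\("), info = fn)
  }
  for (op in c("\\+", "-", "\\*", "/", " div ", " mod ", " and ", " or ",
               " xor ", " implies ", "=", "!=", "<", "<=", ">", ">=", "&",
               "\\|", " is ", " as ")) {
    expect_match(all_text, op, info = op)
  }
})
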