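test_that("the bundled maps parse to the expected structures", {
  ad <- parse_fml(example_map("activity_supply"))
  expect_length(ad$groups, 1)
  modes <- vapply(ad$groups[[1]]$inputs, function(i) i$mode, character(1))
  expect_identical(modes, c("source", "target"))

  noop <- parse_fml(example_map("noop"))
  expect_length(noop$groups[[1]]$rules, 0)

  lab <- parse_fml(example_map("cda_lab_bundle"))
  expect_length(lab$concept_maps, 1)
  cm <- lab$concept_maps[[1]]
  expect_length(cm$groups[[1]]$elements, 10)
  expect_identical(cm$groups[[1]]$elements[[1]],
                   list(source_code = "L1", relationship = "equivalent",
                        target_code = "718-7"))
})

test_that("rules carry names, list modes and embedded FHIRPath", {
  lab <- parse_fml(example_map("cda_lab_bundle"))
  g2 <- lab$groups[[2]]  # PatientRoleToPatient
  expect_identical(g2$rules[[1]]$name, "mkIdentifier")
  expect_identical(g2$rules[[1]]$source$list_mode, "first")
  g3 <- lab$groups[[3]]
  cond_rule <- g3$rules[[3]]
  expect_identical(cond_rule$source$condition$text, "code.exists()")
  expect_identical(cond_rule$source$condition$ast$name, "exists")
  # unnamed rules still get a positional diagnostic id
  expect_match(g2$rules[[1]]$rule_id, "^g2_r1$")
})

test_that("comments, quoted identifiers and escapes are handled", {
  txt <- paste0(
    'map "urn:m" = "M"\n',
    '// line comment\n',
    'uses "http://hl7.org/fhir" alias Patient as source\n',
    'uses "http://hl7.org/fhir" alias Patient as target\n',
    '/* block\ncomment */\n',
    'group G(source s : Patient, target t : Patient) {\n',
    '  s.id as v -> t."id" = v "quoted\\"name";\n',
    '}\n')
  ast <- parse_fml(txt)
  rule <- ast$groups[[1]]$rules[[1]]
  expect_identical(rule$targets[[1]]$element, "id")
  expect_identical(rule$name, "quoted\"name")
})

test_that("embedded FHIRPath may use the full expression character set", {
  txt <- paste0(
    'map "urn:fp" = "FP"\n',
    'uses "http://hl7.org/fhir" alias Patient as source\n',
    'uses "http://hl7.org/fhir" alias Patient as target\n',
    'group G(source s : Patient, target t : Patient) {\n',
    "  s.name as n first where (given[0] = 'Anna' and use != 'x') ->\n",
    "      t.birthDate = evaluate(family & '!') \"r1\";\n",
    '}\n')
  ast <- parse_fml(txt)
  cond <- ast$groups[[1]]$rules[[1]]$source$condition
  expect_identical(cond$text, "given[0] = 'Anna' and use != 'x'")
  both <- run_both_engines(ast, fixture_patient(fixture_models()))
  for (out in list(both$compiled, both$interpreted)) {
    expect_identical(fmlc:::primitive_lexical(node_get(out, "birthDate")[[1]]),
                     "Muster!")
  }
  # the same characters remain illegal outside an expression span
  expect_error(
    parse_fml('map "u" = "M"\ngroup G(source s : X, target t : Y) { s.a & -> t.b = v "n"; }'),
    class = "fmlc_fml_syntax_error")
})

test_that("unsupported and unknown transforms are rejected at parse time", {
  base <- 'map "urn:m" = "M"
group G(source s : X, target t : Y) {
  s.a as v -> t.b = %s(v) "r";
}'
  err <- expect_error(parse_fml(sprintf(base, "pointer")),
                      class = "fmlc_unsupported_transform")
  expect_match(conditionMessage(err), "pointer")
  expect_error(parse_fml(sprintf(base, "frobnicate")),
               class = "fmlc_unsupported_transform")
  expect_error(parse_fml('map "urn:m" = "M"\ngroup G(source s : X) {\n}'),
               class = "fmlc_fml_syntax_error")  # needs a target input
})

test_that("FML, StructureMap XML and StructureMap JSON yield one AST", {
  for (name in c("noop", "activity_supply", "cda_lab_bundle")) {
    ast <- parse_fml(example_map(name))
    for (fmt in c("json", "xml")) {
      round <- parse_structuremap(serialize_structuremap(ast, fmt), fmt)
      expect_identical(round, ast, info = paste(name, fmt))
    }
    x <- parse_structuremap(serialize_structuremap(ast, "xml"), "xml")
    j <- parse_structuremap(serialize_structuremap(ast, "json"), "json")
    expect_identical(x, j, info = name)
    # serialization is deterministic
    expect_identical(serialize_structuremap(ast, "json"),
                     serialize_structuremap(ast, "json"))
  }
})

test_that("StructureMap resources with unsupported elements are rejected", {
  expect_error(parse_structuremap(
    '{"resourceType": "StructureMap", "url": "u", "name": "n",
      "mystery": true, "group": []}', "json"),
    class = "fmlc_unsupported_feature")
  expect_error(parse_structuremap('{"resourceType": "Patient"}', "json"),
               class = "fmlc_parse_error")
})

test_that("empty-group resources parse to empty-rule ASTs", {
  noop <- parse_fml(example_map("noop"))
  sm <- serialize_structuremap(noop, "xml")
  back <- parse_structuremap(sm, "xml")
  expect_length(back$groups[[1]]$rules, 0)
})

test_that("imports resolve to a closed set with cycle detection", {
  lab <- parse_fml(example_map("cda_lab_bundle"))
  cm_text <- paste(readLines(fixture_path("conceptmaps", "lab-codes.xml")),
                   collapse = "\n")
  with_import <- parse_fml(paste0(
    'map "urn:root" = "Root"\n',
    'imports "urn:cm"\n',
    'uses "urn:hl7-org:v3" alias ClinicalDocument as source\n',
    'uses "http://hl7.org/fhir" alias Bundle as target\n',
    'group R(source s : ClinicalDocument, target t : Bundle) {\n}\n'))
  closed <- load_imports(with_import, list("urn:cm" = cm_text))
  expect_named(closed$conceptmaps,
               "http://example.org/fhir/ConceptMap/lab-codes-external")

  expect_error(load_imports(with_import, list()),
               class = "fmlc_unresolved_import")

  selfish_text <- paste0(
    'map "urn:self" = "Selfish"\n',
    'imports "urn:self"\n',
    'uses "urn:hl7-org:v3" alias ClinicalDocument as source\n',
    'uses "http://hl7.org/fhir" alias Bundle as target\n',
    'group S(source s : ClinicalDocument, target t : Bundle) {\n}\n')
  expect_error(load_imports(parse_fml(selfish_text),
                            list("urn:self" = selfish_text)),
               class = "fmlc_import_cycle")

  expect_length(load_imports(lab, list())$maps, 1)
})
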