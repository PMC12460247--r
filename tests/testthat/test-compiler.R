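test_that("generated programs carry group and variable names, never rule names", {
  models <- fixture_models()
  for (name in c("activity_supply", "cda_lab_bundle")) {
    ast <- parse_fml(example_map(name))
    prog <- compile_map(ast, models)
    for (g in ast$groups) {
      expect_identical(prog$symbol_table[[g$name]],
                       fmlc:::sanitize_identifier(g$name))
      expect_match(prog$source_text,
                   paste0(fmlc:::sanitize_identifier(g$name), " <- function"),
                   fixed = TRUE)
      for (inp in g$inputs) {
        expect_true(inp$name %in% names(prog$symbol_table), info = inp$name)
      }
    }
    collect_rule_names <- function(rules) {
      unlist(lapply(rules, function(r) {
        c(r$name, collect_rule_names(r$nested_rules))
      }))
    }
    for (rn in collect_rule_names(do.call(c, lapply(ast$groups, `[[`, "rules")))) {
      expect_false(grepl(rn, prog$source_text, fixed = TRUE), info = rn)
    }
  }
})

test_that("literals are embedded and now() reads the shared timestamp", {
  models <- fixture_models()
  prog <- compile_map(parse_fml(example_map("activity_supply")), models)
  expect_match(prog$source_text, "\"routine\"", fixed = TRUE)
  expect_match(prog$source_text, "fp_now(ctx)", fixed = TRUE)
  expect_false(grepl("Sys.time", prog$source_text, fixed = TRUE))
})

test_that("compilation is deterministic", {
  models <- fixture_models()
  ast <- parse_fml(example_map("cda_lab_bundle"))
  p1 <- compile_map(ast, models)
  p2 <- compile_map(ast, models)
  expect_identical(p1$source_text, p2$source_text)
  expect_identical(p1$symbol_table, p2$symbol_table)
})

test_that("the zero-rule map compiles to a program emitting an empty root", {
  models <- fixture_models()
  prog <- compile_map(parse_fml(example_map("noop")), models)
  env <- load_generated_program(prog)
  out <- env$fml__run(lab_input(2, seed = 1), test_ctx())
  expect_identical(write_xml_instance(out, models),
                   "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n<Bundle xmlns=\"http://hl7.org/fhir\"/>\n")
})

test_that("group extension emits the parent call first", {
  txt <- '
map "urn:ext" = "Ext"
uses "http://hl7.org/fhir" alias Patient as source
uses "http://hl7.org/fhir" alias Patient as target
group Base(source s : Patient, target t : Patient) {
  s.birthDate as b -> t.birthDate = b "base";
}
group Derived(source s : Patient, target t : Patient) extends Base {
  s.active as a -> t.active = a "own";
}'
  models <- fixture_models()
  prog <- compile_map(parse_fml(txt), models)
  lines <- strsplit(prog$source_text, "\n")[[1]]
  derived_at <- grep("^Derived <- function", lines)
  expect_identical(trimws(lines[derived_at + 1]), "Base(s, t, ctx)")
  # behaviour: both rules applied
  env <- load_generated_program(prog)
  pat <- fixture_patient(models)
  ast <- parse_fml(txt)
  # entry group is the first group (Base); run Derived directly
  out <- new_instance_node(models, "Patient")
  env$Derived(pat, out, test_ctx())
  expect_identical(fmlc:::primitive_lexical(node_get(out, "birthDate")[[1]]),
                   "1980-04-12")
  expect_identical(fmlc:::primitive_lexical(node_get(out, "active")[[1]]),
                   "true")
})

test_that("sanitization collisions and unknown references are compile errors", {
  models <- fixture_models()
  collide <- 'map "urn:c" = "C"
uses "http://hl7.org/fhir" alias Patient as source
uses "http://hl7.org/fhir" alias Patient as target
group "a-b"(source s : Patient, target t : Patient) {
}
group "a_b"(source s : Patient, target t : Patient) {
}'
  err <- expect_error(compile_map(parse_fml(collide), models),
                      class = "fmlc_compile_error")
  expect_match(conditionMessage(err), "a-b")

  bad_var <- 'map "urn:v" = "V"
uses "http://hl7.org/fhir" alias Patient as source
uses "http://hl7.org/fhir" alias Patient as target
group G(source s : Patient, target t : Patient) {
  s.name as n -> t.name = ghost "r";
}'
  expect_error(compile_map(parse_fml(bad_var), models),
               class = "fmlc_compile_error")

  bad_dep <- 'map "urn:d" = "D"
uses "http://hl7.org/fhir" alias Patient as source
uses "http://hl7.org/fhir" alias Patient as target
group G(source s : Patient, target t : Patient) {
  s.name as n -> t.name = create(\'HumanName\') as hn then Missing(n, hn) "r";
}'
  expect_error(compile_map(parse_fml(bad_dep), models),
               class = "fmlc_compile_error")
})

test_that("dependent groups resolve explicitly or uniquely by type", {
  txt <- 'map "urn:t" = "T"
uses "http://hl7.org/fhir" alias Patient as source
uses "http://hl7.org/fhir" alias Patient as target
group Entry(source s : Patient, target t : Patient) {
}
group NameMap(source s : HumanName, target t : HumanName) <<types>> {
  s.family as f -> t.family = f "fam";
}'
  ast <- parse_fml(txt)
  expect_identical(resolve_dependent_group(list(group = "NameMap"), ast)$name,
                   "NameMap")
  expect_error(resolve_dependent_group(list(group = "Nope"), ast),
               class = "fmlc_compile_error")
  expect_identical(
    resolve_dependent_group(list(source_type = "HumanName",
                                 target_type = "HumanName"), ast)$name,
    "NameMap")
  expect_error(
    resolve_dependent_group(list(source_type = "Patient",
                                 target_type = "HumanName"), ast),
    class = "fmlc_no_type_group")

  ambiguous <- paste0(txt, '
group NameMap2(source s : HumanName, target t : HumanName) <<types>> {
}')
  expect_error(
    resolve_dependent_group(list(source_type = "HumanName",
                                 target_type = "HumanName"),
                            parse_fml(ambiguous)),
    class = "fmlc_compile_error")
})

test_that("type-mode groups are invoked automatically on matching creates", {
  txt <- 'map "urn:auto" = "Auto"
uses "http://hl7.org/fhir" alias Patient as source
uses "http://hl7.org/fhir" alias Patient as target
group Entry(source s : Patient, target t : Patient) {
  s.name as n -> t.name = create(\'HumanName\') as hn "r1";
}
group NameMap(source sn : HumanName, target tn : HumanName) <<types>> {
  sn.family as f -> tn.family = f "fam";
}'
  ast <- parse_fml(txt)
  models <- fixture_models()
  pat <- fixture_patient(models)
  both <- run_both_engines(ast, pat)
  for (out in list(both$compiled, both$interpreted)) {
    fams <- lapply(node_get(out, "name"), node_get, element = "family")
    expect_identical(fams, list(list("Muster"), list()))
  }
})

test_that("FML comment embedding is off by default and flag-controlled", {
  models <- fixture_models()
  ast <- parse_fml(example_map("activity_supply"))
  plain <- compile_map(ast, models)
  expect_false(grepl("# src", plain$source_text, fixed = TRUE))
  commented <- compile_map(ast, models, emit_fml_comments = TRUE)
  expect_match(commented$source_text, "# src -> tgt.priority = copy",
               fixed = TRUE)
})

test_that("compiled programs are re-entrant and seed-stable", {
  models <- fixture_models()
  ast <- parse_fml(example_map("cda_lab_bundle"))
  env <- load_generated_program(compile_map(ast, models))
  input <- lab_input(3, seed = 9)
  runs <- lapply(1:2, function(i) {
    write_xml_instance(env$fml__run(input, test_ctx(ast, seed = 42)), models)
  })
  expect_identical(runs[[1]], runs[[2]])
  other <- write_xml_instance(env$fml__run(input, test_ctx(ast, seed = 43)),
                              models)
  expect_false(identical(runs[[1]], other))
  # different seeds differ only in generated identifiers
  expect_true(diff_canonical(runs[[1]], other, "xml")$equivalent)
})

test_that("generated programs run standalone from the command line", {
  models <- fixture_models()
  ast <- parse_fml(example_map("cda_lab_bundle"))
  prog <- compile_map(
    ast, models,
    schema_paths = c(fixture_path("schemas", "mini-cda.xsd"),
                     fixture_path("schemas", "mini-fhir.xsd")))
  dir <- tempfile("fmlc-prog-")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  prog_file <- file.path(dir, "cda_to_bundle.R")
  writeLines(prog$source_text, prog_file, sep = "")
  src_file <- file.path(dir, "report.xml")
  writeLines(mini_cda_document(2, seed = 3), src_file, sep = "")
  out_file <- file.path(dir, "bundle.json")
  status <- system2("Rscript",
                    c(prog_file, "-s", src_file, "-t", out_file,
                      "--seed", "7"),
                    stdout = TRUE, stderr = TRUE)
  expect_identical(attr(status, "status"), NULL)
  expect_true(file.exists(out_file))
  bundle <- read_fhir_json(paste(readLines(out_file), collapse = "\n"),
                           models, "Bundle")
  expect_length(node_get(bundle, "entry"), 3)  # patient + 2 observations
})
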