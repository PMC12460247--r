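# Shared fixtures: the bundled model set is immutable, so one instance
# serves the whole suite. A fixed timestamp is injected into execution
# contexts so outputs of the two engines can be compared byte-for-byte.

fixture_models <- function() load_fixture_models()

FIXED_NOW <- "2026-03-01T12:00:00+01:00"

test_ctx <- function(ast = NULL, seed = 1, now = FIXED_NOW) {
  models <- fixture_models()
  if (is.null(ast)) new_execution_context(models, seed = seed, now = now)
  else make_map_context(ast, models, seed = seed, now = now)
}

# run a map through both engines on the same input and return both outputs
run_both_engines <- function(ast, input_node, seed = 1, now = FIXED_NOW) {
  models <- fixture_models()
  interpreted <- interpret_map(ast, input_node, models,
                               ctx = make_map_context(ast, models,
                                                      seed = seed, now = now))
  prog <- compile_map(ast, models)
  env <- load_generated_program(prog)
  compiled <- env$fml__run(input_node,
                           make_map_context(ast, models, seed = seed,
                                            now = now))
  list(interpreted = interpreted, compiled = compiled, program = prog)
}

serialize_node <- function(node, fmt) {
  models <- fixture_models()
  if (fmt == "xml") write_xml_instance(node, models)
  else write_fhir_json(node, models)
}

lab_input <- function(n = 3, seed = 1) {
  read_xml_instance(mini_cda_document(n, seed = seed), fixture_models(),
                    "ClinicalDocument")
}

activity_input <- function(seed = 1) {
  read_xml_instance(mini_activity_definition(seed), fixture_models(),
                    "ActivityDefinition")
}
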