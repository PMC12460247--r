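# Bundled fixtures: mini-CDA and mini-FHIR schemas, example mappings, the
# FHIRPath case suite and the seeded synthetic laboratory-report generator.

the <- new.env(parent = emptyenv())  # package-level cache

#' Path to a bundled fixture file
#'
#' @param ... path components below `inst/extdata`
#' @return file path
#' @export
fixture_path <- function(...) {
  p <- system.file("extdata", ..., package = "fmlc", mustWork = TRUE)
  p
}

#' Load the bundled mini-CDA + mini-FHIR model set
#'
#' @param cached reuse a process-level cache (the descriptor set is
#'   read-only)
#' @return model set
#' @export
load_fixture_models <- function(cached = TRUE) {
  if (cached && !is.null(the$models)) return(the$models)
  models <- load_model_set(c(fixture_path("schemas", "mini-cda.xsd"),
                             fixture_path("schemas", "mini-fhir.xsd")))
  if (cached) the$models <- models
  models
}

#' Bundled example mapping text
#'
#' * `activity_supply`: ActivityDefinition to SupplyRequest (copy/create/
#'   `c()`/literal/now() coverage)
#' * `cda_lab_bundle`: mini-CDA laboratory report to a FHIR-style Bundle
#'   (iteration, embedded conceptmap translate, cc, uuid, cast, truncate)
#' * `noop`: a group with zero rules (the benchmark overhead baseline)
#'
#' @param name one of `"activity_supply"`, `"cda_lab_bundle"`, `"noop"`
#' @return FML text
#' @export
example_map <- function(name = c("activity_supply", "cda_lab_bundle", "noop")) {
  name <- match.arg(name)
  path <- fixture_path("maps", paste0(name, ".map"))
  paste(readLines(path, warn = FALSE), collapse = "\n")
}

# ---- seeded generator -------------------------------------------------------

# Park-Miller multiplicative generator: keeps fixture generation independent
# of R's global RNG stream.
pm_next <- function(state) (state * 16807) %% 2147483647
pm_unif <- function(state) state / 2147483647
pm_pick <- function(state, n) 1L + as.integer(floor(pm_unif(state) * n)) %% n

LAB_CODE_TABLE <- data.frame(
  code = paste0("L", 1:10),
  display = c("Hemoglobin", "Erythrocytes", "Leukocytes", "Platelets",
              "Glucose", "Creatinine", "Urea nitrogen", "ALT", "AST",
              "Cholesterol"),
  unit = c("g/dL", "10*6/uL", "10*3/uL", "10*3/uL", "mg/dL", "mg/dL",
           "mg/dL", "U/L", "U/L", "mg/dL"),
  lo = c(12, 4.2, 4, 150, 70, 0.6, 7, 10, 10, 120),
  hi = c(17, 5.9, 10, 400, 110, 1.2, 20, 50, 40, 240),
  stringsAsFactors = FALSE
)

GIVEN_NAMES <- c("Anna", "Max", "Eva", "Paul", "Lena", "Jonas")
FAMILY_NAMES <- c("Muster", "Huber", "Gruber", "Bauer", "Maier")

#' Generate a synthetic mini-CDA laboratory report
#'
#' Emulates the shape of a CDA laboratory report at a parameterized size:
#' a patient block plus `n_observations` coded observations with value,
#' unit and effective time drawn from seeded tables. The same
#' (n, seed, fields) configuration yields a byte-identical document.
#'
#' @param n_observations number of observation entries
#' @param seed integer seed
#' @param patient_fields subset of `c("name", "birth_date", "id")` to include
#' @param models model set (defaults to the bundled fixture schemas)
#' @return XML text, valid against the mini-CDA fixture schema
#' @export
mini_cda_document <- function(n_observations = 10, seed = 0,
                              patient_fields = c("name", "birth_date", "id"),
                              models = load_fixture_models()) {
  s <- (as.integer(seed) %% 2147483646L) + 1L
  doc <- new_instance_node(models, "ClinicalDocument")

  docid <- new_instance_node(models, "II")
  node_set_raw(docid, "root", list("1.2.40.0.34.3.1"))
  s <- pm_next(s)
  node_set_raw(docid, "extension", list(sprintf("DOC-%06d", pm_pick(s, 999999L))))
  node_append(doc, "id", docid)

  node_append(doc, "title", "Laboratory report")

  et <- new_instance_node(models, "TS")
  s <- pm_next(s)
  day <- pm_pick(s, 28L)
  node_set_raw(et, "value", list(sprintf("2024-03-%02dT09:00:00+01:00", day)))
  node_append(doc, "effectiveTime", et)

  rt <- new_instance_node(models, "RecordTarget")
  prole <- new_instance_node(models, "PatientRole")
  if ("id" %in% patient_fields) {
    pid <- new_instance_node(models, "II")
    node_set_raw(pid, "root", list("1.2.40.0.10.1.4.3.1"))
    s <- pm_next(s)
    node_set_raw(pid, "extension", list(sprintf("PAT-%04d", pm_pick(s, 9999L))))
    node_append(prole, "id", pid)
  }
  patient <- new_instance_node(models, "CdaPatient")
  if ("name" %in% patient_fields) {
    pn <- new_instance_node(models, "PN")
    s <- pm_next(s)
    node_append(pn, "given", GIVEN_NAMES[pm_pick(s, length(GIVEN_NAMES))])
    s <- pm_next(s)
    node_append(pn, "family", FAMILY_NAMES[pm_pick(s, length(FAMILY_NAMES))])
    node_append(patient, "name", pn)
  }
  if ("birth_date" %in% patient_fields) {
    bt <- new_instance_node(models, "TS")
    s <- pm_next(s); yr <- 1940L + pm_pick(s, 70L)
    s <- pm_next(s); mo <- pm_pick(s, 12L)
    s <- pm_next(s); dy <- pm_pick(s, 28L)
    node_set_raw(bt, "value",
                 list(sprintf("%04d-%02d-%02dT00:00:00+01:00", yr, mo, dy)))
    node_append(patient, "birthTime", bt)
  }
  node_append(prole, "patient", patient)
  node_append(rt, "patientRole", prole)
  node_append(doc, "recordTarget", rt)

  comp <- new_instance_node(models, "Component")
  body <- new_instance_node(models, "StructuredBody")
  for (k in seq_len(n_observations)) {
    s <- pm_next(s)
    row <- LAB_CODE_TABLE[pm_pick(s, nrow(LAB_CODE_TABLE)), ]
    obs <- new_instance_node(models, "CdaObservation")
    cd <- new_instance_node(models, "CD")
    node_set_raw(cd, "code", list(row$code))
    node_set_raw(cd, "codeSystem", list("urn:oid:1.2.40.0.34.5.11"))
    node_set_raw(cd, "displayName", list(row$display))
    node_append(obs, "code", cd)
    ots <- new_instance_node(models, "TS")
    s <- pm_next(s); hh <- pm_pick(s, 12L)
    s <- pm_next(s); mi <- pm_pick(s, 59L)
    node_set_raw(ots, "value",
                 list(sprintf("2024-03-%02dT%02d:%02d:00+01:00", day, hh, mi)))
    node_append(obs, "effectiveTime", ots)
    pq <- new_instance_node(models, "PQ")
    s <- pm_next(s)
    val <- row$lo + pm_unif(s) * (row$hi - row$lo)
    node_set_raw(pq, "value", list(canonical_decimal(round(val, 1))))
    node_set_raw(pq, "unit", list(row$unit))
    node_append(obs, "value", pq)
    entry <- new_instance_node(models, "ObservationEntry")
    node_append(entry, "observation", obs)
    node_append(body, "entry", entry)
  }
  node_append(comp, "structuredBody", body)
  node_append(doc, "component", comp)

  write_xml_instance(doc, models)
}

#' Generate a synthetic ActivityDefinition resource
#'
#' Companion input for the ActivityDefinition-to-SupplyRequest example map.
#'
#' @param seed integer seed
#' @param models model set
#' @return XML text valid against the mini-FHIR fixture schema
#' @export
mini_activity_definition <- function(seed = 0, models = load_fixture_models()) {
  s <- (as.integer(seed) %% 2147483646L) + 1L
  ad <- new_instance_node(models, "ActivityDefinition")
  s <- pm_next(s)
  fml_set_primitive <- function(node, element, type, lexical) {
    node_append(node, element, lexical)
  }
  fml_set_primitive(ad, "id", "id", sprintf("ad-%04d", pm_pick(s, 9999L)))
  fml_set_primitive(ad, "url", "uri", "http://example.org/ActivityDefinition/supply")
  fml_set_primitive(ad, "status", "code", "active")
  fml_set_primitive(ad, "name", "string", "BloodTubeSupply")
  cc <- new_instance_node(models, "CodeableConcept")
  coding <- new_instance_node(models, "Coding")
  fml_set_primitive(coding, "system", "uri", "http://snomed.info/sct")
  s <- pm_next(s)
  fml_set_primitive(coding, "code", "code", sprintf("%05d", pm_pick(s, 99999L)))
  fml_set_primitive(coding, "display", "string", "Specimen container")
  node_append(cc, "coding", coding)
  fml_set_primitive(cc, "text", "string", "Blood tube")
  node_append(ad, "code", cc)
  q <- new_instance_node(models, "Quantity")
  s <- pm_next(s)
  fml_set_primitive(q, "value", "decimal", as.character(pm_pick(s, 20L)))
  fml_set_primitive(q, "unit", "string", "units")
  node_append(ad, "quantity", q)
  write_xml_instance(ad, models)
}

# ---- FHIRPath case suite ----------------------------------------------------

#' Fixture Patient resource used by the FHIRPath case suite
#'
#' @param models model set
#' @return instance node
#' @export
fixture_patient <- function(models = load_fixture_models()) {
  json <- paste0(
    '{"resourceType": "Patient", "id": "p1",',
    ' "identifier": [{"system": "urn:sys", "value": "123"}],',
    ' "active": true,',
    ' "name": [',
    '  {"use": "official", "family": "Muster", "given": ["Anna", "Maria"]},',
    '  {"use": "nickname", "given": ["Anni"]}],',
    ' "birthDate": "1980-04-12"}')
  read_fhir_json(json, models, "Patient")
}

#' Load the committed FHIRPath case suite
#'
#' @return list of cases (name, expression, input, variables, expected)
#' @export
fhirpath_case_suite <- function() {
  data <- jsonlite::fromJSON(fixture_path("fhirpath", "cases.json"),
                             simplifyVector = FALSE)
  data$cases
}

#' Run one FHIRPath case through both execution paths
#'
#' Evaluates the case expression with the tree-walking evaluator and with
#' the emitted R expression text, and compares both results against the
#' expected collection.
#'
#' @param case one entry of [fhirpath_case_suite()]
#' @param models model set
#' @param ctx execution context (defaults to a fresh one)
#' @return list with `pass` flag plus the two result collections
#' @export
run_fhirpath_case <- function(case, models = load_fixture_models(),
                              ctx = new_execution_context(models)) {
  ast <- parse_fhirpath(case$expression)
  focus <- if (identical(case$input, "patient")) list(fixture_patient(models))
           else list()
  variables <- lapply(case$variables %||% list(), function(v) {
    if (is.numeric(v) && v == as.integer(v)) as.integer(v) else v
  })
  interp <- fhirpath_evaluate(ast, focus = focus, variables = variables,
                              ctx = ctx)
  scope <- character(0)
  eval_env <- new.env(parent = asNamespace("fmlc"))
  assign(".focus", focus, envir = eval_env)
  assign("ctx", ctx, envir = eval_env)
  for (nm in names(variables)) {
    rn <- paste0(".var_", nm)
    scope[nm] <- rn
    assign(rn, variables[[nm]], envir = eval_env)
  }
  emitted_text <- emit_expression(ast, focus_var = ".focus",
                                  scope_vars = scope,
                                  static_type = if (length(focus)) "Patient",
                                  models = models)
  emitted <- eval(parse(text = emitted_text), envir = eval_env)
  pass <- fp_result_matches(interp, case$expected) &&
    fp_result_matches(emitted, case$expected) &&
    fp_collections_equal(interp, emitted)
  list(pass = pass, interpreted = interp, emitted = emitted,
       emitted_text = emitted_text)
}

# compare a result collection against a JSON-derived expected collection
fp_result_matches <- function(result, expected) {
  expected <- expected %||% list()
  if (length(result) != length(expected)) return(FALSE)
  for (i in seq_along(result)) {
    r <- result[[i]]; e <- expected[[i]]
    ok <- if (is.logical(e)) {
      is.logical(r) && identical(unclass(r), e)
    } else if (is.numeric(e)) {
      fp_item_class(r) %in% c("integer", "decimal") &&
        abs(as.numeric(r) - e) < 1e-9
    } else {
      fp_item_class(r) %in% c("string", "date", "datetime") &&
        identical(as.character(r), as.character(e))
    }
    if (!ok) return(FALSE)
  }
  TRUE
}

#' Pairwise equality of two result collections
#'
#' @param a,b collections
#' @return logical
#' @export
fp_collections_equal <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  for (i in seq_along(a)) if (!fp_item_eq(a[[i]], b[[i]])) return(FALSE)
  TRUE
}

# ---- seeded random expression generator -------------------------------------

#' Generate seeded random FHIRPath expressions from the supported grammar
#'
#' Expressions are typed during generation (numeric, string, boolean,
#' collection sub-grammars) so that every generated expression evaluates
#' without error over the fixture Patient; used for the dual-path
#' (evaluator vs emitted code) agreement property.
#'
#' @param n number of expressions
#' @param seed integer seed
#' @return character vector of expression texts
#' @export
fhirpath_random_exprs <- function(n, seed = 1) {
  st <- new.env(parent = emptyenv())
  st$s <- (as.integer(seed) %% 2147483646L) + 1L
  draw <- function(k) { st$s <- pm_next(st$s); pm_pick(st$s, k) }
  pick <- function(v) v[[draw(length(v))]]

  num <- function(depth) {
    if (depth <= 0) return(pick(c("1", "2", "3", "7", "10", "0", "1.5", "2.25")))
    switch(draw(7L),
      paste0("(", num(depth - 1L), " + ", num(depth - 1L), ")"),
      paste0("(", num(depth - 1L), " - ", num(depth - 1L), ")"),
      paste0("(", num(depth - 1L), " * ", num(depth - 1L), ")"),
      paste0("(", num(depth - 1L), " div ", num(depth - 1L), ")"),
      paste0("(", num(depth - 1L), " mod ", num(depth - 1L), ")"),
      "name.count()",
      "name.given.count()"
    )
  }
  str <- function(depth) {
    if (depth <= 0) return(pick(c("'alpha'", "'beta'", "'hello'", "'x'")))
    switch(draw(5L),
      paste0("(", str(depth - 1L), " & ", str(depth - 1L), ")"),
      paste0("(", str(depth - 1L), " + ", str(depth - 1L), ")"),
      "name.first().family",
      "identifier.value.first()",
      paste0(str(depth - 1L), ".substring(", pick(c("0", "1", "2")), ")")
    )
  }
  bool <- function(depth) {
    if (depth <= 0) return(pick(c("true", "false", "active")))
    switch(draw(9L),
      paste0("(", bool(depth - 1L), " and ", bool(depth - 1L), ")"),
      paste0("(", bool(depth - 1L), " or ", bool(depth - 1L), ")"),
      paste0("(", bool(depth - 1L), " xor ", bool(depth - 1L), ")"),
      paste0("(", bool(depth - 1L), " implies ", bool(depth - 1L), ")"),
      paste0("(", num(depth - 1L), " ", pick(c("=", "!=", "<", "<=", ">", ">=")),
             " ", num(depth - 1L), ")"),
      paste0("(", str(depth - 1L), " = ", str(depth - 1L), ")"),
      paste0(str(depth - 1L), ".contains(", str(0L), ")"),
      paste0(str(depth - 1L), ".startsWith(", str(0L), ")"),
      paste0(coll(depth - 1L), ".exists()")
    )
  }
  coll <- function(depth) {
    base <- pick(c("name", "name.given", "identifier",
                   "name.where(use = 'official')", "name.select(given)"))
    if (depth <= 0) return(base)
    switch(draw(5L),
      paste0("(", coll(depth - 1L), " | ", coll(depth - 1L), ")"),
      paste0(coll(depth - 1L), "[", pick(c("0", "1", "4")), "]"),
      paste0(coll(depth - 1L), ".first()"),
      paste0(coll(depth - 1L), ".last()"),
      base
    )
  }
  any_expr <- function() {
    d <- draw(3L)
    switch(draw(5L),
      num(d), str(d), bool(d), coll(d),
      paste0("iif(", bool(1L), ", ", num(1L), ", ", num(1L), ")")
    )
  }
  vapply(seq_len(n), function(i) any_expr(), character(1))
}
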