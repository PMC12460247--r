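# fmlc — compile FHIR Mapping Language transformations to R

Health data rarely arrives in the format it is needed in: national EHR
systems publish HL7 v3 CDA documents, modern exchange and secondary-use
infrastructures expect FHIR resources, and local laboratory codes must be
translated to reference terminologies such as LOINC. The FHIR Mapping
Language (FML) expresses such conversions declaratively — groups of rules
over typed source and target structures, with embedded FHIRPath expressions
and ConceptMap-based code translation — but most engines execute FML by
interpretation, re-dispatching every rule on every document.

`fmlc` is a compiler for a substantial FML subset. It parses FML text or
StructureMap resources (XML/JSON) into one AST and emits a standalone,
human-traceable R transformation program over typed models derived from XML
Schema:

* generated functions are **named after their FML groups**; parameter and
  variable identifiers are preserved (sanitization only), and rule names are
  deliberately excluded — the generated source reads like the mapping;
* embedded FHIRPath compiles in a single pass to concise R expressions:
  string literals are embedded verbatim, `now()` becomes one
  execution-scoped timestamp evaluated once per run, and statically typed
  navigations compile to direct accessors while unknown types fall back to
  runtime dispatch;
* ConceptMap translation, cardinality-aware assignment and a seeded UUID
  source live in a small runtime shared with a **reference interpreter**
  (`interpret_map()`), which executes the same AST directly and serves as
  the conformance oracle: compiled and interpreted outputs must be
  canonically identical (`diff_canonical()`), generated random identifiers
  being the only permitted difference class.

The package bundles mini-CDA and mini-FHIR fixture schemas, three example
mappings (a zero-rule baseline, an ActivityDefinition-to-SupplyRequest
conversion, and a CDA laboratory report to FHIR Bundle conversion with an
embedded concept map), a FHIRPath case suite, a seeded synthetic
laboratory-report generator, and a benchmark harness measuring
overhead-adjusted runtimes of compiled versus interpreted execution.

## A worked example

```r
library(fmlc)
models <- load_fixture_models()
ast <- parse_fml(example_map("activity_supply"))
prog <- compile_map(ast, models)
cat(prog$source_text)
```

The generated program mirrors the mapping group for group:

```r
# Transformation program generated from map "ActivityDefinitionToSupplyRequest"
# ActivityDefinition -> SupplyRequest

ActivityDefinitionToSupplyRequest <- function(src, tgt, ctx) {
  .items1 <- fml_children(src, "id")
  for (vid in .items1) {
    idf <- fml_add1(tgt, "identifier", fml_new_node("Identifier", NULL))
    fml_set1(idf, "value", fml_copy(vid))
  }
  fml_set1(tgt, "status", "draft")
  fml_set1(tgt, "priority", "routine")
  ...
```

Executing it on a synthetic input and printing the FHIR JSON projection:

```r
input <- read_xml_instance(mini_activity_definition(7), models,
                           "ActivityDefinition")
ctx <- make_map_context(ast, models, seed = 1,
                        now = "2026-03-01T12:00:00+01:00")
env <- load_generated_program(prog)
cat(write_fhir_json(env$fml__run(input, ctx), models))
```

```json
{
  "resourceType": "SupplyRequest",
  "identifier": [
    {
      "value": "ad-0001"
    }
  ],
  "status": "draft",
  "category": {
    "coding": [
      {
        "system": "http://terminology.hl7.org/CodeSystem/supplyrequest-kind",
        "code": "non-stock",
        "display": "Non-Stock"
      }
    ]
  },
  "priority": "routine",
  "itemCodeableConcept": {
    "coding": [
      {
        "system": "http://snomed.info/sct",
        "code": "05231",
        "display": "Specimen container"
      }
    ],
    "text": "Blood tube"
  },
  "quantity": {
    "value": 1,
    "unit": "units"
  },
  "authoredOn": "2026-03-01T12:00:00+01:00"
}
```

The `status` and `priority` values are the embedded string literals from the
mapping; `authoredOn` is the execution-scoped timestamp (here injected for
reproducibility); the identifier value was copied from the source resource's
`id`. Interpreting the same mapping (`interpret_map(ast, input, models,
ctx = ...)`) produces a canonically identical document.

## Command line

```sh
Rscript inst/cli/fmlc.R -m CdaToBundle.map -co cdaToBundle.R   # compile
Rscript cdaToBundle.R -s LabReport.cda.xml -t bundle.fhir.xml  # run standalone
Rscript inst/cli/fmlc.R -m CdaToBundle.map -s in.xml -t out.json --interpret
Rscript inst/cli/fmlc.R benchmark --n 1000
```

Input and output formats are inferred from file extensions (`.xml` /
`.json`). Exit codes: 0 ok, 2 usage, 3 compile error, 4 mapping error.

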