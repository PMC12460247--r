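Package: fmlc
Title: Compile FHIR Mapping Language Transformations to R
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Parses FHIR Mapping Language (FML) text and StructureMap
    resources into a common abstract syntax tree and compiles them -- including
    embedded FHIRPath expressions and ConceptMap-based terminology translation
    -- into standalone, human-traceable R transformation programs over typed
    data models derived from XML Schema. Ships a reference interpreter that
    executes the same mappings directly over in-memory documents, a canonical
    diff for cross-engine conformance checking, mini-CDA and mini-FHIR fixture
    schemas with a seeded synthetic laboratory-report generator, and a
    benchmark harness measuring overhead-adjusted runtimes of the compiled
    versus interpreted execution paths.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    jsonlite,
    compiler,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
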