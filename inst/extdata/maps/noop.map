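// Minimal mapping without transformation instructions: used as the
// overhead baseline in benchmarks.
map "http://example.org/fhir/StructureMap/Noop" = "Noop"

uses "urn:hl7-org:v3" alias ClinicalDocument as source
uses "http://hl7.org/fhir" alias Bundle as target

group Noop(source cda : ClinicalDocument, target bundle : Bundle) {
}
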