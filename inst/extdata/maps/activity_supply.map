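// Order-catalog conversion: ActivityDefinition -> SupplyRequest.
// Exercises copy (literal and variable), create, c(), evaluate/now()
// and chained target variables.
map "http://example.org/fhir/StructureMap/ActivityDefinitionToSupplyRequest" = "ActivityDefinitionToSupplyRequest"

uses "http://hl7.org/fhir" alias ActivityDefinition as source
uses "http://hl7.org/fhir" alias SupplyRequest as target

group ActivityDefinitionToSupplyRequest(source src : ActivityDefinition, target tgt : SupplyRequest) {
  src.id as vid -> tgt.identifier = create('Identifier') as idf, idf.value = vid "mkIdentifier";
  src -> tgt.status = 'draft' "mkStatus";
  src -> tgt.priority = 'routine' "mkPriority";
  src -> tgt.category = create('CodeableConcept') as cat,
         cat.coding = c('http://terminology.hl7.org/CodeSystem/supplyrequest-kind', 'non-stock') as ck,
         ck.display = 'Non-Stock' "mkCategory";
  src.code as cd -> tgt.itemCodeableConcept = cd "mkItem";
  src.quantity as qty -> tgt.quantity = qty "mkQuantity";
  src -> tgt.authoredOn = evaluate(src, now()) "mkAuthoredOn";
}
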