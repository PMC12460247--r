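{
  "comment": "Hand-written manifest of the mini-FHIR fixture schema: declared type names in declaration order, and the declared type of every (type, element) pair. Used as the oracle for schema parsing and element-type resolution tests.",
  "types": [
    "string", "code", "uri", "id", "boolean", "integer", "decimal",
    "date", "dateTime", "instant",
    "Coding", "CodeableConcept", "Quantity", "Identifier", "HumanName",
    "Reference", "Resource", "Patient", "Observation", "ActivityDefinition",
    "SupplyRequest", "ResourceContainer", "BundleEntry", "Bundle"
  ],
  "elements": {
    "string.value": "xs:string",
    "code.value": "xs:string",
    "uri.value": "xs:anyURI",
    "id.value": "xs:string",
    "boolean.value": "xs:boolean",
    "integer.value": "xs:integer",
    "decimal.value": "xs:decimal",
    "date.value": "xs:date",
    "dateTime.value": "xs:dateTime",
    "instant.value": "xs:dateTime",
    "Coding.system": "uri",
    "Coding.code": "code",
    "Coding.display": "string",
    "CodeableConcept.coding": "Coding",
    "CodeableConcept.text": "string",
    "Quantity.value": "decimal",
    "Quantity.unit": "string",
    "Quantity.system": "uri",
    "Quantity.code": "code",
    "Identifier.system": "uri",
    "Identifier.value": "string",
    "HumanName.use": "code",
    "HumanName.family": "string",
    "HumanName.given": "string",
    "Reference.reference": "string",
    "Reference.display": "string",
    "Resource.id": "id",
    "Patient.id": "id",
    "Patient.identifier": "Identifier",
    "Patient.active": "boolean",
    "Patient.name": "HumanName",
    "Patient.birthDate": "date",
    "Observation.id": "id",
    "Observation.identifier": "Identifier",
    "Observation.status": "code",
    "Observation.category": "CodeableConcept",
    "Observation.code": "CodeableConcept",
    "Observation.subject": "Reference",
    "Observation.effectiveDateTime": "dateTime",
    "Observation.issued": "instant",
    "Observation.valueQuantity": "Quantity",
    "Observation.valueString": "string",
    "ActivityDefinition.id": "id",
    "ActivityDefinition.url": "uri",
    "ActivityDefinition.status": "code",
    "ActivityDefinition.name": "string",
    "ActivityDefinition.code": "CodeableConcept",
    "ActivityDefinition.quantity": "Quantity",
    "SupplyRequest.id": "id",
    "SupplyRequest.identifier": "Identifier",
    "SupplyRequest.status": "code",
    "SupplyRequest.category": "CodeableConcept",
    "SupplyRequest.priority": "code",
    "SupplyRequest.itemCodeableConcept": "CodeableConcept",
    "SupplyRequest.itemReference": "Reference",
    "SupplyRequest.quantity": "Quantity",
    "SupplyRequest.authoredOn": "dateTime",
    "ResourceContainer.Patient": "Patient",
    "ResourceContainer.Observation": "Observation",
    "BundleEntry.fullUrl": "uri",
    "BundleEntry.resource": "ResourceContainer",
    "Bundle.id": "id",
    "Bundle.type": "code",
    "Bundle.timestamp": "instant",
    "Bundle.entry": "BundleEntry"
  }
}
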