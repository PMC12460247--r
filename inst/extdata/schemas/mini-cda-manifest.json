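{
  "comment": "Hand-written manifest of the mini-CDA fixture schema (declaration order; element type per (type, element) pair).",
  "types": [
    "II", "TS", "CD", "PQ", "ST", "PN",
    "CdaPatient", "PatientRole", "RecordTarget",
    "CdaObservation", "ObservationEntry", "StructuredBody", "Component",
    "ClinicalDocument"
  ],
  "elements": {
    "II.root": "xs:string",
    "II.extension": "xs:string",
    "TS.value": "xs:string",
    "CD.code": "xs:string",
    "CD.codeSystem": "xs:string",
    "CD.displayName": "xs:string",
    "PQ.value": "xs:string",
    "PQ.unit": "xs:string",
    "PN.given": "ST",
    "PN.family": "ST",
    "CdaPatient.name": "PN",
    "CdaPatient.birthTime": "TS",
    "PatientRole.id": "II",
    "PatientRole.patient": "CdaPatient",
    "RecordTarget.patientRole": "PatientRole",
    "CdaObservation.code": "CD",
    "CdaObservation.effectiveTime": "TS",
    "CdaObservation.value": "PQ",
    "ObservationEntry.observation": "CdaObservation",
    "StructuredBody.entry": "ObservationEntry",
    "Component.structuredBody": "StructuredBody",
    "ClinicalDocument.id": "II",
    "ClinicalDocument.title": "ST",
    "ClinicalDocument.effectiveTime": "TS",
    "ClinicalDocument.recordTarget": "RecordTarget",
    "ClinicalDocument.component": "Component"
  }
}
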