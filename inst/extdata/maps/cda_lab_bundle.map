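// Laboratory-report document conversion: mini-CDA ClinicalDocument ->
// FHIR-style Bundle. Exercises iteration over repeating entries, an
// embedded conceptmap (local lab codes -> LOINC) via translate, uuid(),
// append, cast, truncate, cc() and dependent group calls over untyped
// (dynamically dispatched) inputs.
map "http://example.org/fhir/StructureMap/CdaLabToBundle" = "CdaLabToBundle"

uses "urn:hl7-org:v3" alias ClinicalDocument as source
uses "http://hl7.org/fhir" alias Bundle as target

conceptmap "http://example.org/fhir/ConceptMap/lab-codes" {
  prefix s = "urn:oid:1.2.40.0.34.5.11"
  prefix t = "http://loinc.org"

  s:L1 == t:"718-7"
  s:L2 == t:"789-8"
  s:L3 == t:"6690-2"
  s:L4 == t:"777-3"
  s:L5 == t:"2345-7"
  s:L6 == t:"2160-0"
  s:L7 == t:"3094-0"
  s:L8 == t:"1742-6"
  s:L9 == t:"1920-8"
  s:L10 == t:"2093-3"
}

group CdaToBundle(source cda : ClinicalDocument, target bundle : Bundle) {
  cda -> bundle.type = 'collection' "mkBundleType";
  cda -> bundle.timestamp = evaluate(cda, now()) "mkTimestamp";
  cda.recordTarget as rt then {
    rt.patientRole as pr -> bundle.entry as e,
        e.fullUrl = uuid(),
        e.resource as rc,
        rc.Patient as pat
        then PatientRoleToPatient(pr, pat) "mkPatientEntry";
  } "mkRecordTarget";
  cda.component as comp then {
    comp.structuredBody as body then {
      body.entry as en then {
        en.observation as obs -> bundle.entry as oe,
            oe.fullUrl = uuid(),
            oe.resource as orc,
            orc.Observation as fo
            then ObservationToFhir(obs, fo) "mkObservationEntry";
      } "mkEntries";
    } "mkBody";
  } "mkComponent";
}

group PatientRoleToPatient(source pr, target pat) {
  pr.id as iid first -> pat.identifier = create('Identifier') as pid then {
    iid.root as r -> pid.system = append('urn:oid:', r) "mkIdSystem";
    iid.extension as x -> pid.value = x "mkValue";
  } "mkIdentifier";
  pr.patient as p then {
    p.name as pn -> pat.name = create('HumanName') as hn then {
      pn.given as g -> hn.given = g "mkGiven";
      pn.family as f -> hn.family = f "mkFamily";
    } "mkName";
    p.birthTime as bt then {
      bt.value as bv -> pat.birthDate = truncate(bv, 10) "mkBirthDate";
    } "mkBirthTime";
  } "mkPatientDetails";
}

group ObservationToFhir(source obs, target o) {
  obs -> o.status = 'final' "mkObsStatus";
  obs -> o.category = cc('http://terminology.hl7.org/CodeSystem/observation-category', 'laboratory') "mkObsCategory";
  obs.code as c where (code.exists()) -> o.code = create('CodeableConcept') as occ then {
    c.code as lc -> occ.coding = translate(lc, 'http://example.org/fhir/ConceptMap/lab-codes', 'Coding') as cdg then {
      c.displayName as dn -> cdg.display = dn "mkCodingDisplay";
    } "mkCoding";
    c.displayName as dt -> occ.text = dt "mkCodeText";
  } "mkObsCode";
  obs.effectiveTime as et then {
    et.value as ev -> o.effectiveDateTime = cast(ev, 'dateTime') "mkEffective";
  } "mkEffectiveTime";
  obs -> o.issued = evaluate(obs, now()) "mkIssued";
  obs.value as v -> o.valueQuantity = create('Quantity') as q then {
    v.value as vv -> q.value = cast(vv, 'decimal') "mkQValue";
    v.unit as vu -> q.unit = vu "mkQUnit";
  } "mkValue";
}
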