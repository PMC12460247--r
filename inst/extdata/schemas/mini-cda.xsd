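<?xml version="1.0" encoding="UTF-8"?>
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema"
           targetNamespace="urn:hl7-org:v3"
           elementFormDefault="qualified">

  <!-- CDA-style data types -->
  <xs:complexType name="II">
    <xs:attribute name="root" type="xs:string"/>
    <xs:attribute name="extension" type="xs:string"/>
  </xs:complexType>
  <xs:complexType name="TS">
    <xs:attribute name="value" type="xs:string"/>
  </xs:complexType>
  <xs:complexType name="CD">
    <xs:attribute name="code" type="xs:string"/>
    <xs:attribute name="codeSystem" type="xs:string"/>
    <xs:attribute name="displayName" type="xs:string"/>
  </xs:complexType>
  <xs:complexType name="PQ">
    <xs:attribute name="value" type="xs:string"/>
    <xs:attribute name="unit" type="xs:string"/>
  </xs:complexType>
  <xs:complexType name="ST">
    <xs:simpleContent>
      <xs:extension base="xs:string"/>
    </xs:simpleContent>
  </xs:complexType>
  <xs:complexType name="PN">
    <xs:sequence>
      <xs:element name="given" type="ST" minOccurs="0" maxOccurs="unbounded"/>
      <xs:element name="family" type="ST" minOccurs="0"/>
    </xs:sequence>
  </xs:complexType>

  <!-- document skeleton -->
  <xs:complexType name="CdaPatient">
    <xs:sequence>
      <xs:element name="name" type="PN" minOccurs="0"/>
      <xs:element name="birthTime" type="TS" minOccurs="0"/>
    </xs:sequence>
  </xs:complexType>
  <xs:complexType name="PatientRole">
    <xs:sequence>
      <xs:element name="id" type="II" minOccurs="0" maxOccurs="unbounded"/>
      <xs:element name="patient" type="CdaPatient" minOccurs="0"/>
    </xs:sequence>
  </xs:complexType>
  <xs:complexType name="RecordTarget">
    <xs:sequence>
      <xs:element name="patientRole" type="PatientRole" minOccurs="0"/>
    </xs:sequence>
  </xs:complexType>

  <xs:complexType name="CdaObservation">
    <xs:sequence>
      <xs:element name="code" type="CD" minOccurs="0"/>
      <xs:element name="effectiveTime" type="TS" minOccurs="0"/>
      <xs:element name="value" type="PQ" minOccurs="0"/>
    </xs:sequence>
  </xs:complexType>
  <xs:complexType name="ObservationEntry">
    <xs:sequence>
      <xs:element name="observation" type="CdaObservation" minOccurs="0"/>
    </xs:sequence>
  </xs:complexType>
  <xs:complexType name="StructuredBody">
    <xs:sequence>
      <xs:element name="entry" type="ObservationEntry" minOccurs="0" maxOccurs="unbounded"/>
    </xs:sequence>
  </xs:complexType>
  <xs:complexType name="Component">
    <xs:sequence>
      <xs:element name="structuredBody" type="StructuredBody" minOccurs="0"/>
    </xs:sequence>
  </xs:complexType>

  <xs:complexType name="ClinicalDocument">
    <xs:sequence>
      <xs:element name="id" type="II" minOccurs="0"/>
      <xs:element name="title" type="ST" minOccurs="0"/>
      <xs:element name="effectiveTime" type="TS" minOccurs="0"/>
      <xs:element name="recordTarget" type="RecordTarget" minOccurs="0"/>
      <xs:element name="component" type="Component" minOccurs="0"/>
    </xs:sequence>
  </xs:complexType>

  <xs:element name="ClinicalDocument" type="ClinicalDocument"/>
</xs:schema>
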