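<?xml version="1.0" encoding="UTF-8"?>
<ConceptMap xmlns="http://hl7.org/fhir">
  <url value="http://example.org/fhir/ConceptMap/lab-codes-external"/>
  <group>
    <source value="urn:oid:1.2.40.0.34.5.11"/>
    <target value="http://loinc.org"/>
    <element>
      <code value="L1"/>
      <target>
        <code value="718-7"/>
        <relationship value="equivalent"/>
      </target>
    </element>
    <element>
      <code value="L2"/>
      <target>
        <code value="789-8"/>
        <relationship value="equivalent"/>
      </target>
    </element>
    <element>
      <code value="L3"/>
      <target>
        <code value="6690-2"/>
        <relationship value="equivalent"/>
      </target>
    </element>
    <element>
      <code value="L4"/>
      <target>
        <code value="777-3"/>
        <relationship value="equivalent"/>
      </target>
    </element>
    <element>
      <code value="L5"/>
      <target>
        <code value="2345-7"/>
        <relationship value="wider"/>
      </target>
    </element>
  </group>
</ConceptMap>
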