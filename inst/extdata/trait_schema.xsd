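<?xml version="1.0" encoding="UTF-8"?>
<!-- XML dialect written by floratrait::write_trait_xml(). Attribute order in
     emitted files is fixed as listed here. Optional attributes are omitted
     when empty. -->
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema">
  <xs:element name="description">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="statement" minOccurs="0" maxOccurs="unbounded">
          <xs:complexType>
            <xs:choice minOccurs="0" maxOccurs="unbounded">
              <xs:element name="structure">
                <xs:complexType>
                  <xs:sequence>
                    <xs:element name="character" minOccurs="0"
                                maxOccurs="unbounded">
                      <xs:complexType>
                        <xs:attribute name="id" use="required"/>
                        <xs:attribute name="name" use="required"/>
                        <xs:attribute name="value" use="required"/>
                        <xs:attribute name="char_type"/>
                        <xs:attribute name="from"/>
                        <xs:attribute name="to"/>
                        <xs:attribute name="from_unit"/>
                        <xs:attribute name="to_unit"/>
                        <xs:attribute name="atypical_from"/>
                        <xs:attribute name="atypical_to"/>
                        <xs:attribute name="constraint"/>
                        <xs:attribute name="notes"/>
                      </xs:complexType>
                    </xs:element>
                  </xs:sequence>
                  <xs:attribute name="id" use="required"/>
                  <xs:attribute name="name" use="required"/>
                  <xs:attribute name="constraint"/>
                  <xs:attribute name="modifier"/>
                  <xs:attribute name="ontology_id"/>
                  <xs:attribute name="notes"/>
                </xs:complexType>
              </xs:element>
              <xs:element name="relation">
                <xs:complexType>
                  <xs:attribute name="id" use="required"/>
                  <xs:attribute name="name" use="required"/>
                  <xs:attribute name="from" use="required"/>
                  <xs:attribute name="to" use="required"/>
                  <xs:attribute name="negated"/>
                </xs:complexType>
              </xs:element>
              <xs:element name="constraint_preposition" type="spanType"/>
              <xs:element name="constraint_verb" type="spanType"/>
              <xs:element name="verb_string" type="spanType"/>
            </xs:choice>
            <xs:attribute name="id" use="required"/>
            <xs:attribute name="text" use="required"/>
          </xs:complexType>
        </xs:element>
      </xs:sequence>
      <xs:attribute name="taxon_name" use="required"/>
    </xs:complexType>
  </xs:element>
  <xs:complexType name="spanType">
    <xs:attribute name="text" use="required"/>
    <xs:attribute name="attached_to"/>
  </xs:complexType>
</xs:schema>
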