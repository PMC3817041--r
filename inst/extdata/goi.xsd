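<?xml version="1.0" encoding="UTF-8"?>
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema">
  <xs:element name="goi">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="node" minOccurs="0" maxOccurs="unbounded">
          <xs:complexType>
            <xs:attribute name="id" type="xs:string" use="required"/>
            <xs:attribute name="label" type="xs:string" use="required"/>
            <xs:attribute name="category" type="xs:string" use="required"/>
            <xs:attribute name="colour" type="xs:string" use="required"/>
            <xs:attribute name="x" type="xs:double" use="required"/>
            <xs:attribute name="y" type="xs:double" use="required"/>
          </xs:complexType>
        </xs:element>
        <xs:element name="edge" minOccurs="0" maxOccurs="unbounded">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="url" type="xs:string" minOccurs="0"
                          maxOccurs="unbounded"/>
            </xs:sequence>
            <xs:attribute name="source" type="xs:string" use="required"/>
            <xs:attribute name="target" type="xs:string" use="required"/>
            <xs:attribute name="weight" type="xs:double" use="required"/>
            <xs:attribute name="sign" type="xs:string"/>
            <xs:attribute name="colour" type="xs:string"/>
          </xs:complexType>
        </xs:element>
      </xs:sequence>
      <xs:attribute name="level" type="xs:integer" use="required"/>
      <xs:attribute name="centre" type="xs:string"/>
    </xs:complexType>
  </xs:element>
</xs:schema>
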