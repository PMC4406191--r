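<?xml version="1.0" encoding="UTF-8"?>
<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"
         xmlns:bp="http://www.biopax.org/release/biopax-level3.owl#"
         xmlns:owl="http://www.w3.org/2002/07/owl#">
  <bp:Pathway rdf:about="http://example.org/toy#pw1">
    <bp:displayName>Toy pathway</bp:displayName>
    <bp:pathwayComponent rdf:resource="http://example.org/toy#r1"/>
    <bp:pathwayComponent rdf:resource="http://example.org/toy#r2"/>
  </bp:Pathway>
  <bp:BiochemicalReaction rdf:about="http://example.org/toy#r1">
    <bp:displayName>R1: P1 to P2</bp:displayName>
    <bp:left rdf:resource="http://example.org/toy#p1"/>
    <bp:right rdf:resource="http://example.org/toy#p2"/>
  </bp:BiochemicalReaction>
  <bp:BiochemicalReaction rdf:about="http://example.org/toy#r2">
    <bp:displayName>R2: P3 to P4</bp:displayName>
    <bp:left rdf:resource="http://example.org/toy#p3"/>
    <bp:right rdf:resource="http://example.org/toy#p4"/>
  </bp:BiochemicalReaction>
  <bp:Complex rdf:about="http://example.org/toy#cx1">
    <bp:displayName>P1-P2 complex</bp:displayName>
    <bp:component rdf:resource="http://example.org/toy#p1"/>
    <bp:component rdf:resource="http://example.org/toy#p2"/>
  </bp:Complex>
  <bp:Protein rdf:about="http://example.org/toy#p1">
    <bp:displayName>Protein 1</bp:displayName>
    <bp:entityReference rdf:resource="http://example.org/toy#pr1"/>
  </bp:Protein>
  <bp:Protein rdf:about="http://example.org/toy#p2">
    <bp:displayName>Protein 2</bp:displayName>
    <bp:entityReference rdf:resource="http://example.org/toy#pr2"/>
  </bp:Protein>
  <bp:Protein rdf:about="http://example.org/toy#p3">
    <bp:displayName>Protein 3</bp:displayName>
    <bp:entityReference rdf:resource="http://example.org/toy#pr3"/>
  </bp:Protein>
  <bp:Protein rdf:about="http://example.org/toy#p4">
    <bp:displayName>Protein 4</bp:displayName>
  </bp:Protein>
  <bp:ProteinReference rdf:about="http://example.org/toy#pr1"/>
  <bp:ProteinReference rdf:about="http://example.org/toy#pr2"/>
  <bp:ProteinReference rdf:about="http://example.org/toy#pr3"/>
</rdf:RDF>
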