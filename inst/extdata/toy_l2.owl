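<?xml version="1.0" encoding="UTF-8"?>
<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"
         xmlns:bp="http://www.biopax.org/release/biopax-level2.owl#"
         xmlns:owl="http://www.w3.org/2002/07/owl#">
  <bp:pathway rdf:about="http://example.org/toy#pw1">
    <bp:NAME>Toy pathway</bp:NAME>
    <bp:PATHWAY-COMPONENTS rdf:resource="http://example.org/toy#r1"/>
    <bp:PATHWAY-COMPONENTS rdf:resource="http://example.org/toy#r2"/>
  </bp:pathway>
  <bp:biochemicalReaction rdf:about="http://example.org/toy#r1">
    <bp:NAME>R1: P1 to P2</bp:NAME>
    <bp:LEFT rdf:resource="http://example.org/toy#pep1"/>
    <bp:RIGHT rdf:resource="http://example.org/toy#pep2"/>
  </bp:biochemicalReaction>
  <bp:biochemicalReaction rdf:about="http://example.org/toy#r2">
    <bp:NAME>R2: P3 to P4</bp:NAME>
    <bp:LEFT rdf:resource="http://example.org/toy#pep3"/>
    <bp:RIGHT rdf:resource="http://example.org/toy#pep4"/>
  </bp:biochemicalReaction>
  <bp:complex rdf:about="http://example.org/toy#cx1">
    <bp:NAME>P1-P2 complex</bp:NAME>
    <bp:COMPONENTS rdf:resource="http://example.org/toy#pep5"/>
    <bp:COMPONENTS rdf:resource="http://example.org/toy#pep6"/>
  </bp:complex>
  <bp:physicalEntityParticipant rdf:about="http://example.org/toy#pep1">
    <bp:PHYSICAL-ENTITY rdf:resource="http://example.org/toy#p1"/>
  </bp:physicalEntityParticipant>
  <bp:physicalEntityParticipant rdf:about="http://example.org/toy#pep2">
    <bp:PHYSICAL-ENTITY rdf:resource="http://example.org/toy#p2"/>
  </bp:physicalEntityParticipant>
  <bp:physicalEntityParticipant rdf:about="http://example.org/toy#pep3">
    <bp:PHYSICAL-ENTITY rdf:resource="http://example.org/toy#p3"/>
  </bp:physicalEntityParticipant>
  <bp:physicalEntityParticipant rdf:about="http://example.org/toy#pep4">
    <bp:PHYSICAL-ENTITY rdf:resource="http://example.org/toy#p4"/>
  </bp:physicalEntityParticipant>
  <bp:physicalEntityParticipant rdf:about="http://example.org/toy#pep5">
    <bp:PHYSICAL-ENTITY rdf:resource="http://example.org/toy#p1"/>
  </bp:physicalEntityParticipant>
  <bp:physicalEntityParticipant rdf:about="http://example.org/toy#pep6">
    <bp:PHYSICAL-ENTITY rdf:resource="http://example.org/toy#p2"/>
  </bp:physicalEntityParticipant>
  <bp:protein rdf:about="http://example.org/toy#p1">
    <bp:NAME>Protein 1</bp:NAME>
  </bp:protein>
  <bp:protein rdf:about="http://example.org/toy#p2">
    <bp:NAME>Protein 2</bp:NAME>
  </bp:protein>
  <bp:protein rdf:about="http://example.org/toy#p3">
    <bp:NAME>Protein 3</bp:NAME>
  </bp:protein>
  <bp:protein rdf:about="http://example.org/toy#p4">
    <bp:NAME>Protein 4</bp:NAME>
  </bp:protein>
</rdf:RDF>
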