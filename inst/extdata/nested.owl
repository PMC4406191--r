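<?xml version="1.0" encoding="UTF-8"?>
<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"
         xmlns:bp="http://www.biopax.org/release/biopax-level3.owl#"
         xmlns:owl="http://www.w3.org/2002/07/owl#">
  <bp:Pathway rdf:about="http://example.org/nested#P">
    <bp:displayName>Outer pathway</bp:displayName>
    <bp:pathwayComponent rdf:resource="http://example.org/nested#rx1"/>
    <bp:pathwayComponent rdf:resource="http://example.org/nested#Q"/>
  </bp:Pathway>
  <bp:Pathway rdf:about="http://example.org/nested#Q">
    <bp:displayName>Inner pathway</bp:displayName>
    <bp:pathwayComponent rdf:resource="http://example.org/nested#rx2"/>
    <bp:pathwayComponent rdf:resource="http://example.org/nested#rx3"/>
  </bp:Pathway>
  <bp:BiochemicalReaction rdf:about="http://example.org/nested#rx1">
    <bp:left rdf:resource="http://example.org/nested#pa"/>
    <bp:right rdf:resource="http://example.org/nested#pb"/>
  </bp:BiochemicalReaction>
  <bp:BiochemicalReaction rdf:about="http://example.org/nested#rx2">
    <bp:left rdf:resource="http://example.org/nested#pa"/>
    <bp:right rdf:resource="http://example.org/nested#pb"/>
  </bp:BiochemicalReaction>
  <bp:BiochemicalReaction rdf:about="http://example.org/nested#rx3">
    <bp:left rdf:resource="http://example.org/nested#pb"/>
    <bp:right rdf:resource="http://example.org/nested#pa"/>
  </bp:BiochemicalReaction>
  <bp:Protein rdf:about="http://example.org/nested#pa">
    <bp:displayName>Protein a</bp:displayName>
  </bp:Protein>
  <bp:Protein rdf:about="http://example.org/nested#pb">
    <bp:displayName>Protein b</bp:displayName>
  </bp:Protein>
</rdf:RDF>
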