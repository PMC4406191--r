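<?xml version="1.0" encoding="UTF-8"?>
<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"
         xmlns:bp="http://www.biopax.org/release/biopax-level3.owl#"
         xmlns:owl="http://www.w3.org/2002/07/owl#">
  <bp:Protein rdf:about="http://example.org/diamond#A">
    <bp:displayName>Protein A</bp:displayName>
  </bp:Protein>
  <bp:Protein rdf:about="http://example.org/diamond#B">
    <bp:displayName>Protein B</bp:displayName>
  </bp:Protein>
  <bp:Protein rdf:about="http://example.org/diamond#C">
    <bp:displayName>Protein C (enzyme)</bp:displayName>
  </bp:Protein>
  <bp:Protein rdf:about="http://example.org/diamond#X">
    <bp:displayName>Protein X</bp:displayName>
  </bp:Protein>
  <bp:Protein rdf:about="http://example.org/diamond#Y">
    <bp:displayName>Protein Y</bp:displayName>
  </bp:Protein>
  <bp:BiochemicalReaction rdf:about="http://example.org/diamond#r1">
    <bp:left rdf:resource="http://example.org/diamond#A"/>
    <bp:right rdf:resource="http://example.org/diamond#X"/>
  </bp:BiochemicalReaction>
  <bp:BiochemicalReaction rdf:about="http://example.org/diamond#r2">
    <bp:left rdf:resource="http://example.org/diamond#B"/>
    <bp:right rdf:resource="http://example.org/diamond#X"/>
  </bp:BiochemicalReaction>
  <bp:BiochemicalReaction rdf:about="http://example.org/diamond#r3">
    <bp:left rdf:resource="http://example.org/diamond#X"/>
    <bp:right rdf:resource="http://example.org/diamond#Y"/>
  </bp:BiochemicalReaction>
  <bp:Catalysis rdf:about="http://example.org/diamond#cat1">
    <bp:controller rdf:resource="http://example.org/diamond#C"/>
    <bp:controlled rdf:resource="http://example.org/diamond#r3"/>
  </bp:Catalysis>
</rdf:RDF>
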