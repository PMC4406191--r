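# biopaxnet glyph style table, version 1
# BioPAX type -> mEPN-derived 2D glyph, 3D solid, colour (RGB hex).
# Types absent from this table inherit the style of their nearest listed
# ancestor in the supported hierarchy.
type	shape2d	shape3d	colour
BioPaxElement	circle	sphere	#BBBBBB
Pathway	rounded-rectangle	rounded-cuboid	#14A0C4
Interaction	square	cube	#888888
Control	generic-control	octahedron	#F59B00
Catalysis	circle-c	sphere	#F07000
Modulation	circle-m	sphere	#F0B040
Conversion	transition-bar	cuboid	#666666
BiochemicalReaction	transition-bar	cuboid	#4D4D4D
Transport	double-chevron	cuboid	#6F6FB0
Degradation	empty-set	cone	#9B3030
ComplexAssembly	bracket	cuboid	#5D5D8D
TemplateReaction	arrow-bar	cuboid	#707070
PhysicalEntity	ellipse	sphere	#9ACD32
Protein	rounded-rectangle	rounded-cuboid	#78B41E
SmallMolecule	ion-simple-molecule	sphere	#E6C800
Dna	parallelogram	cuboid	#3C78C8
DnaRegion	parallelogram-open	cuboid	#5A8CD2
Rna	parallelogram	cuboid	#C83C78
RnaRegion	dumbbell	dumbbell	#D25A8C
Complex	octagon	dodecahedron	#32A032
Gene	chevron	torus	#2D6EB4
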