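# Bundled NCBI taxonomy id -> scientific name table (static subset used in
# place of a live name lookup).
taxon	name
9606	Homo sapiens
10090	Mus musculus
10116	Rattus norvegicus
7955	Danio rerio
7227	Drosophila melanogaster
6239	Caenorhabditis elegans
4932	Saccharomyces cerevisiae
562	Escherichia coli
9913	Bos taurus
9031	Gallus gallus
9823	Sus scrofa
3702	Arabidopsis thaliana
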