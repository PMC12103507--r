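term	id	synonyms
Homo sapiens	9606	human
Mus musculus	10090	house mouse|mouse
Rattus norvegicus	10116	Norway rat|rat
Danio rerio	7955	zebrafish
Bos taurus	9913	cattle|cow
Sus scrofa	9823	pig|swine
Caenorhabditis elegans	6239
Drosophila melanogaster	7227	fruit fly
Arabidopsis thaliana	3702	thale cress
Zea mays	4577	maize|corn
Saccharomyces cerevisiae	4932	baker's yeast
Escherichia coli	562	E. coli
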