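term	id	synonyms
leaf	PO:0025034	leaves
root	PO:0009005
stem	PO:0009047
seed	PO:0009010
flower	PO:0009046
fruit	PO:0009001
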