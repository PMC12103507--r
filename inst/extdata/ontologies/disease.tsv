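term	id	synonyms
inflammatory bowel disease	DOID:0050589	IBD
type 2 diabetes mellitus	DOID:9352	type 2 diabetes|T2D
Alzheimer's disease	DOID:10652	Alzheimer disease
asthma	DOID:2841
obesity	DOID:9970
colorectal cancer	DOID:9256
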