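term	id	synonyms
T cell	CL:0000084	T-cell|T-cells|T lymphocyte
B cell	CL:0000236	B-cell|B lymphocyte
hepatocyte	CL:0000182
fibroblast	CL:0000057
macrophage	CL:0000235
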