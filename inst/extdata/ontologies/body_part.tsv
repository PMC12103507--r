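term	id	synonyms
urine	UBERON:0001088
blood plasma	UBERON:0001969	plasma
blood serum	UBERON:0001977	serum
blood	UBERON:0000178	whole blood
liver	UBERON:0002107
heart	UBERON:0000948
myocardium	UBERON:0002349	heart muscle|cardiac muscle
brain	UBERON:0000955
kidney	UBERON:0002113
lung	UBERON:0002048
skin of body	UBERON:0002097	skin
feces	UBERON:0001988	stool|faeces|fecal material
saliva	UBERON:0001836
sweat	UBERON:0001089
cerebrospinal fluid	UBERON:0001359	CSF
skeletal muscle tissue	UBERON:0001134	skeletal muscle
adipose tissue	UBERON:0001013	fat tissue
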