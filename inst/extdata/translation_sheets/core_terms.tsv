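source_pattern	match_mode	target_term	target_column
POSITIVE	exact	electrospray ionization (positive)	IonizationSourceAndPolarity
NEGATIVE	exact	electrospray ionization (negative)	IonizationSourceAndPolarity
POS	exact	electrospray ionization (positive)	IonizationSourceAndPolarity
NEG	exact	electrospray ionization (negative)	IonizationSourceAndPolarity
ESI+	exact	electrospray ionization (positive)	IonizationSourceAndPolarity
ESI-	exact	electrospray ionization (negative)	IonizationSourceAndPolarity
APCI+	exact	atmospheric pressure chemical ionization (positive)	IonizationSourceAndPolarity
APCI-	exact	atmospheric pressure chemical ionization (negative)	IonizationSourceAndPolarity
Human	exact	animal	SampleType
Mammal	exact	animal	SampleType
Animal	exact	animal	SampleType
Plant	exact	plant	SampleType
Bacteria	exact	culture_bacterial	SampleType
Fungi	exact	culture_fungal	SampleType
Food	exact	food	SampleType
Environmental	exact	environmental	SampleType
solvent blank	exact	blank_extraction	SampleType
blank	substring	blank_extraction	SampleType
QC blank	exact	blank_QC	SampleType
Male	exact	male	BiologicalSex
Female	exact	female	BiologicalSex
M	exact	male	BiologicalSex
F	exact	female	BiologicalSex
Healthy	exact	healthy	HealthStatus
Control	exact	healthy	HealthStatus
Diseased	exact	diseased	HealthStatus
plasma	substring	blood plasma	UBERONBodyPartName
serum	substring	blood serum	UBERONBodyPartName
urine	substring	urine	UBERONBodyPartName
stool	substring	feces	UBERONBodyPartName
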