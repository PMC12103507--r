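column	value_kind	descriptive
MRI	mri	FALSE
SourceRepository	repository	FALSE
SampleType	term:animal,plant,culture_bacterial,culture_fungal,culture_mammalian,environmental,food,reference material,blank_extraction,blank_QC,blank_analysis	TRUE
NCBITaxonomy	taxonomy	TRUE
UBERONBodyPartName	vocab:body_part,plant_part,cell_type	TRUE
BiologicalSex	term:male,female,intersex	FALSE
AgeInYears	free	FALSE
LifeStage	free	FALSE
DOIDCommonName	vocab:disease	FALSE
HealthStatus	term:healthy,diseased,not applicable	FALSE
MassSpectrometer	vocab:instrument	FALSE
IonizationSourceAndPolarity	term:electrospray ionization (positive),electrospray ionization (negative),atmospheric pressure chemical ionization (positive),atmospheric pressure chemical ionization (negative)	FALSE
ChromatographyAndPhase	free	FALSE
SampleExtractionMethod	free	FALSE
InternalStandardsUsed	free	FALSE
SubjectIdentifierAsRecorded	free	FALSE
YearOfAnalysis	year	FALSE
LatitudeandLongitude	coordinate	FALSE
Country	free	FALSE
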