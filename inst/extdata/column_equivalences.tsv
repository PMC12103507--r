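redu_column	primary_source	fallback_sources
NCBITaxonomy	Organism	species|organism name
UBERONBodyPartName	Organism part	tissue|body part|body site
BiologicalSex	Sex	gender
AgeInYears	Age	age at sampling
DOIDCommonName	Disease	disease state|diagnosis
HealthStatus	Health status	status
MassSpectrometer	Instrument	mass spectrometer
IonizationSourceAndPolarity	Ion source	scan polarity|polarity|ionization mode
ChromatographyAndPhase	Column type	chromatography instrument|column model
SampleExtractionMethod	Extraction Method	extraction
SubjectIdentifierAsRecorded	Subject ID	subject|individual
Country	Country	geographic location
LatitudeandLongitude	Latitude and Longitude	coordinates
SampleType	Sample type	material type
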