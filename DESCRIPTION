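Package: MetaboHarmonize
Title: Cross-Repository Harmonization of Public Metabolomics Metadata
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ingests heterogeneous metabolomics repository metadata (mwTab
    documents from the Metabolomics Workbench, ISA-Tab study folders in the
    MetaboLights dialect, and ReDU-format tables), links raw mass
    spectrometry files to sample records through a multi-tier matching
    cascade with polarity-based disambiguation, translates free-text terms
    into a controlled vocabulary via translation sheets and ontology
    snapshots, and emits a single harmonized sample-metadata table keyed by
    MS Run Identifiers (MRIs). Includes a minimal mzML/mzXML scan-header
    reader, a cache-aware MRI retrieval layer with integrity verification,
    and a synthetic mini-repository generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    utils,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
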