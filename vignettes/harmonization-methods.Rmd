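---
title: "Harmonizing public metabolomics metadata across repositories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing public metabolomics metadata across repositories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MetaboHarmonize)
```

## The problem

The three main public metabolomics repositories made different metadata
design choices. MetaboLights (MTBLS) uses the ISA framework: linked
investigation/sample/assay tables with partial ontology annotation. The
Metabolomics Workbench's National Metabolomics Data Repository (NMDR) uses
mwTab, a line-oriented sectioned key-value format, one document per
analysis. GNPS/MassIVE metadata submissions follow the ReDU controlled
vocabulary but are optional. As a consequence, finding all raw mass
spectrometry files for, say, human urine across all three repositories
requires three different parsers, three different file-naming conventions,
and a way to decide which raw file belongs to which sample record.

MetaboHarmonize implements that harmonization engine: it parses each
dialect, links deposited raw files to sample records, converts free-text
terms into a controlled vocabulary, and emits one validated table keyed by
MS Run Identifiers (MRIs) — `mzspec:<accession>:<run path>`, the
dataset-and-path subset of the Universal Spectrum Identifier standard. A
cache-aware retrieval layer turns a list of MRIs back into files.

## MRI grammar

No normative grammar exists for the dataset-level identifier, so the
package adopts the USI scheme prefix and splits at the first two colons:
`mzspec:<accession>:<path>`. Paths may contain colons only
percent-encoded; a bare colon is a parse error, except for the `:scan:`
suffix of a full USI, which is accepted and truncated to the MRI. Spaces
pass through unchanged — a local convention, recorded here because public
deposits are inconsistent about encoding them. Accessions are classified
by anchored patterns (`MSV` + 9 digits, `MTBLS` + digits, `ST` + 6
digits); the registry is a plain data.frame argument, so pattern drift
does not require code changes.

## File-sample association

Repositories store raw files; submitters describe samples. The link
between them is free text: a metadata cell may hold a full path, a base
name, a name with the wrong extension, several names joined by a
separator, or a fragment. The association cascade tries, strictly in
order:

1. full path equality,
2. base-name equality,
3. base-name equality after stripping one extension,
4. the first three tiers again after splitting descriptor values on the
   separator set (default `,`, `;`, `|`),
5. substring matching between descriptors and file base names.

All comparisons are case-insensitive. The first tier that yields any
match for a file fixes that file's link; a file matching descriptors of
two or more samples at that tier is ambiguous and excluded. One file
links to at most one sample; a sample may own many files. A study in
which no file could be linked is discarded entirely.

Two decisions here were genuinely open:

* **The separator set.** The third separator is configurable and defaults
  to `|`, alongside `,` and `;`. Splitting is simultaneous over the set,
  and split pieces re-enter the full exact-tier comparison.
* **Substring ambiguity.** Substring matching needs guards to avoid
  trivial hits: both compared strings must be at least 4 characters, and
  matching runs in both directions (descriptor inside base name or base
  name inside descriptor). When several samples match one file, samples
  whose matched descriptor is longest are preferred — `sample_10` beats
  `sample_1` for file `sample_10.mzML` — and a unique survivor is
  accepted only if its descriptor matches exactly one file at this tier.
  Everything else is ambiguous and excluded. This is the strictest
  reading of "unambiguous matches were accepted" that still resolves
  nested descriptors.

The test suite checks the cascade against a brute-force oracle — a
separate, enumerate-everything implementation of the same written rule
table — on hundreds of randomized studies of up to 10 files and 10
samples, plus planted-truth fixtures in which every tier and both
ambiguity constructs appear by construction.

## Polarity disambiguation

NMDR studies may deposit several mwTab analyses (typically positive- and
negative-mode) without recording which raw file belongs to which. The
engine reads the ionization polarity of every scan from the mzML/mzXML
headers (per spectrum, never a file-level default, because mixed-polarity
files exist). A file whose scans are uniformly one polarity is assigned
to the unique analysis reporting that polarity; its analysis-level
metadata (instrument, chromatography, ionization mode) then attaches to
the record. When zero or two-plus analyses remain compatible the
analysis-level metadata is dropped while sample-level metadata survives.
Two conservative choices: mixed-polarity files are compatible with no
single-polarity analysis, and an analysis reporting no polarity is
compatible with either mode (so its presence makes assignment
impossible). Single-analysis studies bypass the step.

## Vocabulary translation

Raw terms resolve through three layers, in a fixed order: exact
translation-sheet entries, whole-string ontology canonical/synonym lookup,
then substring translation-sheet entries. Substring patterns must be at
least 3 characters; the longest matching pattern wins, ties break
lexicographically, so the result is independent of sheet row order. A
term already valid for its column passes through unchanged. Anything
unresolvable is an explicit unmapped marker, exported to a review TSV —
mirroring the manual curation loop the translation sheets came from — and
never silently carried into the table.

Sheet-before-ontology precedence for exact matches is a local decision:
sheets encode deliberate curation (for example, mapping a repository's
`POSITIVE` to `electrospray ionization (positive)`), which should not be
overridden by an accidental synonym collision.

Ontology registries ship as small curated TSV snapshots (taxonomy with
NCBI taxids, UBERON body parts, PO plant parts, CL cell types, DOID
diseases, PSI-MS instruments). Flat term/id/synonym lookup is all the
procedure needs; no OBO reasoning is attempted. Taxonomy terms serialize
as `taxid|name` (`9606|Homo sapiens`), coordinates as `lat|lon`.

## The harmonized table

The column registry is a packaged TSV (`redu_schema.tsv`) — the single
source of truth for column order and allowed terms, extensible without
code changes. A candidate row is accepted only if at least one
sample-descriptive field is populated: organism, body part, or sample
type (blank/QC designations count — a solvent blank is information about
the nature of the sample). Technical metadata alone (instrument,
chromatography, year) never suffices. Missing values are written as the
explicit token `missing value` rather than empty cells, because
downstream filters treat explicit fillers reliably; the token is
configurable through `missingToken()`. Serialization is deterministic
and round-trips exactly, including filler cells and per-record
provenance. An SDRF export maps column headers only.

## Retrieval

`fetchMris()` follows three steps per MRI: cache probe with integrity
verification (mzML/mzXML must be well-formed XML with the right root;
other formats only need non-zero size, a documented weaker check),
download from the repository backend on miss or corruption, and a
per-MRI outcome report whose totals always conserve
(`cache hits + downloads + errors = requests`). Downloads are written to
a temporary file and renamed atomically, so an interrupted transfer never
appears as a cache entry. The cache key is `accession/run_path`, matching
MRI semantics; content addressing was rejected because repositories do
not publish digests. Backends are pluggable; the local-directory mock is
the test surface, and the HTTP adapter is configuration (a URL template),
deliberately excluded from the offline tests. Vendor-format conversion is
out of scope: `requestConversion()` only issues a ticket with a 30-day
expiry against an injected converter.

## What the synthetic studies emulate — and what they do not

`generateStudy()` materializes studies with planted ground truth: every
association tier, both ambiguity constructs, multi-analysis polarity
splits including mixed files, vendor/open sibling deposits, unlinked
files, and studies carrying no sample metadata at all. Generation is a
pure function of the specification; the same seed yields byte-identical
trees, and the manifest of expected links, scan tallies and harmonized
rows is computed by construction from the planted term pool, never by
running the pipeline. The planted mzML/mzXML files are schema-minimal:
correct scan headers, 1-point dummy peak arrays.

Real deposits are messier in ways the generator does not emulate:
encoding noise, typos inside file names (the cascade is deliberately
exact/substring only — no edit-distance matching), terms outside the
packaged ontology snapshots, assay tables with exotic column layouts,
and vendor containers whose internal structure the integrity check
cannot see. Passing tests therefore demonstrate that the rules are
implemented exactly as stated, not that the rules recover every link in
arbitrary real-world submissions.

## Problem sizes and numerical choices

Randomized checks use 500 linkage cases of at most 10 files by 10
samples (where the brute-force oracle is trivially correct), 100 random
scan specifications of up to 15 spectra split across the mzML and mzXML
dialects, and a four-study demo repository of 13 raw files — sizes chosen
so the whole suite and the acceptance script run in seconds while every
rule is exercised at least once. Degenerate inputs are all defined:
zero-spectrum files are valid and empty (distinct from integrity errors),
empty sample-factor blocks parse to zero rows, empty file lists pass
through the format preference unchanged, and an empty table validates
with an empty report.

## Known limitations

* The matching cascade has no fuzzy tier; misspelled descriptors stay
  unlinked by design.
* The packaged ontology snapshots cover common terms only; production use
  is expected to merge user sheets and registries over them.
* MSn levels above 2 are kept distinct; the MS/MS flag is defined as any
  scan with level at least 2.
* Open-format preference is applied in the MetaboLights path, where
  duplicate-format deposits occur; other dialects pass file lists through
  unchanged.
* XML parsing reads whole documents rather than streaming; scan-header
  files at these sizes make this immaterial, but very large production
  mzML files would warrant a streaming reader.
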