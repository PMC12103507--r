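#' @title Synthetic mini-repositories with planted ground truth
#'
#' @description
#' The generator materializes small, fully synthetic studies in each
#' repository dialect — mwTab documents, ISA-Tab folders, ReDU-format
#' tables — together with minimal, well-formed mzML/mzXML files, and
#' returns a manifest stating the expected outcome of every pipeline
#' stage (file-sample links with their tiers, scan tallies, polarity
#' assignments, accepted records). Generation is a pure function of the
#' study specification: the same seed yields byte-identical output trees.
#'
#' The planted metadata pool pairs each raw deposit term with the
#' controlled term it must harmonize to, so manifests are built by
#' construction rather than by running the harmonizer.
#'
#' @name fixtures
NULL

.randAlpha <- function(n) paste(sample(letters, n, replace = TRUE),
                                collapse = "")

# base64 payload of a single little-endian double (dummy 1-point peak
# array, keeps the mzML schema-minimal but non-empty).
.dummyBinary <- function() jsonlite::base64_enc(writeBin(101.0, raw()))

# ---- raw file writers ------------------------------------------------------

# Normalize a scan spec to one row per spectrum.
.expandScanSpec <- function(scans) {
  if (is.null(scans) || !nrow(scans))
    return(data.frame(ms_level = integer(), polarity = character(),
                      stringsAsFactors = FALSE))
  if ("n" %in% names(scans)) {
    idx <- rep(seq_len(nrow(scans)), scans$n)
    scans <- data.frame(ms_level = scans$ms_level[idx],
                        polarity = scans$polarity[idx],
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(scans$ms_level >= 1L))
  scans
}

# Expected ScanSummary count table for a spec (what summarizeScans returns).
.specTally <- function(scans) {
  scans <- .expandScanSpec(scans)
  if (!nrow(scans))
    return(data.frame(ms_level = integer(), polarity = character(),
                      n = integer(), stringsAsFactors = FALSE))
  df <- as.data.frame(table(ms_level = scans$ms_level,
                            polarity = scans$polarity),
                      stringsAsFactors = FALSE)
  df <- df[df$Freq > 0L, , drop = FALSE]
  df <- data.frame(ms_level = as.integer(df$ms_level), polarity = df$polarity,
                   n = as.integer(df$Freq), stringsAsFactors = FALSE)
  df <- df[order(df$ms_level, df$polarity), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Generate a schema-minimal mzML file
#'
#' @param scans data.frame with columns `ms_level` and `polarity`
#'   (`positive`/`negative`/`unknown`), one row per spectrum, or with an
#'   extra `n` count column. Zero rows give a valid file with no spectra.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
generateMzml <- function(scans, path) {
  scans <- .expandScanSpec(scans)
  bin <- .dummyBinary()
  spec <- character(0)
  if (nrow(scans)) {
    pol <- c(positive = '\n      <cvParam cvRef="MS" accession="MS:1000130" name="positive scan" value=""/>',
             negative = '\n      <cvParam cvRef="MS" accession="MS:1000129" name="negative scan" value=""/>',
             unknown = "")
    spec <- sprintf(paste0(
      '    <spectrum index="%d" id="scan=%d" defaultArrayLength="1">\n',
      '      <cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="%d"/>%s\n',
      '      <binaryDataArrayList count="2">\n',
      '        <binaryDataArray encodedLength="%d">\n',
      '          <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value=""/>\n',
      '          <binary>%s</binary>\n',
      '        </binaryDataArray>\n',
      '        <binaryDataArray encodedLength="%d">\n',
      '          <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value=""/>\n',
      '          <binary>%s</binary>\n',
      '        </binaryDataArray>\n',
      '      </binaryDataArrayList>\n',
      '    </spectrum>'),
      seq_len(nrow(scans)) - 1L, seq_len(nrow(scans)), scans$ms_level,
      unname(pol[scans$polarity]), nchar(bin), bin, nchar(bin), bin)
  }
  lines <- c(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '  <cvList count="1">',
    '    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://github.com/HUPO-PSI/psi-ms-CV"/>',
    '  </cvList>',
    '  <run id="run1">',
    sprintf('  <spectrumList count="%d">', nrow(scans)),
    spec,
    '  </spectrumList>',
    '  </run>',
    '</mzML>')
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  .writeLines(lines, path)
  invisible(path)
}

#' Generate a schema-minimal mzXML file
#'
#' @inheritParams generateMzml
#' @return `path`, invisibly.
#' @export
generateMzxml <- function(scans, path) {
  scans <- .expandScanSpec(scans)
  pol <- c(positive = ' polarity="+"', negative = ' polarity="-"',
           unknown = "")
  spec <- character(0)
  if (nrow(scans))
    spec <- sprintf(paste0(
      '  <scan num="%d" msLevel="%d"%s peaksCount="1">\n',
      '   <peaks precision="64" byteOrder="network" contentType="m/z-int">%s</peaks>\n',
      '  </scan>'),
      seq_len(nrow(scans)), scans$ms_level, unname(pol[scans$polarity]),
      .dummyBinary())
  lines <- c(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzXML xmlns="http://sashimi.sourceforge.net/schema_revision/mzXML_3.2">',
    sprintf(' <msRun scanCount="%d">', nrow(scans)),
    spec,
    ' </msRun>',
    '</mzXML>')
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  .writeLines(lines, path)
  invisible(path)
}

#' Truncate a file to a fraction of its bytes
#'
#' Used to fabricate corrupted raw files for integrity tests.
#'
#' @param path File to truncate in place.
#' @param frac Fraction of bytes to keep (default 0.5).
#' @return `path`, invisibly.
#' @export
truncateFile <- function(path, frac = 0.5) {
  n <- file.info(path)$size
  keep <- max(1L, floor(n * frac))
  content <- readBin(path, "raw", n = keep)
  writeBin(content, path)
  invisible(path)
}

# ---- study specification ---------------------------------------------------

# Planted metadata pool: raw deposit term + the controlled term it
# harmonizes to (ground truth by construction).
.organismPool <- function() data.frame(
  raw = c("Homo sapiens", "Mus musculus", "Rattus norvegicus"),
  controlled = c("9606|Homo sapiens", "10090|Mus musculus",
                 "10116|Rattus norvegicus"),
  subjectType = c("Human", "Mammal", "Mammal"),
  sampleType = c("animal", "animal", "animal"),
  taxid = c(9606L, 10090L, 10116L),
  stringsAsFactors = FALSE)

.bodyPool <- function() data.frame(
  raw = c("urine", "Plasma", "Liver"),
  controlled = c("urine", "blood plasma", "liver"),
  stringsAsFactors = FALSE)

#' Specify a synthetic study
#'
#' @param repository `"NMDR"`, `"MTBLS"` or `"GNPS"`.
#' @param index Small integer making the accession unique.
#' @param tiers Character vector: the association tier planted for each
#'   raw file (one sample per file). GNPS studies always link at
#'   `full_path` (their metadata rows name the file directly).
#' @param organism,bodyPart Raw metadata terms from the planted pool.
#' @param ambiguity List of planted ambiguous constructs; each element is
#'   `list(type = "shared_descriptor")` (one extra file whose descriptor
#'   is deposited under two samples) or `list(type = "substring_tie")`
#'   (one extra file matched by equal-length substring descriptors of two
#'   samples).
#' @param polarity `NULL` for a single analysis, or
#'   `list(analysisPolarities = c(...), filePolarities = c(...))` where
#'   `analysisPolarities` has one entry per mwTab analysis and
#'   `filePolarities` one entry per planted file
#'   (`"positive"`, `"negative"`, `"mixed"`). NMDR only.
#' @param vendorSiblings Also deposit a vendor-format (`.raw`) copy of
#'   each raw file (MTBLS only; exercises the open-format preference).
#' @param includeMetadata `FALSE` plants a study carrying no
#'   sample-descriptive metadata at all (every candidate is rejected).
#' @param unlinked Number of extra raw files with no descriptor.
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return A `StudySpec` list.
#' @export
studySpec <- function(repository, index = 1L,
                      tiers = c("full_path", "base_name", "base_name_no_ext",
                                "separator_split", "substring"),
                      organism = "Homo sapiens", bodyPart = "urine",
                      ambiguity = list(), polarity = NULL,
                      vendorSiblings = FALSE, includeMetadata = TRUE,
                      unlinked = 0L, seed = 1L) {
  stopifnot(repository %in% c("NMDR", "MTBLS", "GNPS"),
            all(tiers %in% .TIERS))
  if (repository == "GNPS") tiers <- rep("full_path", length(tiers))
  if (!is.null(polarity))
    stopifnot(repository == "NMDR",
              length(polarity$filePolarities) == length(tiers))
  structure(list(repository = repository, index = as.integer(index),
                 tiers = tiers, organism = organism, bodyPart = bodyPart,
                 ambiguity = ambiguity, polarity = polarity,
                 vendorSiblings = vendorSiblings,
                 includeMetadata = includeMetadata,
                 unlinked = as.integer(unlinked), seed = as.integer(seed)),
            class = "StudySpec")
}

.specAccession <- function(spec) {
  switch(spec$repository,
         NMDR = sprintf("ST%06d", 100L + spec$index),
         MTBLS = sprintf("MTBLS%d", 1000L + spec$index),
         GNPS = sprintf("MSV%09d", 84000L + spec$index))
}

# Descriptor string planting a given tier for file `path` (base name with
# a directory prefix, so base_name never collides with full_path).
.plantDescriptor <- function(tier, path) {
  base <- basename(path)
  noExt <- .stripExt(base)
  switch(tier,
    full_path = path,
    base_name = base,
    base_name_no_ext = paste0(noExt, ".raw"),
    separator_split = paste0(noExt, ".raw, ", "zz_", noExt, "_extra.raw"),
    substring = substr(noExt, max(1L, nchar(noExt) - 6L), nchar(noExt)))
}

# Default scan plan for a planted polarity label.
.scanPlanFor <- function(label) {
  switch(label,
    positive = data.frame(ms_level = c(1L, 1L, 2L),
                          polarity = "positive", stringsAsFactors = FALSE),
    negative = data.frame(ms_level = c(1L, 1L, 2L),
                          polarity = "negative", stringsAsFactors = FALSE),
    mixed = data.frame(ms_level = c(1L, 1L),
                       polarity = c("positive", "negative"),
                       stringsAsFactors = FALSE))
}

# ---- study generation ------------------------------------------------------

#' Generate a synthetic study with its ground-truth manifest
#'
#' Writes the repository-dialect metadata plus minimal raw files under
#' `out/<accession>/` and returns the manifest of expected outcomes.
#'
#' @param spec A [studySpec()].
#' @param out Parent output directory.
#' @return A list with elements `accession`, `repository`, `dir`, `files`,
#'   `linkage` (expected accepted/ambiguous/unlinked with tiers),
#'   `analysisAssignment` (run path to analysis id or `NA`), `scans`
#'   (run path to expected count table) and `records` (expected accepted
#'   harmonized rows as a data.frame; zero rows when the study carries no
#'   usable metadata).
#' @export
generateStudy <- function(spec, out) {
  stopifnot(inherits(spec, "StudySpec"))
  set.seed(spec$seed)
  acc <- .specAccession(spec)
  dir <- file.path(out, acc)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  org <- .organismPool(); org <- org[org$raw == spec$organism, ]
  body <- .bodyPool(); body <- body[body$raw == spec$bodyPart, ]
  stopifnot(nrow(org) == 1L, nrow(body) == 1L)

  nFiles <- length(spec$tiers)
  rawDir <- switch(spec$repository, NMDR = "raw", MTBLS = "FILES",
                   GNPS = "ccms_peak")
  bases <- sprintf("%s_run%02d%s", tolower(acc), seq_len(nFiles),
                   vapply(seq_len(nFiles), function(i) .randAlpha(3L),
                          character(1)))
  paths <- if (nFiles) file.path(rawDir, paste0(bases, ".mzML"))
           else character(0)
  samples <- sprintf("S%02d", seq_len(nFiles))

  filePol <- if (is.null(spec$polarity)) rep("positive", nFiles)
             else spec$polarity$filePolarities
  names(filePol) <- paths

  # Extra files: unlinked and ambiguous constructs.
  extraPaths <- character(0)
  ambDesc <- list()   # sample_id -> extra descriptors
  ambFiles <- character(0)
  nextIdx <- nFiles
  addFile <- function() {
    nextIdx <<- nextIdx + 1L
    file.path(rawDir, sprintf("%s_run%02d%s.mzML", tolower(acc), nextIdx,
                              .randAlpha(3L)))
  }
  extraSamples <- character(0)
  for (a in spec$ambiguity) {
    p <- addFile()
    ambFiles <- c(ambFiles, p)
    s1 <- sprintf("S%02d", nextIdx)
    s2 <- sprintf("S%02d", nextIdx + 50L)
    extraSamples <- c(extraSamples, s1, s2)
    if (a$type == "shared_descriptor") {
      d <- basename(p)
      ambDesc[[s1]] <- c(ambDesc[[s1]], d)
      ambDesc[[s2]] <- c(ambDesc[[s2]], d)
    } else if (a$type == "substring_tie") {
      # Equal-length overlapping substrings of the file-unique tail (run
      # number + random suffix), so neither matches any other file.
      noExt <- .stripExt(basename(p))
      n <- nchar(noExt)
      d1 <- substr(noExt, n - 6L, n - 1L)
      d2 <- substr(noExt, n - 5L, n)
      ambDesc[[s1]] <- c(ambDesc[[s1]], d1)
      ambDesc[[s2]] <- c(ambDesc[[s2]], d2)
    } else stop("unknown ambiguity type: ", a$type)
    filePol[p] <- "positive"
  }
  for (i in seq_len(spec$unlinked)) {
    p <- addFile()
    extraPaths <- c(extraPaths, p)
    filePol[p] <- "positive"
  }

  allPaths <- c(paths, ambFiles, extraPaths)
  for (p in allPaths)
    generateMzml(.scanPlanFor(filePol[[p]]), file.path(dir, p))

  descriptors <- stats::setNames(
    lapply(seq_len(nFiles),
           function(i) .plantDescriptor(spec$tiers[i], paths[i])),
    samples)
  for (s in names(ambDesc)) descriptors[[s]] <- ambDesc[[s]]

  year <- "2021"
  instrumentRaw <- "Q Exactive"; instrumentTerm <- "Q Exactive"
  chromRaw <- "Reversed phase"
  writer <- switch(spec$repository, NMDR = .writeNmdrStudy,
                   MTBLS = .writeMtblsStudy, GNPS = .writeGnpsStudy)
  analyses <- writer(spec, dir, acc, descriptors, org, body, year,
                     instrumentRaw, chromRaw, paths)

  if (spec$vendorSiblings && spec$repository == "MTBLS") {
    for (p in paths)
      .writeLines("vendor stub", file.path(dir, sub("\\.mzML$", ".raw", p)))
  }

  # ---- expected outcomes ---------------------------------------------------
  accepted <- data.frame(run_path = paths, sample_id = samples,
                         tier = spec$tiers, stringsAsFactors = FALSE)
  linkage <- list(accepted = accepted,
                  ambiguous = ambFiles,
                  unlinked = extraPaths,
                  discarded = nrow(accepted) == 0L)

  assignment <- stats::setNames(rep(NA_character_, length(allPaths)), allPaths)
  if (is.null(spec$polarity)) {
    assignment[] <- analyses[1]
  } else {
    pol <- spec$polarity$analysisPolarities
    for (p in allPaths) {
      fp <- filePol[[p]]
      if (fp %in% c("positive", "negative") && sum(pol == fp) == 1L)
        assignment[p] <- analyses[which(pol == fp)]
    }
  }

  scans <- lapply(filePol[allPaths], function(l) .specTally(.scanPlanFor(l)))
  names(scans) <- allPaths

  records <- .expectedRecords(spec, acc, accepted, assignment, org, body,
                              year, instrumentTerm, chromRaw)

  list(accession = acc, repository = spec$repository, dir = dir,
       files = allPaths, linkage = linkage,
       analysisAssignment = assignment, scans = scans, records = records)
}

# Expected harmonized rows, built from the planted pool (by construction).
.expectedRecords <- function(spec, acc, accepted, assignment, org, body,
                             year, instrumentTerm, chromRaw) {
  schema <- reduSchema()
  if (!spec$includeMetadata || !nrow(accepted))
    return(reduRecords(reduTable(list(), data.frame(
      MRI = character(), SourceStudy = character(),
      SourceAnalysis = character(), stringsAsFactors = FALSE))))
  repoName <- switch(spec$repository, NMDR = "NMDR", MTBLS = "MTBLS",
                     GNPS = "GNPS/MassIVE")
  polForAnalysis <- function(p) {
    if (is.null(spec$polarity)) return("electrospray ionization (positive)")
    i <- match(assignment[[p]], .analysisIds(spec))
    if (is.na(i)) return(missingToken())
    sprintf("electrospray ionization (%s)",
            spec$polarity$analysisPolarities[i])
  }
  rows <- lapply(seq_len(nrow(accepted)), function(i) {
    p <- accepted$run_path[i]
    rec <- stats::setNames(rep(missingToken(), nrow(schema)), schema$column)
    rec["MRI"] <- paste0("mzspec:", acc, ":", p)
    rec["SourceRepository"] <- repoName
    rec["NCBITaxonomy"] <- org$controlled
    rec["UBERONBodyPartName"] <- body$controlled
    rec["SampleType"] <- org$sampleType
    rec["YearOfAnalysis"] <- year
    if (spec$repository == "MTBLS") {
      # MTBLS plants no SampleType column and carries per-sample sex.
      rec["SampleType"] <- missingToken()
      rec["BiologicalSex"] <- "female"
      rec["MassSpectrometer"] <- instrumentTerm
    } else if (spec$repository == "NMDR") {
      hasAnalysis <- !is.na(assignment[[p]])
      rec["MassSpectrometer"] <- if (hasAnalysis) instrumentTerm
                                 else missingToken()
      rec["ChromatographyAndPhase"] <- if (hasAnalysis) chromRaw
                                       else missingToken()
      rec["IonizationSourceAndPolarity"] <- polForAnalysis(p)
    } else {
      rec["MassSpectrometer"] <- instrumentTerm
    }
    rec
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

.analysisIds <- function(spec) {
  n <- if (is.null(spec$polarity)) 1L
       else length(spec$polarity$analysisPolarities)
  sprintf("AN%06d", seq_len(n))
}

# ---- dialect writers -------------------------------------------------------

.writeNmdrStudy <- function(spec, dir, acc, descriptors, org, body, year,
                            instrumentRaw, chromRaw, paths) {
  analyses <- .analysisIds(spec)
  pols <- if (is.null(spec$polarity)) "POSITIVE"
          else toupper(spec$polarity$analysisPolarities)
  for (i in seq_along(analyses)) {
    sections <- list(
      PROJECT = c(PROJECT_TITLE = sprintf("Synthetic study %s", acc),
                  SUBMIT_DATE = sprintf("%s-03-01", year)),
      SUBJECT = if (spec$includeMetadata)
        c(SUBJECT_TYPE = org$subjectType, SUBJECT_SPECIES = org$raw)
      else c(SUBJECT_COMMENT = "none"),
      COLLECTION = if (spec$includeMetadata)
        c(SAMPLE_TYPE = body$raw) else c(COLLECTION_COMMENT = "none"),
      CHROMATOGRAPHY = c(CHROMATOGRAPHY_TYPE = chromRaw),
      MS = c(INSTRUMENT_NAME = instrumentRaw, ION_MODE = pols[i])
    )
    factorRows <- lapply(names(descriptors), function(s) {
      add <- stats::setNames(
        as.list(descriptors[[s]]),
        sprintf("RAW_FILE_NAME%s",
                c("", seq_len(max(0L, length(descriptors[[s]]) - 1L)) + 1L)))
      list(sample_id = s, subject = "-",
           factors = c(Treatment = "none"),
           additional = unlist(add))
    })
    doc <- new("MwTabDocument", analysisId = analyses[i], studyId = acc,
               sections = sections, sampleFactors = factorRows,
               polarity = .mapPolarity(pols[i]))
    writeMwTab(doc, file.path(dir, sprintf("%s_%s.mwtab", acc, analyses[i])))
  }
  analyses
}

.writeMtblsStudy <- function(spec, dir, acc, descriptors, org, body, year,
                             instrumentRaw, chromRaw, paths) {
  inv <- c(sprintf("Study Identifier\t%s", acc),
           sprintf("Study Title\tSynthetic study %s", acc),
           sprintf("Study Public Release Date\t%s-01-15", year))
  .writeLines(inv, file.path(dir, "i_Investigation.txt"))

  sampleIds <- names(descriptors)
  orgVal <- if (spec$includeMetadata) org$raw else ""
  orgAcc <- if (spec$includeMetadata)
    sprintf("http://purl.obolibrary.org/obo/NCBITaxon_%d", org$taxid) else ""
  bodyVal <- if (spec$includeMetadata) body$raw else ""
  sTab <- c(paste("Sample Name", "Characteristics[Organism]",
                  "Term Source REF", "Term Accession Number",
                  "Characteristics[Organism part]", "Term Source REF",
                  "Term Accession Number", "Factor Value[gender]",
                  sep = "\t"),
            vapply(sampleIds, function(s)
              paste(s, orgVal, "NCBITAXON", orgAcc, bodyVal, "UBERON", "",
                    if (spec$includeMetadata) "Female" else "",
                    sep = "\t"), character(1)))
  .writeLines(sTab, file.path(dir, sprintf("s_%s.txt", acc)))

  aTab <- c(paste("Sample Name", "Parameter Value[Instrument]",
                  "Raw Spectral Data File", sep = "\t"),
            vapply(seq_along(sampleIds), function(i)
              paste(sampleIds[i], instrumentRaw,
                    descriptors[[sampleIds[i]]][1], sep = "\t"),
              character(1)))
  .writeLines(aTab, file.path(dir, sprintf("a_%s_metabolite_profiling.txt",
                                           acc)))
  "assay1"
}

.writeGnpsStudy <- function(spec, dir, acc, descriptors, org, body, year,
                            instrumentRaw, chromRaw, paths) {
  sampleIds <- names(descriptors)[seq_along(paths)]
  rows <- vapply(seq_along(paths), function(i) {
    if (spec$includeMetadata)
      paste(paths[i], sampleIds[i], org$controlled, body$controlled,
            org$sampleType, instrumentRaw, year, sep = "\t")
    else
      paste(paths[i], sampleIds[i], "", "", "", instrumentRaw, year,
            sep = "\t")
  }, character(1))
  tab <- c(paste("filename", "SampleID", "NCBITaxonomy",
                 "UBERONBodyPartName", "SampleType", "MassSpectrometer",
                 "YearOfAnalysis", sep = "\t"), rows)
  .writeLines(tab, file.path(dir, "redu_metadata.tsv"))
  "redu_metadata"
}

# ---- randomized in-memory linkage cases ------------------------------------

#' Draw a random in-memory linkage case
#'
#' Bounded generator (at most 10 files x 10 samples) used by the
#' property tests that compare [associateFiles()] with the brute-force
#' tier oracle: files and descriptor sets with planted links for every
#' tier, junk descriptors, deliberately shared descriptors and unlinked
#' files. Uses the current RNG state; seed outside.
#'
#' @return List with elements `files` and `descriptors`.
#' @export
randomLinkageCase <- function() {
  nFiles <- sample(1:8, 1L)
  nSamples <- sample(1:6, 1L)
  bases <- sprintf("run%03d%s", sample(100:999, nFiles),
                   vapply(seq_len(nFiles), function(i) .randAlpha(4L),
                          character(1)))
  dirs <- sample(c("", "raw/", "data/pos/"), nFiles, replace = TRUE)
  files <- paste0(dirs, bases, ".mzML")
  samples <- sprintf("SA%02d", seq_len(nSamples))
  descriptors <- stats::setNames(vector("list", nSamples), samples)
  plans <- sample(c(.TIERS, "junk", "shared"), nFiles, replace = TRUE)
  for (i in seq_len(nFiles)) {
    s <- sample(samples, 1L)
    d <- switch(plans[i],
      junk = NULL,
      shared = basename(files[i]),
      .plantDescriptor(plans[i], files[i]))
    if (!is.null(d)) descriptors[[s]] <- c(descriptors[[s]], d)
    if (plans[i] == "shared") {
      s2 <- sample(samples, 1L)
      descriptors[[s2]] <- c(descriptors[[s2]], d)
    }
  }
  # Random junk descriptors.
  for (s in samples) {
    if (stats::runif(1) < 0.4)
      descriptors[[s]] <- c(descriptors[[s]],
                            paste0("note_", .randAlpha(sample(2:8, 1L))))
  }
  descriptors <- lapply(descriptors, function(d) unique(d %||% character(0)))
  list(files = files, descriptors = descriptors)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Materialize the demo mini-repository
#'
#' Three small studies, one per dialect: an NMDR study exercising all five
#' association tiers, an MTBLS study with vendor/open sibling files, and a
#' GNPS study with ReDU-native metadata. Human/urine rows are planted in
#' all three so a cross-repository metadata query has hits from every
#' source.
#'
#' @param out Output directory (one subdirectory per study accession).
#' @param seed Integer seed.
#' @return Named list of study manifests (see [generateStudy()]), plus a
#'   `humanUrineMris` element naming the planted MRIs a query for
#'   `NCBITaxonomy = "9606|Homo sapiens"` and
#'   `UBERONBodyPartName = "urine"` must return.
#' @export
demoRepository <- function(out, seed = 1L) {
  specs <- list(
    nmdr = studySpec("NMDR", index = 1L, seed = seed),
    mtbls = studySpec("MTBLS", index = 1L,
                      tiers = c("full_path", "base_name"),
                      vendorSiblings = TRUE, seed = seed + 1L),
    gnps = studySpec("GNPS", index = 1L, tiers = c("full_path", "full_path"),
                     organism = "Mus musculus", bodyPart = "Liver",
                     seed = seed + 2L),
    gnps2 = studySpec("GNPS", index = 2L, tiers = "full_path",
                      organism = "Homo sapiens", bodyPart = "urine",
                      seed = seed + 3L))
  manifests <- lapply(specs, generateStudy, out = out)
  names(manifests) <- names(specs)
  urine <- unlist(lapply(manifests, function(m) {
    r <- m$records
    r$MRI[r$NCBITaxonomy == "9606|Homo sapiens" &
            r$UBERONBodyPartName == "urine"]
  }), use.names = FALSE)
  manifests$humanUrineMris <- urine
  manifests
}
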