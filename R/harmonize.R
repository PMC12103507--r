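#' @title The harmonization pipeline
#'
#' @description
#' `harmonizeRepositoryRoot()` walks a directory of study folders (one per
#' dataset accession, each in a recognized dialect: mwTab, ISA-Tab, or a
#' ReDU-native table), runs ingest, file-sample association,
#' polarity disambiguation, vocabulary translation and the record
#' acceptance rule, and returns a single harmonized [ReduTable-class]
#' together with a linkage report, the unmapped-term review table, and a
#' structured per-study log in which every discard decision names the rule
#' it invoked.
#'
#' @name harmonize
NULL

# mwTab section/key -> schema column registry. `date` columns go through
# year extraction; `analysis` marks analysis-level fields subject to
# polarity disambiguation in multi-analysis studies.
.nmdrKeyMap <- function() data.frame(
  section = c("SUBJECT", "SUBJECT", "SUBJECT", "COLLECTION", "PROJECT",
              "MS", "MS", "CHROMATOGRAPHY"),
  key = c("SUBJECT_SPECIES", "SUBJECT_TYPE", "GENDER", "SAMPLE_TYPE",
          "SUBMIT_DATE", "INSTRUMENT_NAME", "ION_MODE",
          "CHROMATOGRAPHY_TYPE"),
  column = c("NCBITaxonomy", "SampleType", "BiologicalSex",
             "UBERONBodyPartName", "YearOfAnalysis", "MassSpectrometer",
             "IonizationSourceAndPolarity", "ChromatographyAndPhase"),
  date = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
  analysis = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
  stringsAsFactors = FALSE)

.extractYear <- function(v) {
  if (is.null(v) || is.na(v) || !nzchar(v)) return(NA_character_)
  m <- regmatches(v, regexpr("(18|19|20)[0-9]{2}", v))
  if (length(m)) m else NA_character_
}

#' Detect the metadata dialect of a study folder
#'
#' @param dir Study directory.
#' @return `"MTBLS"`, `"NMDR"`, `"GNPS"` or `NA` when unrecognized.
#' @export
detectDialect <- function(dir) {
  if (length(list.files(dir, pattern = "^i_.*\\.txt$"))) return("MTBLS")
  if (length(list.files(dir, pattern = "\\.mwtab$"))) return("NMDR")
  if (file.exists(file.path(dir, "redu_metadata.tsv"))) return("GNPS")
  NA_character_
}

# Resolve one raw value for a column: keep it when already schema-valid,
# otherwise translate; an unresolvable value is reported as unmapped.
.resolveTerm <- function(raw, column, ctx) {
  raw <- .normWs(raw)
  if (!nzchar(raw)) return(list(value = NULL, unmapped = FALSE))
  if (isTRUE(.checkValue(column, raw, ctx$schema, ctx$registries)))
    return(list(value = raw, unmapped = FALSE))
  term <- translateTerm(raw, column, ctx$sheets, ctx$registries, ctx$schema)
  if (!is.na(term) &&
      isTRUE(.checkValue(column, term, ctx$schema, ctx$registries)))
    return(list(value = term, unmapped = FALSE))
  list(value = NULL, unmapped = TRUE)
}

# Shared per-study context.
.harmonizeContext <- function(schema, sheets, registries, separators) {
  list(schema = schema, sheets = sheets, registries = registries,
       separators = separators)
}

# Apply .resolveTerm over a named raw-field vector; collect unmapped terms.
.resolveFields <- function(fields, ctx, unmappedSink) {
  out <- character(0)
  for (col in names(fields)) {
    res <- .resolveTerm(fields[[col]], col, ctx)
    if (!is.null(res$value)) out[col] <- res$value
    else if (res$unmapped)
      unmappedSink$add(fields[[col]], col)
  }
  out
}

.makeSink <- function(study) {
  env <- new.env()
  env$rows <- list()
  env$add <- function(raw, column) {
    env$rows[[length(env$rows) + 1L]] <- data.frame(
      raw_term = raw, column = column, study = study,
      stringsAsFactors = FALSE)
  }
  env
}

.sinkDf <- function(env) {
  if (!length(env$rows))
    return(data.frame(raw_term = character(), column = character(),
                      study = character(), stringsAsFactors = FALSE))
  unique(do.call(rbind, env$rows))
}

# Raw data files of a study folder (sorted relative paths, supported
# extensions only).
.studyRawFiles <- function(dir) {
  f <- .listRelFiles(dir)
  f[hasSupportedExtension(f)]
}

# ---- per-dialect study harmonizers ----------------------------------------

.harmonizeNmdr <- function(dir, acc, ctx, log) {
  files <- .studyRawFiles(dir)
  mwtabs <- sort(list.files(dir, pattern = "\\.mwtab$", full.names = TRUE))
  docs <- lapply(mwtabs, parseMwTab)
  docs <- docs[order(vapply(docs, analysisId, character(1)))]

  fileTable <- NULL
  ftPath <- file.path(dir, "files_by_sample.tsv")
  if (file.exists(ftPath)) {
    ft <- .readTsv(ftPath)
    fileTable <- split(ft$run_path, ft$sample_id)
  }
  descriptors <- list()
  for (doc in docs) {
    d <- extractSampleDescriptors(doc, fileTable)
    for (s in names(d))
      descriptors[[s]] <- unique(c(descriptors[[s]], d[[s]]))
  }
  if (!length(files))
    return(list(candidates = list(), provenance = NULL, linkage = NULL))
  linkage <- associateFiles(files, descriptors, ctx$separators)

  ids <- vapply(docs, analysisId, character(1))
  if (length(docs) >= 2L) {
    openFiles <- files[.fileExt(files) %in% openExtensions()]
    summaries <- lapply(openFiles, function(f)
      tryCatch(summarizeScans(file.path(dir, f)), error = function(e) NULL))
    names(summaries) <- openFiles
    summaries <- Filter(Negate(is.null), summaries)
    assignment <- disambiguateByPolarity(docs, summaries)
    log$add(acc, "polarity_disambiguation", sprintf(
      "%d/%d files assigned to a unique analysis by scan polarity",
      sum(!is.na(assignment)), length(assignment)))
  } else {
    assignment <- stats::setNames(rep(ids[1], length(files)), files)
  }

  keyMap <- .nmdrKeyMap()
  sink <- .makeSink(acc)
  readMapped <- function(doc, analysisLevel) {
    fields <- character(0)
    rows <- keyMap[keyMap$analysis == analysisLevel, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      sec <- mwtabSections(doc)[[rows$section[i]]]
      v <- sec[rows$key[i]]
      if (is.null(sec) || is.na(v) || !nzchar(v)) next
      v <- unname(v)
      if (rows$date[i]) {
        y <- .extractYear(v)
        if (!is.na(y)) fields[rows$column[i]] <- y
      } else {
        fields[rows$column[i]] <- v
      }
    }
    fields
  }
  # Sample/study-level fields: first (sorted) analysis providing a value
  # wins; per-sample sex factors override the study-level default.
  sampleLevel <- character(0)
  for (doc in docs) {
    f <- readMapped(doc, FALSE)
    add <- setdiff(names(f), names(sampleLevel))
    sampleLevel <- c(sampleLevel, f[add])
  }
  sexBySample <- list()
  for (doc in docs) {
    for (row in sampleFactors(doc)) {
      hit <- grepl("^(sex|gender)$", .lc(names(row$factors)))
      if (any(hit) && is.null(sexBySample[[row$sample_id]]))
        sexBySample[[row$sample_id]] <- unname(row$factors[hit][1])
    }
  }
  analysisLevel <- lapply(docs, readMapped, analysisLevel = TRUE)
  names(analysisLevel) <- ids

  acceptedDf <- acceptedLinks(linkage)
  candidates <- list()
  provenance <- list()
  for (i in seq_len(nrow(acceptedDf))) {
    f <- acceptedDf$run_path[i]
    s <- acceptedDf$sample_id[i]
    fields <- sampleLevel
    if (!is.null(sexBySample[[s]]))
      fields["BiologicalSex"] <- sexBySample[[s]]
    an <- assignment[f]
    if (!is.na(an)) fields <- c(fields, analysisLevel[[an]])
    resolved <- .resolveFields(fields, ctx, sink)
    cand <- c(MRI = paste0("mzspec:", acc, ":", f),
              SourceRepository = "NMDR", resolved)
    candidates[[length(candidates) + 1L]] <- cand
    provenance[[length(provenance) + 1L]] <- data.frame(
      MRI = unname(cand["MRI"]), SourceStudy = acc,
      SourceAnalysis = if (is.na(an)) missingToken() else unname(an),
      stringsAsFactors = FALSE)
  }
  list(candidates = candidates, provenance = provenance, linkage = linkage,
       unmapped = .sinkDf(sink))
}

.harmonizeMtbls <- function(dir, acc, ctx, log) {
  study <- parseIsaTab(dir)
  files <- preferOpenFormat(.studyRawFiles(dir))
  descriptors <- list()
  for (aName in names(assayTables(study))) {
    aTab <- assayTables(study)[[aName]]
    orphan <- orphanedAssayRows(study)[[aName]]
    fileCol <- which(.lc(names(aTab)) %in% .isaFileColumns)
    if (!length(fileCol)) next
    for (r in seq_len(nrow(aTab))) {
      if (isTRUE(orphan[r])) next
      s <- aTab[["Sample Name"]][r]
      v <- trimws(aTab[[fileCol[1]]][r])
      d <- c(v[nzchar(v)], s)
      descriptors[[s]] <- unique(c(descriptors[[s]], d))
    }
  }
  if (!length(files))
    return(list(candidates = list(), provenance = NULL, linkage = NULL))
  linkage <- associateFiles(files, descriptors, ctx$separators)

  fieldsByRaw <- mapColumns(study)
  # Merge each sample's assay-row fields (first sorted descriptor wins).
  bySample <- list()
  for (aName in names(assayTables(study))) {
    aTab <- assayTables(study)[[aName]]
    fileCol <- which(.lc(names(aTab)) %in% .isaFileColumns)
    if (!length(fileCol)) next
    for (r in seq_len(nrow(aTab))) {
      s <- aTab[["Sample Name"]][r]
      v <- trimws(aTab[[fileCol[1]]][r])
      if (!nzchar(v) || is.null(fieldsByRaw[[v]])) next
      existing <- bySample[[s]]
      f <- fieldsByRaw[[v]]
      if (is.null(existing)) bySample[[s]] <- f
      else bySample[[s]] <- c(existing, f[setdiff(names(f), names(existing))])
    }
  }
  year <- .extractYear(
    unname(study@investigationFields["Study Public Release Date"]))

  sink <- .makeSink(acc)
  acceptedDf <- acceptedLinks(linkage)
  candidates <- list()
  provenance <- list()
  for (i in seq_len(nrow(acceptedDf))) {
    f <- acceptedDf$run_path[i]
    s <- acceptedDf$sample_id[i]
    fields <- bySample[[s]] %||% character(0)
    if (!is.na(year)) fields["YearOfAnalysis"] <- year
    resolved <- .resolveFields(fields, ctx, sink)
    cand <- c(MRI = paste0("mzspec:", acc, ":", f),
              SourceRepository = "MTBLS", resolved)
    candidates[[length(candidates) + 1L]] <- cand
    provenance[[length(provenance) + 1L]] <- data.frame(
      MRI = unname(cand["MRI"]), SourceStudy = acc,
      SourceAnalysis = missingToken(), stringsAsFactors = FALSE)
  }
  list(candidates = candidates, provenance = provenance, linkage = linkage,
       unmapped = .sinkDf(sink))
}

.harmonizeGnps <- function(dir, acc, ctx, log) {
  meta <- .readTsv(file.path(dir, "redu_metadata.tsv"))
  files <- .studyRawFiles(dir)
  key <- if ("SampleID" %in% names(meta)) meta$SampleID else meta$filename
  descriptors <- stats::setNames(as.list(meta$filename), key)
  if (!length(files))
    return(list(candidates = list(), provenance = NULL, linkage = NULL))
  linkage <- associateFiles(files, descriptors, ctx$separators)

  sink <- .makeSink(acc)
  acceptedDf <- acceptedLinks(linkage)
  candidates <- list()
  provenance <- list()
  metaCols <- intersect(names(meta), ctx$schema$column)
  metaCols <- setdiff(metaCols, "MRI")
  for (i in seq_len(nrow(acceptedDf))) {
    f <- acceptedDf$run_path[i]
    s <- acceptedDf$sample_id[i]
    row <- match(s, key)
    fields <- character(0)
    for (col in metaCols) {
      v <- meta[[col]][row]
      if (!is.na(v) && nzchar(trimws(v))) fields[col] <- trimws(v)
    }
    resolved <- .resolveFields(fields, ctx, sink)
    cand <- c(MRI = paste0("mzspec:", acc, ":", f),
              SourceRepository = "GNPS/MassIVE", resolved)
    candidates[[length(candidates) + 1L]] <- cand
    provenance[[length(provenance) + 1L]] <- data.frame(
      MRI = unname(cand["MRI"]), SourceStudy = acc,
      SourceAnalysis = missingToken(), stringsAsFactors = FALSE)
  }
  list(candidates = candidates, provenance = provenance, linkage = linkage,
       unmapped = .sinkDf(sink))
}

# ---- repository-level driver ----------------------------------------------

.makeLog <- function() {
  env <- new.env()
  env$entries <- list()
  env$add <- function(study, event, detail) {
    env$entries[[length(env$entries) + 1L]] <- list(
      study = study, event = event, detail = detail)
  }
  env
}

#' Harmonize every study under a directory root
#'
#' @param root Directory with one study folder per dataset accession.
#' @param schema,sheets,registries Registries (packaged defaults).
#' @param separators Separator set for the linker.
#' @return List with elements `table` ([ReduTable-class]), `linkage`
#'   (per-file report data.frame with a `study` column), `unmapped`
#'   (review table of unresolvable terms), `rejections` (per-MRI record
#'   rejections with reasons) and `log` (list of structured entries).
#'   An error of class `harmonize_error` is raised when no study folder
#'   in a recognized dialect exists.
#' @export
harmonizeRepositoryRoot <- function(root,
                                    schema = reduSchema(),
                                    sheets = reduTranslationSheets(),
                                    registries = reduOntologies(),
                                    separators = defaultSeparators()) {
  dirs <- sort(list.dirs(root, recursive = FALSE))
  ctx <- .harmonizeContext(schema, sheets, registries, separators)
  log <- .makeLog()
  allCand <- list()
  allProv <- list()
  linkRows <- list()
  unmapped <- list()
  rejections <- list()
  recognized <- 0L
  for (dir in dirs) {
    acc <- basename(dir)
    dialect <- detectDialect(dir)
    if (is.na(dialect)) {
      log$add(acc, "skipped", "unrecognized study dialect")
      next
    }
    recognized <- recognized + 1L
    fn <- switch(dialect, NMDR = .harmonizeNmdr, MTBLS = .harmonizeMtbls,
                 GNPS = .harmonizeGnps)
    res <- fn(dir, acc, ctx, log)
    if (is.null(res$linkage)) {
      log$add(acc, "study_discarded", "no raw data files found")
      next
    }
    lr <- linkageReport(res$linkage)
    lr <- cbind(study = rep(acc, nrow(lr)), lr, stringsAsFactors = FALSE)
    linkRows[[length(linkRows) + 1L]] <- lr
    if (discardedStudy(res$linkage)) {
      log$add(acc, "study_discarded",
              "no spectral data could be associated with specific samples")
      next
    }
    if (!is.null(res$unmapped) && nrow(res$unmapped))
      unmapped[[length(unmapped) + 1L]] <- res$unmapped
    nAccepted <- 0L
    for (j in seq_along(res$candidates)) {
      verdict <- acceptRecord(res$candidates[[j]], schema)
      if (verdict$accepted) {
        allCand[[length(allCand) + 1L]] <- verdict$record
        allProv[[length(allProv) + 1L]] <- res$provenance[[j]]
        nAccepted <- nAccepted + 1L
      } else {
        rejections[[length(rejections) + 1L]] <- data.frame(
          MRI = unname(res$candidates[[j]]["MRI"]), study = acc,
          reason = verdict$reason, stringsAsFactors = FALSE)
        log$add(acc, "record_rejected", verdict$reason)
      }
    }
    if (nAccepted == 0L)
      log$add(acc, "study_discarded",
              "no raw file carried sample-descriptive metadata")
    else
      log$add(acc, "study_harmonized",
              sprintf("%d record(s) accepted", nAccepted))
  }
  if (recognized == 0L)
    .err("harmonize_error", "no study folder in a recognized dialect under '%s'",
         root)
  prov <- if (length(allProv)) do.call(rbind, allProv)
          else data.frame(MRI = character(), SourceStudy = character(),
                          SourceAnalysis = character(),
                          stringsAsFactors = FALSE)
  table <- reduTable(allCand, prov, schema)
  list(table = table,
       linkage = if (length(linkRows)) do.call(rbind, linkRows)
                 else data.frame(study = character(), run_path = character(),
                                 sample_id = character(), tier = character(),
                                 status = character(),
                                 stringsAsFactors = FALSE),
       unmapped = if (length(unmapped)) unique(do.call(rbind, unmapped))
                  else data.frame(raw_term = character(),
                                  column = character(), study = character(),
                                  stringsAsFactors = FALSE),
       rejections = if (length(rejections)) do.call(rbind, rejections)
                    else data.frame(MRI = character(), study = character(),
                                    reason = character(),
                                    stringsAsFactors = FALSE),
       log = log$entries)
}

#' Run the harmonizer and write all outputs
#'
#' Writes `redu_table.tsv`, `linkage_report.tsv`, `unmapped_terms.tsv`,
#' `rejections.tsv` and the JSON-lines log `harmonize_log.jsonl` into
#' `outDir`. Outputs are deterministic: rerunning on unchanged input
#' yields byte-identical files.
#'
#' @param root Input directory of study folders.
#' @param outDir Output directory (created).
#' @param ... Passed to [harmonizeRepositoryRoot()].
#' @return The [harmonizeRepositoryRoot()] result, invisibly.
#' @export
cmdHarmonize <- function(root, outDir, ...) {
  res <- harmonizeRepositoryRoot(root, ...)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeReduTable(res$table, file.path(outDir, "redu_table.tsv"))
  .writeTsv(res$linkage, file.path(outDir, "linkage_report.tsv"))
  .writeTsv(res$unmapped, file.path(outDir, "unmapped_terms.tsv"))
  .writeTsv(res$rejections, file.path(outDir, "rejections.tsv"))
  logLines <- vapply(res$log, function(e)
    as.character(jsonlite::toJSON(e, auto_unbox = TRUE)), character(1))
  .writeLines(logLines, file.path(outDir, "harmonize_log.jsonl"))
  invisible(res)
}

#' Query a harmonized table for MRIs
#'
#' Conjunctive exact-match filtering on controlled columns, the
#' cross-repository search semantics of the metadata dashboard: e.g.
#' organism `"9606|Homo sapiens"` and body part `"urine"` return the MRIs
#' of all matching raw files.
#'
#' @param table A [ReduTable-class] or path to a table TSV.
#' @param filters Named character vector `column = term`. An empty filter
#'   set returns all MRIs; an unknown column name raises `query_error`.
#' @return Character vector of MRIs, in stable (table) order.
#' @export
queryTable <- function(table, filters = character(0)) {
  if (is.character(table)) table <- readReduTable(table)
  df <- reduRecords(table)
  unknown <- setdiff(names(filters), names(df))
  if (length(unknown))
    .err("query_error", "unknown column(s): %s",
         paste(unknown, collapse = ", "))
  keep <- rep(TRUE, nrow(df))
  for (col in names(filters)) keep <- keep & (df[[col]] == filters[[col]])
  df$MRI[keep]
}

#' Scan-level statistics for every raw file under a directory
#'
#' @param root Directory searched recursively for mzML/mzXML files.
#' @return data.frame with one row per (file, MS level, polarity)
#'   combination plus an `has_msms` flag per file.
#' @export
scanStats <- function(root) {
  files <- .listRelFiles(root)
  files <- files[.fileExt(files) %in% openExtensions()]
  rows <- lapply(files, function(f) {
    s <- tryCatch(summarizeScans(file.path(root, f)), error = function(e) NULL)
    if (is.null(s))
      return(data.frame(run_path = f, ms_level = NA_integer_,
                        polarity = "error", n = 0L, has_msms = FALSE,
                        stringsAsFactors = FALSE))
    counts <- scanCounts(s)
    if (!nrow(counts))
      return(data.frame(run_path = f, ms_level = NA_integer_,
                        polarity = "none", n = 0L, has_msms = FALSE,
                        stringsAsFactors = FALSE))
    cbind(run_path = f, counts, has_msms = hasMsms(s),
          stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
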