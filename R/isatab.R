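#' @title ISA-Tab studies
#'
#' @description
#' `IsaStudy` holds one parsed ISA-Tab study folder in the MetaboLights
#' dialect: a vertical-key/value investigation file (`i_*.txt`), one sample
#' table (`s_*.txt`) and one or more assay tables (`a_*.txt`), all
#' tab-delimited. Ontology-annotation column triplets (term, `Term Source
#' REF`, `Term Accession Number`) are preserved positionally so an
#' accession can be associated with its parent column.
#'
#' @slot studyId Study accession (folder name, falling back to the
#'   investigation's `Study Identifier`).
#' @slot sampleTable Sample-level data.frame; duplicated column names kept.
#' @slot assayTables Named list of assay data.frames.
#' @slot investigationFields Named character vector of investigation
#'   key/value pairs.
#' @slot orphanedAssayRows Named list (per assay) of logical vectors
#'   flagging rows whose `Sample Name` is absent from the sample table.
#'
#' @seealso [parseIsaTab()], [mapColumns()], [preferOpenFormat()]
#' @export
setClass("IsaStudy",
  representation(studyId = "character",
                 sampleTable = "data.frame",
                 assayTables = "list",
                 investigationFields = "character",
                 orphanedAssayRows = "list"))

setValidity("IsaStudy", function(object) {
  msg <- character()
  if (!identical(names(object@assayTables), names(object@orphanedAssayRows)))
    msg <- c(msg, "orphan flags must cover every assay table")
  if (length(msg)) msg else TRUE
})

setMethod("show", "IsaStudy", function(object) {
  cat("IsaStudy", object@studyId, "\n")
  cat("  samples:", nrow(object@sampleTable),
      " assay tables:", length(object@assayTables), "\n")
  invisible(object)
})

#' @describeIn IsaStudy-class Sample table accessor
#' @param x An `IsaStudy`.
#' @export
sampleTable <- function(x) x@sampleTable

#' @describeIn IsaStudy-class Assay table list accessor
#' @export
assayTables <- function(x) x@assayTables

#' @describeIn IsaStudy-class Orphaned-row flags accessor
#' @export
orphanedAssayRows <- function(x) x@orphanedAssayRows

# Read one ISA-Tab table keeping duplicate column names and padding ragged
# rows (with a row-level warning).
.readIsaTable <- function(path) {
  nf <- utils::count.fields(path, sep = "\t", quote = "\"")
  if (length(nf) > 1L && any(nf[-1] != nf[1]))
    warning(sprintf("ragged rows in %s padded to header width", basename(path)),
            call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", quote = "\"", header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          na.strings = NULL, fill = TRUE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  df
}

#' Parse an ISA-Tab study folder
#'
#' @param folder Directory containing `i_*.txt`, at least one `s_*.txt`
#'   and at least one `a_*.txt`. A missing sample or assay file raises
#'   `isa_parse_error`. Assay rows referencing a sample absent from the
#'   sample table are flagged orphaned, not dropped.
#' @return An [IsaStudy-class].
#' @export
parseIsaTab <- function(folder) {
  if (!dir.exists(folder))
    .err("isa_parse_error", "study folder '%s' does not exist", folder)
  sFiles <- sort(list.files(folder, pattern = "^s_.*\\.txt$"))
  aFiles <- sort(list.files(folder, pattern = "^a_.*\\.txt$"))
  iFiles <- sort(list.files(folder, pattern = "^i_.*\\.txt$"))
  if (!length(sFiles))
    .err("isa_parse_error", "no sample (s_*.txt) file in '%s'", folder)
  if (!length(aFiles))
    .err("isa_parse_error", "no assay (a_*.txt) file in '%s'", folder)

  invFields <- character(0)
  if (length(iFiles)) {
    for (line in readLines(file.path(folder, iFiles[1]), warn = FALSE)) {
      parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(parts) >= 2L && nzchar(parts[1]))
        invFields[parts[1]] <- gsub("^\"|\"$", "", parts[2])
    }
  }

  sampleTab <- .readIsaTable(file.path(folder, sFiles[1]))
  assays <- lapply(aFiles, function(f) .readIsaTable(file.path(folder, f)))
  names(assays) <- aFiles

  sampleNames <- sampleTab[["Sample Name"]]
  if (is.null(sampleNames)) sampleNames <- character(0)
  orphans <- lapply(assays, function(a) {
    sn <- a[["Sample Name"]]
    if (is.null(sn)) rep(FALSE, nrow(a)) else !(sn %in% sampleNames)
  })

  studyId <- basename(normalizePath(folder, mustWork = FALSE))
  if (!is.na(invFields["Study Identifier"]) &&
      nzchar(invFields["Study Identifier"]))
    studyId <- unname(invFields["Study Identifier"])

  new("IsaStudy", studyId = studyId, sampleTable = sampleTab,
      assayTables = assays, investigationFields = invFields,
      orphanedAssayRows = orphans)
}

#' Default MetaboLights-to-ReDU column equivalences
#'
#' Each row maps one controlled ReDU column to its MetaboLights primary
#' source column plus ordered fallback column names. Fallbacks are looked
#' up case-insensitively inside `Factor Value[...]`, `Characteristics[...]`
#' and `Parameter Value[...]` wrappers as well as bare headers. The shipped
#' registry (a packaged TSV) covers the standard mappings and is
#' user-extensible.
#'
#' @param path TSV with columns `redu_column`, `primary_source`,
#'   `fallback_sources` (pipe-separated).
#' @return data.frame registry.
#' @export
reduColumnEquivalences <- function(path = system.file("extdata",
    "column_equivalences.tsv", package = "MetaboHarmonize")) {
  df <- .readTsv(path)
  stopifnot(all(c("redu_column", "primary_source", "fallback_sources")
                %in% names(df)))
  df
}

# Look a column up in a single-row context: exact header match first
# (case-insensitive), then wrapped fallback forms. Returns the first
# non-empty value plus the matched column index, or NULL.
.lookupField <- function(df, row, name, wrappers = TRUE) {
  nms <- names(df)
  lnms <- .lc(nms)
  target <- .lc(name)
  idx <- which(lnms == target)
  if (!length(idx) && wrappers) {
    wrapped <- .lc(c(sprintf("factor value[%s]", name),
                     sprintf("characteristics[%s]", name),
                     sprintf("parameter value[%s]", name)))
    idx <- which(lnms %in% wrapped)
  }
  for (i in idx) {
    v <- df[[i]][row]
    if (!is.na(v) && nzchar(trimws(v)))
      return(list(value = trimws(v), col = i))
  }
  NULL
}

# If the matched column is followed by an ontology-annotation triplet,
# return the Term Accession Number value for this row (or NULL).
.termAccession <- function(df, row, col) {
  nms <- .lc(names(df))
  for (i in (col + 1L):min(col + 2L, ncol(df))) {
    if (i > ncol(df)) break
    if (nms[i] == "term accession number") {
      v <- df[[i]][row]
      if (!is.na(v) && nzchar(trimws(v))) return(trimws(v))
    }
    if (!nms[i] %in% c("term source ref", "term accession number")) break
  }
  NULL
}

# Columns that carry the raw data file name in MTBLS assay tables.
.isaFileColumns <- c("raw spectral data file", "derived spectral data file")

#' Map MetaboLights columns onto the ReDU schema
#'
#' For every raw-file-bearing assay row, joins sample-level and assay-level
#' fields through the column-equivalence registry. The primary source
#' column wins over fallbacks; a field with neither stays unset (never an
#' empty string). When the taxonomy column carries an NCBITaxon term
#' accession, the `taxid|name` form is produced directly.
#'
#' @param study An [IsaStudy-class].
#' @param equivalences Registry from [reduColumnEquivalences()].
#' @return Named list: raw file name (as deposited) to a named character
#'   vector of partial ReDU fields.
#' @export
mapColumns <- function(study, equivalences = reduColumnEquivalences()) {
  stopifnot(is(study, "IsaStudy"), nrow(equivalences) > 0L)
  sTab <- study@sampleTable
  sNames <- sTab[["Sample Name"]]
  out <- list()
  for (aName in names(study@assayTables)) {
    aTab <- study@assayTables[[aName]]
    orphan <- study@orphanedAssayRows[[aName]]
    fileCol <- which(.lc(names(aTab)) %in% .isaFileColumns)
    if (!length(fileCol)) next
    fileCol <- fileCol[1]
    for (r in seq_len(nrow(aTab))) {
      rawFile <- trimws(aTab[[fileCol]][r])
      if (!nzchar(rawFile) || isTRUE(orphan[r])) next
      sRow <- match(aTab[["Sample Name"]][r], sNames)
      fields <- character(0)
      for (e in seq_len(nrow(equivalences))) {
        reduCol <- equivalences$redu_column[e]
        sources <- c(equivalences$primary_source[e],
                     strsplit(equivalences$fallback_sources[e], "|",
                              fixed = TRUE)[[1]])
        sources <- sources[nzchar(sources)]
        hit <- NULL
        hitDf <- NULL
        hitRow <- NULL
        for (src in sources) {
          hit <- .lookupField(aTab, r, src)
          if (!is.null(hit)) { hitDf <- aTab; hitRow <- r; break }
          if (!is.na(sRow)) {
            hit <- .lookupField(sTab, sRow, src)
            if (!is.null(hit)) { hitDf <- sTab; hitRow <- sRow; break }
          }
        }
        if (is.null(hit)) next
        value <- hit$value
        if (reduCol == "NCBITaxonomy") {
          acc <- .termAccession(hitDf, hitRow, hit$col)
          if (!is.null(acc) && grepl("NCBITaxon[_:]?[0-9]+", acc)) {
            taxid <- sub(".*NCBITaxon[_:]?([0-9]+).*", "\\1", acc)
            value <- formatTaxonomy(as.integer(taxid), value)
          }
        }
        fields[reduCol] <- value
      }
      # Merge across assay tables; the first (sorted) occurrence wins.
      existing <- out[[rawFile]]
      if (is.null(existing)) {
        out[[rawFile]] <- fields
      } else {
        add <- setdiff(names(fields), names(existing))
        out[[rawFile]] <- c(existing, fields[add])
      }
    }
  }
  out
}

#' Keep only the open format when a raw file is deposited in several
#'
#' When two paths share a base name modulo one stripped extension
#' (case-insensitive) and one is an open XML format (mzML/mzXML) while
#' another is a vendor format, the vendor copies are removed. Files without
#' an open-format sibling are never removed; the function is idempotent.
#'
#' @param files Character vector of run paths for one study.
#' @return The filtered vector, original order preserved.
#' @examples
#' preferOpenFormat(c("a.raw", "a.mzML", "b.raw"))
#' @export
preferOpenFormat <- function(files) {
  if (!length(files)) return(files)
  key <- .lc(.stripExt(basename(files)))
  ext <- .fileExt(files)
  isOpen <- ext %in% openExtensions()
  isVendor <- ext %in% setdiff(supportedExtensions(), openExtensions())
  openKeys <- unique(key[isOpen])
  drop <- isVendor & key %in% openKeys
  files[!drop]
}
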