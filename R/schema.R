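#' @title The harmonized metadata table
#'
#' @description
#' The harmonizer's output is a single table across all repositories: one
#' row per raw file, keyed by MRI, with every populated field drawn from a
#' controlled vocabulary. The column registry ships as a packaged schema
#' TSV — the single source of truth for column order and allowed terms —
#' and can be extended without code changes.
#'
#' A candidate row is accepted only if it carries at least one piece of
#' sample-descriptive metadata (analyzed organism, body part, or a sample
#' type such as a solvent blank); purely technical metadata (instrument,
#' chromatography, ...) does not qualify. Missing values are serialized as
#' the explicit filler token rather than empty cells.
#'
#' @name redu-schema
NULL

#' Load the schema registry
#'
#' @param path TSV with columns `column`, `value_kind`, `descriptive`.
#'   `value_kind` is one of `mri`, `repository`, `taxonomy`,
#'   `vocab:<domains>`, `term:<allowed terms>`, `year`, `coordinate`,
#'   `free`. `descriptive` marks the sample-descriptive acceptance set.
#' @return data.frame registry (column order = table column order).
#' @export
reduSchema <- function(path = system.file("extdata", "redu_schema.tsv",
                                          package = "MetaboHarmonize")) {
  df <- .readTsv(path)
  stopifnot(all(c("column", "value_kind", "descriptive") %in% names(df)))
  df$descriptive <- df$descriptive == "TRUE"
  df
}

#' The canonical missing-value filler token
#' @return `"missing value"`.
#' @export
missingToken <- function() "missing value"

# Validate one populated value against its column's registry.
# Returns TRUE or a character reason.
.checkValue <- function(column, value, schema, registries = reduOntologies()) {
  kind <- schema$value_kind[schema$column == column]
  if (!length(kind)) return(sprintf("unknown column '%s'", column))
  if (identical(value, missingToken())) return(TRUE)
  switch(
    sub(":.*$", "", kind),
    mri = {
      ok <- tryCatch({ parseMri(value); TRUE }, error = function(e) FALSE)
      if (ok) TRUE else "not a valid MRI"
    },
    repository = {
      if (value %in% repositoryRegistry()$name) TRUE
      else "not a registered repository"
    },
    taxonomy = {
      if (grepl("^[0-9]+\\|.+$", value)) TRUE
      else "taxonomy terms must be 'taxid|name'"
    },
    vocab = {
      domains <- strsplit(sub("^vocab:", "", kind), ",", fixed = TRUE)[[1]]
      terms <- unlist(lapply(registries[domains], function(r) r$term),
                      use.names = FALSE)
      if (value %in% terms) TRUE
      else sprintf("'%s' is not a registered %s term", value,
                   paste(domains, collapse = "/"))
    },
    term = {
      allowed <- strsplit(sub("^term:", "", kind), ",", fixed = TRUE)[[1]]
      if (value %in% allowed) TRUE
      else sprintf("'%s' is not an allowed term", value)
    },
    year = {
      if (grepl("^[0-9]{4}$", value)) TRUE else "not a 4-digit year"
    },
    coordinate = {
      if (grepl("^-?[0-9]+(\\.[0-9]+)?\\|-?[0-9]+(\\.[0-9]+)?$", value)) TRUE
      else "coordinates must be 'lat|lon' decimal degrees"
    },
    free = TRUE,
    sprintf("unhandled value kind '%s'", kind)
  )
}

#' Accept or reject one candidate record
#'
#' The candidate must carry a structurally valid MRI (otherwise an error of
#' class `redu_structural_error` is raised — a different failure mode than
#' metadata rejection). It is accepted iff at least one field of the
#' sample-descriptive set (the schema rows flagged `descriptive`:
#' organism, body part, sample type including blank designations) is
#' populated; the rejection reason names the rule otherwise.
#'
#' @param candidate Named character vector of populated fields (must
#'   include `MRI`).
#' @param schema Schema registry.
#' @return A list with elements `accepted` (logical), `record` (full named
#'   character vector over all schema columns, filler-padded; `NULL` on
#'   rejection) and `reason` (`NA` on acceptance).
#' @examples
#' acceptRecord(c(MRI = "mzspec:ST000123:raw/a.mzML",
#'                NCBITaxonomy = "9606|Homo sapiens"))
#' @export
acceptRecord <- function(candidate, schema = reduSchema()) {
  mri <- candidate["MRI"]
  if (is.na(mri))
    .err("redu_structural_error", "candidate lacks an MRI")
  tryCatch(parseMri(unname(mri)), error = function(e)
    .err("redu_structural_error", "invalid MRI: %s", conditionMessage(e)))
  descriptive <- schema$column[schema$descriptive]
  populated <- function(col) {
    v <- candidate[col]
    !is.na(v) && nzchar(trimws(v)) && !identical(unname(v), missingToken())
  }
  if (!any(vapply(descriptive, populated, logical(1)))) {
    return(list(accepted = FALSE, record = NULL,
                reason = sprintf(
                  "no sample-descriptive metadata (need one of: %s)",
                  paste(descriptive, collapse = ", "))))
  }
  record <- stats::setNames(rep(missingToken(), nrow(schema)), schema$column)
  keep <- intersect(names(candidate), schema$column)
  for (col in keep) if (populated(col)) record[col] <- candidate[col]
  list(accepted = TRUE, record = record, reason = NA_character_)
}

#' @title Harmonized table container
#' @description A validated collection of harmonized records with
#'   per-record provenance (the source study/analysis each row came from).
#' @slot records data.frame with the schema columns, all character.
#' @slot provenance data.frame with columns `MRI`, `SourceStudy`,
#'   `SourceAnalysis`, covering every record.
#' @export
setClass("ReduTable",
  representation(records = "data.frame",
                 provenance = "data.frame"))

setValidity("ReduTable", function(object) {
  msg <- character()
  if (!all(c("MRI", "SourceStudy", "SourceAnalysis")
           %in% names(object@provenance)))
    msg <- c(msg, "provenance needs MRI/SourceStudy/SourceAnalysis columns")
  else if (!all(object@records$MRI %in% object@provenance$MRI))
    msg <- c(msg, "provenance must cover every record")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ReduTable", function(object) {
  cat("ReduTable:", nrow(object@records), "records,",
      ncol(object@records), "columns\n")
  invisible(object)
})

#' Construct a harmonized table
#'
#' @param records List of accepted records (named character vectors from
#'   [acceptRecord()]) or an equivalent data.frame.
#' @param provenance data.frame with `MRI`, `SourceStudy`,
#'   `SourceAnalysis`.
#' @param schema Schema registry (fixes column order).
#' @return A [ReduTable-class].
#' @export
reduTable <- function(records, provenance, schema = reduSchema()) {
  if (is.data.frame(records)) {
    df <- records
  } else if (length(records)) {
    df <- as.data.frame(do.call(rbind, records), stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(stats::setNames(
      rep(list(character()), nrow(schema)), schema$column),
      check.names = FALSE)
  }
  miss <- setdiff(schema$column, names(df))
  for (m in miss) df[[m]] <- rep(missingToken(), nrow(df))
  df <- df[, schema$column, drop = FALSE]
  rownames(df) <- NULL
  rownames(provenance) <- NULL
  new("ReduTable", records = df, provenance = provenance)
}

#' @describeIn ReduTable-class Record data.frame accessor
#' @param x A `ReduTable`.
#' @export
reduRecords <- function(x) x@records

#' @describeIn ReduTable-class Provenance accessor
#' @export
reduProvenance <- function(x) x@provenance

#' Validate a harmonized table
#'
#' Checks every populated cell against its column's term registry, and
#' detects duplicate MRIs. Every failure is listed with row, column and
#' offending value; an empty report means the table is valid.
#'
#' @param table A [ReduTable-class].
#' @param schema Schema registry.
#' @param registries Ontology registries.
#' @return data.frame with columns `row`, `column`, `value`, `rule`.
#' @export
validateTable <- function(table, schema = reduSchema(),
                          registries = reduOntologies()) {
  df <- reduRecords(table)
  failures <- list()
  addFail <- function(row, column, value, rule) {
    failures[[length(failures) + 1L]] <<- data.frame(
      row = row, column = column, value = value, rule = rule,
      stringsAsFactors = FALSE)
  }
  dup <- duplicated(df$MRI)
  for (r in which(dup)) addFail(r, "MRI", df$MRI[r], "duplicate MRI")
  for (col in names(df)) {
    for (r in seq_len(nrow(df))) {
      v <- df[[col]][r]
      if (identical(v, missingToken())) next
      res <- .checkValue(col, v, schema, registries)
      if (!isTRUE(res)) addFail(r, col, v, res)
    }
  }
  if (!length(failures))
    return(data.frame(row = integer(), column = character(),
                      value = character(), rule = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, failures)
}

#' Write a harmonized table as TSV
#'
#' Columns follow the schema registry order, with the provenance columns
#' appended; missing values are written as the filler token. Refuses a
#' table that fails [validateTable()]. `readReduTable(writeReduTable(t))`
#' reproduces `t`.
#'
#' @param table A [ReduTable-class].
#' @param path Output path.
#' @param schema,registries Passed to [validateTable()].
#' @return `path`, invisibly.
#' @export
writeReduTable <- function(table, path, schema = reduSchema(),
                           registries = reduOntologies()) {
  report <- validateTable(table, schema, registries)
  if (nrow(report))
    .err("redu_validation_error",
         "table fails validation (%d failure%s); first: row %d column %s: %s",
         nrow(report), if (nrow(report) == 1L) "" else "s",
         report$row[1], report$column[1], report$rule[1])
  df <- reduRecords(table)
  prov <- reduProvenance(table)
  prov <- prov[match(df$MRI, prov$MRI), c("SourceStudy", "SourceAnalysis"),
               drop = FALSE]
  out <- cbind(df, prov)
  .writeTsv(out, path)
  invisible(path)
}

#' Read a harmonized table from TSV
#'
#' @param path TSV written by [writeReduTable()].
#' @param schema Schema registry.
#' @return A [ReduTable-class].
#' @export
readReduTable <- function(path, schema = reduSchema()) {
  df <- .readTsv(path)
  prov <- data.frame(MRI = df$MRI,
                     SourceStudy = df$SourceStudy,
                     SourceAnalysis = df$SourceAnalysis,
                     stringsAsFactors = FALSE)
  df$SourceStudy <- NULL
  df$SourceAnalysis <- NULL
  reduTable(df, prov, schema)
}

#' Export a table in SDRF layout
#'
#' Header-mapping-only export to the Sample and Data Relationship Format:
#' harmonized columns are renamed to SDRF `characteristics[...]` /
#' `comment[...]` headers; values are passed through unchanged and the
#' filler token becomes SDRF's `not available`.
#'
#' @param table A [ReduTable-class].
#' @param path Output TSV path.
#' @return The exported data.frame, invisibly.
#' @export
exportSdrf <- function(table, path) {
  df <- reduRecords(table)
  map <- c(MRI = "comment[data file]",
           NCBITaxonomy = "characteristics[organism]",
           UBERONBodyPartName = "characteristics[organism part]",
           BiologicalSex = "characteristics[sex]",
           DOIDCommonName = "characteristics[disease]",
           AgeInYears = "characteristics[age]",
           MassSpectrometer = "comment[instrument]")
  out <- df[, names(map), drop = FALSE]
  names(out) <- unname(map)
  out[] <- lapply(out, function(v) ifelse(v == missingToken(),
                                          "not available", v))
  out <- cbind(data.frame("source name" = df$MRI, check.names = FALSE,
                          stringsAsFactors = FALSE), out)
  .writeTsv(out, path)
  invisible(out)
}
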