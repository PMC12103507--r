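#' @title mwTab documents
#'
#' @description
#' `MwTabDocument` holds one parsed mwTab analysis document: the
#' line-oriented, sectioned key-value metadata format of the Metabolomics
#' Workbench / National Metabolomics Data Repository (NMDR). One document
#' describes one analysis; a study may map to several documents (e.g. a
#' positive- and a negative-mode analysis).
#'
#' @slot analysisId Analysis accession (from the mandatory header line).
#' @slot studyId Study accession (from the mandatory header line).
#' @slot sections Ordered named list; each element is a named character
#'   vector of key/value entries for one section. Unknown sections are
#'   preserved verbatim.
#' @slot sampleFactors List of sample rows; each row is a list with
#'   elements `sample_id`, `subject`, `factors` (named character) and
#'   `additional` (named character, includes any raw-file descriptors).
#' @slot polarity One of `"positive"`, `"negative"`, `"unspecified"`,
#'   read from the MS section when present.
#'
#' @seealso [parseMwTab()], [writeMwTab()], [extractSampleDescriptors()]
#' @export
setClass("MwTabDocument",
  representation(analysisId = "character",
                 studyId = "character",
                 sections = "list",
                 sampleFactors = "list",
                 polarity = "character"))

setValidity("MwTabDocument", function(object) {
  msg <- character()
  if (!object@polarity %in% c("positive", "negative", "unspecified"))
    msg <- c(msg, "polarity must be positive/negative/unspecified")
  sids <- vapply(object@sampleFactors, function(r) r$sample_id, character(1))
  if (any(!nzchar(sids)))
    msg <- c(msg, "every sample factor row must carry a sample identifier")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MwTabDocument", function(object) {
  cat("MwTabDocument", object@analysisId, "(study", paste0(object@studyId, ")"), "\n")
  cat("  sections:", paste(names(object@sections), collapse = ", "), "\n")
  cat("  samples:", length(object@sampleFactors),
      " polarity:", object@polarity, "\n")
  invisible(object)
})

#' @describeIn MwTabDocument-class Analysis accession accessor
#' @param x A `MwTabDocument`.
#' @export
analysisId <- function(x) x@analysisId

#' @describeIn MwTabDocument-class Section list accessor
#' @export
mwtabSections <- function(x) x@sections

#' @describeIn MwTabDocument-class Sample factor rows accessor
#' @export
sampleFactors <- function(x) x@sampleFactors

#' @describeIn MwTabDocument-class Reported ionization polarity accessor
#' @export
mwtabPolarity <- function(x) x@polarity

# Normalize a reported ionization mode to the controlled polarity set.
.mapPolarity <- function(value) {
  if (is.null(value) || is.na(value)) return("unspecified")
  v <- toupper(.normWs(value))
  # Both the ASCII hyphen and the unicode minus occur in deposits.
  if (v %in% c("POSITIVE", "POS", "ESI+")) return("positive")
  if (v %in% c("NEGATIVE", "NEG", "ESI-", "ESI\u2212")) return("negative")
  "unspecified"
}

# Split a key/value line: first delimiter (tab or colon) wins.
.splitKeyLine <- function(line) {
  tabAt <- regexpr("\t", line, fixed = TRUE)
  colonAt <- regexpr(":", line, fixed = TRUE)
  at <- c(tabAt, colonAt)
  at <- at[at > 0L]
  if (!length(at)) return(NULL)
  at <- min(at)
  key <- trimws(substr(line, 1L, at - 1L))
  value <- trimws(substr(line, at + 1L, nchar(line)))
  if (!nzchar(key)) return(NULL)
  c(key, value)
}

# Parse "k:v | k:v" factor strings and "k=v; k=v" additional-data strings.
.parsePairs <- function(text, pairSep, kvSep) {
  text <- trimws(text)
  if (!nzchar(text) || text == "-") return(character(0))
  out <- character(0)
  for (piece in trimws(strsplit(text, pairSep, fixed = TRUE)[[1]])) {
    if (!nzchar(piece)) next
    at <- regexpr(kvSep, piece, fixed = TRUE)
    if (at > 0L) {
      k <- trimws(substr(piece, 1L, at - 1L))
      v <- trimws(substr(piece, at + 1L, nchar(piece)))
      out[k] <- v
    } else {
      out[piece] <- ""
    }
  }
  out
}

.formatPairs <- function(x, pairSep, kvSep) {
  if (!length(x)) return("-")
  paste(paste0(names(x), kvSep, unname(x)), collapse = pairSep)
}

#' Parse an mwTab document
#'
#' Accepts the line-oriented mwTab dialect: a mandatory
#' `#METABOLOMICS WORKBENCH STUDY_ID:... ANALYSIS_ID:...` header line,
#' `#SECTION` headers, and key/value lines delimited by a tab or a colon
#' (first delimiter wins). The `SUBJECT_SAMPLE_FACTORS` section holds
#' tab-delimited rows `subject TAB sample TAB factors TAB additional data`
#' with `name:value | name:value` factors and `key=value; key=value`
#' additional data. Unknown sections are preserved. Malformed key lines are
#' skipped with a warning; a missing header raises `mwtab_parse_error`.
#'
#' @param x Path to a file, or a character vector of lines (length > 1 or
#'   containing newlines).
#' @return A [MwTabDocument-class].
#' @export
parseMwTab <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    lines <- strsplit(.readTextMaybeGz(x), "\r?\n")[[1]]
  } else {
    lines <- unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- sub("\r$", "", lines)
  hdrIdx <- which(startsWith(lines, "#METABOLOMICS WORKBENCH"))
  if (!length(hdrIdx))
    .err("mwtab_parse_error",
         "missing mandatory '#METABOLOMICS WORKBENCH' header section")
  hdr <- lines[hdrIdx[1]]
  getTok <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, ":[^ \t]+"), hdr))
    if (!length(m)) "" else sub(paste0(key, ":"), "", m)
  }
  studyId <- getTok("STUDY_ID")
  analysisIdent <- getTok("ANALYSIS_ID")
  if (!nzchar(analysisIdent))
    .err("mwtab_parse_error", "header line lacks an ANALYSIS_ID token")

  sections <- list()
  factorRows <- list()
  current <- NULL
  for (line in lines[-seq_len(hdrIdx[1])]) {
    if (!nzchar(trimws(line))) next
    if (startsWith(line, "#")) {
      # Section name = token up to the first ':' or whitespace.
      nm <- sub("^#", "", line)
      nm <- sub("[:\t ].*$", "", nm)
      if (nm == "END") { current <- NULL; next }  # document terminator
      current <- nm
      if (is.null(sections[[nm]]) && nm != "SUBJECT_SAMPLE_FACTORS")
        sections[[nm]] <- character(0)
      next
    }
    if (is.null(current)) next
    if (current == "SUBJECT_SAMPLE_FACTORS") {
      fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
      length(fields) <- 4L
      fields[is.na(fields)] <- ""
      sid <- trimws(fields[2])
      if (!nzchar(sid)) {
        warning(sprintf("sample factor row without a sample id skipped: '%s'",
                        line), call. = FALSE)
        next
      }
      factorRows[[length(factorRows) + 1L]] <- list(
        sample_id = sid,
        subject = trimws(fields[1]),
        factors = .parsePairs(fields[3], "|", ":"),
        additional = .parsePairs(fields[4], ";", "=")
      )
    } else {
      kv <- .splitKeyLine(line)
      if (is.null(kv)) {
        warning(sprintf("malformed key line skipped in section %s: '%s'",
                        current, line), call. = FALSE)
        next
      }
      sec <- sections[[current]]
      sec[kv[1]] <- kv[2]
      sections[[current]] <- sec
    }
  }

  polarity <- "unspecified"
  ms <- sections[["MS"]]
  if (!is.null(ms)) {
    for (key in c("ION_MODE", "POLARITY")) {
      if (!is.na(ms[key]) && nzchar(ms[key])) {
        polarity <- .mapPolarity(ms[[key]])
        if (polarity != "unspecified") break
      }
    }
  }

  new("MwTabDocument", analysisId = analysisIdent, studyId = studyId,
      sections = sections, sampleFactors = factorRows, polarity = polarity)
}

#' Serialize an mwTab document
#'
#' Emits the tab-delimited dialect. Round trip:
#' `parseMwTab(writeMwTab(doc))` reproduces all sections, sample factor
#' rows and polarity (comments and the original delimiter style are not
#' preserved).
#'
#' @param doc A [MwTabDocument-class].
#' @param path Optional output path; when `NULL` the lines are returned.
#' @return Character vector of lines (invisibly when `path` is given).
#' @export
writeMwTab <- function(doc, path = NULL) {
  stopifnot(is(doc, "MwTabDocument"))
  lines <- sprintf("#METABOLOMICS WORKBENCH STUDY_ID:%s ANALYSIS_ID:%s",
                   doc@studyId, doc@analysisId)
  for (nm in names(doc@sections)) {
    lines <- c(lines, paste0("#", nm))
    sec <- doc@sections[[nm]]
    if (length(sec))
      lines <- c(lines, paste0(names(sec), "\t", unname(sec)))
  }
  if (length(doc@sampleFactors)) {
    lines <- c(lines, "#SUBJECT_SAMPLE_FACTORS")
    for (row in doc@sampleFactors) {
      lines <- c(lines, paste(
        if (nzchar(row$subject)) row$subject else "-",
        row$sample_id,
        .formatPairs(row$factors, " | ", ":"),
        .formatPairs(row$additional, "; ", "="),
        sep = "\t"))
    }
  }
  lines <- c(lines, "#END")
  if (!is.null(path)) {
    .writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Extract per-sample raw-file descriptor candidates
#'
#' Gathers, for every sample row, the strings that may name that sample's
#' raw files, in cascade priority order: entries of a repository-provided
#' per-sample file table first, then "additional sample data" values, then
#' factor values, then the sample identifier itself. Values are kept
#' verbatim (multi-file values are split later, by the linker).
#'
#' @param doc A [MwTabDocument-class].
#' @param fileTable Optional named list/character: `sample_id` to file
#'   name(s), the stand-in for the repository REST file table.
#' @return Named list: `sample_id` to character vector of descriptors.
#' @export
extractSampleDescriptors <- function(doc, fileTable = NULL) {
  out <- list()
  for (row in doc@sampleFactors) {
    d <- character(0)
    if (!is.null(fileTable) && !is.null(fileTable[[row$sample_id]]))
      d <- c(d, as.character(fileTable[[row$sample_id]]))
    d <- c(d, unname(row$additional), unname(row$factors), row$sample_id)
    d <- d[nzchar(trimws(d))]
    existing <- out[[row$sample_id]]
    out[[row$sample_id]] <- unique(c(existing, d))
  }
  out
}
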