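#' @title Scan-level summaries of raw MS files
#'
#' @description
#' `ScanSummary` tallies the scans of one raw file by MS level and
#' ionization polarity. Only spectrum headers are consulted; peak arrays
#' are never decoded. Polarity is read per spectrum (the
#' positive-scan/negative-scan controlled-vocabulary terms in mzML, the
#' `polarity` attribute in mzXML); no file-level default is assumed, since
#' mixed-polarity files exist and drive the linker's disambiguation.
#'
#' @slot runPath Path the summary was computed from.
#' @slot counts data.frame with columns `ms_level` (integer >= 1),
#'   `polarity` (`positive`/`negative`/`unknown`) and `n`.
#' @slot totalScans Total number of spectra; equals `sum(counts$n)`.
#'
#' @seealso [summarizeScans()], [hasMsms()], [verifyIntegrity()]
#' @export
setClass("ScanSummary",
  representation(runPath = "character",
                 counts = "data.frame",
                 totalScans = "integer"))

setValidity("ScanSummary", function(object) {
  msg <- character()
  if (!identical(object@totalScans, as.integer(sum(object@counts$n))))
    msg <- c(msg, "totalScans must equal the sum over counts")
  if (nrow(object@counts) && any(object@counts$ms_level < 1L))
    msg <- c(msg, "ms_level keys must be >= 1")
  if (nrow(object@counts) &&
      !all(object@counts$polarity %in% c("positive", "negative", "unknown")))
    msg <- c(msg, "polarity must be positive/negative/unknown")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ScanSummary", function(object) {
  cat("ScanSummary:", object@runPath, "-", object@totalScans, "scans\n")
  if (nrow(object@counts)) print(object@counts)
  invisible(object)
})

#' @describeIn ScanSummary-class Count table accessor
#' @param x A `ScanSummary`.
#' @export
scanCounts <- function(x) x@counts

#' @describeIn ScanSummary-class Total scan count accessor
#' @export
totalScans <- function(x) x@totalScans

# Build a ScanSummary from per-spectrum level/polarity vectors.
.tallyScans <- function(path, levels, polarities) {
  if (length(levels)) {
    df <- as.data.frame(table(ms_level = levels, polarity = polarities),
                        stringsAsFactors = FALSE)
    df <- df[df$Freq > 0L, , drop = FALSE]
    df <- data.frame(ms_level = as.integer(df$ms_level),
                     polarity = df$polarity,
                     n = as.integer(df$Freq),
                     stringsAsFactors = FALSE)
    df <- df[order(df$ms_level, df$polarity), , drop = FALSE]
    rownames(df) <- NULL
  } else {
    df <- data.frame(ms_level = integer(), polarity = character(),
                     n = integer(), stringsAsFactors = FALSE)
  }
  new("ScanSummary", runPath = path, counts = df,
      totalScans = as.integer(sum(df$n)))
}

.parseMsXml <- function(path) {
  text <- tryCatch(.readTextMaybeGz(path), error = function(e) NULL)
  if (is.null(text) || !nzchar(text))
    .err("ms_integrity_error", "'%s' is empty or unreadable", path)
  doc <- tryCatch(xml2::read_xml(text), error = function(e) NULL)
  if (is.null(doc))
    .err("ms_integrity_error", "'%s' is not well-formed XML", path)
  xml2::xml_ns_strip(doc)
  doc
}

#' Summarize the scans of an mzML/mzXML file
#'
#' The format is detected from the root element (`mzML`, `indexedmzML`, or
#' `mzXML`); plain and gzip-compressed files are accepted. A file that is
#' not well-formed XML, or whose root is unexpected, raises an error of
#' class `ms_integrity_error` — distinct from a valid file with zero
#' spectra, which yields an empty summary.
#'
#' @param path File path.
#' @return A [ScanSummary-class].
#' @export
summarizeScans <- function(path) {
  doc <- .parseMsXml(path)
  root <- xml2::xml_name(doc)
  ext <- .fileExt(sub("\\.gz$", "", .lc(basename(path))))
  if ((ext == "mzml" && !root %in% c("mzML", "indexedmzML")) ||
      (ext == "mzxml" && root != "mzXML"))
    .err("ms_integrity_error",
         "root element <%s> does not match the extension of '%s'", root, path)
  if (root == "indexedmzML") {
    inner <- xml2::xml_find_first(doc, "./mzML")
    if (inherits(inner, "xml_missing"))
      .err("ms_integrity_error", "indexedmzML wrapper without mzML in '%s'",
           path)
    doc <- inner
    root <- "mzML"
  }
  if (root == "mzML") {
    spectra <- xml2::xml_find_all(doc, ".//spectrumList/spectrum")
    levels <- vapply(spectra, function(s) {
      v <- xml2::xml_attr(
        xml2::xml_find_first(s, "./cvParam[@accession='MS:1000511']"),
        "value")
      if (is.na(v)) 1L else as.integer(v)
    }, integer(1))
    polarities <- vapply(spectra, function(s) {
      if (!inherits(xml2::xml_find_first(
        s, "./cvParam[@accession='MS:1000130']"), "xml_missing"))
        return("positive")
      if (!inherits(xml2::xml_find_first(
        s, "./cvParam[@accession='MS:1000129']"), "xml_missing"))
        return("negative")
      "unknown"
    }, character(1))
  } else if (root == "mzXML") {
    scans <- xml2::xml_find_all(doc, ".//scan")
    levels <- vapply(scans, function(s) {
      v <- xml2::xml_attr(s, "msLevel")
      if (is.na(v)) 1L else as.integer(v)
    }, integer(1))
    polarities <- vapply(scans, function(s) {
      v <- xml2::xml_attr(s, "polarity")
      if (is.na(v)) "unknown"
      else if (v == "+") "positive"
      else if (v == "-") "negative"
      else "unknown"
    }, character(1))
  } else {
    .err("ms_integrity_error",
         "unexpected root element <%s> in '%s'", root, path)
  }
  .tallyScans(path, levels, polarities)
}

#' Does a file contain fragmentation (MS/MS) scans?
#'
#' @param summary A [ScanSummary-class].
#' @return `TRUE` iff any scan with MS level >= 2 was counted.
#' @export
hasMsms <- function(summary) {
  counts <- scanCounts(summary)
  any(counts$ms_level >= 2L & counts$n > 0L)
}

#' Verify the integrity of a raw data file
#'
#' For the open XML formats the file must be well-formed XML with the root
#' element expected for its extension (mzML or the indexed wrapper for
#' `.mzML`, mzXML for `.mzXML`). For other formats only a non-zero size is
#' required — a deliberately weaker check, since no portable structural
#' test exists for vendor containers.
#'
#' @param path File path (must exist).
#' @return `TRUE` or `FALSE`; never throws for malformed content.
#' @export
verifyIntegrity <- function(path) {
  if (!file.exists(path)) return(FALSE)
  ext <- sub("\\.gz$", "", .lc(basename(path)))
  ext <- .fileExt(ext)
  if (!ext %in% c("mzml", "mzxml")) {
    info <- file.info(path)
    return(isTRUE(info$size > 0) || isTRUE(info$isdir))
  }
  doc <- tryCatch(.parseMsXml(path), error = function(e) NULL)
  if (is.null(doc)) return(FALSE)
  root <- xml2::xml_name(doc)
  (ext == "mzml" && root %in% c("mzML", "indexedmzML")) ||
    (ext == "mzxml" && root == "mzXML")
}
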