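#' @title MS Run Identifiers
#'
#' @description
#' An MS Run Identifier (MRI) names one raw mass spectrometry run in a public
#' repository. It is the dataset-and-file-path subset of the Universal
#' Spectrum Identifier (USI) standard: `mzspec:<accession>:<run path>`. The
#' accession determines the source repository; the run path is the file's
#' location inside the dataset.
#'
#' @slot datasetAccession Repository study/dataset accession
#'   (e.g. `"MSV000085852"`, `"MTBLS1234"`, `"ST000123"`).
#' @slot runPath Relative path of the raw file inside the dataset
#'   (slash-separated, no leading slash, no `..` segments).
#' @slot repository Repository name resolved from the accession pattern.
#'
#' @seealso [parseMri()], [formatMri()], [classifyRepository()]
#' @export
setClass("MsRunIdentifier",
  representation(datasetAccession = "character",
                 runPath = "character",
                 repository = "character"))

setValidity("MsRunIdentifier", function(object) {
  msg <- character()
  if (length(object@datasetAccession) != 1L || !nzchar(object@datasetAccession))
    msg <- c(msg, "datasetAccession must be a single non-empty string")
  if (length(object@runPath) != 1L || !nzchar(object@runPath))
    msg <- c(msg, "runPath must be a single non-empty string")
  else {
    segs <- strsplit(object@runPath, "/", fixed = TRUE)[[1]]
    if (any(segs == ".."))
      msg <- c(msg, "runPath must not contain path-traversal ('..') segments")
    if (startsWith(object@runPath, "/"))
      msg <- c(msg, "runPath must not start with '/'")
  }
  if (length(msg)) msg else TRUE
})

# USI scheme prefix for an MRI.
.MRI_SCHEME <- "mzspec"

#' Repository accession registry
#'
#' The registry used to classify dataset accessions. Patterns are anchored
#' and mutually exclusive: an accession matches at most one repository.
#'
#' @return A data.frame with columns `name` and `pattern`.
#' @examples
#' repositoryRegistry()
#' @export
repositoryRegistry <- function() {
  data.frame(
    name = c("GNPS/MassIVE", "MTBLS", "NMDR"),
    pattern = c("^MSV[0-9]{9}$", "^MTBLS[0-9]+$", "^ST[0-9]{6}$"),
    stringsAsFactors = FALSE
  )
}

#' Classify a dataset accession into a repository
#'
#' @param accession Dataset accession string.
#' @param registry Accession registry, see [repositoryRegistry()].
#' @return The repository name (single character string). An accession that
#'   matches none of the registered patterns raises an error of class
#'   `mri_accession_error`.
#' @examples
#' classifyRepository("MTBLS1234")
#' classifyRepository("ST001234")
#' @export
classifyRepository <- function(accession, registry = repositoryRegistry()) {
  if (length(accession) != 1L || is.na(accession) || !nzchar(accession))
    .err("mri_accession_error", "accession must be a non-empty string")
  hits <- vapply(registry$pattern, function(p) grepl(p, accession), logical(1))
  if (sum(hits) == 0L)
    .err("mri_accession_error",
         "accession '%s' does not match any supported repository", accession)
  if (sum(hits) > 1L)
    .err("mri_accession_error",
         "accession '%s' matches more than one repository pattern", accession)
  registry$name[hits]
}

#' Supported raw-data file extensions
#'
#' Raw mass spectrometry data formats indexed by the harmonizer: the open
#' XML formats plus the common vendor formats.
#'
#' @return Character vector of lower-case extensions.
#' @export
supportedExtensions <- function() c("mzml", "mzxml", "raw", "wiff", "cdf", "d")

#' Open (non-vendor) raw-data extensions
#' @return Character vector of lower-case extensions.
#' @export
openExtensions <- function() c("mzml", "mzxml")

#' Test whether a run path has a supported raw-data extension
#'
#' Matching is case-insensitive on the terminal extension; directory-style
#' formats (`.d`) are matched as a terminal suffix like the others.
#'
#' @param runPath Character vector of paths.
#' @return Logical vector.
#' @examples
#' hasSupportedExtension(c("x/y/sample.mzML", "x/sample.WIFF", "x/readme.txt"))
#' @export
hasSupportedExtension <- function(runPath) {
  .fileExt(runPath) %in% supportedExtensions()
}

#' Construct an MS Run Identifier
#'
#' @param datasetAccession Dataset accession.
#' @param runPath Relative file path within the dataset.
#' @param registry Accession registry, see [repositoryRegistry()].
#' @return A [MsRunIdentifier-class] object.
#' @examples
#' MsRunIdentifier("MSV000085852", "ccms_peak/a/sample1.mzML")
#' @export
MsRunIdentifier <- function(datasetAccession, runPath,
                            registry = repositoryRegistry()) {
  repo <- classifyRepository(datasetAccession, registry)
  new("MsRunIdentifier", datasetAccession = datasetAccession,
      runPath = runPath, repository = repo)
}

#' Parse an MRI string
#'
#' Splits `mzspec:<accession>:<path>` at the first two colons. Scan-level
#' USIs (carrying a `:scan:` suffix) are accepted and truncated to the MRI.
#' Bare colons inside run paths are rejected (percent-encode them); spaces
#' pass through unchanged.
#'
#' @param text A single MRI string.
#' @param registry Accession registry, see [repositoryRegistry()].
#' @return A [MsRunIdentifier-class].
#'   Malformed prefixes raise `mri_prefix_error`, unrecognized accessions
#'   `mri_accession_error`, and empty/invalid paths `mri_path_error`.
#' @examples
#' parseMri("mzspec:MSV000085852:ccms_peak/a/sample1.mzML")
#' @export
parseMri <- function(text, registry = repositoryRegistry()) {
  if (length(text) != 1L || is.na(text))
    .err("mri_prefix_error", "MRI must be a single string")
  parts <- regmatches(text, regexpr(":", text, fixed = TRUE), invert = TRUE)[[1]]
  if (length(parts) != 2L || parts[1] != .MRI_SCHEME)
    .err("mri_prefix_error",
         "MRI must begin with the '%s:' scheme prefix (got '%s')",
         .MRI_SCHEME, text)
  rest <- parts[2]
  parts2 <- regmatches(rest, regexpr(":", rest, fixed = TRUE), invert = TRUE)[[1]]
  if (length(parts2) != 2L)
    .err("mri_path_error", "MRI '%s' has no run path component", text)
  accession <- parts2[1]
  path <- parts2[2]
  # Accept-and-truncate scan-level USIs: mzspec:ACC:path:scan:N
  if (grepl(":", path, fixed = TRUE)) {
    scanAt <- regexpr(":scan:", path, fixed = TRUE)
    if (scanAt > 0L) {
      path <- substr(path, 1L, scanAt - 1L)
    } else {
      .err("mri_path_error",
           "run path of '%s' contains an unencoded ':'", text)
    }
  }
  if (!nzchar(path))
    .err("mri_path_error", "MRI '%s' has an empty run path", text)
  if (startsWith(path, "/"))
    .err("mri_path_error", "run path of '%s' must be relative", text)
  if (any(strsplit(path, "/", fixed = TRUE)[[1]] == ".."))
    .err("mri_path_error", "run path of '%s' contains '..'", text)
  MsRunIdentifier(accession, path, registry)
}

#' Format an MRI as a string
#'
#' Inverse of [parseMri()]: `formatMri(parseMri(s)) == s` for every valid
#' MRI string `s`.
#'
#' @param x A [MsRunIdentifier-class].
#' @return The MRI string.
#' @export
formatMri <- function(x) {
  stopifnot(is(x, "MsRunIdentifier"))
  paste(.MRI_SCHEME, x@datasetAccession, x@runPath, sep = ":")
}

#' @describeIn MsRunIdentifier-class Dataset accession accessor
#' @param x A `MsRunIdentifier`.
#' @export
datasetAccession <- function(x) x@datasetAccession

#' @describeIn MsRunIdentifier-class Run path accessor
#' @export
runPath <- function(x) x@runPath

#' @describeIn MsRunIdentifier-class Repository name accessor
#' @export
repositoryOf <- function(x) x@repository

setMethod("show", "MsRunIdentifier", function(object) {
  cat("MsRunIdentifier:", formatMri(object), "\n")
  cat("  repository:", object@repository, "\n")
  invisible(object)
})

#' Read a one-MRI-per-line text file
#'
#' The bulk input format of the retrieval layer. Blank lines and lines
#' starting with `#` are skipped.
#'
#' @param path File path.
#' @return Character vector of MRI strings (unparsed).
#' @export
readMriList <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}
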