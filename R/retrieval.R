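#' @title MRI-based raw data retrieval
#'
#' @description
#' Retrieval follows a three-step workflow per MRI: (1) probe an internal
#' cache and verify the cached file's integrity (mzML/mzXML must be valid
#' XML; other formats only need non-zero size); (2) on a miss or an
#' integrity failure, download from the repository backend, writing to a
#' temporary file and renaming atomically so interrupted downloads never
#' appear as cache entries; (3) report, per MRI, the path taken
#' (`cache_hit`, `downloaded`, `integrity_failed_then_redownloaded`, or
#' `error` with a reason). Partial failures never abort a batch.
#'
#' Backends are pluggable: [LocalFileBackend()] serves files from a local
#' directory tree (the mock used throughout the test suite) and
#' [HttpBackend()] adapts a URL template to the public repositories.
#' The cache key is `accession/run_path`, matching MRI semantics.
#'
#' @name retrieval
NULL

#' @title Repository backend interface
#' @description Virtual parent class of retrieval backends. A backend
#'   resolves an [MsRunIdentifier-class] to file content or not-found, and
#'   must be repeatable: two calls for the same MRI yield byte-identical
#'   content or a consistent not-found.
#' @export
setClass("RepositoryBackend", representation("VIRTUAL"))

#' Resolve one MRI through a backend
#' @param backend A [RepositoryBackend-class].
#' @param mri A [MsRunIdentifier-class].
#' @return A raw vector of file content, or `NULL` when not found.
#' @export
setGeneric("resolveRun", function(backend, mri) standardGeneric("resolveRun"))

#' @title Local filesystem backend
#' @description Serves `<root>/<accession>/<run path>`; the mock backend
#'   used in tests and offline demos.
#' @slot root Directory holding one subdirectory per dataset accession.
#' @export
setClass("LocalFileBackend", contains = "RepositoryBackend",
         representation(root = "character"))

#' @rdname LocalFileBackend-class
#' @param root Backend root directory.
#' @export
LocalFileBackend <- function(root) new("LocalFileBackend", root = root)

#' @describeIn LocalFileBackend-class Resolve from the directory tree
#' @param backend,mri See [resolveRun()].
#' @export
setMethod("resolveRun", "LocalFileBackend", function(backend, mri) {
  path <- file.path(backend@root, datasetAccession(mri), runPath(mri))
  if (!file.exists(path)) return(NULL)
  readBin(path, "raw", n = file.info(path)$size)
})

#' @title HTTP repository backend
#' @description Adapter for live repository downloads. The URL template
#'   uses `{accession}` and `{path}` placeholders; endpoints are
#'   configuration, not code. Excluded from the offline test surface.
#' @slot urlTemplate Template string.
#' @export
setClass("HttpBackend", contains = "RepositoryBackend",
         representation(urlTemplate = "character"))

#' @rdname HttpBackend-class
#' @param urlTemplate URL template with `{accession}`/`{path}`.
#' @export
HttpBackend <- function(urlTemplate) new("HttpBackend",
                                         urlTemplate = urlTemplate)

#' @describeIn HttpBackend-class Resolve via HTTP download
#' @param backend,mri See [resolveRun()].
#' @export
setMethod("resolveRun", "HttpBackend", function(backend, mri) {
  url <- gsub("{accession}", datasetAccession(mri),
              gsub("{path}", runPath(mri), backend@urlTemplate,
                   fixed = TRUE), fixed = TRUE)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  ok <- tryCatch(utils::download.file(url, tmp, quiet = TRUE,
                                      mode = "wb") == 0L,
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(tmp)) return(NULL)
  readBin(tmp, "raw", n = file.info(tmp)$size)
})

#' Backend registry with one backend for every repository
#'
#' @param backend A single backend serving all three repositories (the
#'   usual mock setup), or `NULL` to build an entry-per-repository list
#'   yourself.
#' @return Named list keyed by repository name.
#' @export
backendRegistry <- function(backend) {
  stats::setNames(rep(list(backend), nrow(repositoryRegistry())),
                  repositoryRegistry()$name)
}

#' @title Retrieval report
#' @description Per-MRI outcome bookkeeping of one [fetchMris()] batch.
#'   Every requested MRI appears exactly once; the totals are derived from
#'   (and therefore always consistent with) the per-MRI table:
#'   `cache hits + downloads + errors == requests`.
#' @slot perMri data.frame with columns `mri`, `outcome`, `reason`.
#' @export
setClass("RetrievalReport", representation(perMri = "data.frame"))

setValidity("RetrievalReport", function(object) {
  ok <- all(c("mri", "outcome", "reason") %in% names(object@perMri)) &&
    !anyDuplicated(object@perMri$mri) &&
    all(object@perMri$outcome %in%
          c("cache_hit", "downloaded", "integrity_failed_then_redownloaded",
            "error"))
  if (ok) TRUE else "malformed per-MRI outcome table"
})

#' @describeIn RetrievalReport-class Per-MRI outcome accessor
#' @param x A `RetrievalReport`.
#' @export
perMriOutcomes <- function(x) x@perMri

#' @describeIn RetrievalReport-class Totals (success, cache hits, downloads,
#'   errors)
#' @export
retrievalTotals <- function(x) {
  o <- x@perMri$outcome
  list(requests = length(o),
       success = sum(o != "error"),
       cache_hits = sum(o == "cache_hit"),
       downloads = sum(o %in% c("downloaded",
                                "integrity_failed_then_redownloaded")),
       errors = sum(o == "error"))
}

setMethod("show", "RetrievalReport", function(object) {
  t <- retrievalTotals(object)
  cat("RetrievalReport:", t$requests, "requested |",
      t$cache_hits, "cache hits,", t$downloads, "downloaded,",
      t$errors, "errors\n")
  invisible(object)
})

.cacheIntegrity <- function(path) verifyIntegrity(path)

# Atomically place `content` at `path` (write-to-temp, rename).
.atomicWrite <- function(content, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".part")
  writeBin(content, tmp)
  if (!file.rename(tmp, path)) {
    unlink(tmp)
    .err("retrieval_error", "could not place '%s' into the cache", path)
  }
  invisible(path)
}

#' Fetch a batch of MRIs through the cache
#'
#' @param mris Character vector of MRI strings, or a list of
#'   [MsRunIdentifier-class] objects.
#' @param cache Writable cache directory.
#' @param backends Named backend registry (see [backendRegistry()]).
#' @return A [RetrievalReport-class]. Unknown repositories and backend
#'   failures become per-MRI `error` outcomes, never exceptions.
#' @export
fetchMris <- function(mris, cache, backends) {
  dir.create(cache, recursive = TRUE, showWarnings = FALSE)
  if (is.character(mris)) mriStrings <- mris
  else mriStrings <- vapply(mris, formatMri, character(1))
  rows <- lapply(mriStrings, function(s) {
    mri <- tryCatch(parseMri(s), error = function(e) e)
    if (inherits(mri, "error"))
      return(data.frame(mri = s, outcome = "error",
                        reason = conditionMessage(mri),
                        stringsAsFactors = FALSE))
    backend <- backends[[repositoryOf(mri)]]
    if (is.null(backend))
      return(data.frame(mri = s, outcome = "error",
                        reason = sprintf("no backend registered for %s",
                                         repositoryOf(mri)),
                        stringsAsFactors = FALSE))
    target <- file.path(cache, datasetAccession(mri), runPath(mri))
    hadEntry <- file.exists(target)
    if (hadEntry && .cacheIntegrity(target))
      return(data.frame(mri = s, outcome = "cache_hit", reason = "",
                        stringsAsFactors = FALSE))
    content <- tryCatch(resolveRun(backend, mri), error = function(e) e)
    if (inherits(content, "error"))
      return(data.frame(mri = s, outcome = "error",
                        reason = conditionMessage(content),
                        stringsAsFactors = FALSE))
    if (is.null(content))
      return(data.frame(mri = s, outcome = "error",
                        reason = "not found in repository",
                        stringsAsFactors = FALSE))
    .atomicWrite(content, target)
    if (!.cacheIntegrity(target)) {
      unlink(target)
      return(data.frame(mri = s, outcome = "error",
                        reason = "downloaded file failed integrity check",
                        stringsAsFactors = FALSE))
    }
    data.frame(mri = s,
               outcome = if (hadEntry) "integrity_failed_then_redownloaded"
                         else "downloaded",
               reason = "", stringsAsFactors = FALSE)
  })
  new("RetrievalReport", perMri = do.call(rbind, rows))
}

#' Write a retrieval report (TSV and/or JSON)
#'
#' @param report A [RetrievalReport-class].
#' @param tsvPath,jsonPath Output paths (either may be `NULL`).
#' @return The per-MRI data.frame, invisibly.
#' @export
writeRetrievalReport <- function(report, tsvPath = NULL, jsonPath = NULL) {
  df <- perMriOutcomes(report)
  if (!is.null(tsvPath)) .writeTsv(df, tsvPath)
  if (!is.null(jsonPath))
    jsonlite::write_json(list(per_mri = df, totals = retrievalTotals(report)),
                         jsonPath, auto_unbox = TRUE, pretty = TRUE)
  invisible(df)
}

# Vendor formats that require conversion before open-format use.
.vendorExtensions <- function() setdiff(supportedExtensions(), openExtensions())

#' Request conversion of a vendor-format file (stub interface)
#'
#' Vendor files are converted by an external converter service; this
#' package only issues the request ticket. The ticket records the MRI and
#' an expiry 30 days after issue, after which the converted copy is no
#' longer guaranteed to be available.
#'
#' @param mri A [MsRunIdentifier-class] whose run path has a vendor
#'   extension; an open-format MRI raises `conversion_error`.
#' @param issuedAt Issue time (exposed for deterministic tests).
#' @return A list of class `ConversionTicket` with elements `mri`,
#'   `issuedAt`, `expiresAt`.
#' @export
requestConversion <- function(mri, issuedAt = Sys.time()) {
  ext <- .fileExt(runPath(mri))
  if (!ext %in% .vendorExtensions())
    .err("conversion_error",
         "'%s' is not a vendor format; no conversion needed", runPath(mri))
  structure(list(mri = formatMri(mri), issuedAt = issuedAt,
                 expiresAt = issuedAt + 30 * 86400),
            class = "ConversionTicket")
}
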