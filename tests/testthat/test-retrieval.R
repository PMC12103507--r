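# A mock repository tree with one valid mzML file per MRI.
makeMockRepo <- function(root, mris) {
  for (s in mris) {
    m <- parseMri(s)
    p <- file.path(root, datasetAccession(m), runPath(m))
    generateMzml(data.frame(ms_level = 1L, polarity = "positive"), p)
  }
  LocalFileBackend(root)
}

test_that("the cache is filled on first fetch and hit on the second", {
  repo <- withr::local_tempdir()
  cache <- withr::local_tempdir()
  mri <- "mzspec:ST000001:raw/a.mzML"
  backend <- makeMockRepo(repo, mri)
  r1 <- fetchMris(mri, cache, backendRegistry(backend))
  expect_equal(perMriOutcomes(r1)$outcome, "downloaded")
  r2 <- fetchMris(mri, cache, backendRegistry(backend))
  expect_equal(perMriOutcomes(r2)$outcome, "cache_hit")
  # cached bytes are identical to the backend's bytes
  src <- file.path(repo, "ST000001/raw/a.mzML")
  dst <- file.path(cache, "ST000001/raw/a.mzML")
  expect_identical(readBin(dst, "raw", file.info(dst)$size),
                   readBin(src, "raw", file.info(src)$size))
})

test_that("corrupted cache entries heal through re-download", {
  repo <- withr::local_tempdir()
  cache <- withr::local_tempdir()
  mri <- "mzspec:MTBLS77:FILES/x.mzML"
  backend <- makeMockRepo(repo, mri)
  fetchMris(mri, cache, backendRegistry(backend))
  truncateFile(file.path(cache, "MTBLS77/FILES/x.mzML"), 0.4)
  r <- fetchMris(mri, cache, backendRegistry(backend))
  expect_equal(perMriOutcomes(r)$outcome,
               "integrity_failed_then_redownloaded")
  expect_true(verifyIntegrity(file.path(cache, "MTBLS77/FILES/x.mzML")))
})

test_that("batch bookkeeping is conserved and failures never abort the batch", {
  repo <- withr::local_tempdir()
  cache <- withr::local_tempdir()
  served <- c("mzspec:ST000001:raw/a.mzML", "mzspec:MSV000000001:p/b.mzML")
  backend <- makeMockRepo(repo, served)
  batch <- c(served, "mzspec:ST000002:raw/missing.mzML")
  r <- fetchMris(batch, cache, backendRegistry(backend))
  t <- retrievalTotals(r)
  expect_equal(t$success, 2L)
  expect_equal(t$errors, 1L)
  expect_equal(t$cache_hits + t$downloads + t$errors, length(batch))
  df <- perMriOutcomes(r)
  expect_equal(df$mri, batch)  # every requested MRI, exactly once, in order
  expect_match(df$reason[df$outcome == "error"], "not found")
  # an unparsable MRI and an unregistered repository are per-MRI errors
  r2 <- fetchMris(c("garbage", served[1]), cache,
                  list(NMDR = backend))  # registry lacking GNPS/MassIVE
  expect_equal(perMriOutcomes(r2)$outcome[1], "error")
  r3 <- fetchMris("mzspec:MSV000000001:p/b.mzML", cache,
                  list(NMDR = backend))
  expect_match(perMriOutcomes(r3)$reason, "no backend")
})

test_that("a second fetch of an unchanged batch is all cache hits with identical bytes", {
  repo <- withr::local_tempdir()
  cache <- withr::local_tempdir()
  mris <- sprintf("mzspec:ST00000%d:raw/f%d.mzML", 1:3, 1:3)
  backend <- makeMockRepo(repo, mris)
  fetchMris(mris, cache, backendRegistry(backend))
  snapshot <- lapply(list.files(cache, recursive = TRUE, full.names = TRUE),
                     function(p) readBin(p, "raw", file.info(p)$size))
  r <- fetchMris(mris, cache, backendRegistry(backend))
  expect_true(all(perMriOutcomes(r)$outcome == "cache_hit"))
  now <- lapply(list.files(cache, recursive = TRUE, full.names = TRUE),
                function(p) readBin(p, "raw", file.info(p)$size))
  expect_identical(now, snapshot)
})

test_that("conversion tickets are issued for vendor formats only, expiring after 30 days", {
  m <- MsRunIdentifier("MSV000000001", "raw/a.raw")
  issued <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC")
  ticket <- requestConversion(m, issuedAt = issued)
  expect_s3_class(ticket, "ConversionTicket")
  expect_equal(as.numeric(difftime(ticket$expiresAt, issued, units = "days")),
               30)
  open <- MsRunIdentifier("MSV000000001", "raw/a.mzML")
  expect_error(requestConversion(open), class = "conversion_error")
})

test_that("retrieval reports serialize to TSV and JSON", {
  repo <- withr::local_tempdir()
  cache <- withr::local_tempdir()
  mri <- "mzspec:ST000001:raw/a.mzML"
  backend <- makeMockRepo(repo, mri)
  r <- fetchMris(mri, cache, backendRegistry(backend))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  writeRetrievalReport(r, tsv, js)
  expect_equal(nrow(read.delim(tsv)), 1L)
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$totals$success, 1)
})
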