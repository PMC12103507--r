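mwtabLines <- function(...) {
  c("#METABOLOMICS WORKBENCH STUDY_ID:ST000123 ANALYSIS_ID:AN000201", ...)
}

test_that("mwTab sections, sample factor rows and polarity are captured", {
  doc <- parseMwTab(mwtabLines(
    "#SUBJECT",
    "SUBJECT_SPECIES\tHomo sapiens",
    "SUBJECT_TYPE:Human",
    "#MS",
    "ION_MODE\tNEGATIVE",
    "#CUSTOM_SECTION",
    "SOME_KEY\tsome value",
    "#SUBJECT_SAMPLE_FACTORS",
    "-\tS1\tTreatment:control | Sex:Female\tRAW_FILE_NAME=s1.raw",
    "-\tS2\tTreatment:case\t-"))
  expect_equal(analysisId(doc), "AN000201")
  expect_equal(mwtabSections(doc)$SUBJECT[["SUBJECT_SPECIES"]],
               "Homo sapiens")
  # colon-delimited key lines are accepted too (first delimiter wins)
  expect_equal(mwtabSections(doc)$SUBJECT[["SUBJECT_TYPE"]], "Human")
  # unknown sections are preserved verbatim
  expect_equal(mwtabSections(doc)$CUSTOM_SECTION[["SOME_KEY"]], "some value")
  expect_equal(mwtabPolarity(doc), "negative")
  rows <- sampleFactors(doc)
  expect_length(rows, 2L)
  expect_equal(rows[[1]]$sample_id, "S1")
  expect_equal(rows[[1]]$factors[["Sex"]], "Female")
  expect_equal(rows[[1]]$additional[["RAW_FILE_NAME"]], "s1.raw")
  expect_length(rows[[2]]$additional, 0L)
})

test_that("polarity spellings map onto the controlled polarity set", {
  cases <- list(POSITIVE = "positive", pos = "positive", `ESI+` = "positive",
                NEGATIVE = "negative", Neg = "negative", `ESI-` = "negative",
                UNKNOWN = "unspecified")
  for (raw in names(cases)) {
    doc <- parseMwTab(mwtabLines("#MS", paste0("ION_MODE\t", raw)))
    expect_equal(mwtabPolarity(doc), cases[[raw]], label = raw)
  }
  # no MS section at all
  doc <- parseMwTab(mwtabLines("#SUBJECT", "SUBJECT_TYPE\tHuman"))
  expect_equal(mwtabPolarity(doc), "unspecified")
})

test_that("degenerate documents parse without errors, malformed input is flagged", {
  # empty SUBJECT_SAMPLE_FACTORS block: zero rows, no error
  doc <- parseMwTab(mwtabLines("#SUBJECT_SAMPLE_FACTORS"))
  expect_length(sampleFactors(doc), 0L)
  # missing mandatory header
  expect_error(parseMwTab(c("#SUBJECT", "KEY\tv")),
               class = "mwtab_parse_error")
  # malformed key line: warning, line skipped, rest intact
  expect_warning(
    doc <- parseMwTab(mwtabLines("#SUBJECT", "NO DELIMITER HERE",
                                 "SUBJECT_SPECIES\tMus musculus")),
    "malformed")
  expect_equal(mwtabSections(doc)$SUBJECT[["SUBJECT_SPECIES"]],
               "Mus musculus")
})

test_that("serialize/parse round-trips reproduce all key/value content", {
  set.seed(23)
  for (i in 1:10) {
    sections <- list(
      PROJECT = c(PROJECT_TITLE = paste("t", i), SUBMIT_DATE = "2020-01-02"),
      SUBJECT = c(SUBJECT_SPECIES = sample(c("Homo sapiens", "Mus musculus"),
                                           1)),
      MS = c(ION_MODE = sample(c("POSITIVE", "NEGATIVE"), 1),
             INSTRUMENT_NAME = "Q Exactive"))
    rows <- lapply(seq_len(sample(0:4, 1)), function(j) {
      list(sample_id = sprintf("S%02d", j), subject = "-",
           factors = c(Treatment = sample(c("case", "control"), 1)),
           additional = c(RAW_FILE_NAME = sprintf("f%02d.raw", j)))
    })
    doc <- new("MwTabDocument", analysisId = sprintf("AN%06d", i),
               studyId = "ST000999", sections = sections,
               sampleFactors = rows,
               polarity = if (sections$MS[["ION_MODE"]] == "POSITIVE")
                 "positive" else "negative")
    back <- parseMwTab(writeMwTab(doc))
    expect_identical(mwtabSections(back), mwtabSections(doc))
    expect_identical(sampleFactors(back), sampleFactors(doc))
    expect_identical(mwtabPolarity(back), mwtabPolarity(doc))
    expect_identical(analysisId(back), analysisId(doc))
  }
})

test_that("descriptor extraction follows the stated priority order", {
  doc <- parseMwTab(mwtabLines(
    "#SUBJECT_SAMPLE_FACTORS",
    "-\tS1\tGroup:a\tRAW_FILE_NAME=s1.raw",
    "-\tS2\tFiles:a.mzML;b.mzML\t-",
    "-\tS3\t-\t-"))
  d <- extractSampleDescriptors(doc)
  # additional data first, then factor values, then the sample id
  expect_equal(d$S1, c("s1.raw", "a", "S1"))
  # multi-file factor values are retained unsplit (splitting is the
  # linker's job); note ";" inside a factor value survives
  expect_equal(d$S2, c("a.mzML;b.mzML", "S2"))
  expect_equal(d$S3, "S3")
  # a repository-provided file table takes highest priority
  d2 <- extractSampleDescriptors(doc, fileTable = list(S1 = "table.mzML"))
  expect_equal(d2$S1[1], "table.mzML")
})
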