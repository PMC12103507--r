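mri1 <- "mzspec:ST000123:raw/a.mzML"

test_that("one piece of sample-descriptive metadata is necessary and sufficient", {
  # organism alone suffices
  v <- acceptRecord(c(MRI = mri1, NCBITaxonomy = "9606|Homo sapiens"))
  expect_true(v$accepted)
  expect_equal(unname(v$record["NCBITaxonomy"]), "9606|Homo sapiens")
  expect_equal(unname(v$record["BiologicalSex"]), missingToken())
  # a solvent-blank designation suffices
  expect_true(acceptRecord(c(MRI = mri1,
                             SampleType = "blank_extraction"))$accepted)
  # body part alone suffices
  expect_true(acceptRecord(c(MRI = mri1,
                             UBERONBodyPartName = "urine"))$accepted)
  # technical metadata alone is not sample-specific
  v <- acceptRecord(c(MRI = mri1, MassSpectrometer = "Q Exactive",
                      ChromatographyAndPhase = "Reversed phase",
                      YearOfAnalysis = "2021"))
  expect_false(v$accepted)
  expect_match(v$reason, "sample-descriptive")
  # an invalid MRI is a structural error, not a metadata rejection
  expect_error(acceptRecord(c(MRI = "nonsense",
                              NCBITaxonomy = "9606|Homo sapiens")),
               class = "redu_structural_error")
  expect_error(acceptRecord(c(NCBITaxonomy = "9606|Homo sapiens")),
               class = "redu_structural_error")
})

test_that("table validation reports duplicates and term violations with locations", {
  rec1 <- acceptRecord(c(MRI = mri1, NCBITaxonomy = "9606|Homo sapiens"))$record
  rec2 <- rec1
  prov <- data.frame(MRI = mri1, SourceStudy = "ST000123",
                     SourceAnalysis = missingToken(),
                     stringsAsFactors = FALSE)
  tbl <- reduTable(list(rec1, rec2), prov)
  rep <- validateTable(tbl)
  expect_true(any(rep$rule == "duplicate MRI" & rep$row == 2L))

  rec3 <- rec1
  rec3["NCBITaxonomy"] <- "Homo sapiens"  # missing taxid prefix
  rec3["BiologicalSex"] <- "woman"        # not an allowed term
  tbl3 <- reduTable(list(rec3), prov)
  rep3 <- validateTable(tbl3)
  expect_true(any(rep3$column == "NCBITaxonomy" &
                    grepl("taxid", rep3$rule)))
  expect_true(any(rep3$column == "BiologicalSex"))

  # empty table: empty report, valid
  empty <- reduTable(list(), prov[0, ])
  expect_equal(nrow(validateTable(empty)), 0L)
})

test_that("serialization round-trips randomized tables including filler cells", {
  set.seed(31)
  dir <- withr::local_tempdir()
  for (i in 1:15) {
    tbl <- randomReduTable(sample(1:7, 1))
    p <- file.path(dir, sprintf("t%02d.tsv", i))
    writeReduTable(tbl, p)
    back <- readReduTable(p)
    expect_identical(reduRecords(back), reduRecords(tbl))
    expect_identical(reduProvenance(back)[order(reduProvenance(back)$MRI), ],
                     reduProvenance(tbl)[order(reduProvenance(tbl)$MRI), ])
    # deterministic bytes across repeated writes
    p2 <- file.path(dir, "again.tsv")
    writeReduTable(tbl, p2)
    expect_identical(readBin(p, "raw", file.info(p)$size),
                     readBin(p2, "raw", file.info(p2)$size))
  }
})

test_that("an invalid table is refused by the writer", {
  rec <- acceptRecord(c(MRI = mri1, NCBITaxonomy = "9606|Homo sapiens"))$record
  rec["YearOfAnalysis"] <- "20x1"
  tbl <- reduTable(list(rec), data.frame(
    MRI = mri1, SourceStudy = "ST000123", SourceAnalysis = missingToken(),
    stringsAsFactors = FALSE))
  expect_error(writeReduTable(tbl, tempfile()),
               class = "redu_validation_error")
})

test_that("SDRF export maps headers and missing cells only", {
  rec <- acceptRecord(c(MRI = mri1, NCBITaxonomy = "9606|Homo sapiens"))$record
  tbl <- reduTable(list(rec), data.frame(
    MRI = mri1, SourceStudy = "ST000123", SourceAnalysis = missingToken(),
    stringsAsFactors = FALSE))
  p <- withr::local_tempfile(fileext = ".tsv")
  out <- exportSdrf(tbl, p)
  expect_true(all(c("source name", "characteristics[organism]",
                    "comment[data file]") %in% names(out)))
  expect_equal(out[["characteristics[organism]"]], "9606|Homo sapiens")
  expect_equal(out[["characteristics[sex]"]], "not available")
})
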