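writeIsaFixture <- function(dir, sRows, aRows,
                            sHeader = paste("Sample Name",
                                            "Characteristics[Organism]",
                                            "Term Source REF",
                                            "Term Accession Number",
                                            "Characteristics[Organism part]",
                                            "Factor Value[gender]",
                                            sep = "\t"),
                            aHeader = paste("Sample Name",
                                            "Parameter Value[Instrument]",
                                            "Raw Spectral Data File",
                                            sep = "\t")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(c("Study Identifier\tMTBLS777",
               "Study Public Release Date\t2019-06-01"),
             file.path(dir, "i_Investigation.txt"))
  writeLines(c(sHeader, sRows), file.path(dir, "s_MTBLS777.txt"))
  writeLines(c(aHeader, aRows), file.path(dir, "a_MTBLS777_pos.txt"))
  dir
}

test_that("ISA-Tab folders load with ontology triplets and orphan flags", {
  dir <- withr::local_tempdir()
  writeIsaFixture(dir,
    sRows = paste("S1", "Homo sapiens", "NCBITAXON",
                  "http://purl.obolibrary.org/obo/NCBITaxon_9606",
                  "urine", "Female", sep = "\t"),
    aRows = c(paste("S1", "Q Exactive", "FILES/a.mzML", sep = "\t"),
              paste("S99", "Q Exactive", "FILES/ghost.mzML", sep = "\t")))
  study <- parseIsaTab(dir)
  expect_equal(study@studyId, "MTBLS777")
  expect_equal(sampleTable(study)[["Characteristics[Organism]"]],
               "Homo sapiens")
  # assay row naming an absent sample is flagged orphaned, not dropped
  orphan <- orphanedAssayRows(study)[[1]]
  expect_equal(orphan, c(FALSE, TRUE))
  expect_equal(nrow(assayTables(study)[[1]]), 2L)
})

test_that("missing tables are structured errors; ragged rows warn and pad", {
  dir <- withr::local_tempdir()
  expect_error(parseIsaTab(file.path(dir, "nope")), class = "isa_parse_error")
  writeLines("Study Identifier\tX", file.path(dir, "i_Investigation.txt"))
  expect_error(parseIsaTab(dir), class = "isa_parse_error")
  writeLines(c("Sample Name\tOrganism", "S1\tHomo sapiens"),
             file.path(dir, "s_X.txt"))
  expect_error(parseIsaTab(dir), class = "isa_parse_error")
  writeLines(c("Sample Name\tRaw Spectral Data File\tExtra",
               "S1\ta.mzML"),  # ragged: one field short
             file.path(dir, "a_X.txt"))
  expect_warning(study <- parseIsaTab(dir), "ragged")
  expect_equal(assayTables(study)[[1]][["Extra"]], "")
})

test_that("a study with positive- and negative-mode assay files yields two tables", {
  dir <- withr::local_tempdir()
  writeIsaFixture(dir,
    sRows = paste("S1", "Homo sapiens", "", "", "urine", "", sep = "\t"),
    aRows = paste("S1", "QE", "FILES/pos.mzML", sep = "\t"))
  writeLines(c(paste("Sample Name", "Raw Spectral Data File", sep = "\t"),
               paste("S1", "FILES/neg.mzML", sep = "\t")),
             file.path(dir, "a_MTBLS777_neg.txt"))
  study <- parseIsaTab(dir)
  expect_length(assayTables(study), 2L)
})

test_that("column mapping joins sample and assay fields with fallbacks", {
  dir <- withr::local_tempdir()
  writeIsaFixture(dir,
    sRows = c(paste("S1", "Homo sapiens", "NCBITAXON",
                    "http://purl.obolibrary.org/obo/NCBITaxon_9606",
                    "urine", "female", sep = "\t"),
              paste("S2", "Mus musculus", "", "", "", "", sep = "\t")),
    aRows = c(paste("S1", "Q Exactive", "FILES/a.mzML", sep = "\t"),
              paste("S2", "Q Exactive", "FILES/b.mzML", sep = "\t")))
  study <- parseIsaTab(dir)
  m <- mapColumns(study)
  # taxid from the term accession takes precedence: taxid|name directly
  expect_equal(m[["FILES/a.mzML"]][["NCBITaxonomy"]], "9606|Homo sapiens")
  expect_equal(m[["FILES/a.mzML"]][["UBERONBodyPartName"]], "urine")
  # "gender" factor is found through the BiologicalSex fallback list
  expect_equal(m[["FILES/a.mzML"]][["BiologicalSex"]], "female")
  expect_equal(m[["FILES/a.mzML"]][["MassSpectrometer"]], "Q Exactive")
  # absent values leave the field unset, never empty-string
  expect_false("UBERONBodyPartName" %in% names(m[["FILES/b.mzML"]]))
  expect_false("BiologicalSex" %in% names(m[["FILES/b.mzML"]]))
  # no accession for S2: raw organism name is carried as-is
  expect_equal(m[["FILES/b.mzML"]][["NCBITaxonomy"]], "Mus musculus")
  # every mapped field is a schema column
  expect_true(all(unlist(lapply(m, names)) %in% reduSchema()$column))
})

test_that("open-format preference removes exactly the vendor siblings", {
  expect_equal(preferOpenFormat(c("a.raw", "a.mzML", "b.raw")),
               c("a.mzML", "b.raw"))
  # two open formats of the same run: no vendor involved, both kept
  expect_equal(preferOpenFormat(c("a.mzML", "a.mzXML")),
               c("a.mzML", "a.mzXML"))
  expect_equal(preferOpenFormat(character(0)), character(0))
  # case-insensitive pairing, one extension stripped
  expect_equal(preferOpenFormat(c("x/A.RAW", "y/a.mzml")), "y/a.mzml")
  expect_equal(preferOpenFormat(c("a.peak.raw", "a.mzML")),
               c("a.peak.raw", "a.mzML"))

  set.seed(41)
  for (i in 1:25) {
    n <- sample(1:8, 1)
    base <- replicate(n, paste(sample(letters, 6), collapse = ""))
    ext <- sample(c("mzML", "raw", "wiff", "cdf", "d", "mzXML"), n,
                  replace = TRUE)
    files <- paste0(base, ".", ext)
    kept <- preferOpenFormat(files)
    # idempotent
    expect_identical(preferOpenFormat(kept), kept)
    # a removed file always has an open-format sibling; survivors with
    # vendor extensions never do
    removed <- setdiff(files, kept)
    openBase <- tolower(base[tolower(ext) %in% c("mzml", "mzxml")])
    for (f in removed)
      expect_true(tolower(sub("\\.[^.]+$", "", f)) %in% openBase)
    for (f in kept[!tolower(sub("^.*\\.", "", kept)) %in% c("mzml", "mzxml")])
      expect_false(tolower(sub("\\.[^.]+$", "", f)) %in% openBase)
  }
})
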