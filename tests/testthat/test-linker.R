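test_that("each cascade tier fires in order and labels its links", {
  # full path: exact equality
  lk <- associateFiles("data/pos/s1.mzML", list(A = "data/pos/s1.mzML"))
  expect_equal(acceptedLinks(lk),
               data.frame(run_path = "data/pos/s1.mzML", sample_id = "A",
                          tier = "full_path", stringsAsFactors = FALSE))
  # base name with differing directories
  lk <- associateFiles("raw/s1.mzML", list(A = "other/s1.mzML"))
  expect_equal(acceptedLinks(lk)$tier, "base_name")
  # base name without extension (vendor name deposited for an open file)
  lk <- associateFiles("raw/s1.mzML", list(A = "s1.raw"))
  expect_equal(acceptedLinks(lk)$tier, "base_name_no_ext")
  # matching is case-insensitive at every tier
  lk <- associateFiles("raw/S1.mzML", list(A = "s1.RAW"))
  expect_equal(acceptedLinks(lk)$tier, "base_name_no_ext")
})

test_that("multiple file names deposited as one value link after separator splitting", {
  lk <- associateFiles(c("s1.mzML", "s2.mzML"), list(A = "s1.raw; s2.raw"))
  acc <- acceptedLinks(lk)
  expect_equal(nrow(acc), 2L)
  expect_equal(unique(acc$sample_id), "A")
  expect_equal(unique(acc$tier), "separator_split")
  # all three separators work
  for (sep in c(",", ";", "|")) {
    lk <- associateFiles(c("s1.mzML", "s2.mzML"),
                         list(A = paste("s1.raw", "s2.raw", sep = sep)))
    expect_equal(nrow(acceptedLinks(lk)), 2L, label = sep)
  }
})

test_that("substring matches require uniqueness and prefer the maximal match", {
  # the longer of two nested descriptors wins
  lk <- associateFiles("sample_10.mzML",
                       list(A = "ample_1", B = "ample_10"))
  acc <- acceptedLinks(lk)
  expect_equal(acc$sample_id, "B")
  expect_equal(acc$tier, "substring")
  # a descriptor equal to the base name matches at an earlier exact tier
  lk <- associateFiles("sample_10.mzML",
                       list(A = "sample_1", B = "sample_10"))
  expect_equal(acceptedLinks(lk)$sample_id, "B")
  # equal-length substring descriptors of two samples: ambiguous, excluded
  lk <- associateFiles("sample_10.mzML",
                       list(A = "ample_1", B = "mple_10"))
  expect_equal(nrow(acceptedLinks(lk)), 0L)
  expect_equal(ambiguousFiles(lk)$run_path, "sample_10.mzML")
  expect_true(discardedStudy(lk))
  # a descriptor substring-matching two files is not a unique pairing
  lk <- associateFiles(c("run_alpha_01.mzML", "run_alpha_02.mzML"),
                       list(A = "n_alpha_"))
  expect_equal(nrow(acceptedLinks(lk)), 0L)
  expect_equal(nrow(ambiguousFiles(lk)), 2L)
  # short descriptors (< 4 chars) never fire at the substring tier
  lk <- associateFiles("abcdef.mzML", list(A = "abc"))
  expect_equal(unlinkedFiles(lk), "abcdef.mzML")
})

test_that("a file matching two samples at its first tier is excluded, later files unaffected", {
  lk <- associateFiles(c("raw/s1.mzML", "raw/s2.mzML"),
                       list(A = c("s1.mzML", "s2.mzML"),
                            B = "s1.mzML"))
  expect_equal(ambiguousFiles(lk)$run_path, "raw/s1.mzML")
  acc <- acceptedLinks(lk)
  expect_equal(acc$run_path, "raw/s2.mzML")
  expect_equal(acc$sample_id, "A")
  expect_false(discardedStudy(lk))
})

test_that("adding a descriptor never demotes an existing link (tier monotonicity)", {
  set.seed(19)
  for (i in 1:25) {
    case <- randomLinkageCase()
    before <- associateFiles(case$files, case$descriptors)
    unl <- unlinkedFiles(before)
    if (!length(unl)) next
    f <- unl[1]
    d2 <- case$descriptors
    d2[[names(d2)[1]]] <- c(d2[[names(d2)[1]]], f)
    after <- associateFiles(case$files, d2)
    # the previously unlinked file now links at the top tier
    accAfter <- acceptedLinks(after)
    expect_true(f %in% accAfter$run_path)
    expect_equal(accAfter$tier[accAfter$run_path == f], "full_path")
    # existing full-path links are untouched
    accBefore <- acceptedLinks(before)
    fp <- accBefore[accBefore$tier == "full_path", , drop = FALSE]
    for (j in seq_len(nrow(fp))) {
      expect_equal(
        accAfter$sample_id[accAfter$run_path == fp$run_path[j]],
        fp$sample_id[j])
    }
  }
})

test_that("the cascade agrees with the brute-force tier oracle on random cases", {
  set.seed(101)
  for (i in 1:60) {
    case <- randomLinkageCase()
    got <- linkageAsOracle(associateFiles(case$files, case$descriptors))
    want <- oracleAssociate(case$files, case$descriptors)
    expect_identical(got, want, label = sprintf("case %d", i))
  }
})

makeDoc <- function(id, polarity) {
  new("MwTabDocument", analysisId = id, studyId = "ST000001",
      sections = list(), sampleFactors = list(), polarity = polarity)
}
makeSummary <- function(pos = 0L, neg = 0L, unknown = 0L) {
  counts <- data.frame(
    ms_level = 1L,
    polarity = c("positive", "negative", "unknown"),
    n = as.integer(c(pos, neg, unknown)), stringsAsFactors = FALSE)
  counts <- counts[counts$n > 0L, , drop = FALSE]
  rownames(counts) <- NULL
  new("ScanSummary", runPath = "f.mzML", counts = counts,
      totalScans = as.integer(pos + neg + unknown))
}

test_that("polarity disambiguation follows the compatibility rule table", {
  posNeg <- list(makeDoc("A1", "positive"), makeDoc("A2", "negative"))
  # uniformly positive file maps to the unique positive analysis
  expect_equal(
    unname(disambiguateByPolarity(posNeg, list(f = makeSummary(pos = 10)))),
    "A1")
  expect_equal(
    unname(disambiguateByPolarity(posNeg, list(f = makeSummary(neg = 4)))),
    "A2")
  # two analyses report the same polarity: dropped
  posPos <- list(makeDoc("A1", "positive"), makeDoc("A2", "positive"))
  expect_true(is.na(
    disambiguateByPolarity(posPos, list(f = makeSummary(pos = 10)))))
  # mixed-polarity files are compatible with no single-polarity analysis
  expect_true(is.na(
    disambiguateByPolarity(posNeg, list(f = makeSummary(pos = 5, neg = 5)))))
  # a polarity-silent analysis is compatible with either mode
  posUnspec <- list(makeDoc("A1", "positive"), makeDoc("A2", "unspecified"))
  expect_true(is.na(
    disambiguateByPolarity(posUnspec, list(f = makeSummary(pos = 3)))))
  expect_equal(
    unname(disambiguateByPolarity(posUnspec, list(f = makeSummary(neg = 3)))),
    "A2")
  # unknown-polarity-only files cannot be assigned
  expect_true(is.na(
    disambiguateByPolarity(posNeg, list(f = makeSummary(unknown = 3)))))
  # single-analysis studies bypass this step entirely
  expect_error(disambiguateByPolarity(posNeg[1],
                                      list(f = makeSummary(pos = 1))))
})
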