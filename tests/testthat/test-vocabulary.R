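test_that("taxonomy terms resolve to the taxid|name form", {
  expect_equal(translateTerm("Homo sapiens", "NCBITaxonomy"),
               "9606|Homo sapiens")
  # case-insensitive on canonical terms and synonyms
  expect_equal(translateTerm("homo sapiens", "NCBITaxonomy"),
               "9606|Homo sapiens")
  expect_equal(translateTerm("HUMAN", "NCBITaxonomy"), "9606|Homo sapiens")
  expect_equal(translateTerm("Mus musculus", "NCBITaxonomy"),
               "10090|Mus musculus")
  expect_equal(formatTaxonomy(9606, "Homo sapiens"), "9606|Homo sapiens")
  expect_equal(formatTaxonomy(10090, "Mus musculus"), "10090|Mus musculus")
  expect_error(formatTaxonomy(0, "x"), class = "vocab_error")
  expect_error(formatTaxonomy(-1, "x"), class = "vocab_error")
})

test_that("the resolution order is exact sheet, then ontology, then substring sheet", {
  sheet <- data.frame(
    source_pattern = c("special term", "ventricular", "myo"),
    match_mode = c("exact", "substring", "substring"),
    target_term = c("liver", "heart", "brain"),
    target_column = "UBERONBodyPartName",
    stringsAsFactors = FALSE)
  # Brute-force application of the stated order for
  # "left ventricular myocardium tissue": no exact entry matches the full
  # string; the ontology synonym "myocardium" only matches whole strings,
  # so it does not fire; among substring entries "ventricular" (11 chars)
  # beats "myo" (3 chars). Expected winner: "heart".
  expect_equal(
    translateTerm("left ventricular myocardium tissue",
                  "UBERONBodyPartName", sheets = sheet),
    "heart")
  # the exact layer beats everything when it matches the whole string
  expect_equal(translateTerm("Special  Term", "UBERONBodyPartName",
                             sheets = sheet), "liver")
  # a whole-string ontology synonym beats substring entries
  expect_equal(translateTerm("heart muscle", "UBERONBodyPartName",
                             sheets = sheet), "myocardium")
})

test_that("substring ties break by pattern length then lexicographic order, independent of row order", {
  sheet <- data.frame(
    source_pattern = c("abcd", "bcde", "abc"),
    match_mode = "substring",
    target_term = c("liver", "kidney", "lung"),
    target_column = "UBERONBodyPartName",
    stringsAsFactors = FALSE)
  # both 4-char patterns match "xabcdex"; "abcd" < "bcde" lexicographically
  expect_equal(translateTerm("xabcdex", "UBERONBodyPartName",
                             sheets = sheet), "liver")
  set.seed(5)
  for (i in 1:10) {
    shuffled <- sheet[sample(nrow(sheet)), , drop = FALSE]
    expect_equal(translateTerm("xabcdex", "UBERONBodyPartName",
                               sheets = shuffled), "liver")
  }
})

test_that("unmapped terms come back as an explicit marker, never a pass-through", {
  expect_true(is.na(translateTerm("completely unknown organ",
                                  "UBERONBodyPartName")))
  expect_error(translateTerm("   ", "UBERONBodyPartName"),
               class = "vocab_error")
})

test_that("every packaged translation target validates against its column", {
  schema <- reduSchema()
  registries <- reduOntologies()
  sheet <- reduTranslationSheets()
  for (i in seq_len(nrow(sheet))) {
    ok <- MetaboHarmonize:::.checkValue(sheet$target_column[i],
                                        sheet$target_term[i],
                                        schema, registries)
    expect_true(isTRUE(ok), label = sprintf("%s -> %s", sheet$source_pattern[i],
                                            sheet$target_term[i]))
  }
  # and ontology lookups emit registered terms for their columns
  for (raw in c("plasma", "Urine", "LIVER", "stool")) {
    term <- translateTerm(raw, "UBERONBodyPartName")
    expect_true(isTRUE(MetaboHarmonize:::.checkValue(
      "UBERONBodyPartName", term, schema, registries)), label = raw)
  }
})
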