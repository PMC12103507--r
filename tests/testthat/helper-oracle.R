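# Brute-force oracles, written directly from the rule tables and kept
# deliberately independent of the package internals: plain nested loops,
# no shared helpers.

# Exhaustive application of the association-cascade tier rules.
oracleAssociate <- function(files, descriptors) {
  files <- unique(files)
  low <- function(x) tolower(trimws(x))
  noext <- function(x) sub("\\.[^./]+$", "", x)
  squish <- function(x) {
    x <- gsub("[[:space:]]+", " ", x)
    sub("^ ", "", sub(" $", "", x))
  }
  pieces <- function(d) {
    p <- trimws(unlist(strsplit(d, "[,;|]")))
    unique(p[nzchar(p)])
  }
  eqAt <- function(d, f, tier) {
    if (tier == 1) low(d) == low(f)
    else if (tier == 2) basename(low(d)) == basename(low(f))
    else noext(basename(low(d))) == noext(basename(low(f)))
  }

  acc <- list(); amb <- character(0); sub <- character(0)
  tierName <- c("full_path", "base_name", "base_name_no_ext")
  for (f in files) {
    found <- FALSE
    for (tier in 1:3) {
      hits <- character(0)
      for (s in names(descriptors))
        for (d in descriptors[[s]])
          if (eqAt(d, f, tier)) hits <- c(hits, s)
      hits <- unique(hits)
      if (length(hits)) {
        if (length(hits) == 1) acc[[f]] <- c(hits, tierName[tier])
        else amb <- c(amb, f)
        found <- TRUE
        break
      }
    }
    if (found) next
    for (tier in 1:3) {
      hits <- character(0)
      for (s in names(descriptors))
        for (d in descriptors[[s]])
          for (p in pieces(d))
            if (eqAt(p, f, tier)) hits <- c(hits, s)
      hits <- unique(hits)
      if (length(hits)) {
        if (length(hits) == 1) acc[[f]] <- c(hits, "separator_split")
        else amb <- c(amb, f)
        found <- TRUE
        break
      }
    }
    if (!found) sub <- c(sub, f)
  }

  # Substring tier over the remaining files.
  subHit <- function(d, f) {
    dn <- low(squish(d)); fb <- low(basename(f)); fe <- noext(fb)
    if (nchar(dn) < 4 || nchar(fe) < 4) return(FALSE)
    grepl(dn, fb, fixed = TRUE) || grepl(dn, fe, fixed = TRUE) ||
      grepl(fe, dn, fixed = TRUE) || grepl(fb, dn, fixed = TRUE)
  }
  unlinked <- character(0)
  for (f in sub) {
    hits <- data.frame(s = character(0), d = character(0))
    for (s in names(descriptors))
      for (d in descriptors[[s]])
        if (subHit(d, f))
          hits <- rbind(hits, data.frame(s = s, d = low(squish(d))))
    if (!nrow(hits)) { unlinked <- c(unlinked, f); next }
    samples <- unique(hits$s)
    if (length(samples) > 1) {
      best <- max(nchar(hits$d))
      samples <- unique(hits$s[nchar(hits$d) == best])
    }
    if (length(samples) != 1) { amb <- c(amb, f); next }
    mine <- hits$d[hits$s == samples]
    mine <- unique(mine[nchar(mine) == max(nchar(mine))])
    unique_pair <- TRUE
    for (d in mine) {
      n <- 0
      for (g in sub) if (subHit(d, g)) n <- n + 1
      if (n > 1) unique_pair <- FALSE
    }
    if (unique_pair) acc[[f]] <- c(samples, "substring")
    else amb <- c(amb, f)
  }

  accepted <- data.frame(run_path = if (length(acc)) names(acc)
                                    else character(0),
                         sample_id = vapply(acc, `[`, character(1), 1),
                         tier = vapply(acc, `[`, character(1), 2),
                         stringsAsFactors = FALSE)
  accepted <- accepted[order(accepted$run_path), , drop = FALSE]
  rownames(accepted) <- NULL
  list(accepted = accepted,
       ambiguous = sort(unique(amb)),
       unlinked = sort(unlinked))
}

# Normalize a StudyLinkage for comparison with the oracle.
linkageAsOracle <- function(linkage) {
  acc <- acceptedLinks(linkage)
  acc <- acc[order(acc$run_path), , drop = FALSE]
  rownames(acc) <- NULL
  list(accepted = acc,
       ambiguous = sort(unique(ambiguousFiles(linkage)$run_path)),
       unlinked = sort(unlinkedFiles(linkage)))
}

# Independent text-level spectrum counter for generated mzML/mzXML (no XML
# library involved).
oracleCountSpectra <- function(path) {
  text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (grepl("<mzXML", text, fixed = TRUE)) {
    total <- lengths(regmatches(text, gregexpr("<scan ", text, fixed = TRUE)))
    pos <- lengths(regmatches(text, gregexpr('polarity="+"', text,
                                             fixed = TRUE)))
    neg <- lengths(regmatches(text, gregexpr('polarity="-"', text,
                                             fixed = TRUE)))
  } else {
    total <- lengths(regmatches(text, gregexpr("<spectrum ", text,
                                               fixed = TRUE)))
    pos <- lengths(regmatches(text, gregexpr("MS:1000130", text,
                                             fixed = TRUE)))
    neg <- lengths(regmatches(text, gregexpr("MS:1000129", text,
                                             fixed = TRUE)))
  }
  list(total = total, positive = pos, negative = neg)
}

# Random scan specification (uses the current RNG state).
randomScanSpec <- function(maxScans = 15L) {
  n <- sample(0:maxScans, 1L)
  data.frame(ms_level = sample(1:3, n, replace = TRUE),
             polarity = sample(c("positive", "negative", "unknown"), n,
                               replace = TRUE, prob = c(0.45, 0.45, 0.1)),
             stringsAsFactors = FALSE)
}

# Random valid harmonized table (uses the current RNG state).
randomReduTable <- function(nRecords = 5L) {
  schema <- reduSchema()
  tax <- loadOntologyRegistry("taxonomy")
  body <- loadOntologyRegistry("body_part")
  accs <- sprintf("ST%06d", sample(1:999999, nRecords))
  recs <- lapply(seq_len(nRecords), function(i) {
    cand <- c(MRI = sprintf("mzspec:%s:raw/f%02d.mzML", accs[i], i),
              SourceRepository = "NMDR")
    if (runif(1) < 0.8) {
      j <- sample(nrow(tax), 1)
      cand["NCBITaxonomy"] <- sprintf("%s|%s", tax$id[j], tax$term[j])
    }
    if (runif(1) < 0.7)
      cand["UBERONBodyPartName"] <- body$term[sample(nrow(body), 1)]
    if (runif(1) < 0.5)
      cand["SampleType"] <- sample(c("animal", "plant", "blank_extraction"), 1)
    if (runif(1) < 0.5)
      cand["BiologicalSex"] <- sample(c("male", "female"), 1)
    if (runif(1) < 0.5)
      cand["YearOfAnalysis"] <- as.character(sample(1999:2024, 1))
    if (runif(1) < 0.3)
      cand["LatitudeandLongitude"] <- sprintf("%.3f|%.3f",
                                              runif(1, -90, 90),
                                              runif(1, -180, 180))
    if (is.na(cand["NCBITaxonomy"]) && is.na(cand["UBERONBodyPartName"]) &&
        is.na(cand["SampleType"]))
      cand["SampleType"] <- "blank_QC"
    acceptRecord(cand, schema)$record
  })
  prov <- data.frame(
    MRI = vapply(recs, function(r) unname(r["MRI"]), character(1)),
    SourceStudy = accs,
    SourceAnalysis = rep(missingToken(), nRecords),
    stringsAsFactors = FALSE)
  reduTable(recs, prov, schema)
}
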