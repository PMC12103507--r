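#' @title File-to-sample association cascade
#'
#' @description
#' Raw files deposited in a repository are linked to the sample records of
#' the user-provided metadata through a strict cascade of matching tiers:
#'
#' 1. `full_path` — descriptor equals the file's full relative path;
#' 2. `base_name` — descriptor's base name equals the file's base name;
#' 3. `base_name_no_ext` — base names compared after stripping one
#'    terminal extension;
#' 4. `separator_split` — descriptor values are split on the separator set
#'    (default `,`, `;`, `|`) and the split pieces re-enter tiers 1-3;
#' 5. `substring` — substring matching between file base names and
#'    descriptors (either direction, minimum length 4).
#'
#' All comparisons are case-insensitive. The first tier that yields any
#' match for a file fixes that file's link. A file matching descriptors of
#' two or more samples at its first matching tier is ambiguous and
#' excluded — except at the substring tier, where samples whose matched
#' descriptor has maximal length are preferred first, and a unique
#' survivor is additionally required to have a descriptor matching exactly
#' one file at that tier. A study where no file could be linked is
#' discarded.
#'
#' @name linker
NULL

.TIERS <- c("full_path", "base_name", "base_name_no_ext",
            "separator_split", "substring")

#' @title Study linkage result
#' @description Result of [associateFiles()] for one study.
#' @slot accepted data.frame with columns `run_path`, `sample_id`, `tier`.
#' @slot ambiguous data.frame with columns `run_path`, `tier` (the tier at
#'   which the ambiguity arose). Ambiguous results are never part of the
#'   accepted set.
#' @slot unlinkedFiles Character vector of files no tier matched.
#' @slot discardedStudy `TRUE` iff the accepted set is empty.
#' @export
setClass("StudyLinkage",
  representation(accepted = "data.frame",
                 ambiguous = "data.frame",
                 unlinkedFiles = "character",
                 discardedStudy = "logical"))

setValidity("StudyLinkage", function(object) {
  msg <- character()
  if (!identical(object@discardedStudy, nrow(object@accepted) == 0L))
    msg <- c(msg, "discardedStudy must be TRUE iff no link was accepted")
  if (anyDuplicated(object@accepted$run_path))
    msg <- c(msg, "a run_path may link to at most one sample")
  if (length(intersect(object@accepted$run_path, object@ambiguous$run_path)))
    msg <- c(msg, "ambiguous files must not appear in the accepted set")
  if (length(msg)) msg else TRUE
})

setMethod("show", "StudyLinkage", function(object) {
  cat("StudyLinkage:", nrow(object@accepted), "accepted,",
      nrow(object@ambiguous), "ambiguous,",
      length(object@unlinkedFiles), "unlinked",
      if (object@discardedStudy) "(study discarded)" else "", "\n")
  invisible(object)
})

#' @describeIn StudyLinkage-class Accepted links accessor
#' @param x A `StudyLinkage`.
#' @export
acceptedLinks <- function(x) x@accepted

#' @describeIn StudyLinkage-class Ambiguous files accessor
#' @export
ambiguousFiles <- function(x) x@ambiguous

#' @describeIn StudyLinkage-class Unlinked files accessor
#' @export
unlinkedFiles <- function(x) x@unlinkedFiles

#' @describeIn StudyLinkage-class Study discard flag accessor
#' @export
discardedStudy <- function(x) x@discardedStudy

.emptyAccepted <- function() {
  data.frame(run_path = character(), sample_id = character(),
             tier = character(), stringsAsFactors = FALSE)
}

# Exact-tier comparison keys for a descriptor or file path.
.tierKey <- function(x, tier) {
  x <- .lc(trimws(x))
  switch(tier,
         full_path = x,
         base_name = basename(x),
         base_name_no_ext = .stripExt(basename(x)))
}

# Samples whose descriptor set matches `file` at an exact tier.
.matchExactTier <- function(file, descriptors, tier) {
  fkey <- .tierKey(file, tier)
  hit <- vapply(descriptors, function(d) {
    any(.tierKey(d, tier) == fkey)
  }, logical(1))
  names(descriptors)[hit]
}

#' Separator set used to split multi-file descriptor values
#' @return Character vector of single-character separators.
#' @export
defaultSeparators <- function() c(",", ";", "|")

# Split every descriptor on each separator; trimmed non-empty pieces.
.splitDescriptors <- function(descriptors, separators) {
  cls <- paste0("[", paste(gsub("([|\\\\^\\]])", "\\\\\\1", separators),
                           collapse = ""), "]")
  lapply(descriptors, function(d) {
    pieces <- unlist(strsplit(d, cls), use.names = FALSE)
    pieces <- trimws(pieces)
    unique(pieces[nzchar(pieces)])
  })
}

# Substring-tier match between one descriptor and one file: either string
# contains the other; both compared strings must be >= minLen characters.
.substringHit <- function(desc, file, minLen = 4L) {
  d <- .lc(.normWs(desc))
  fb <- .lc(basename(file))
  fbne <- .stripExt(fb)
  if (nchar(d) < minLen || nchar(fbne) < minLen) return(FALSE)
  grepl(d, fb, fixed = TRUE) || grepl(d, fbne, fixed = TRUE) ||
    grepl(fbne, d, fixed = TRUE) || grepl(fb, d, fixed = TRUE)
}

#' Associate raw files with sample records
#'
#' Runs the matching cascade described in [linker] over one study's file
#' list and per-sample descriptor lists.
#'
#' @param files Character vector of run paths (non-empty).
#' @param descriptors Named list: `sample_id` to character vector of
#'   descriptor strings (may be empty).
#' @param separators Separator set for the `separator_split` tier.
#' @return A [StudyLinkage-class].
#' @examples
#' associateFiles("data/pos/s1.mzML", list(A = "data/pos/s1.mzML"))
#' @export
associateFiles <- function(files, descriptors,
                           separators = defaultSeparators()) {
  stopifnot(length(files) > 0L)
  files <- unique(files)
  descriptors <- descriptors[order(names(descriptors))]

  accepted <- .emptyAccepted()
  ambiguous <- data.frame(run_path = character(), tier = character(),
                          stringsAsFactors = FALSE)
  substage <- character(0)  # files that fall through to the substring tier

  splitDesc <- .splitDescriptors(descriptors, separators)

  for (f in files) {
    hitSamples <- character(0)
    hitTier <- NA_character_
    for (tier in c("full_path", "base_name", "base_name_no_ext")) {
      hitSamples <- .matchExactTier(f, descriptors, tier)
      if (length(hitSamples)) { hitTier <- tier; break }
    }
    if (!length(hitSamples)) {
      for (tier in c("full_path", "base_name", "base_name_no_ext")) {
        hitSamples <- .matchExactTier(f, splitDesc, tier)
        if (length(hitSamples)) { hitTier <- "separator_split"; break }
      }
    }
    if (length(hitSamples)) {
      if (length(hitSamples) == 1L) {
        accepted <- rbind(accepted, data.frame(
          run_path = f, sample_id = hitSamples, tier = hitTier,
          stringsAsFactors = FALSE))
      } else {
        ambiguous <- rbind(ambiguous, data.frame(
          run_path = f, tier = hitTier, stringsAsFactors = FALSE))
      }
    } else {
      substage <- c(substage, f)
    }
  }

  # Substring tier over the files no exact tier matched.
  unlinked <- character(0)
  if (length(substage)) {
    # Per-file candidate (sample, descriptor) pairs.
    cand <- lapply(substage, function(f) {
      rows <- list()
      for (s in names(descriptors)) {
        for (d in descriptors[[s]]) {
          if (.substringHit(d, f))
            rows[[length(rows) + 1L]] <- list(sample = s, desc = .lc(.normWs(d)))
        }
      }
      rows
    })
    names(cand) <- substage
    for (f in substage) {
      rows <- cand[[f]]
      if (!length(rows)) { unlinked <- c(unlinked, f); next }
      samples <- unique(vapply(rows, `[[`, character(1), "sample"))
      if (length(samples) > 1L) {
        # Prefer samples whose matched descriptor has maximal length.
        lens <- vapply(samples, function(s) {
          max(vapply(rows, function(r)
            if (r$sample == s) nchar(r$desc) else 0L, integer(1)))
        }, integer(1))
        samples <- samples[lens == max(lens)]
      }
      if (length(samples) != 1L) {
        ambiguous <- rbind(ambiguous, data.frame(
          run_path = f, tier = "substring", stringsAsFactors = FALSE))
        next
      }
      # Winning descriptor(s) of the surviving sample must match exactly
      # one file at this tier; otherwise the pairing is not unique.
      winDesc <- unique(vapply(
        Filter(function(r) r$sample == samples, rows),
        `[[`, character(1), "desc"))
      winDesc <- winDesc[nchar(winDesc) == max(nchar(winDesc))]
      nFiles <- vapply(winDesc, function(d)
        sum(vapply(substage, function(g) .substringHit(d, g), logical(1))),
        integer(1))
      if (any(nFiles > 1L)) {
        ambiguous <- rbind(ambiguous, data.frame(
          run_path = f, tier = "substring", stringsAsFactors = FALSE))
      } else {
        accepted <- rbind(accepted, data.frame(
          run_path = f, sample_id = samples, tier = "substring",
          stringsAsFactors = FALSE))
      }
    }
  }

  new("StudyLinkage",
      accepted = accepted,
      ambiguous = ambiguous,
      unlinkedFiles = unlinked,
      discardedStudy = nrow(accepted) == 0L)
}

# Uniform scan polarity of a file: "positive"/"negative" when all scans
# with a known polarity agree (and at least one exists), NA otherwise.
.uniformPolarity <- function(summary) {
  counts <- scanCounts(summary)
  nPos <- sum(counts$n[counts$polarity == "positive"])
  nNeg <- sum(counts$n[counts$polarity == "negative"])
  if (nPos > 0L && nNeg == 0L) return("positive")
  if (nNeg > 0L && nPos == 0L) return("negative")
  NA_character_
}

#' Disambiguate multi-analysis studies by scan polarity
#'
#' When several mwTab analyses exist for one study, the repository does not
#' record which raw file belongs to which analysis. A file whose scans are
#' uniformly one polarity is assigned to the unique analysis reporting that
#' polarity; when zero or two-or-more analyses remain compatible (analyses
#' reporting no polarity count as compatible with either mode, and
#' mixed-polarity files are compatible with no single-polarity analysis),
#' the file's analysis-level metadata is dropped (`NA`). Single-analysis
#' studies bypass this step.
#'
#' @param analyses List of [MwTabDocument-class] (length >= 2).
#' @param fileSummaries Named list: run path to [ScanSummary-class].
#' @return Named character vector: run path to analysis id or `NA`.
#' @export
disambiguateByPolarity <- function(analyses, fileSummaries) {
  if (length(analyses) < 2L)
    stop("polarity disambiguation requires at least two analyses")
  pol <- vapply(analyses, mwtabPolarity, character(1))
  ids <- vapply(analyses, analysisId, character(1))
  out <- rep(NA_character_, length(fileSummaries))
  names(out) <- names(fileSummaries)
  for (f in names(fileSummaries)) {
    fp <- .uniformPolarity(fileSummaries[[f]])
    if (is.na(fp)) next
    compatible <- pol == fp | pol == "unspecified"
    if (sum(compatible) == 1L) out[f] <- ids[compatible]
  }
  out
}

#' Write a linkage report TSV
#'
#' One row per file with its status (`accepted`, `ambiguous`, `unlinked`),
#' the linked sample and the tier that produced the link.
#'
#' @param linkage A [StudyLinkage-class].
#' @param path Output TSV path.
#' @return The report data.frame, invisibly.
#' @export
writeLinkageReport <- function(linkage, path) {
  df <- linkageReport(linkage)
  .writeTsv(df, path)
  invisible(df)
}

#' @rdname writeLinkageReport
#' @export
linkageReport <- function(linkage) {
  acc <- linkage@accepted
  amb <- linkage@ambiguous
  rbind(
    data.frame(run_path = acc$run_path, sample_id = acc$sample_id,
               tier = acc$tier, status = rep("accepted", nrow(acc)),
               stringsAsFactors = FALSE),
    data.frame(run_path = amb$run_path, sample_id = rep("", nrow(amb)),
               tier = amb$tier, status = rep("ambiguous", nrow(amb)),
               stringsAsFactors = FALSE),
    data.frame(run_path = linkage@unlinkedFiles,
               sample_id = rep("", length(linkage@unlinkedFiles)),
               tier = rep("", length(linkage@unlinkedFiles)),
               status = rep("unlinked", length(linkage@unlinkedFiles)),
               stringsAsFactors = FALSE))
}
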