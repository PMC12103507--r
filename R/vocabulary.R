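#' @title Controlled-vocabulary translation
#'
#' @description
#' Free-text or repository-controlled terms are converted into the
#' harmonized controlled vocabulary through three layers, applied in a
#' fixed resolution order: exact translation-sheet entries, ontology
#' canonical-term/synonym lookup, then substring translation-sheet entries
#' (longest pattern wins ties, then lexicographically smallest pattern).
#' A term none of the layers resolves is reported as unmapped
#' (`NA_character_`) — never passed through silently.
#'
#' Translation sheets are TSVs with columns `source_pattern`, `match_mode`
#' (`exact` or `substring`), `target_term`, `target_column`. Ontology
#' registries are packaged TSV snapshots (`term`, `id`, `synonyms`
#' pipe-separated) of public ontologies: NCBI taxonomy, UBERON body parts,
#' PO plant parts, CL cell types, DOID diseases, and the PSI-MS instrument
#' vocabulary.
#'
#' @name vocabulary
NULL

#' Load an ontology registry snapshot
#'
#' @param domain Registry name (file name without extension), one of the
#'   packaged domains: `taxonomy`, `body_part`, `plant_part`, `cell_type`,
#'   `disease`, `instrument`.
#' @param path Optional TSV path overriding the packaged snapshot.
#' @return data.frame with columns `term`, `id`, `synonyms`.
#' @export
loadOntologyRegistry <- function(domain, path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "ontologies", paste0(domain, ".tsv"),
                        package = "MetaboHarmonize")
  df <- .readTsv(path)
  stopifnot(all(c("term", "id", "synonyms") %in% names(df)))
  attr(df, "domain") <- domain
  df
}

#' All packaged ontology registries
#'
#' @return Named list of registries (see [loadOntologyRegistry()]).
#' @export
reduOntologies <- function() {
  dir <- system.file("extdata", "ontologies", package = "MetaboHarmonize")
  files <- sort(list.files(dir, pattern = "\\.tsv$"))
  out <- lapply(sub("\\.tsv$", "", files), loadOntologyRegistry)
  names(out) <- sub("\\.tsv$", "", files)
  out
}

#' Load translation sheets
#'
#' Later sheets merge over earlier ones (user sheets over packaged ones);
#' within the merged sheet, resolution-order rules are fixed by
#' [translateTerm()], not by row order.
#'
#' @param paths Character vector of TSV paths.
#' @return data.frame with the four sheet columns.
#' @export
loadTranslationSheet <- function(paths) {
  out <- do.call(rbind, lapply(paths, .readTsv))
  need <- c("source_pattern", "match_mode", "target_term", "target_column")
  stopifnot(all(need %in% names(out)))
  bad <- !out$match_mode %in% c("exact", "substring")
  if (any(bad))
    .err("sheet_error", "unknown match_mode '%s'", out$match_mode[bad][1])
  out
}

#' Packaged core translation sheet
#' @return data.frame sheet.
#' @export
reduTranslationSheets <- function() {
  loadTranslationSheet(system.file("extdata", "translation_sheets",
                                   "core_terms.tsv",
                                   package = "MetaboHarmonize"))
}

# Case-insensitive canonical/synonym lookup. For the taxonomy domain the
# canonical form is "taxid|name".
.ontologyLookup <- function(registry, raw) {
  key <- .lc(.normWs(raw))
  canon <- .lc(registry$term)
  hit <- which(canon == key)
  if (!length(hit)) {
    for (i in seq_len(nrow(registry))) {
      syns <- strsplit(registry$synonyms[i], "|", fixed = TRUE)[[1]]
      if (key %in% .lc(trimws(syns))) { hit <- i; break }
    }
  }
  if (!length(hit)) return(NA_character_)
  i <- hit[1]
  if (identical(attr(registry, "domain"), "taxonomy"))
    formatTaxonomy(as.integer(registry$id[i]), registry$term[i])
  else
    registry$term[i]
}

# Ontology domains backing a schema column (from the schema registry's
# value_kind, e.g. "vocab:body_part,plant_part,cell_type" or "taxonomy").
.columnDomains <- function(column, schema) {
  kind <- schema$value_kind[schema$column == column]
  if (!length(kind)) return(character(0))
  if (kind == "taxonomy") return("taxonomy")
  if (startsWith(kind, "vocab:"))
    return(strsplit(sub("^vocab:", "", kind), ",", fixed = TRUE)[[1]])
  character(0)
}

#' Translate one raw term into the controlled vocabulary
#'
#' Resolution order: exact sheet entry, then ontology canonical/synonym
#' lookup over the column's domains, then substring sheet entry (pattern
#' length >= 3; longest pattern wins, ties broken by lexicographic
#' pattern order, so shuffling sheet rows never changes the answer). All
#' comparisons are case-insensitive on whitespace-collapsed text.
#'
#' @param raw Raw term (non-empty after whitespace normalization).
#' @param column Target schema column name.
#' @param sheets Translation sheet data.frame.
#' @param registries Named list of ontology registries.
#' @param schema Schema registry (see [reduSchema()]).
#' @return The controlled term, or `NA_character_` when unmapped.
#' @examples
#' translateTerm("Homo sapiens", "NCBITaxonomy")
#' @export
translateTerm <- function(raw, column,
                          sheets = reduTranslationSheets(),
                          registries = reduOntologies(),
                          schema = reduSchema()) {
  norm <- .normWs(raw)
  if (!nzchar(norm))
    .err("vocab_error", "raw term is empty after whitespace normalization")
  key <- .lc(norm)

  colSheet <- sheets[sheets$target_column == column, , drop = FALSE]

  exact <- colSheet[colSheet$match_mode == "exact", , drop = FALSE]
  hit <- which(.lc(.normWs(exact$source_pattern)) == key)
  if (length(hit)) {
    hit <- hit[order(exact$source_pattern[hit])][1]
    return(exact$target_term[hit])
  }

  for (domain in .columnDomains(column, schema)) {
    reg <- registries[[domain]]
    if (is.null(reg)) next
    term <- .ontologyLookup(reg, norm)
    if (!is.na(term)) return(term)
  }

  subs <- colSheet[colSheet$match_mode == "substring", , drop = FALSE]
  subs <- subs[nchar(subs$source_pattern) >= 3L, , drop = FALSE]
  if (nrow(subs)) {
    pat <- .lc(.normWs(subs$source_pattern))
    match <- vapply(pat, function(p) grepl(p, key, fixed = TRUE), logical(1))
    if (any(match)) {
      cand <- which(match)
      cand <- cand[order(-nchar(pat[cand]), subs$source_pattern[cand])]
      return(subs$target_term[cand[1]])
    }
  }
  NA_character_
}

#' Format a taxonomy term as `taxid|name`
#'
#' @param taxid Positive NCBI taxonomy identifier.
#' @param name Scientific name.
#' @return The controlled term string, e.g. `"9606|Homo sapiens"`.
#' @examples
#' formatTaxonomy(9606, "Homo sapiens")
#' @export
formatTaxonomy <- function(taxid, name) {
  taxid <- as.integer(taxid)
  if (is.na(taxid) || taxid <= 0L)
    .err("vocab_error", "taxid must be a positive integer")
  if (!nzchar(name))
    .err("vocab_error", "taxonomy name must be non-empty")
  sprintf("%d|%s", taxid, name)
}
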