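# Internal helpers shared across modules.

# Collapse runs of whitespace and trim ends.
.normWs <- function(x) {
  x <- gsub("[[:space:]]+", " ", x)
  sub("^ ", "", sub(" $", "", x))
}

.lc <- function(x) tolower(x)

# Strip one terminal extension ("a.peak.raw" -> "a.peak"); ".d" counts as a
# terminal suffix like any other extension.
.stripExt <- function(p) sub("\\.[^./\\\\]+$", "", p)

.fileExt <- function(p) {
  ext <- tools::file_ext(p)
  tolower(ext)
}

# Raise a classed condition so callers can distinguish failure modes.
.err <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# TSV helpers: everything read as character, "" preserved, no name mangling.
.readTsv <- function(path) {
  utils::read.delim(path, sep = "\t", quote = "\"", header = TRUE,
                    check.names = FALSE, colClasses = "character",
                    na.strings = NULL, stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8")
}

.writeTsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "", eol = "\n",
                     fileEncoding = "UTF-8")
  invisible(path)
}

# Write lines with "\n" endings regardless of platform (byte-determinism).
.writeLines <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

# Read a possibly gzip-compressed text file as a single string.
.readTextMaybeGz <- function(path) {
  magic <- readBin(path, "raw", n = 2L)
  if (length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)) {
    con <- gzfile(path, open = "rb")
    on.exit(close(con))
    chunks <- character()
    repeat {
      piece <- readLines(con, n = 10000L, warn = FALSE)
      if (!length(piece)) break
      chunks <- c(chunks, piece)
    }
    paste(chunks, collapse = "\n")
  } else {
    readChar(path, file.info(path)$size, useBytes = TRUE)
  }
}

# List files under a root as sorted relative paths (forward slashes).
.listRelFiles <- function(root) {
  f <- list.files(root, recursive = TRUE, all.files = FALSE, full.names = FALSE)
  sort(f)
}
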