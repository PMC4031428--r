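## Minimal BibTeX reader/writer for bibliographic metadata. Covers the
## common entry grammar: @type{key, field = {value} | "value" | bareword}.
## Values may contain balanced braces; authors are split on " and ".

#' Import BibTeX entries
#'
#' @param bibText Character scalar (or vector of lines) of BibTeX text;
#'   may contain zero or more entries.
#' @return A list of [BibRecord-class] objects, one per entry, in file
#'   order; names are the citation keys.
#' @export
#' @examples
#' recs <- importBibtex("@article{smith2001,
#'   author = {Smith, A. and Jones, B.},
#'   title = {An example}, year = {2001}, journal = {J. Ex.}}")
#' recs[[1]]@authors
importBibtex <- function(bibText) {
  txt <- paste(bibText, collapse = "\n")
  entries <- .bibSplitEntries(txt)
  if (length(entries) == 0L) return(list())
  records <- vector("list", length(entries))
  for (i in seq_along(entries)) {
    rec <- tryCatch(.bibParseEntry(entries[[i]]),
                    error = function(e) e)
    if (inherits(rec, "error"))
      stop("failed to parse BibTeX entry ", i, ": ", conditionMessage(rec))
    records[[i]] <- rec
  }
  keys <- vapply(records, function(r) r@key, character(1))
  if (anyDuplicated(keys))
    stop("duplicate BibTeX keys: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  names(records) <- keys
  records
}

## Split raw text into entry strings "@type{...}" with balanced braces.
.bibSplitEntries <- function(txt) {
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  starts <- which(chars == "@")
  out <- list()
  pos <- 1L
  for (s in starts) {
    if (s < pos) next
    open <- s
    while (open <= length(chars) && chars[open] != "{") open <- open + 1L
    if (open > length(chars)) stop("BibTeX entry without opening brace")
    depth <- 0L
    end <- open
    repeat {
      if (end > length(chars)) stop("unbalanced braces in BibTeX entry")
      if (chars[end] == "{") depth <- depth + 1L
      if (chars[end] == "}") {
        depth <- depth - 1L
        if (depth == 0L) break
      }
      end <- end + 1L
    }
    out[[length(out) + 1L]] <- paste(chars[s:end], collapse = "")
    pos <- end + 1L
  }
  out
}

.bibKnownFields <- c("author", "title", "year", "journal", "booktitle",
                     "volume", "pages", "doi")

.bibParseEntry <- function(entry) {
  m <- regmatches(entry, regexec("^@([A-Za-z]+)\\s*\\{\\s*([^,\\s]+)\\s*,",
                                 entry, perl = TRUE))[[1]]
  if (length(m) != 3L) stop("cannot read entry type/key")
  entryType <- tolower(m[2])
  key <- m[3]
  body <- sub("^@[A-Za-z]+\\s*\\{\\s*[^,\\s]+\\s*,", "", entry, perl = TRUE)
  body <- sub("\\}\\s*$", "", body)
  fields <- .bibParseFields(body)
  fn <- tolower(names(fields))
  names(fields) <- fn
  year <- NA_integer_
  if ("year" %in% fn) {
    y <- suppressWarnings(as.integer(fields[["year"]]))
    if (is.na(y)) stop("non-integer year in entry '", key, "'")
    year <- y
  }
  authors <- character(0)
  if ("author" %in% fn)
    authors <- .bibSplitAuthors(fields[["author"]])
  extra <- fields[!fn %in% .bibKnownFields]
  getf <- function(f) if (f %in% fn) fields[[f]] else NA_character_
  BibRecord(key = key, entryType = entryType, authors = authors,
            title = getf("title"), year = year, journal = getf("journal"),
            booktitle = getf("booktitle"), volume = getf("volume"),
            pages = getf("pages"), doi = getf("doi"),
            extraFields = if (length(extra)) unlist(extra) else character(0))
}

## Parse "name = value, name = value" with brace/quote-aware scanning.
.bibParseFields <- function(body) {
  chars <- strsplit(body, "", fixed = TRUE)[[1]]
  fields <- list()
  i <- 1L
  n <- length(chars)
  skipWs <- function(i) { while (i <= n && grepl("\\s", chars[i])) i <- i + 1L; i }
  while (TRUE) {
    i <- skipWs(i)
    if (i > n) break
    if (chars[i] == ",") { i <- i + 1L; next }
    j <- i
    while (j <= n && grepl("[A-Za-z0-9_-]", chars[j])) j <- j + 1L
    if (j == i) stop("malformed field near position ", i)
    name <- paste(chars[i:(j - 1L)], collapse = "")
    i <- skipWs(j)
    if (i > n || chars[i] != "=") stop("expected '=' after field '", name, "'")
    i <- skipWs(i + 1L)
    if (i > n) stop("missing value for field '", name, "'")
    if (chars[i] == "{") {
      depth <- 0L; j <- i
      repeat {
        if (j > n) stop("unbalanced braces in field '", name, "'")
        if (chars[j] == "{") depth <- depth + 1L
        if (chars[j] == "}") { depth <- depth - 1L; if (depth == 0L) break }
        j <- j + 1L
      }
      value <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      if (j - 1L < i + 1L) value <- ""
      i <- j + 1L
    } else if (chars[i] == "\"") {
      j <- i + 1L
      while (j <= n && chars[j] != "\"") j <- j + 1L
      if (j > n) stop("unterminated quoted value in field '", name, "'")
      value <- if (j > i + 1L) paste(chars[(i + 1L):(j - 1L)], collapse = "") else ""
      i <- j + 1L
    } else {
      j <- i
      while (j <= n && !grepl("[,[:space:]]", chars[j])) j <- j + 1L
      value <- paste(chars[i:(j - 1L)], collapse = "")
      i <- j
    }
    fields[[name]] <- gsub("\\s+", " ", trimws(value))
  }
  fields
}

## BibTeX author lists use " and " as the separator between names.
.bibSplitAuthors <- function(x) {
  parts <- strsplit(x, "\\s+and\\s+")[[1]]
  trimws(parts[nzchar(trimws(parts))])
}

#' Export BibRecords as BibTeX text
#'
#' Deterministic output: fields in a fixed order (author, title, year,
#' journal, booktitle, volume, pages, doi, then extra fields in stored
#' order), brace-delimited values. `importBibtex(exportBibtex(x))`
#' reproduces every parsed field.
#'
#' @param records A list of [BibRecord-class] objects (or a single one).
#' @return A single character string of BibTeX text.
#' @export
exportBibtex <- function(records) {
  if (is(records, "BibRecord")) records <- list(records)
  out <- vapply(records, .bibFormatEntry, character(1))
  paste(out, collapse = "\n\n")
}

.bibFormatEntry <- function(r) {
  lines <- character(0)
  add <- function(name, value) {
    if (length(value) == 1L && is.na(value)) return(invisible())
    lines <<- c(lines, sprintf("  %s = {%s},", name, value))
  }
  if (length(r@authors)) add("author", paste(r@authors, collapse = " and "))
  add("title", r@title)
  if (!is.na(r@year)) add("year", as.character(r@year))
  add("journal", r@journal)
  add("booktitle", r@booktitle)
  add("volume", r@volume)
  add("pages", r@pages)
  add("doi", r@doi)
  for (nm in names(r@extraFields)) add(nm, r@extraFields[[nm]])
  if (length(lines))
    lines[length(lines)] <- sub(",$", "", lines[length(lines)])
  paste0("@", r@entryType, "{", r@key, ",\n",
         paste(lines, collapse = "\n"), "\n}")
}
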