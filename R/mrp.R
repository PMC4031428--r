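## Baum-Ragan matrix representation with parsimony (MRP): each informative
## clade of each source tree becomes one binary character; clade members
## are scored 1, the tree's other taxa 0, and taxa absent from that tree ?.
## Characters are unweighted and unordered; the root clade is excluded.

#' Informative clades of a tree
#'
#' One taxon set per internal node other than the root, in pre-order;
#' trivial sets (singletons or all leaves) are excluded. These are the
#' clades coded as MRP characters.
#'
#' @param t A phylo tree or empty-tree sentinel.
#' @return A list of sorted character vectors.
#' @export
#' @examples
#' informativeClades(parseNewick("((A,B),(C,D));"))
informativeClades <- function(t) {
  if (isEmptyTree(t)) return(list())
  n <- length(leafLabels(t))
  cl <- cladeSets(t)
  cl[lengths(cl) >= 2L & lengths(cl) < n]
}

#' Build the MRP matrix of a dataset
#'
#' Taxa are the union over all trees, sorted lexically; when
#' `withOutgroup = TRUE` a synthetic all-zero row named `MRP_Outgroup` is
#' prepended so the downstream parsimony analysis can be rooted. Column
#' order is source order, then tree order, then pre-order clade order.
#'
#' @param ds A [PhyloDataset-class]; all trees must contribute at least
#'   one informative clade (run [cleanData()] first) and polyphyly
#'   markers must already have been resolved (see [permuteTree()]).
#' @param withOutgroup Add the `MRP_Outgroup` row (default `TRUE`).
#' @return An [MRPMatrix-class].
#' @export
buildMatrix <- function(ds, withOutgroup = TRUE) {
  trees <- sourceTrees(ds)
  if (length(trees) == 0L) stop("dataset has no trees")
  parsed <- lapply(trees, function(st) parseNewick(st@treeString))
  labs <- unlist(lapply(parsed, leafLabels), use.names = FALSE)
  if (any(!is.na(polyphylyMarker(labs))))
    stop("dataset still contains %d polyphyly markers; ",
         "resolve them with permuteTree() before building a matrix")
  cladeLists <- lapply(parsed, informativeClades)
  bad <- names(trees)[lengths(cladeLists) == 0L]
  if (length(bad))
    stop("uninformative trees (no clades): ", paste(bad, collapse = ", "),
         "; run cleanData() first")
  taxaAll <- sort(unique(labs))
  nchar <- sum(lengths(cladeLists))
  rows <- c(if (withOutgroup) "MRP_Outgroup", taxaAll)
  m <- matrix("?", nrow = length(rows), ncol = nchar,
              dimnames = list(rows, NULL))
  prov <- data.frame(source = character(nchar), tree = integer(nchar),
                     clade = integer(nchar), stringsAsFactors = FALSE)
  ids <- names(trees)
  col <- 0L
  for (i in seq_along(parsed)) {
    treeTaxa <- leafLabels(parsed[[i]])
    key <- sub(":[0-9]+$", "", ids[i])
    ti <- as.integer(sub("^.*:", "", ids[i]))
    for (ci in seq_along(cladeLists[[i]])) {
      col <- col + 1L
      m[treeTaxa, col] <- "0"
      m[cladeLists[[i]][[ci]], col] <- "1"
      if (withOutgroup) m["MRP_Outgroup", col] <- "0"
      prov$source[col] <- key
      prov$tree[col] <- ti
      prov$clade[col] <- ci
    }
  }
  colnames(m) <- paste0(prov$source, ":", prov$tree, ":", prov$clade)
  MRPMatrix(m, prov)
}

## NEXUS/TNT name handling: plain names pass through; NEXUS quotes others,
## TNT has no quoting mechanism so offending names are rejected.
.plainName <- function(x) grepl("^[A-Za-z0-9_.%]+$", x)

.nexusName <- function(x) {
  ifelse(.plainName(x), x,
         paste0("'", gsub("'", "''", x, fixed = TRUE), "'"))
}

#' Write an MRP matrix as a NEXUS DATA block
#'
#' Standard-datatype DATA block (`SYMBOLS="01" MISSING=?`), one row per
#' taxon, names single-quoted when they contain characters outside
#' `[A-Za-z0-9_.%]`. Output is deterministic.
#'
#' @param m An [MRPMatrix-class].
#' @return A single string of NEXUS text.
#' @seealso [readNexus()], [writeTnt()]
#' @export
writeNexus <- function(m) {
  validObject(m)
  cm <- cells(m)
  names <- .nexusName(rownames(cm))
  width <- max(nchar(names)) + 1L
  rows <- paste0(formatC(names, width = -width), apply(cm, 1, paste, collapse = ""))
  paste0("#NEXUS\n\nBEGIN DATA;\n",
         "\tDIMENSIONS NTAX=", nrow(cm), " NCHAR=", ncol(cm), ";\n",
         "\tFORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=?;\n",
         "\tMATRIX\n",
         paste0("\t", rows, collapse = "\n"),
         "\n\t;\nEND;\n")
}

#' Write an MRP matrix in TNT (Hennig) xread format
#'
#' @param m An [MRPMatrix-class]. Taxon names must be plain
#'   (`[A-Za-z0-9_.%]`); TNT has no name quoting, so other names are
#'   rejected with guidance to rename them first.
#' @return A single string of TNT text.
#' @export
writeTnt <- function(m) {
  validObject(m)
  cm <- cells(m)
  bad <- rownames(cm)[!.plainName(rownames(cm))]
  if (length(bad))
    stop("taxon names not representable in TNT: ",
         paste(bad, collapse = ", "),
         "; rename them (e.g. with substituteTaxa) before writing TNT")
  width <- max(nchar(rownames(cm))) + 1L
  rows <- paste0(formatC(rownames(cm), width = -width),
                 apply(cm, 1, paste, collapse = ""))
  paste0("xread\n'MRP matrix'\n", ncol(cm), " ", nrow(cm), "\n",
         paste(rows, collapse = "\n"),
         "\n;\nproc /;\n")
}

## Tokenise a matrix row line into (name, states).
.matrixRowTokens <- function(line) {
  line <- trimws(line)
  if (startsWith(line, "'")) {
    chars <- strsplit(line, "", fixed = TRUE)[[1]]
    i <- 2L; name <- character(0)
    repeat {
      if (i > length(chars)) stop("unterminated quoted taxon name: ", line)
      if (chars[i] == "'") {
        if (i < length(chars) && chars[i + 1L] == "'") {
          name <- c(name, "'"); i <- i + 2L      # '' escapes a quote
        } else break
      } else {
        name <- c(name, chars[i]); i <- i + 1L
      }
    }
    name <- paste(name, collapse = "")
    rest <- trimws(substr(line, i + 1L, nchar(line)))
  } else {
    name <- sub("\\s.*$", "", line)
    rest <- trimws(sub("^\\S+", "", line))
  }
  states <- gsub("\\s+", "", rest)
  list(name = name, states = states)
}

.statesToCells <- function(rowList, ntax, nchar, what) {
  if (length(rowList) != ntax)
    stop(what, ": expected ", ntax, " rows, found ", length(rowList))
  names <- vapply(rowList, `[[`, character(1), "name")
  states <- vapply(rowList, `[[`, character(1), "states")
  if (any(nchar(states) != nchar))
    stop(what, ": rows with wrong character count: ",
         paste(names[nchar(states) != nchar], collapse = ", "))
  m <- do.call(rbind, strsplit(states, "", fixed = TRUE))
  rownames(m) <- names
  if (!all(m %in% c("0", "1", "?")))
    stop(what, ": states other than 0/1/? found")
  m
}

#' Read a binary matrix from NEXUS or TNT text
#'
#' Parses the non-interleaved `{0,1,?}` matrices this package writes
#' (NEXUS DATA/CHARACTERS block, or TNT xread). Provenance is unknown for
#' matrices read from disk.
#'
#' @param text A string or character vector of lines.
#' @return An [MRPMatrix-class].
#' @export
readNexus <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  if (!grepl("#NEXUS", lines[1], ignore.case = TRUE))
    stop("not a NEXUS file (missing #NEXUS header)")
  txt <- paste(lines, collapse = "\n")
  dim <- regmatches(txt, regexec(
    "DIMENSIONS\\s+NTAX\\s*=\\s*([0-9]+)\\s+NCHAR\\s*=\\s*([0-9]+)", txt,
    ignore.case = TRUE))[[1]]
  if (length(dim) != 3L) stop("no DIMENSIONS NTAX=... NCHAR=... found")
  ntax <- as.integer(dim[2]); nchar <- as.integer(dim[3])
  im <- grep("^\\s*MATRIX\\s*$", lines, ignore.case = TRUE)
  if (length(im) != 1L) stop("expected exactly one MATRIX line")
  rowList <- list()
  for (line in lines[-seq_len(im)]) {
    s <- trimws(line)
    if (!nzchar(s)) next
    if (s == ";" || grepl("^END", s, ignore.case = TRUE)) break
    rowList[[length(rowList) + 1L]] <- .matrixRowTokens(s)
  }
  MRPMatrix(.statesToCells(rowList, ntax, nchar, "NEXUS matrix"))
}

#' @rdname readNexus
#' @export
readTnt <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  ix <- grep("^\\s*xread\\s*$", lines)
  if (length(ix) != 1L) stop("not a TNT xread file")
  rest <- lines[-seq_len(ix)]
  rest <- rest[nzchar(trimws(rest))]
  if (startsWith(trimws(rest[1]), "'")) rest <- rest[-1]  # optional title
  hdr <- as.integer(strsplit(trimws(rest[1]), "\\s+")[[1]])
  if (length(hdr) != 2L || anyNA(hdr))
    stop("expected 'nchar ntax' header after xread")
  nchar <- hdr[1]; ntax <- hdr[2]
  rowList <- list()
  for (line in rest[-1]) {
    s <- trimws(line)
    if (!nzchar(s)) next
    if (s == ";" || grepl("^proc", s)) break
    rowList[[length(rowList) + 1L]] <- .matrixRowTokens(s)
  }
  MRPMatrix(.statesToCells(rowList, ntax, nchar, "TNT matrix"))
}
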