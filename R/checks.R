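## Dataset-level curation: summary, cleaning, independence checking,
## taxonomic overlap connectivity, and metadata-based subsetting.

#' Text summary of a dataset
#'
#' Counts of sources, trees, distinct taxa and total MRP characters, plus
#' the sorted taxa list, a publication-year histogram, and the distinct
#' character names and analyses used.
#'
#' @param ds A [PhyloDataset-class].
#' @return A single string.
#' @export
dataSummary <- function(ds) {
  trees <- sourceTrees(ds)
  parsed <- lapply(trees, function(st) parseNewick(st@treeString))
  allTaxa <- sort(unique(baseName(unlist(lapply(parsed, leafLabels),
                                         use.names = FALSE))))
  nChars <- sum(vapply(parsed, function(t) length(informativeClades(t)),
                       integer(1)))
  years <- vapply(ds@sources, function(s) s@bibliographic@year, integer(1))
  years <- years[!is.na(years)]
  yearTab <- table(years)
  charNames <- sort(unique(unlist(lapply(trees, function(st)
    st@characterData$name), use.names = FALSE)))
  analyses <- vapply(trees, function(st) st@analysisUsed, character(1))
  analyses <- sort(unique(analyses[!is.na(analyses)]))
  lines <- c(
    sprintf("Dataset: %s", ds@name),
    sprintf("Sources: %d", nSources(ds)),
    sprintf("Trees: %d", nTrees(ds)),
    sprintf("Distinct taxa: %d", length(allTaxa)),
    sprintf("Total MRP characters: %d", nChars),
    "",
    "Publication years:",
    if (length(yearTab))
      sprintf("  %s: %d", names(yearTab), as.integer(yearTab))
    else "  (none)",
    "",
    "Characters used:",
    if (length(charNames)) paste0("  ", charNames) else "  (none)",
    "",
    "Analyses used:",
    if (length(analyses)) paste0("  ", analyses) else "  (none)",
    "",
    "Taxa list:",
    if (length(allTaxa)) paste0("  ", allTaxa) else "  (none)")
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Remove uninformative trees and emptied sources
#'
#' Drops every tree failing [isInformative()] (fewer than four leaves, or
#' no clade) and every source left with no trees. Safe to run repeatedly;
#' intended between processing steps, since substitution and polyphyly
#' handling can leave trees uninformative.
#'
#' @param ds A [PhyloDataset-class].
#' @param timestamp History timestamp (exposed for reproducible outputs).
#' @return A list with elements `dataset` (cleaned, one history entry
#'   appended) and `log` (character vector naming each removal).
#' @export
cleanData <- function(ds, timestamp = historyTimestamp()) {
  log <- character(0)
  keepSources <- logical(length(ds@sources))
  for (si in seq_along(ds@sources)) {
    src <- ds@sources[[si]]
    keep <- vapply(seq_along(src@sourceTrees), function(ti) {
      ok <- isInformative(parseNewick(src@sourceTrees[[ti]]@treeString))
      if (!ok)
        log <<- c(log, sprintf("removed uninformative tree %s:%d",
                               src@citationKey, ti))
      ok
    }, logical(1))
    src@sourceTrees <- src@sourceTrees[keep]
    keepSources[si] <- length(src@sourceTrees) > 0L
    if (!keepSources[si])
      log <- c(log, sprintf("removed source %s (no trees left)",
                            src@citationKey))
    ds@sources[[si]] <- src
  }
  ds@sources <- ds@sources[keepSources]
  ds <- appendHistory(ds, "clean_data", paste(log, collapse = "; "),
                      timestamp)
  list(dataset = ds, log = log)
}

.normChar <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

#' Check data independence of source trees
#'
#' Source trees entering a supertree analysis should be independent:
#' trees using identical character sets and the same (or nested) taxa
#' duplicate evidence. Trees are grouped by their normalised
#' character-name sets; within a group, equal taxon sets form an
#' identical group (keep the earliest source by year, then citation key)
#' and a strict subset flags the smaller tree for removal.
#'
#' @param ds A [PhyloDataset-class]; every tree must have non-empty
#'   character data.
#' @param autoRemove Drop the suggested trees (default `FALSE`).
#' @param timestamp History timestamp (exposed for reproducible outputs).
#' @return A list with elements `report` ([IndependenceReport-class]) and
#'   `dataset` (unchanged unless `autoRemove`).
#' @export
checkIndependence <- function(ds, autoRemove = FALSE,
                              timestamp = historyTimestamp()) {
  trees <- sourceTrees(ds)
  ids <- names(trees) %||% character(0)
  empty <- vapply(trees, function(st) nrow(st@characterData) == 0L,
                  logical(1))
  if (any(empty))
    stop("trees without character data (required for the independence ",
         "check): ", paste(ids[empty], collapse = ", "))
  charKey <- vapply(trees, function(st)
    paste(sort(unique(.normChar(st@characterData$name))), collapse = "|"),
    character(1))
  leafSets <- lapply(trees, function(st)
    sort(unique(baseName(leafLabels(parseNewick(st@treeString))))))
  keyOf <- sub(":[0-9]+$", "", ids)
  yearOf <- vapply(keyOf, function(k) {
    y <- sources(ds)[[k]]@bibliographic@year
    if (is.na(y)) 9999L else y
  }, integer(1))

  identicalGroups <- list()
  subsetPairs <- data.frame(smaller = character(0), larger = character(0),
                            stringsAsFactors = FALSE)
  suggested <- character(0)
  for (grp in split(seq_along(trees), charKey)) {
    if (length(grp) < 2L) next
    sig <- vapply(grp, function(i) paste(leafSets[[i]], collapse = ","),
                  character(1))
    for (same in split(grp, sig)) {
      if (length(same) < 2L) next
      members <- ids[same]
      identicalGroups[[length(identicalGroups) + 1L]] <- members
      ord <- order(yearOf[same], ids[same], method = "radix")
      suggested <- c(suggested, members[ord][-1])
    }
    for (a in grp) for (b in grp) {
      if (a == b) next
      la <- leafSets[[a]]; lb <- leafSets[[b]]
      if (length(la) < length(lb) && all(la %in% lb)) {
        subsetPairs <- rbind(subsetPairs,
                             data.frame(smaller = ids[a], larger = ids[b],
                                        stringsAsFactors = FALSE))
        suggested <- c(suggested, ids[a])
      }
    }
  }
  suggested <- sort(unique(suggested), method = "radix")
  report <- new("IndependenceReport", identicalGroups = identicalGroups,
                subsetPairs = subsetPairs, suggestedRemovals = suggested)
  if (autoRemove && length(suggested)) {
    keepSrc <- logical(length(ds@sources))
    for (si in seq_along(ds@sources)) {
      src <- ds@sources[[si]]
      tids <- paste0(src@citationKey, ":", seq_along(src@sourceTrees))
      src@sourceTrees <- src@sourceTrees[!tids %in% suggested]
      keepSrc[si] <- length(src@sourceTrees) > 0L
      ds@sources[[si]] <- src
    }
    ds@sources <- ds@sources[keepSrc]
  }
  if (autoRemove)
    ds <- appendHistory(ds, "check_independence",
                        paste0("removed: ",
                               paste(suggested, collapse = ", ")),
                        timestamp)
  list(report = report, dataset = ds)
}

#' Check taxonomic overlap between source trees
#'
#' Builds the overlap graph: one node per source tree, an edge when two
#' trees share at least `k` taxa (edge weight = shared count). Sufficient
#' overlap for supertree construction means a connected graph.
#'
#' @param ds A [PhyloDataset-class].
#' @param k Minimum shared-taxon count for an edge; must be >= 2 (a single
#'   shared taxon carries no grouping information).
#' @return An [OverlapResult-class].
#' @seealso [exportOverlap()] for DOT/GraphML export.
#' @export
checkOverlap <- function(ds, k = 2L) {
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop("minimum overlap k must be >= 2")
  trees <- sourceTrees(ds)
  ids <- names(trees) %||% character(0)
  leafSets <- lapply(trees, function(st)
    unique(baseName(leafLabels(parseNewick(st@treeString)))))
  n <- length(ids)
  from <- character(0); to <- character(0); w <- integer(0)
  if (n >= 2L) for (a in 1:(n - 1L)) for (b in (a + 1L):n) {
    shared <- length(intersect(leafSets[[a]], leafSets[[b]]))
    if (shared >= k) {
      from <- c(from, ids[a]); to <- c(to, ids[b]); w <- c(w, shared)
    }
  }
  edges <- data.frame(from = from, to = to, weight = w,
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)
  components <- unname(split(ids, comp$membership))
  new("OverlapResult", nodes = ids, edges = edges, minOverlap = k,
      connected = comp$no <= 1L, components = components)
}

#' Export an overlap graph as DOT or GraphML
#'
#' @param x An [OverlapResult-class].
#' @param path Output file path.
#' @param format `"dot"` or `"graphml"`.
#' @return Invisibly, `path`.
#' @export
exportOverlap <- function(x, path, format = c("dot", "graphml")) {
  format <- match.arg(format)
  g <- igraph::graph_from_data_frame(
    x@edges, directed = FALSE, vertices = data.frame(name = x@nodes))
  igraph::write_graph(g, path, format = format)
  invisible(path)
}

#' Extract a metadata-defined subset of a dataset
#'
#' Keeps the trees matching every given filter (conjunction); sources left
#' with no matching trees are dropped. The original dataset is untouched;
#' the result's history notes the filter. Useful for building, say, a
#' molecular-only supertree to compare against the full analysis.
#'
#' @param ds A [PhyloDataset-class].
#' @param years Length-2 numeric range of publication years (inclusive),
#'   or `NULL`.
#' @param characterType Keep trees having at least one character of one
#'   of these types (`molecular`, `morphological`, `behavioural`,
#'   `other`), or `NULL`.
#' @param characterNames Keep trees using at least one of these character
#'   names (case-insensitive), or `NULL`.
#' @param analysis Keep trees whose `analysisUsed` is one of these, or
#'   `NULL`.
#' @param fossilStatus Keep trees with one of these fossil statuses, or
#'   `NULL`.
#' @param timestamp History timestamp (exposed for reproducible outputs).
#' @return A new [PhyloDataset-class] (empty, with a warning, if nothing
#'   matches).
#' @export
createSubset <- function(ds, years = NULL, characterType = NULL,
                         characterNames = NULL, analysis = NULL,
                         fossilStatus = NULL,
                         timestamp = historyTimestamp()) {
  matchTree <- function(src, st) {
    if (!is.null(years)) {
      y <- src@bibliographic@year
      if (is.na(y) || y < years[1] || y > years[2]) return(FALSE)
    }
    if (!is.null(characterType) &&
        !any(st@characterData$type %in% characterType)) return(FALSE)
    if (!is.null(characterNames) &&
        !any(.normChar(st@characterData$name) %in%
             .normChar(characterNames))) return(FALSE)
    if (!is.null(analysis) &&
        (is.na(st@analysisUsed) || !st@analysisUsed %in% analysis))
      return(FALSE)
    if (!is.null(fossilStatus) &&
        (is.na(st@fossilStatus) || !st@fossilStatus %in% fossilStatus))
      return(FALSE)
    TRUE
  }
  newSources <- list()
  for (src in ds@sources) {
    keep <- vapply(src@sourceTrees, function(st) matchTree(src, st),
                   logical(1))
    if (any(keep)) {
      src@sourceTrees <- src@sourceTrees[keep]
      newSources[[length(newSources) + 1L]] <- src
    }
  }
  if (length(newSources) == 0L)
    warning("subset filter matched no trees; returning an empty dataset")
  filt <- c(
    if (!is.null(years)) paste0("years=", years[1], "-", years[2]),
    if (!is.null(characterType))
      paste0("character_type=", paste(characterType, collapse = ",")),
    if (!is.null(characterNames))
      paste0("character_names=", paste(characterNames, collapse = ",")),
    if (!is.null(analysis))
      paste0("analysis=", paste(analysis, collapse = ",")),
    if (!is.null(fossilStatus))
      paste0("fossil_status=", paste(fossilStatus, collapse = ",")))
  out <- PhyloDataset(name = ds@name, sources = newSources,
                      history = ds@history)
  appendHistory(out, "create_subset", paste(filt, collapse = "; "),
                timestamp)
}
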