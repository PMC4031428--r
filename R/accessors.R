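#' Accessors for dataset and matrix objects
#'
#' Standard read accessors; slots are never accessed directly by user code.
#'
#' @param x A [PhyloDataset-class], [Source-class], [MRPMatrix-class],
#'   [EquivalenceReport-class] or [OverlapResult-class] object as
#'   appropriate.
#' @param ... For `taxa`: `markers = FALSE` strips `%d` polyphyly markers
#'   from leaf labels before taking the union.
#' @return The corresponding component (see each method).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("datasetName", "PhyloDataset", function(x) x@name)

#' @rdname accessors
#' @export
setMethod("sources", "PhyloDataset", function(x) {
  out <- x@sources
  names(out) <- vapply(out, function(s) s@citationKey, character(1))
  out
})

#' @rdname accessors
#' @export
setMethod("sourceTrees", "Source", function(x) x@sourceTrees)

#' @rdname accessors
#' @export
setMethod("sourceTrees", "PhyloDataset", function(x) {
  out <- list()
  for (s in x@sources) {
    trees <- s@sourceTrees
    if (length(trees))
      names(trees) <- paste0(s@citationKey, ":", seq_along(trees))
    out <- c(out, trees)
  }
  out
})

#' @rdname accessors
#' @export
setMethod("history", "PhyloDataset", function(x) x@history)

#' @rdname accessors
#' @export
setMethod("nSources", "PhyloDataset", function(x) length(x@sources))

#' @rdname accessors
#' @export
setMethod("nTrees", "PhyloDataset", function(x) {
  sum(vapply(x@sources, function(s) length(s@sourceTrees), integer(1)))
})

#' @rdname accessors
#' @export
setMethod("treeIds", "PhyloDataset", function(x) names(sourceTrees(x)) %||% character(0))

#' @rdname accessors
#' @export
setMethod("taxa", "PhyloDataset", function(x, markers = TRUE) {
  labs <- unlist(lapply(sourceTrees(x), function(st) {
    leafLabels(parseNewick(st@treeString))
  }), use.names = FALSE)
  if (!markers) labs <- baseName(labs)
  sort(unique(labs))
})

#' @rdname accessors
#' @export
setMethod("taxa", "MRPMatrix", function(x, ...) rownames(x@cells))

#' @rdname accessors
#' @export
setMethod("cells", "MRPMatrix", function(x) x@cells)

#' @rdname accessors
#' @export
setMethod("provenance", "MRPMatrix", function(x) x@provenance)

#' @rdname accessors
#' @export
setMethod("removals", "EquivalenceReport", function(x) x@removals)

#' @rdname accessors
#' @export
setMethod("pairRelations", "EquivalenceReport", function(x) x@pairs)

#' @rdname accessors
#' @export
setMethod("isConnected", "OverlapResult", function(x) x@connected)

#' Dataset equality, field by field
#'
#' Compares two datasets slot by slot (name, every source's citation key,
#' bibliographic fields, source trees with their metadata and preserved
#' extension fragments, and the history log). Used to verify that a
#' write-then-read round trip through the Phyml format is lossless.
#'
#' @param a,b [PhyloDataset-class] objects.
#' @return `TRUE` or `FALSE`.
#' @export
datasetIdentical <- function(a, b) {
  isTRUE(all.equal(.dsList(a), .dsList(b), check.attributes = TRUE))
}

.bibList <- function(b) {
  list(key = b@key, entryType = b@entryType, authors = b@authors,
       title = b@title, year = b@year, journal = b@journal,
       booktitle = b@booktitle, volume = b@volume, pages = b@pages,
       doi = b@doi, extraFields = b@extraFields)
}

.treeList <- function(st) {
  list(treeString = st@treeString,
       characterData = st@characterData[, c("type", "name")],
       analysisUsed = st@analysisUsed, fossilStatus = st@fossilStatus,
       figureRef = st@figureRef, pageRef = st@pageRef,
       treeLegend = st@treeLegend, extensions = st@extensions)
}

.dsList <- function(ds) {
  list(name = ds@name,
       sources = lapply(ds@sources, function(s) {
         list(citationKey = s@citationKey,
              bibliographic = .bibList(s@bibliographic),
              sourceTrees = lapply(s@sourceTrees, .treeList),
              extensions = s@extensions)
       }),
       history = ds@history)
}

#' Append an entry to a dataset's history log
#'
#' Every processing operation records itself through this; scripted
#' pipelines can use it to log their own steps into the audit trail.
#'
#' @param ds A [PhyloDataset-class].
#' @param operation Short operation name.
#' @param parameters Free-text parameter description.
#' @param timestamp Timestamp string; defaults to the current UTC time.
#' @return The dataset with one more history row.
#' @export
appendHistory <- function(ds, operation, parameters = "",
                          timestamp = historyTimestamp()) {
  ds@history <- rbind(ds@history,
                      data.frame(timestamp = timestamp, operation = operation,
                                 parameters = parameters,
                                 stringsAsFactors = FALSE))
  rownames(ds@history) <- NULL
  ds
}
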