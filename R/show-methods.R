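#' Show methods
#'
#' Compact printing for the package's S4 objects.
#'
#' @param object The object to display.
#' @name show-methods
#' @keywords internal
NULL

#' @rdname show-methods
setMethod("show", "PhyloDataset", function(object) {
  cat("PhyloDataset '", object@name, "'\n", sep = "")
  cat("  sources: ", nSources(object), "  trees: ", nTrees(object),
      "  history entries: ", nrow(object@history), "\n", sep = "")
})

#' @rdname show-methods
setMethod("show", "Source", function(object) {
  b <- object@bibliographic
  cat("Source [", object@citationKey, "] ",
      if (length(b@authors)) b@authors[1] else "?",
      if (!is.na(b@year)) paste0(" (", b@year, ")") else "",
      ", ", length(object@sourceTrees), " tree(s)\n", sep = "")
})

#' @rdname show-methods
setMethod("show", "SourceTree", function(object) {
  nTaxa <- length(leafLabels(parseNewick(object@treeString)))
  cat("SourceTree: ", nTaxa, " taxa, ", nrow(object@characterData),
      " character(s)", sep = "")
  if (!is.na(object@analysisUsed))
    cat(", analysis: ", object@analysisUsed, sep = "")
  cat("\n")
})

#' @rdname show-methods
setMethod("show", "BibRecord", function(object) {
  cat("BibRecord @", object@entryType, "{", object@key, "}: ", sep = "")
  if (length(object@authors)) cat(object@authors[1])
  if (length(object@authors) > 1) cat(" et al.")
  if (!is.na(object@year)) cat(" (", object@year, ")", sep = "")
  cat("\n")
})

#' @rdname show-methods
setMethod("show", "MRPMatrix", function(object) {
  cm <- object@cells
  cat("MRPMatrix: ", nrow(cm), " taxa x ", ncol(cm), " characters; ",
      round(100 * mean(cm == "?"), 1), "% missing\n", sep = "")
})

#' @rdname show-methods
setMethod("show", "EquivalenceReport", function(object) {
  cat("EquivalenceReport: ", nrow(object@pairs), " non-trivial pair(s), ",
      nrow(object@removals), " safely removable taxon/taxa\n", sep = "")
})

#' @rdname show-methods
setMethod("show", "OverlapResult", function(object) {
  cat("OverlapResult (k >= ", object@minOverlap, "): ",
      length(object@nodes), " trees, ", nrow(object@edges), " edges, ",
      length(object@components), " component(s) -> ",
      if (object@connected) "connected" else "NOT connected", "\n",
      sep = "")
})

#' @rdname show-methods
setMethod("show", "IndependenceReport", function(object) {
  cat("IndependenceReport: ", length(object@identicalGroups),
      " identical group(s), ", nrow(object@subsetPairs),
      " subset pair(s); suggested removals: ",
      length(object@suggestedRemovals), "\n", sep = "")
})

#' @rdname show-methods
setMethod("show", "SubstitutionSet", function(object) {
  cat("SubstitutionSet with ", length(object@old), " rule(s)\n", sep = "")
  n <- min(length(object@old), 5L)
  for (i in seq_len(n)) {
    repl <- object@replacements[[i]]
    cat("  ", object@old[i], " -> ",
        if (length(repl)) paste(repl, collapse = ", ") else "(delete)",
        "\n", sep = "")
  }
  if (length(object@old) > n) cat("  ...\n")
})
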