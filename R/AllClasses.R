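## S4 classes for the curation pipeline. Trees themselves are ape "phylo"
## objects; these classes hold the dataset, matrix and report structures
## around them.

setOldClass("data.frame")

#' BibRecord: one bibliographic entry
#'
#' Holds the fields of a single BibTeX entry. Absent optional fields are
#' `NA_character_` (or `NA_integer_` for the year). Fields outside the
#' modelled set are kept verbatim in `extraFields` so that an imported
#' entry re-exports losslessly.
#'
#' @slot key Citation key (the BibTeX entry key).
#' @slot entryType Entry type, e.g. `"article"` or `"book"`.
#' @slot authors Character vector of author names, in order.
#' @slot title,journal,booktitle,volume,pages,doi Optional fields.
#' @slot year Four-digit integer year, or `NA`.
#' @slot extraFields Named character vector of unmodelled fields.
#' @export
setClass("BibRecord", representation(
  key = "character",
  entryType = "character",
  authors = "character",
  title = "character",
  year = "integer",
  journal = "character",
  booktitle = "character",
  volume = "character",
  pages = "character",
  doi = "character",
  extraFields = "character"
))

setValidity("BibRecord", function(object) {
  msg <- character(0)
  if (length(object@key) != 1L || !nzchar(object@key))
    msg <- c(msg, "citation key must be a non-empty string")
  if (length(object@year) != 1L)
    msg <- c(msg, "year must be length 1")
  else if (!is.na(object@year) && (object@year < 1000L || object@year > 9999L))
    msg <- c(msg, "year must be a 4-digit integer or NA")
  if (length(msg)) msg else TRUE
})

#' @param key,entryType,authors,title,year,journal,booktitle,volume,pages,doi,extraFields
#'   See the corresponding slots.
#' @rdname BibRecord-class
#' @return A `BibRecord` object.
#' @export
#' @examples
#' BibRecord("hill2014", authors = c("Hill, J.", "Davis, K. E."),
#'           title = "A curation pipeline", year = 2014L,
#'           journal = "J. Examples")
BibRecord <- function(key, entryType = "article", authors = character(0),
                      title = NA_character_, year = NA_integer_,
                      journal = NA_character_, booktitle = NA_character_,
                      volume = NA_character_, pages = NA_character_,
                      doi = NA_character_, extraFields = character(0)) {
  if (length(extraFields) && is.null(names(extraFields)))
    stop("extraFields must be named")
  new("BibRecord", key = key, entryType = tolower(entryType),
      authors = as.character(authors), title = title,
      year = as.integer(year), journal = journal, booktitle = booktitle,
      volume = as.character(volume), pages = as.character(pages),
      doi = doi, extraFields = extraFields)
}

#' SourceTree: one published tree plus its metadata
#'
#' @slot treeString Newick text of the tree (topology only; leaf labels may
#'   carry `%d` polyphyly markers).
#' @slot characterData data.frame with columns `type` (one of `molecular`,
#'   `morphological`, `behavioural`, `other`) and `name`.
#' @slot analysisUsed Free text, e.g. `"parsimony"`, `"Bayesian"`.
#' @slot fossilStatus One of `all_extant`, `some_fossil`, `all_fossil`, or `NA`.
#' @slot figureRef,pageRef,treeLegend Optional free text.
#' @slot extensions Character vector of verbatim XML fragments preserved
#'   from unknown elements in the source file.
#' @export
setClass("SourceTree", representation(
  treeString = "character",
  characterData = "data.frame",
  analysisUsed = "character",
  fossilStatus = "character",
  figureRef = "character",
  pageRef = "character",
  treeLegend = "character",
  extensions = "character"
))

.characterTypes <- c("molecular", "morphological", "behavioural", "other")
.fossilLevels <- c("all_extant", "some_fossil", "all_fossil")

setValidity("SourceTree", function(object) {
  msg <- character(0)
  if (length(object@treeString) != 1L || !nzchar(object@treeString))
    msg <- c(msg, "treeString must be a single non-empty Newick string")
  else {
    p <- tryCatch(parseNewick(object@treeString), error = function(e) e)
    if (inherits(p, "error"))
      msg <- c(msg, paste0("treeString does not parse as Newick: ",
                           conditionMessage(p)))
  }
  cd <- object@characterData
  if (!all(c("type", "name") %in% names(cd)))
    msg <- c(msg, "characterData must have columns 'type' and 'name'")
  else if (nrow(cd) && !all(cd$type %in% .characterTypes))
    msg <- c(msg, paste0("character types must be one of: ",
                         paste(.characterTypes, collapse = ", ")))
  if (!is.na(object@fossilStatus) && !object@fossilStatus %in% .fossilLevels)
    msg <- c(msg, paste0("fossilStatus must be NA or one of: ",
                         paste(.fossilLevels, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' @param treeString,characterData,analysisUsed,fossilStatus,figureRef,pageRef,treeLegend,extensions
#'   See the corresponding slots. `characterData` may also be given as a
#'   character vector of names (type defaults to `"other"`).
#' @rdname SourceTree-class
#' @return A `SourceTree` object.
#' @export
#' @examples
#' SourceTree("(A,(B,C));", characterData = data.frame(
#'   type = "molecular", name = "cytb"))
SourceTree <- function(treeString, characterData = emptyCharacterData(),
                       analysisUsed = NA_character_,
                       fossilStatus = NA_character_,
                       figureRef = NA_character_, pageRef = NA_character_,
                       treeLegend = NA_character_,
                       extensions = character(0)) {
  if (is.character(characterData))
    characterData <- data.frame(type = rep("other", length(characterData)),
                                name = characterData,
                                stringsAsFactors = FALSE)
  new("SourceTree", treeString = treeString,
      characterData = characterData, analysisUsed = analysisUsed,
      fossilStatus = fossilStatus, figureRef = figureRef, pageRef = pageRef,
      treeLegend = treeLegend, extensions = extensions)
}

#' @rdname SourceTree-class
#' @export
emptyCharacterData <- function() {
  data.frame(type = character(0), name = character(0),
             stringsAsFactors = FALSE)
}

#' Source: one publication with its trees
#'
#' @slot citationKey Unique key within the dataset.
#' @slot bibliographic A [BibRecord-class].
#' @slot sourceTrees Ordered list of [SourceTree-class] objects.
#' @slot extensions Verbatim XML fragments preserved from unknown elements.
#' @export
setClass("Source", representation(
  citationKey = "character",
  bibliographic = "BibRecord",
  sourceTrees = "list",
  extensions = "character"
))

setValidity("Source", function(object) {
  msg <- character(0)
  if (length(object@citationKey) != 1L || !nzchar(object@citationKey))
    msg <- c(msg, "citationKey must be non-empty")
  if (!all(vapply(object@sourceTrees, is, logical(1), "SourceTree")))
    msg <- c(msg, "sourceTrees must all be SourceTree objects")
  if (length(msg)) msg else TRUE
})

#' @param citationKey Unique key; defaults to the bibliographic record's key.
#' @param bibliographic,sourceTrees,extensions See the corresponding slots.
#' @rdname Source-class
#' @return A `Source` object.
#' @export
Source <- function(bibliographic, sourceTrees = list(),
                   citationKey = bibliographic@key,
                   extensions = character(0)) {
  if (is(sourceTrees, "SourceTree")) sourceTrees <- list(sourceTrees)
  new("Source", citationKey = citationKey, bibliographic = bibliographic,
      sourceTrees = sourceTrees, extensions = extensions)
}

#' PhyloDataset: a named project of source trees with metadata
#'
#' The in-memory twin of a Phyml file: a project name, an ordered list of
#' [Source-class] objects, and a history log to which every processing
#' operation appends one entry.
#'
#' @slot name Project name.
#' @slot sources Ordered list of [Source-class] objects with unique
#'   citation keys.
#' @slot history data.frame with character columns `timestamp`, `operation`
#'   and `parameters`.
#' @export
setClass("PhyloDataset", representation(
  name = "character",
  sources = "list",
  history = "data.frame"
))

setValidity("PhyloDataset", function(object) {
  msg <- character(0)
  if (length(object@name) != 1L)
    msg <- c(msg, "name must be a single string")
  if (!all(vapply(object@sources, is, logical(1), "Source")))
    msg <- c(msg, "sources must all be Source objects")
  keys <- vapply(object@sources, function(s) s@citationKey, character(1))
  if (anyDuplicated(keys))
    msg <- c(msg, paste0("duplicate citation keys: ",
                         paste(unique(keys[duplicated(keys)]), collapse = ", ")))
  if (!identical(names(object@history),
                 c("timestamp", "operation", "parameters")))
    msg <- c(msg, "history must have columns timestamp/operation/parameters")
  if (length(msg)) msg else TRUE
})

#' @param name Project name.
#' @param sources List of [Source-class] objects (or a single one).
#' @param history History data.frame; usually left at its default.
#' @rdname PhyloDataset-class
#' @return A `PhyloDataset` object.
#' @export
#' @examples
#' bib <- BibRecord("smith2001", authors = "Smith, A.", year = 2001L)
#' ds <- PhyloDataset("demo", Source(bib, SourceTree("(A,(B,C),D);")))
#' nTrees(ds)
PhyloDataset <- function(name = "dataset", sources = list(),
                         history = emptyHistory()) {
  if (is(sources, "Source")) sources <- list(sources)
  new("PhyloDataset", name = name, sources = sources, history = history)
}

#' @rdname PhyloDataset-class
#' @export
emptyHistory <- function() {
  data.frame(timestamp = character(0), operation = character(0),
             parameters = character(0), stringsAsFactors = FALSE)
}

#' SubstitutionSet: ordered taxon rename/delete rules
#'
#' Each rule maps an old taxon name to zero or more replacement names; an
#' empty replacement list means deletion. The same grammar is consumed and
#' produced by Safe Taxonomic Reduction for post-analysis reinsertion.
#'
#' @slot old Character vector of old names (no duplicates).
#' @slot replacements List of character vectors, parallel to `old`.
#' @export
setClass("SubstitutionSet", representation(
  old = "character",
  replacements = "list"
))

setValidity("SubstitutionSet", function(object) {
  msg <- character(0)
  if (length(object@old) != length(object@replacements))
    msg <- c(msg, "old and replacements must be parallel")
  if (anyDuplicated(object@old))
    msg <- c(msg, paste0("duplicate old names: ",
                         paste(unique(object@old[duplicated(object@old)]),
                               collapse = ", ")))
  reps <- unlist(object@replacements, use.names = FALSE)
  if (length(reps) && !all(validTaxonLabel(reps)))
    msg <- c(msg, "replacement names must be valid taxon labels")
  if (length(msg)) msg else TRUE
})

#' @param old,replacements See the corresponding slots; `replacements`
#'   entries may be `character(0)` for deletions.
#' @rdname SubstitutionSet-class
#' @return A `SubstitutionSet` object.
#' @export
#' @examples
#' SubstitutionSet(c("Bos", "Felis"),
#'                 list(c("Bos_taurus", "Bos_indicus"), character(0)))
SubstitutionSet <- function(old = character(0), replacements = list()) {
  replacements <- lapply(replacements, as.character)
  new("SubstitutionSet", old = as.character(old), replacements = replacements)
}

#' MRPMatrix: Baum-Ragan matrix representation of source trees
#'
#' A taxa-by-characters matrix over `{0, 1, ?}`: for each informative clade
#' of each source tree, clade members are `1`, other taxa of that tree `0`,
#' and taxa absent from the tree `?`. Per-character provenance records the
#' source citation key, tree index and clade index each column came from.
#'
#' @slot cells Character matrix with taxon rownames; entries `"0"`, `"1"`
#'   or `"?"`. Every column carries at least one `0` and one `1`.
#' @slot provenance data.frame with columns `source`, `tree`, `clade`,
#'   one row per column of `cells`.
#' @export
setClass("MRPMatrix", representation(
  cells = "matrix",
  provenance = "data.frame"
))

setValidity("MRPMatrix", function(object) {
  msg <- character(0)
  m <- object@cells
  if (!is.character(m))
    msg <- c(msg, "cells must be a character matrix")
  else {
    if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
      msg <- c(msg, "cells must have unique taxon rownames")
    if (length(m) && !all(m %in% c("0", "1", "?")))
      msg <- c(msg, "cells must contain only 0, 1 and ?")
    if (ncol(m)) {
      ones <- colSums(m == "1") > 0
      zeros <- colSums(m == "0") > 0
      if (!all(ones & zeros))
        msg <- c(msg, paste0("columns without both a 0 and a 1: ",
                             paste(which(!(ones & zeros)), collapse = ", ")))
    }
  }
  if (!identical(names(object@provenance), c("source", "tree", "clade")))
    msg <- c(msg, "provenance must have columns source/tree/clade")
  else if (nrow(object@provenance) != ncol(object@cells))
    msg <- c(msg, "provenance must have one row per character")
  if (length(msg)) msg else TRUE
})

#' @param cells,provenance See the corresponding slots; `provenance`
#'   defaults to unknown provenance (e.g. a matrix read from NEXUS).
#' @rdname MRPMatrix-class
#' @return An `MRPMatrix` object.
#' @export
MRPMatrix <- function(cells, provenance = NULL) {
  if (is.null(provenance))
    provenance <- data.frame(source = rep(NA_character_, ncol(cells)),
                             tree = rep(NA_integer_, ncol(cells)),
                             clade = rep(NA_integer_, ncol(cells)),
                             stringsAsFactors = FALSE)
  new("MRPMatrix", cells = cells, provenance = provenance)
}

#' EquivalenceReport: pairwise taxonomic equivalence and removal plan
#'
#' Result of scanning an [MRPMatrix-class] for taxonomic equivalence in the
#' Wilkinson sense: two taxa are equivalent when no character is known and
#' different in both. The removal plan lists taxa whose rows are subsumed
#' by (or identical to) a retained representative and are therefore safe
#' to remove.
#'
#' Category letters used in reports: `A` identical rows with no missing
#' entries; `B` symmetric equivalence (complementary missing data, not
#' safe); `C` removed because subsumed by its representative; `C*` removed
#' member of an identical-rows group (exactly reinsertable); `E` no
#' equivalence.
#'
#' @slot pairs data.frame of non-trivial pair relations: columns `taxonA`,
#'   `taxonB`, `relation` (one of `identical`, `a_subsumed_by_b`,
#'   `b_subsumed_by_a`, `symmetric_equivalent`).
#' @slot removals data.frame with columns `taxon`, `representative`,
#'   `category`.
#' @slot categories Named character vector, one category label per taxon.
#' @export
setClass("EquivalenceReport", representation(
  pairs = "data.frame",
  removals = "data.frame",
  categories = "character"
))

setValidity("EquivalenceReport", function(object) {
  msg <- character(0)
  if (!all(c("taxonA", "taxonB", "relation") %in% names(object@pairs)))
    msg <- c(msg, "pairs must have columns taxonA/taxonB/relation")
  if (!all(c("taxon", "representative", "category") %in% names(object@removals)))
    msg <- c(msg, "removals must have columns taxon/representative/category")
  else if (any(object@removals$representative %in% object@removals$taxon))
    msg <- c(msg, "a removed taxon may not serve as a representative")
  if (length(msg)) msg else TRUE
})

#' OverlapResult: taxonomic overlap graph of a dataset
#'
#' Nodes are source trees (identified as `citationKey:treeIndex`); an edge
#' joins two trees sharing at least `minOverlap` taxa, weighted by the
#' shared count. Sufficient overlap for supertree construction means the
#' graph is connected.
#'
#' @slot nodes Character vector of tree identifiers.
#' @slot edges data.frame with columns `from`, `to`, `weight`.
#' @slot minOverlap The overlap threshold used (k >= 2).
#' @slot connected Logical flag.
#' @slot components List of character vectors partitioning `nodes`.
#' @export
setClass("OverlapResult", representation(
  nodes = "character",
  edges = "data.frame",
  minOverlap = "integer",
  connected = "logical",
  components = "list"
))

setValidity("OverlapResult", function(object) {
  msg <- character(0)
  if (object@connected != (length(object@components) == 1L))
    msg <- c(msg, "connected must agree with the number of components")
  if (nrow(object@edges) && any(object@edges$weight < object@minOverlap))
    msg <- c(msg, "edge weights must be >= minOverlap")
  if (length(msg)) msg else TRUE
})

#' IndependenceReport: non-independent source trees
#'
#' Trees using identical character sets are compared by taxon set: equal
#' sets form identical groups; a strict subset flags the smaller tree for
#' removal.
#'
#' @slot identicalGroups List of character vectors of tree identifiers.
#' @slot subsetPairs data.frame with columns `smaller`, `larger`.
#' @slot suggestedRemovals Character vector of tree identifiers.
#' @export
setClass("IndependenceReport", representation(
  identicalGroups = "list",
  subsetPairs = "data.frame",
  suggestedRemovals = "character"
))
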