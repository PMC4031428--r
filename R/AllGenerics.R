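#' @importFrom methods new is validObject show slot
NULL

#' @export
setGeneric("datasetName", function(x) standardGeneric("datasetName"))

#' @export
setGeneric("sources", function(x) standardGeneric("sources"))

#' @export
setGeneric("sourceTrees", function(x) standardGeneric("sourceTrees"))

#' @export
setGeneric("history", function(x) standardGeneric("history"))

#' @export
setGeneric("taxa", function(x, ...) standardGeneric("taxa"))

#' @export
setGeneric("nSources", function(x) standardGeneric("nSources"))

#' @export
setGeneric("nTrees", function(x) standardGeneric("nTrees"))

#' @export
setGeneric("cells", function(x) standardGeneric("cells"))

#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @export
setGeneric("removals", function(x) standardGeneric("removals"))

#' @export
setGeneric("pairRelations", function(x) standardGeneric("pairRelations"))

#' @export
setGeneric("treeIds", function(x) standardGeneric("treeIds"))

#' @export
setGeneric("isConnected", function(x) standardGeneric("isConnected"))
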