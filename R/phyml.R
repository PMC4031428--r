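## The Phyml single-file XML dataset format: one project holding sources,
## each source a publication (bibliographic block) plus one or more source
## trees with their metadata, and a history log of processing operations.
## The element names are this package's documented schema (see the
## vignette); the format is versioned via the format_version attribute.
## Reading uses xml2; writing emits deterministic, indented XML so two
## consecutive writes of the same dataset are byte-identical.

PHYML_FORMAT_VERSION <- "1.0"

.xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

#' Parse Phyml XML into a dataset
#'
#' @param xmlText A single string of Phyml XML, or a vector of lines.
#' @return A [PhyloDataset-class].
#' @details Unknown child elements of `<source>` and `<source_tree>` are
#'   preserved verbatim and re-emitted by [writePhyml()], so third-party
#'   extensions (conservation status, accession numbers, ...) survive a
#'   round trip. Malformed XML raises a parse error naming the line; a
#'   tree string that fails Newick parsing raises a validation error
#'   naming the citation key and tree index.
#' @seealso [writePhyml()], [readPhyml()]
#' @export
parsePhyml <- function(xmlText) {
  doc <- xml2::read_xml(paste(xmlText, collapse = "\n"))
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "phylo_dataset")
    stop("not a Phyml file: root element is <", xml2::xml_name(root),
         ">, expected <phylo_dataset>")
  name <- xml2::xml_attr(root, "name")
  if (is.na(name)) name <- ""
  srcNodes <- xml2::xml_find_all(root, "./sources/source")
  sources <- lapply(srcNodes, .parseSource)
  evNodes <- xml2::xml_find_all(root, "./history/event")
  history <- data.frame(
    timestamp = vapply(evNodes, xml2::xml_attr, character(1), "timestamp"),
    operation = vapply(evNodes, xml2::xml_attr, character(1), "operation"),
    parameters = vapply(evNodes, xml2::xml_attr, character(1), "parameters"),
    stringsAsFactors = FALSE)
  PhyloDataset(name = name, sources = sources, history = history)
}

.childText <- function(node, tag) {
  hit <- xml2::xml_find_first(node, paste0("./", tag))
  if (inherits(hit, "xml_missing")) return(NA_character_)
  xml2::xml_text(hit)
}

.parseSource <- function(node) {
  key <- xml2::xml_attr(node, "citation_key")
  if (is.na(key) || !nzchar(key))
    stop("source without citation_key attribute")
  bibNode <- xml2::xml_find_first(node, "./bibliographic")
  if (inherits(bibNode, "xml_missing"))
    stop("source '", key, "' has no <bibliographic> block")
  bib <- .parseBibNode(bibNode, key)
  treeNodes <- xml2::xml_find_all(node, "./source_tree")
  trees <- vector("list", length(treeNodes))
  for (i in seq_along(treeNodes)) {
    st <- tryCatch(.parseSourceTree(treeNodes[[i]]), error = function(e) e)
    if (inherits(st, "error"))
      stop("invalid source tree ", i, " of source '", key, "': ",
           conditionMessage(st))
    trees[[i]] <- st
  }
  known <- c("bibliographic", "source_tree")
  kids <- xml2::xml_children(node)
  ext <- vapply(kids[!xml2::xml_name(kids) %in% known], as.character,
                character(1))
  Source(bibliographic = bib, sourceTrees = trees, citationKey = key,
         extensions = unname(ext))
}

.parseBibNode <- function(node, key) {
  yearTxt <- .childText(node, "year")
  year <- if (is.na(yearTxt)) NA_integer_ else {
    y <- suppressWarnings(as.integer(yearTxt))
    if (is.na(y)) stop("source '", key, "': year '", yearTxt,
                       "' is not an integer")
    y
  }
  authors <- vapply(xml2::xml_find_all(node, "./author"), xml2::xml_text,
                    character(1))
  extraNodes <- xml2::xml_find_all(node, "./field")
  extra <- vapply(extraNodes, xml2::xml_text, character(1))
  names(extra) <- vapply(extraNodes, xml2::xml_attr, character(1), "name")
  et <- xml2::xml_attr(node, "entry_type")
  BibRecord(key = key, entryType = if (is.na(et)) "article" else et,
            authors = authors, title = .childText(node, "title"),
            year = year, journal = .childText(node, "journal"),
            booktitle = .childText(node, "booktitle"),
            volume = .childText(node, "volume"),
            pages = .childText(node, "pages"),
            doi = .childText(node, "doi"),
            extraFields = if (length(extra)) extra else character(0))
}

.parseSourceTree <- function(node) {
  treeString <- .childText(node, "tree_string")
  if (is.na(treeString)) stop("missing <tree_string>")
  chNodes <- xml2::xml_find_all(node, "./character")
  cd <- data.frame(
    type = vapply(chNodes, xml2::xml_attr, character(1), "type"),
    name = vapply(chNodes, xml2::xml_attr, character(1), "name"),
    stringsAsFactors = FALSE)
  known <- c("tree_string", "character", "analysis_used", "fossil_status",
             "figure_ref", "page_ref", "tree_legend")
  kids <- xml2::xml_children(node)
  ext <- vapply(kids[!xml2::xml_name(kids) %in% known], as.character,
                character(1))
  SourceTree(treeString = trimws(treeString), characterData = cd,
             analysisUsed = .childText(node, "analysis_used"),
             fossilStatus = .childText(node, "fossil_status"),
             figureRef = .childText(node, "figure_ref"),
             pageRef = .childText(node, "page_ref"),
             treeLegend = .childText(node, "tree_legend"),
             extensions = unname(ext))
}

#' Write a dataset as Phyml XML
#'
#' Output is deterministic: fixed element and attribute order, fixed
#' indentation, UTF-8. Two consecutive writes of the same dataset are
#' byte-identical, and `parsePhyml(writePhyml(ds))` equals `ds` field by
#' field (see [datasetIdentical()]).
#'
#' @param ds A [PhyloDataset-class].
#' @return A single string of Phyml XML.
#' @export
writePhyml <- function(ds) {
  validObject(ds)
  L <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf("<phylo_dataset format_version=\"%s\" name=\"%s\">",
            PHYML_FORMAT_VERSION, .xmlEscape(ds@name)),
    "  <sources>",
    unlist(lapply(ds@sources, .writeSource)),
    "  </sources>",
    "  <history>",
    if (nrow(ds@history))
      sprintf("    <event timestamp=\"%s\" operation=\"%s\" parameters=\"%s\"/>",
              .xmlEscape(ds@history$timestamp),
              .xmlEscape(ds@history$operation),
              .xmlEscape(ds@history$parameters)),
    "  </history>",
    "</phylo_dataset>")
  paste0(paste(L, collapse = "\n"), "\n")
}

.optLine <- function(indent, tag, value) {
  if (is.na(value)) return(character(0))
  sprintf("%s<%s>%s</%s>", indent, tag, .xmlEscape(value), tag)
}

.writeSource <- function(s) {
  b <- s@bibliographic
  bibLines <- c(
    sprintf("      <bibliographic entry_type=\"%s\">", .xmlEscape(b@entryType)),
    if (length(b@authors))
      sprintf("        <author>%s</author>", .xmlEscape(b@authors)),
    .optLine("        ", "title", b@title),
    if (!is.na(b@year)) sprintf("        <year>%d</year>", b@year),
    .optLine("        ", "journal", b@journal),
    .optLine("        ", "booktitle", b@booktitle),
    .optLine("        ", "volume", b@volume),
    .optLine("        ", "pages", b@pages),
    .optLine("        ", "doi", b@doi),
    if (length(b@extraFields))
      sprintf("        <field name=\"%s\">%s</field>",
              .xmlEscape(names(b@extraFields)), .xmlEscape(b@extraFields)),
    "      </bibliographic>")
  treeLines <- unlist(lapply(s@sourceTrees, .writeSourceTree))
  extLines <- if (length(s@extensions)) paste0("      ", s@extensions)
  c(sprintf("    <source citation_key=\"%s\">", .xmlEscape(s@citationKey)),
    bibLines, treeLines, extLines,
    "    </source>")
}

.writeSourceTree <- function(st) {
  c("      <source_tree>",
    sprintf("        <tree_string>%s</tree_string>", .xmlEscape(st@treeString)),
    if (nrow(st@characterData))
      sprintf("        <character type=\"%s\" name=\"%s\"/>",
              .xmlEscape(st@characterData$type),
              .xmlEscape(st@characterData$name)),
    .optLine("        ", "analysis_used", st@analysisUsed),
    .optLine("        ", "fossil_status", st@fossilStatus),
    .optLine("        ", "figure_ref", st@figureRef),
    .optLine("        ", "page_ref", st@pageRef),
    .optLine("        ", "tree_legend", st@treeLegend),
    if (length(st@extensions)) paste0("        ", st@extensions),
    "      </source_tree>")
}

#' Read or write a Phyml file on disk
#'
#' @param path File path.
#' @return `readPhyml` returns a [PhyloDataset-class]; `savePhyml`
#'   invisibly returns `path`.
#' @export
readPhyml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  parsePhyml(paste(readLines(path, warn = FALSE), collapse = "\n"))
}

#' @param ds A [PhyloDataset-class].
#' @rdname readPhyml
#' @export
savePhyml <- function(ds, path) {
  writeLines(sub("\n$", "", writePhyml(ds)), path, useBytes = TRUE)
  invisible(path)
}

#' Export all trees of a dataset as a Newick treefile
#'
#' One tree per line, in source order then tree order — the companion
#' treefile that downstream parsimony programs read alongside the matrix.
#'
#' @param ds A [PhyloDataset-class].
#' @return A single string (possibly empty) of newline-separated Newick
#'   trees.
#' @export
exportTrees <- function(ds) {
  trees <- sourceTrees(ds)
  if (length(trees) == 0L) return("")
  lines <- vapply(trees, function(st) writeNewick(parseNewick(st@treeString)),
                  character(1))
  paste0(paste(lines, collapse = "\n"), "\n")
}
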